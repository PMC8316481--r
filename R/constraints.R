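#' Supported model identifiers
#'
#' The eight maximum-entropy models implemented by the package:
#' `"ubcm"` (undirected binary configuration model, degree sequence),
#' `"dbcm"` (directed binary, out-/in-degrees), `"bicm"` (bipartite binary,
#' per-layer degrees), `"uecm"` (undirected enhanced, degrees + integer
#' strengths), `"decm"` (directed enhanced), `"crem_und"` / `"crem_dir"`
#' (conditional reconstruction with continuous weights given edge marginals),
#' and `"dcgm"` (one-parameter degree-corrected gravity model).
#'
#' @return character vector of model ids.
#' @export
model_ids <- function() {
  c("ubcm", "dbcm", "bicm", "uecm", "decm", "crem_und", "crem_dir", "dcgm")
}

check_model <- function(model) {
  model <- tolower(model)
  if (!model %in% model_ids()) {
    stop("unknown model id '", model, "'; see model_ids()", call. = FALSE)
  }
  model
}

#' Extract the sufficient statistics of a model from a graph
#'
#' Builds the constraint set (degree and/or strength sequences plus the link
#' and weight totals) that the chosen model fixes on average. The returned
#' object is what the solvers and analytic functions consume; it can also be
#' built directly from vectors via [constraint_set()].
#'
#' @param g a `maxent_graph`.
#' @param model a model id, see [model_ids()].
#' @return an object of class `constraint_set`.
#' @export
constraints <- function(g, model) {
  model <- check_model(model)
  stopifnot(inherits(g, "maxent_graph"))
  switch(model,
    ubcm = constraint_set("ubcm", k = degrees(g)),
    dbcm = {
      d <- directed_degrees(g)
      constraint_set("dbcm", k_out = d$out, k_in = d$`in`)
    },
    bicm = {
      d <- bipartite_degrees(g)
      constraint_set("bicm", k_bottom = d$bottom, d_top = d$top)
    },
    uecm = constraint_set("uecm", k = degrees(binarize(g)), s = strengths(g)),
    decm = {
      d <- directed_degrees(binarize(g)); s <- strengths(g)
      constraint_set("decm", k_out = d$out, k_in = d$`in`,
                     s_out = s$out, s_in = s$`in`)
    },
    crem_und = constraint_set("crem_und", s = strengths(g)),
    crem_dir = {
      s <- strengths(g)
      constraint_set("crem_dir", s_out = s$out, s_in = s$`in`)
    },
    dcgm = constraint_set("dcgm", s = strengths(g),
                          L = sum(binarize(g)$mat) / 2)
  )
}

#' @rdname constraints
#' @param k,k_out,k_in,k_bottom,d_top,s,s_out,s_in constraint vectors as
#'   required by the model (non-negative; degrees integer).
#' @param L observed link count (required for `"dcgm"`, derived otherwise).
#' @export
constraint_set <- function(model, k = NULL, k_out = NULL, k_in = NULL,
                           k_bottom = NULL, d_top = NULL,
                           s = NULL, s_out = NULL, s_in = NULL, L = NULL) {
  model <- check_model(model)
  cs <- switch(model,
    ubcm = {
      stopifnot(!is.null(k), all(k >= 0), all(k == round(k)))
      if (sum(k) %% 2 != 0) stop("degree sum must be even", call. = FALSE)
      list(kind = "degrees", k = as.numeric(k), L = sum(k) / 2, n = length(k))
    },
    dbcm = {
      stopifnot(!is.null(k_out), !is.null(k_in),
                length(k_out) == length(k_in),
                all(k_out >= 0), all(k_in >= 0))
      if (sum(k_out) != sum(k_in)) {
        stop("sum(k_out) must equal sum(k_in)", call. = FALSE)
      }
      list(kind = "in-out-degrees", k_out = as.numeric(k_out),
           k_in = as.numeric(k_in), L = sum(k_out), n = length(k_out))
    },
    bicm = {
      stopifnot(!is.null(k_bottom), !is.null(d_top),
                all(k_bottom >= 0), all(d_top >= 0))
      if (sum(k_bottom) != sum(d_top)) {
        stop("layer degree sums must agree", call. = FALSE)
      }
      list(kind = "bipartite-degrees", k_bottom = as.numeric(k_bottom),
           d_top = as.numeric(d_top), L = sum(k_bottom),
           n_bottom = length(k_bottom), n_top = length(d_top))
    },
    uecm = {
      stopifnot(!is.null(k), !is.null(s), length(k) == length(s),
                all(k >= 0), all(s >= 0), all(s >= k))
      if (any(xor(k == 0, s == 0))) {
        stop("degrees and strengths must vanish together", call. = FALSE)
      }
      list(kind = "degrees+strengths", k = as.numeric(k), s = as.numeric(s),
           L = sum(k) / 2, W = sum(s) / 2, n = length(k))
    },
    decm = {
      stopifnot(!is.null(k_out), !is.null(k_in), !is.null(s_out),
                !is.null(s_in), all(k_out >= 0), all(k_in >= 0),
                all(s_out >= k_out), all(s_in >= k_in))
      if (any(xor(k_out == 0, s_out == 0)) || any(xor(k_in == 0, s_in == 0))) {
        stop("degrees and strengths must vanish together", call. = FALSE)
      }
      list(kind = "in-out-degrees+strengths", k_out = as.numeric(k_out),
           k_in = as.numeric(k_in), s_out = as.numeric(s_out),
           s_in = as.numeric(s_in), L = sum(k_out), W = sum(s_out),
           n = length(k_out))
    },
    crem_und = {
      stopifnot(!is.null(s), all(s >= 0))
      list(kind = "strengths", s = as.numeric(s), W = sum(s) / 2,
           n = length(s))
    },
    crem_dir = {
      stopifnot(!is.null(s_out), !is.null(s_in),
                length(s_out) == length(s_in),
                all(s_out >= 0), all(s_in >= 0))
      list(kind = "in-out-strengths", s_out = as.numeric(s_out),
           s_in = as.numeric(s_in), W = sum(s_out), n = length(s_out))
    },
    dcgm = {
      stopifnot(!is.null(s), all(s >= 0), !is.null(L))
      list(kind = "strengths", s = as.numeric(s), L = as.numeric(L),
           W = sum(s) / 2, n = length(s))
    }
  )
  cs$model <- model
  structure(cs, class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  n <- if (x$model == "bicm") paste0(x$n_bottom, "+", x$n_top) else x$n
  cat(sprintf("<constraint_set> model %s (%s), %s nodes\n",
              x$model, x$kind, n))
  invisible(x)
}

# Length and block layout of the multiplier vector for a model.
param_layout <- function(model, observed) {
  switch(model,
    ubcm = list(blocks = c(theta = observed$n)),
    dbcm = list(blocks = c(alpha = observed$n, beta = observed$n)),
    bicm = list(blocks = c(gamma = observed$n_bottom, beta = observed$n_top)),
    uecm = list(blocks = c(alpha = observed$n, beta = observed$n)),
    decm = list(blocks = c(alpha = observed$n, beta = observed$n,
                           gamma = observed$n, delta = observed$n)),
    crem_und = list(blocks = c(theta = observed$n)),
    crem_dir = list(blocks = c(alpha = observed$n, beta = observed$n)),
    dcgm = list(blocks = c(z = 1L))
  )
}

check_params <- function(model, params, observed) {
  lay <- param_layout(model, observed)
  if (length(params) != sum(lay$blocks)) {
    stop(sprintf("parameter vector for %s must have length %d (got %d)",
                 model, sum(lay$blocks), length(params)), call. = FALSE)
  }
  invisible(lay)
}

split_params <- function(model, params, observed) {
  lay <- check_params(model, params, observed)
  ends <- cumsum(lay$blocks)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- Map(function(a, b) params[a:b], starts, ends)
  names(out) <- names(lay$blocks)
  out
}
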