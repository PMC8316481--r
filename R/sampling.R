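#' Ensemble specification
#'
#' Bundles everything needed to draw graphs from a fitted canonical ensemble:
#' the model, its multipliers, the constraint set (for dimensions and, for
#' the gravity model, the strengths), the marginal matrix for the CReM, the
#' number of samples and the seed.
#'
#' @inheritParams link_probabilities
#' @param n_samples number of graphs to draw.
#' @param seed integer seed; the sample sequence is a deterministic function
#'   of the spec.
#' @return an `ensemble_spec` object.
#' @export
ensemble_spec <- function(model, params, observed, n_samples = 1L,
                          seed = 1L, marginals = NULL) {
  model <- check_model(model)
  stopifnot(n_samples >= 1L)
  structure(list(model = model, params = params, observed = observed,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 marginals = marginals),
            class = "ensemble_spec")
}

#' Sample graphs from a fitted ensemble
#'
#' Draws independent graphs from the canonical ensemble at the fitted
#' multipliers. Every pair is an independent Bernoulli trial on the link
#' probability; for the enhanced models a present link carries an integer
#' weight `1 + G` with `G` geometric (parameter `exp(-beta_i-beta_j)`, or
#' `exp(-gamma_i-delta_j)` for the directed variant), and for the CReM a
#' present link carries an exponential weight with rate `theta_i + theta_j`
#' (`alpha_i + beta_j` directed), so weights are zero exactly where links are
#' absent. One uniform variate is consumed per ordered node pair for the link
#' layer and (for weighted models) one for the weight layer, in fixed
#' row-major order, so a given spec reproduces bit-identical samples.
#'
#' @param spec an [ensemble_spec()].
#' @return list of `maxent_graph` objects of the model's kind.
#' @export
sample_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  model <- spec$model
  obs <- spec$observed
  if (model %in% c("ubcm", "dbcm", "bicm", "dcgm")) {
    sample_binary(spec)
  } else if (model %in% c("uecm", "decm")) {
    sample_enhanced(spec)
  } else {
    sample_crem(spec)
  }
}

draw_uniform <- function(nr, nc) matrix(stats::runif(nr * nc), nr, nc,
                                        byrow = TRUE)

#' @rdname sample_ensemble
#' @export
sample_binary <- function(spec) {
  model <- spec$model
  stopifnot(model %in% c("ubcm", "dbcm", "bicm", "dcgm"))
  p <- link_probabilities(model, spec$params, spec$observed)
  if (any(p < 0 | p > 1)) stop("probabilities outside [0,1]", call. = FALSE)
  set.seed(spec$seed)
  lapply(seq_len(spec$n_samples), function(r) {
    u <- draw_uniform(nrow(p), ncol(p))
    a <- (u < p) + 0
    if (model == "bicm") {
      bipartite_graph(a)
    } else if (model == "dbcm") {
      diag(a) <- 0
      binary_graph(a, directed = TRUE)
    } else {
      a[lower.tri(a, diag = TRUE)] <- 0
      binary_graph(a + t(a), directed = FALSE)
    }
  })
}

geom_extra <- function(v, u) {
  # number of weight units beyond the first: G with P(G = g) = v^g (1 - v)
  out <- floor(log(1 - u) / log(v))
  out[v == 0] <- 0
  out
}

#' @rdname sample_ensemble
#' @export
sample_enhanced <- function(spec) {
  model <- spec$model
  stopifnot(model %in% c("uecm", "decm"))
  obs <- spec$observed
  p <- link_probabilities(model, spec$params, obs)
  pr <- split_params(model, spec$params, obs)
  v <- if (model == "uecm") {
    exp(-outer(pr$beta, pr$beta, "+"))
  } else {
    exp(-outer(pr$gamma, pr$delta, "+"))
  }
  v[!is.finite(v)] <- 0
  active <- p > 0
  if (any(v[active] >= 1)) {
    stop("improper geometric parameter (>= 1) on a feasible pair",
         call. = FALSE)
  }
  set.seed(spec$seed)
  n <- nrow(p)
  lapply(seq_len(spec$n_samples), function(r) {
    u1 <- draw_uniform(n, n)
    u2 <- draw_uniform(n, n)
    a <- (u1 < p) + 0
    w <- a * (1 + geom_extra(v, u2))
    diag(w) <- 0
    if (model == "uecm") {
      w[lower.tri(w)] <- 0
      w <- w + t(w)
      weighted_graph(w, directed = FALSE, domain = "integer")
    } else {
      weighted_graph(w, directed = TRUE, domain = "integer")
    }
  })
}

#' @rdname sample_ensemble
#' @export
sample_crem <- function(spec) {
  model <- spec$model
  stopifnot(model %in% c("crem_und", "crem_dir"))
  obs <- spec$observed
  f <- as.matrix(spec$marginals)
  diag(f) <- 0
  if (any(f < 0 | f > 1)) stop("marginals outside [0,1]", call. = FALSE)
  pr <- split_params(model, spec$params, obs)
  rate <- if (model == "crem_und") {
    outer(pr$theta, pr$theta, "+")
  } else {
    outer(pr$alpha, pr$beta, "+")
  }
  if (any(f > 0 & !(rate > 0))) {
    stop("non-positive exponential rate on a feasible pair", call. = FALSE)
  }
  set.seed(spec$seed)
  n <- nrow(f)
  lapply(seq_len(spec$n_samples), function(r) {
    u1 <- draw_uniform(n, n)
    u2 <- draw_uniform(n, n)
    a <- (u1 < f) + 0
    w <- a * (-log(1 - u2) / rate)
    w[a == 0] <- 0
    diag(w) <- 0
    if (model == "crem_und") {
      w[lower.tri(w)] <- 0
      w <- w + t(w)
      weighted_graph(w, directed = FALSE, domain = "real")
    } else {
      weighted_graph(w, directed = TRUE, domain = "real")
    }
  })
}
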