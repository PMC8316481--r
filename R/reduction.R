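#' Collapse identical-constraint nodes into classes
#'
#' Nodes sharing the same constraint tuple can be assigned the same multiplier,
#' so the likelihood system collapses to one equation per *distinct* tuple
#' with a multiplicity count -- the f(k), n(k, h), g(d) class sizes. Classes
#' are keyed by exact tuple equality (no binning, also for real-valued
#' strengths) and ordered lexicographically so reduced outputs are
#' reproducible.
#'
#' The coefficient of reduction `c_r` follows each model's conventional
#' definition: the number of distinct degree values over N for `ubcm` (and
#' distinct tuples over N for `uecm`/`decm`), the number of distinct
#' out-/in-degree pairs over 2N for `dbcm`, and the distinct per-layer degree
#' counts over the total node count for `bicm`. The CReM has no reduced form
#' (its marginal matrix is pair-specific) and is rejected.
#'
#' @param observed a `constraint_set` for a reducible model
#'   (`ubcm`, `dbcm`, `bicm`, `uecm`, `decm`).
#' @return an object of class `reduced_problem`: `keys` (data frame of class
#'   constraint tuples), `mult` (class sizes), `node_to_class` (per-node class
#'   index; a two-element list for `bicm`), and `c_r`.
#' @export
reduce_constraints <- function(observed) {
  stopifnot(inherits(observed, "constraint_set"))
  model <- observed$model
  if (model %in% c("crem_und", "crem_dir", "dcgm")) {
    stop("model '", model, "' has no reduced form", call. = FALSE)
  }
  if (model == "bicm") {
    rb <- class_index(list(k = observed$k_bottom))
    rt <- class_index(list(d = observed$d_top))
    cr <- (nrow(rb$keys) + nrow(rt$keys)) /
      (observed$n_bottom + observed$n_top)
    return(structure(list(model = model, bottom = rb, top = rt,
                          keys = list(bottom = rb$keys, top = rt$keys),
                          mult = list(bottom = rb$mult, top = rt$mult),
                          node_to_class = list(bottom = rb$map, top = rt$map),
                          c_r = cr, observed = observed),
                     class = "reduced_problem"))
  }
  cols <- switch(model,
    ubcm = list(k = observed$k),
    dbcm = list(k_out = observed$k_out, k_in = observed$k_in),
    uecm = list(k = observed$k, s = observed$s),
    decm = list(k_out = observed$k_out, k_in = observed$k_in,
                s_out = observed$s_out, s_in = observed$s_in))
  r <- class_index(cols)
  denom <- switch(model, ubcm = observed$n, dbcm = 2 * observed$n,
                  uecm = observed$n, decm = observed$n)
  structure(list(model = model, keys = r$keys, mult = r$mult,
                 node_to_class = r$map, c_r = nrow(r$keys) / denom,
                 observed = observed),
            class = "reduced_problem")
}

# Lexicographic exact-equality classes over a list of constraint columns.
class_index <- function(cols) {
  key <- do.call(paste, c(lapply(cols, function(v) {
    format(v, digits = 17, trim = TRUE, scientific = TRUE)
  }), sep = "\r"))
  df <- as.data.frame(cols)
  first <- !duplicated(key)
  keys <- df[first, , drop = FALSE]
  ord <- do.call(order, as.list(keys))
  keys <- keys[ord, , drop = FALSE]
  rownames(keys) <- NULL
  ukey <- key[first][ord]
  map <- match(key, ukey)
  list(keys = keys, mult = as.vector(table(factor(map, seq_len(nrow(keys))))),
       map = map)
}

#' @export
print.reduced_problem <- function(x, ...) {
  ncls <- if (x$model == "bicm") {
    sum(vapply(x$keys, nrow, 0L))
  } else nrow(x$keys)
  cat(sprintf("<reduced_problem> model %s: %d classes, c_r = %.4g\n",
              x$model, ncls, x$c_r))
  invisible(x)
}

#' Class-level likelihood system of a reduced problem
#'
#' Returns the reduced likelihood, gradient, Hessian and fixed-point map over
#' class multipliers: class-level pair sums carry the multiplicity factors
#' f(k)[f(k') - delta_kk'] and the within-class self-term is excluded. At
#' multiplicities of one this is algebraically identical to the full system.
#'
#' @param reduced a `reduced_problem`.
#' @return a list of closures (`loglik`, `grad`, `hessian`, `hess_diag`,
#'   `fpmap`, `expected`) over the class-level parameter vector.
#' @export
reduced_system <- function(reduced) {
  stopifnot(inherits(reduced, "reduced_problem"))
  switch(reduced$model,
    ubcm = sys_ubcm(reduced$keys$k, reduced$mult),
    dbcm = sys_dbcm(reduced$keys$k_out, reduced$keys$k_in, reduced$mult),
    bicm = sys_bicm(reduced$keys$bottom$k, reduced$keys$top$d,
                    reduced$mult$bottom, reduced$mult$top),
    uecm = sys_uecm(reduced$keys$k, reduced$keys$s, reduced$mult),
    decm = sys_decm(reduced$keys$k_out, reduced$keys$k_in,
                    reduced$keys$s_out, reduced$keys$s_in, reduced$mult))
}

#' Expand a class-level solution to node-level multipliers
#'
#' Every node receives the multiplier(s) of its constraint class; the inverse
#' of the class assignment of [reduce_constraints()].
#'
#' @param reduced a `reduced_problem`.
#' @param params class-level parameter vector as returned by solving
#'   [reduced_system()].
#' @return node-level parameter vector in the model's layout.
#' @export
expand_parameters <- function(reduced, params) {
  stopifnot(inherits(reduced, "reduced_problem"))
  if (reduced$model == "bicm") {
    nb <- nrow(reduced$keys$bottom)
    nt <- nrow(reduced$keys$top)
    stopifnot(length(params) == nb + nt)
    return(c(params[1:nb][reduced$node_to_class$bottom],
             params[nb + (1:nt)][reduced$node_to_class$top]))
  }
  ncls <- nrow(reduced$keys)
  nfam <- length(params) / ncls
  stopifnot(nfam == round(nfam))
  map <- reduced$node_to_class
  unlist(lapply(seq_len(nfam), function(b) {
    params[(b - 1L) * ncls + (1:ncls)][map]
  }), use.names = FALSE)
}
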