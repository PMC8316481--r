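#' Model analytics: link probabilities, likelihood, gradient, Hessian
#'
#' Closed-form quantities of the maximum-entropy ensembles at a given
#' multiplier vector `params`. The parameter layout is flat and per model:
#' `ubcm` theta (length N); `dbcm` (alpha, beta); `bicm` (gamma over the
#' bottom layer, beta over the top layer); `uecm` (alpha, beta); `decm`
#' (alpha, beta, gamma, delta); `crem_und` theta (positive); `crem_dir`
#' (alpha, beta); `dcgm` the scalar z. Infinite entries are allowed as
#' sentinels for analytically resolved degenerate nodes (zero or saturated
#' constraints) and map to hard 0/1 link probabilities.
#'
#' @param model model id, see [model_ids()].
#' @param params numeric multiplier vector in the model's layout.
#' @param observed a `constraint_set` for the same model (defines problem
#'   dimensions and the observed constraints).
#' @param marginals edge-marginal probability matrix f (CReM models only).
#' @return `link_probabilities()`: matrix of pairwise connection
#'   probabilities in `[0,1]` (rectangular for `bicm`, zero diagonal
#'   otherwise). `log_likelihood()`: scalar (`-Inf` for inadmissible
#'   enhanced-model parameters). `gradient()`: vector matching the parameter
#'   layout, with component i equal to minus the observed constraint plus its
#'   ensemble expectation. `hessian()`: the full second-derivative matrix,
#'   equal to minus the covariance matrix of the constraints;
#'   `hessian_diagonal()` its diagonal only.
#' @export
link_probabilities <- function(model, params, observed, marginals = NULL) {
  model <- check_model(model)
  if (model == "dcgm") {
    stopifnot(length(params) == 1L, params > 0)
    zs <- params * outer(observed$s, observed$s)
    p <- zs / (1 + zs)
    diag(p) <- 0
    return(p)
  }
  check_params(model, params, observed)
  sys <- build_system(model, observed, marginals)
  if (model %in% c("uecm", "decm") && sys$improper(params)) {
    stop("improper parameters: geometric factor >= 1 for some pair",
         call. = FALSE)
  }
  p <- sys$pmat(params)
  if (model != "bicm") diag(p) <- 0
  p
}

#' @rdname link_probabilities
#' @export
log_likelihood <- function(model, params, observed, marginals = NULL) {
  model <- check_model(model)
  check_params(model, params, observed)
  build_system(model, observed, marginals)$loglik(params)
}

#' @rdname link_probabilities
#' @export
gradient <- function(model, params, observed, marginals = NULL) {
  model <- check_model(model)
  check_params(model, params, observed)
  build_system(model, observed, marginals)$grad(params)
}

#' @rdname link_probabilities
#' @export
hessian <- function(model, params, observed, marginals = NULL) {
  model <- check_model(model)
  check_params(model, params, observed)
  build_system(model, observed, marginals)$hessian(params)
}

#' @rdname link_probabilities
#' @export
hessian_diagonal <- function(model, params, observed, marginals = NULL) {
  model <- check_model(model)
  check_params(model, params, observed)
  build_system(model, observed, marginals)$hess_diag(params)
}

#' Ensemble expectations of the constraints and of pair weights
#'
#' `expected_constraints()` evaluates the canonical-ensemble expectation of
#' each constrained quantity at `params` (for the binary models the expected
#' degrees, for the enhanced models expected degrees and strengths, for the
#' CReM the expected strengths). At a likelihood maximum these equal the
#' observed constraints. `expected_weights()` returns the pairwise expected
#' weight matrix of a weighted model; its row sums reproduce the expected
#' strengths.
#'
#' @inheritParams link_probabilities
#' @return a named list of numeric vectors (one per constraint family), or a
#'   matrix for `expected_weights()`.
#' @export
expected_constraints <- function(model, params, observed, marginals = NULL) {
  model <- check_model(model)
  if (model == "dcgm") {
    p <- link_probabilities(model, params, observed)
    return(list(L = sum(p) / 2))
  }
  check_params(model, params, observed)
  ex <- build_system(model, observed, marginals)$expected(params)
  names(ex) <- switch(model,
    ubcm = "k", dbcm = c("k_out", "k_in"), bicm = c("k_bottom", "d_top"),
    uecm = c("k", "s"), decm = c("k_out", "k_in", "s_out", "s_in"),
    crem_und = "s", crem_dir = c("s_out", "s_in"))
  ex
}

#' @rdname expected_constraints
#' @export
expected_weights <- function(model, params, observed, marginals = NULL) {
  model <- check_model(model)
  if (!model %in% c("uecm", "decm", "crem_und", "crem_dir")) {
    stop("expected_weights() is defined for weighted models only",
         call. = FALSE)
  }
  check_params(model, params, observed)
  w <- build_system(model, observed, marginals)$wmat(params)
  diag(w) <- 0
  w
}

#' One application of the fixed-point map
#'
#' The stationarity conditions of each model can be rearranged as
#' `theta = G(theta)`; iterating G is the fixed-point solver. This function
#' applies G once. It requires strictly positive observed constraints
#' (degenerate nodes must be resolved beforehand, see [solve_model()]).
#'
#' @inheritParams link_probabilities
#' @return updated parameter vector in the same layout.
#' @export
fixed_point_map <- function(model, params, observed, marginals = NULL) {
  model <- check_model(model)
  check_params(model, params, observed)
  build_system(model, observed, marginals)$fpmap(params)
}

#' Initial multiplier values
#'
#' Three initialization schemes: `"sparse"` uses the closed-form sparse-limit
#' solution (degrees scaled by the square root of twice the link count, or of
#' the link count for directed/bipartite models; strengths scaled by the
#' analogous weight totals); `"sqrtN"` replaces the denominator by the square
#' root of the node count; `"uniform"` draws every entry from U(0,1) and
#' requires a seed. CReM initial values are floored at 1e-8 so that the
#' positivity constraint on theta holds from the first iterate.
#'
#' @inheritParams link_probabilities
#' @param scheme one of `"sparse"`, `"sqrtN"`, `"uniform"`.
#' @param seed integer seed, mandatory for `"uniform"`.
#' @return parameter vector in the model's layout.
#' @export
initial_parameters <- function(model, observed,
                               scheme = c("sparse", "sqrtN", "uniform"),
                               seed = NULL) {
  model <- check_model(model)
  scheme <- match.arg(scheme)
  lay <- param_layout(model, observed)
  npar <- sum(lay$blocks)
  if (scheme == "uniform") {
    if (is.null(seed)) stop("uniform initialization requires a seed",
                            call. = FALSE)
    set.seed(as.integer(seed))
    init <- stats::runif(npar)
    if (model %in% c("crem_und", "crem_dir")) init <- pmax(init, 1e-8)
    return(init)
  }
  ilog <- function(v, denom) {
    if (any(v <= 0)) {
      stop("zero constraint: degenerate node must be resolved before ",
           "initialization", call. = FALSE)
    }
    -log(v / denom)
  }
  init <- switch(model,
    ubcm = ilog(observed$k,
                if (scheme == "sparse") sqrt(2 * observed$L)
                else sqrt(observed$n)),
    dbcm = {
      d <- if (scheme == "sparse") sqrt(observed$L) else sqrt(observed$n)
      c(ilog(observed$k_out, d), ilog(observed$k_in, d))
    },
    bicm = {
      d <- if (scheme == "sparse") sqrt(observed$L)
           else sqrt(observed$n_bottom + observed$n_top)
      c(ilog(observed$k_bottom, d), ilog(observed$d_top, d))
    },
    uecm = {
      dk <- if (scheme == "sparse") sqrt(2 * observed$L) else sqrt(observed$n)
      ds <- if (scheme == "sparse") sqrt(2 * observed$W) else sqrt(observed$n)
      c(ilog(observed$k, dk), ilog(observed$s, ds))
    },
    decm = {
      dk <- if (scheme == "sparse") sqrt(observed$L) else sqrt(observed$n)
      ds <- if (scheme == "sparse") sqrt(observed$W) else sqrt(observed$n)
      c(ilog(observed$k_out, dk), ilog(observed$k_in, dk),
        ilog(observed$s_out, ds), ilog(observed$s_in, ds))
    },
    crem_und = pmax(ilog(observed$s,
                         if (scheme == "sparse") sqrt(2 * observed$W)
                         else sqrt(observed$n)), 1e-8),
    crem_dir = {
      d <- if (scheme == "sparse") sqrt(observed$W) else sqrt(observed$n)
      pmax(c(ilog(observed$s_out, d), ilog(observed$s_in, d)), 1e-8)
    },
    dcgm = stop("dcgm has no multiplier vector; use dcgm_solve_z()",
                call. = FALSE)
  )
  init
}

#' Calibrate the degree-corrected gravity model
#'
#' Solves for the single parameter z of the gravity-model link probability
#' `p_ij = z s_i s_j / (1 + z s_i s_j)` so that the expected link count
#' matches a target `L_star`. The expected link count is strictly increasing
#' in z, so the root is unique; it is bracketed by bisection and polished by
#' Newton iterations.
#'
#' @param s vector of strictly positive node strengths (or fitnesses).
#' @param L_star target number of undirected links, in
#'   `(0, N(N-1)/2)`.
#' @param tol absolute tolerance on the reproduced link count.
#' @return a list with `z`, the link-probability matrix `p`, the reproduced
#'   `expected_links`, and the iteration count.
#' @export
dcgm_solve_z <- function(s, L_star, tol = 1e-10) {
  stopifnot(all(s > 0), length(s) >= 2L)
  n <- length(s)
  if (L_star <= 0 || L_star >= n * (n - 1) / 2) {
    stop("L_star must lie strictly between 0 and N(N-1)/2", call. = FALSE)
  }
  ss <- outer(s, s)
  diag(ss) <- 0
  exp_links <- function(z) sum(z * ss / (1 + z * ss)) / 2
  dexp_links <- function(z) sum(ss / (1 + z * ss)^2) / 2
  lo <- 1e-16; hi <- 1
  while (exp_links(hi) < L_star) hi <- hi * 10
  while (exp_links(lo) > L_star) lo <- lo / 10
  it <- 0L
  while (hi / lo > 1.0001 && it < 2000L) {
    mid <- sqrt(lo * hi)
    if (exp_links(mid) < L_star) lo <- mid else hi <- mid
    it <- it + 1L
  }
  z <- sqrt(lo * hi)
  repeat {
    fz <- exp_links(z) - L_star
    if (abs(fz) <= tol || it >= 2100L) break
    z_new <- z - fz / dexp_links(z)
    if (!is.finite(z_new) || z_new <= 0) z_new <- z / 2
    z <- z_new
    it <- it + 1L
  }
  p <- z * ss / (1 + z * ss)
  diag(p) <- 0
  list(z = z, p = p, expected_links = exp_links(z), iterations = it)
}
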