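#' Accuracy metrics for fitted constraints
#'
#' `made()` is the maximum absolute error between observed and expected
#' constraints (the infinity norm of the difference); `mase()` is the same
#' score evaluated on strengths. `mrde()` and `mrse()` are the corresponding
#' maximum *relative* errors, undefined where an observed constraint is zero
#' (degenerate nodes are resolved and excluded upstream). Directed and
#' bipartite variants take the maximum over both constraint families: pass
#' lists of vectors and they are concatenated.
#'
#' @param observed,expected numeric vectors (or lists of vectors) of equal
#'   total length.
#' @return a non-negative scalar; zero iff the vectors agree exactly.
#' @export
made <- function(observed, expected) {
  o <- unlist(observed, use.names = FALSE)
  e <- unlist(expected, use.names = FALSE)
  if (length(o) != length(e)) stop("length mismatch", call. = FALSE)
  max(abs(o - e))
}

#' @rdname made
#' @export
mase <- made

#' @rdname made
#' @export
mrde <- function(observed, expected) {
  o <- unlist(observed, use.names = FALSE)
  e <- unlist(expected, use.names = FALSE)
  if (length(o) != length(e)) stop("length mismatch", call. = FALSE)
  if (any(o == 0)) {
    stop("relative error undefined for zero observed constraints",
         call. = FALSE)
  }
  max(abs(o - e) / abs(o))
}

#' @rdname made
#' @export
mrse <- mrde

#' Coefficient of variation of a degree distribution
#'
#' Population standard deviation over mean; a rule-of-thumb predictor of how
#' reducible a configuration-model system is (the broader the distribution,
#' the more distinct constraint classes survive).
#'
#' @param x numeric vector with positive mean.
#' @return non-negative scalar.
#' @export
coefficient_of_variation <- function(x) {
  stopifnot(length(x) >= 1L)
  m <- mean(x)
  if (m == 0) stop("zero mean", call. = FALSE)
  sqrt(mean((x - m)^2)) / m
}

#' Brute-force enumeration of a small binary ensemble
#'
#' Enumerates every graph of a binary model on a handful of nodes and sums
#' exactly: the partition function, all graph probabilities, the expected
#' constraints and their covariance matrix. This is the package's independent
#' ground truth: the graph probability factorizes over pairs, so the summed
#' quantities must match the closed-form link probabilities, expectations and
#' (minus) the likelihood Hessian to machine precision.
#'
#' @inheritParams link_probabilities
#' @param max_states safety cap on the number of enumerated graphs.
#' @return a list with `Z` (partition function), `probs`, `expected`
#'   (constraint expectations in the parameter layout) and `cov` (constraint
#'   covariance matrix).
#' @export
enumerate_ensemble <- function(model, params, observed, max_states = 2^20) {
  model <- check_model(model)
  if (!model %in% c("ubcm", "dbcm", "bicm")) {
    stop("enumeration oracle supports the binary models only", call. = FALSE)
  }
  if (model == "ubcm") {
    n <- observed$n
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    cvec <- function(a) as.vector(rowSums(a))
    ham <- function(cv) sum(params * cv)
  } else if (model == "dbcm") {
    n <- observed$n
    pairs <- which(diag(n) == 0, arr.ind = TRUE)
    cvec <- function(a) c(rowSums(a), colSums(a))
    ham <- function(cv) sum(params * cv)
  } else {
    nb <- observed$n_bottom; nt <- observed$n_top
    pairs <- as.matrix(expand.grid(row = 1:nb, col = 1:nt))
    cvec <- function(a) c(rowSums(a), colSums(a))
    ham <- function(cv) sum(params * cv)
  }
  m <- nrow(pairs)
  if (2^m > max_states) stop("too many states to enumerate", call. = FALSE)
  nr <- if (model == "bicm") observed$n_bottom else observed$n
  nc <- if (model == "bicm") observed$n_top else observed$n
  nstate <- 2^m
  weights <- numeric(nstate)
  cmat <- matrix(0, nstate, length(params))
  for (g in seq_len(nstate)) {
    bits <- as.integer(intToBits(g - 1L))[seq_len(m)]
    a <- matrix(0, nr, nc)
    a[pairs] <- bits
    if (model == "ubcm") a <- a + t(a)
    cv <- cvec(a)
    cmat[g, ] <- cv
    weights[g] <- exp(-ham(cv))
  }
  Z <- sum(weights)
  probs <- weights / Z
  expected <- as.vector(crossprod(cmat, probs))
  second <- crossprod(cmat, cmat * probs)
  covc <- second - tcrossprod(expected)
  list(Z = Z, probs = probs, expected = expected, cov = covc)
}

#' Compare ensemble samples with their analytic expectations
#'
#' For each constrained quantity, compares the empirical mean over a set of
#' sampled graphs to its analytic ensemble expectation, normalized by the
#' analytic standard error of the mean (the per-constraint variances come in
#' closed form from the fluctuation-response identity: they are minus the
#' likelihood Hessian diagonal). Constraints with zero variance (degenerate,
#' analytically fixed nodes) get an `NA` z-score.
#'
#' @param samples list of `maxent_graph` objects from [sample_ensemble()].
#' @inheritParams link_probabilities
#' @return data frame with one row per constraint: family, expected value,
#'   empirical mean, analytic standard error of the mean, and z-score.
#' @export
validate_ensemble <- function(samples, model, params, observed,
                              marginals = NULL) {
  model <- check_model(model)
  stopifnot(length(samples) >= 2L)
  ex <- expected_constraints(model, params, observed, marginals)
  fam <- names(ex)
  emp <- lapply(samples, function(g) {
    cs <- constraints(g, model)
    unlist(cs[fam], use.names = FALSE)
  })
  emp <- do.call(rbind, emp)
  mu <- colMeans(emp)
  vars <- constraint_variances(model, params, observed, marginals)
  vars[vars < 0] <- 0
  se <- sqrt(vars / length(samples))
  exv <- unlist(ex, use.names = FALSE)
  z <- ifelse(se > 0, (mu - exv) / se, NA_real_)
  data.frame(family = rep(fam, times = lengths(ex)),
             expected = exv, mean = mu, se = se, z = z)
}

# Sampling variances of the constraints. For the proper ERGMs these follow
# from fluctuation-response (minus the Hessian diagonal); the CReM objective
# is a conditional likelihood, so its strength variances are assembled from
# the Bernoulli-exponential pair law directly, and the gravity model fixes a
# single scalar constraint (the link count).
constraint_variances <- function(model, params, observed, marginals = NULL) {
  if (model == "dcgm") {
    p <- link_probabilities(model, params, observed)
    return(sum(p * (1 - p)) / 2)
  }
  if (model %in% c("crem_und", "crem_dir")) {
    f <- as.matrix(marginals)
    diag(f) <- 0
    pr <- split_params(model, params, observed)
    rate <- if (model == "crem_und") outer(pr$theta, pr$theta, "+")
            else outer(pr$alpha, pr$beta, "+")
    v <- (2 * f - f^2) / rate^2
    v[f == 0] <- 0
    if (model == "crem_und") return(rowSums(v))
    return(c(rowSums(v), colSums(v)))
  }
  -hessian_diagonal(model, params, observed, marginals)
}

#' Fit report: accuracy and convergence summary
#'
#' Summarizes a solver result against the observed constraints: per-family
#' maximum absolute and relative errors (relative errors are computed over
#' the non-degenerate nodes only), the reduction coefficient, the coefficient
#' of variation of the degree (or strength) distribution, and the
#' convergence record.
#'
#' @param fit a `solver_result` from [solve_model()].
#' @param observed the `constraint_set` that was fitted.
#' @inheritParams link_probabilities
#' @return an object of class `fit_report` (a list; see Details).
#' @export
fit_report <- function(fit, observed, marginals = NULL) {
  stopifnot(inherits(fit, "solver_result"))
  model <- fit$model
  ex <- fitted_values(fit, observed, marginals)$expected
  fam <- names(ex)
  obs <- observed[fam]
  abs_err <- Map(function(o, e) abs(o - e), obs, ex)
  nz <- lapply(obs, function(o) o > 0)
  rel_err <- Map(function(a, o, keep) a[keep] / o[keep], abs_err, obs, nz)
  deg_fams <- intersect(fam, c("k", "k_out", "k_in", "k_bottom", "d_top"))
  str_fams <- intersect(fam, c("s", "s_out", "s_in"))
  mx <- function(x) if (length(unlist(x))) max(unlist(x)) else NA_real_
  out <- list(
    model = model,
    made = mx(abs_err[deg_fams]),
    mase = mx(abs_err[str_fams]),
    mrde = mx(rel_err[deg_fams]),
    mrse = mx(rel_err[str_fams]),
    abs_err = abs_err, rel_err = rel_err,
    n_degenerate = sum(!unlist(nz)),
    c_r = fit$c_r,
    c_v = coefficient_of_variation(unlist(obs[if (length(deg_fams))
                                               deg_fams else fam])),
    converged_by = fit$converged_by,
    iterations = fit$iterations,
    final_grad_norm = fit$final_grad_norm)
  structure(out, class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %s: %s after %d iterations (||grad|| = %.3g)\n",
              x$model, x$converged_by, x$iterations, x$final_grad_norm))
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.3g", v)
  cat(sprintf("  MADE %s  MASE %s  MRDE %s  MRSE %s\n",
              fmt(x$made), fmt(x$mase), fmt(x$mrde), fmt(x$mrse)))
  cat(sprintf("  c_r %s  c_v %.3g  degenerate nodes %d\n",
              fmt(x$c_r), x$c_v, x$n_degenerate))
  invisible(x)
}
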