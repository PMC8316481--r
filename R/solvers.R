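#' Solver configuration
#'
#' Collects the numerical settings of [solve_model()]. Defaults left `NULL`
#' are resolved per model: gradient/step tolerances 1e-8 and an iteration cap
#' of 1000 for `ubcm`, 1e-10 and 1000 for `bicm`, and 1e-8 with a cap of
#' 10000 for the remaining models. The Armijo backtracking parameters must
#' satisfy `gamma` in (0, 0.5] and `beta` in (0, 1); the conservative
#' defaults are `gamma = 1e-4`, `beta = 0.5`.
#'
#' @param method `"newton"` (full-Hessian step), `"quasinewton"` (diagonal
#'   Hessian), `"fixedpoint"` (plain iteration of the consistency map, no
#'   line search), or `"coupled"` (fixed-point run followed by quasi-Newton
#'   refinement).
#' @param tol_grad stop when the Euclidean norm of the gradient drops to
#'   this value.
#' @param tol_step stop when the Euclidean norm of the parameter update
#'   drops to this value.
#' @param max_iter iteration cap.
#' @param armijo_gamma,armijo_beta line-search parameters.
#' @param init initialization scheme, see [initial_parameters()].
#' @param seed seed for the `"uniform"` scheme.
#' @param use_reduction collapse identical-constraint nodes before solving
#'   (automatic for reducible models on non-degenerate inputs).
#' @param rescale_kappa optional positive rescaling factor for the CReM
#'   strengths (the solution is mapped back exactly, see
#'   [crem_rescaled_solve()]).
#' @param relax optional relaxation factor in `[0, 1)` mixing the previous
#'   iterate into the fixed-point update; 0 (off) reproduces the plain map.
#' @param trace record per-iteration likelihood, gradient norm and step size.
#' @return a `solver_config` list.
#' @export
solver_config <- function(method = c("newton", "quasinewton", "fixedpoint",
                                     "coupled"),
                          tol_grad = NULL, tol_step = NULL, max_iter = NULL,
                          armijo_gamma = 1e-4, armijo_beta = 0.5,
                          init = c("sparse", "sqrtN", "uniform"), seed = NULL,
                          use_reduction = TRUE, rescale_kappa = NULL,
                          relax = 0, trace = FALSE) {
  method <- match.arg(method)
  init <- match.arg(init)
  stopifnot(armijo_gamma > 0, armijo_gamma <= 0.5,
            armijo_beta > 0, armijo_beta < 1,
            relax >= 0, relax < 1)
  if (!is.null(rescale_kappa)) stopifnot(rescale_kappa > 0)
  structure(list(method = method, tol_grad = tol_grad, tol_step = tol_step,
                 max_iter = max_iter, armijo_gamma = armijo_gamma,
                 armijo_beta = armijo_beta, init = init, seed = seed,
                 use_reduction = use_reduction,
                 rescale_kappa = rescale_kappa, relax = relax,
                 trace = trace),
            class = "solver_config")
}

model_defaults <- function(model, cfg) {
  tg <- if (model == "bicm") 1e-10 else 1e-8
  mi <- if (model %in% c("ubcm", "bicm")) 1000L else 10000L
  if (is.null(cfg$tol_grad)) cfg$tol_grad <- tg
  if (is.null(cfg$tol_step)) cfg$tol_step <- tg
  if (is.null(cfg$max_iter)) cfg$max_iter <- mi
  cfg
}

#' Regularized Newton and quasi-Newton step directions
#'
#' `newton_step()` solves `(H + dH) step = -grad` where `dH` is the smallest
#' uniform shift making the Hessian safely negative definite (eigenvalue
#' clip at `-eps`, `eps = 1e-10 (1 + max|H|)`), so the returned direction is
#' always an ascent direction for the likelihood. If the shifted system is
#' still numerically singular a pseudo-inverse solve is used with a warning.
#' `quasi_newton_step()` does the same with the Hessian diagonal only:
#' entries are clipped to at most `-eps` and the step is the component-wise
#' quotient.
#'
#' @param grad gradient vector at the current iterate.
#' @param hess full Hessian matrix (symmetric, negative semidefinite up to
#'   rounding).
#' @param hess_diag Hessian diagonal vector.
#' @return the step direction vector.
#' @export
newton_step <- function(grad, hess) {
  hess <- (hess + t(hess)) / 2
  eps <- 1e-10 * (1 + max(abs(hess)))
  lam_max <- max(eigen(hess, symmetric = TRUE, only.values = TRUE)$values)
  shift <- if (lam_max > -eps) lam_max + eps else 0
  H <- hess - diag(shift, nrow(hess))
  step <- tryCatch(solve(H, -grad), error = function(e) NULL)
  if (is.null(step) || !all(is.finite(step))) {
    warning("singular regularized Hessian; falling back to pseudo-inverse")
    sv <- svd(H)
    dinv <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
    step <- sv$v %*% (dinv * crossprod(sv$u, -grad))
    step <- as.vector(step)
  }
  step
}

#' @rdname newton_step
#' @export
quasi_newton_step <- function(grad, hess_diag) {
  eps <- 1e-10 * (1 + max(abs(hess_diag)))
  -grad / pmin(hess_diag, -eps)
}

#' Armijo backtracking line search
#'
#' Starting from a unit step, the step size is shrunk geometrically
#' (`alpha <- beta * alpha`) until the sufficient-increase condition
#' `L(theta + alpha step) >= L(theta) + gamma alpha grad' step` holds, which
#' guarantees a strict likelihood increase for an ascent direction. An
#' objective value of `-Inf` (inadmissible parameters of the enhanced
#' models) simply fails the condition and shrinks the step further.
#'
#' @param objective function of the parameter vector returning the
#'   log-likelihood.
#' @param theta current iterate.
#' @param step ascent direction.
#' @param slope directional derivative `grad' step` (must be positive).
#' @param gamma,beta Armijo parameters, `gamma` in (0, 0.5], `beta` in (0,1).
#' @param noise_alpha step size taken once the predicted increase falls below
#'   the floating-point resolution of the objective (sufficient increase can
#'   no longer be measured): 1 for Newton, whose unit step is the
#'   asymptotically exact one; 0.5 for the diagonal quasi-Newton step, whose
#'   undamped Jacobi-type iteration has a non-contracting mode on the
#'   conditional models.
#' @return the accepted step size `alpha`.
#' @export
armijo_backtracking <- function(objective, theta, step, slope,
                                gamma = 1e-4, beta = 0.5, noise_alpha = 1) {
  if (!is.finite(slope) || slope <= 0) {
    stop("line search requires an ascent direction (positive slope)",
         call. = FALSE)
  }
  f0 <- objective(theta)
  # At convergence the predicted increase drops below the floating-point
  # resolution of the objective and the sufficient-increase test compares
  # rounding noise; take the method's asymptotic step instead.
  if (slope <= 1e-12 * (1 + abs(f0)) &&
      is.finite(objective(theta + noise_alpha * step))) {
    return(noise_alpha)
  }
  alpha <- 1
  repeat {
    f1 <- objective(theta + alpha * step)
    if (is.finite(f1) && f1 >= f0 + gamma * alpha * slope) return(alpha)
    alpha <- beta * alpha
    if (alpha < 1e-14) {
      stop("line search failure: step underflow (non-ascent direction or ",
           "numerical breakdown)", call. = FALSE)
    }
  }
}

# ---------------------------------------------------------------------------
# Degenerate-node pre-resolution. Multipliers of nodes with zero (or, for the
# undirected binary models, saturated) constraints diverge; such nodes are
# resolved analytically (+Inf multiplier -> probability-0 row, -Inf ->
# probability-1 row with the neighbours' residual constraints decremented)
# and excluded from the numerical system.

prepare_problem <- function(model, observed, marginals = NULL, cfg) {
  switch(model,
    ubcm = prep_ubcm(observed, cfg),
    dbcm = prep_dbcm(observed, cfg),
    bicm = prep_bicm(observed, cfg),
    uecm = prep_uecm(observed, cfg),
    decm = prep_decm(observed, cfg),
    crem_und = prep_crem_und(observed, marginals),
    crem_dir = prep_crem_dir(observed, marginals))
}

prep_ubcm <- function(observed, cfg) {
  k <- observed$k
  n <- length(k)
  fixed <- rep(NA_real_, n)   # NA = active, +Inf isolate, -Inf saturated hub
  fixed_p <- matrix(NA_real_, n, n)  # analytically resolved pair entries
  diag(fixed_p) <- 0
  kk <- k
  repeat {
    act <- is.na(fixed)
    na <- sum(act)
    iso <- act & kk == 0
    if (any(iso)) {
      others <- act & !iso
      fixed_p[iso, others] <- 0; fixed_p[others, iso] <- 0
      fixed_p[iso, iso] <- 0; diag(fixed_p) <- 0
      fixed[iso] <- Inf
      next
    }
    sat <- act & kk == na - 1 & na > 1
    if (any(sat)) {
      i <- which(sat)[1L]
      others <- which(act & seq_len(n) != i)
      fixed_p[i, others] <- 1; fixed_p[others, i] <- 1
      fixed[i] <- -Inf
      kk[is.na(fixed) & seq_len(n) != i] <-
        kk[is.na(fixed) & seq_len(n) != i] - 1
      kk[i] <- 0
      next
    }
    break
  }
  if (all(is.na(fixed))) fixed_p <- NULL
  act <- which(is.na(fixed))
  k_res <- kk[act]
  red <- NULL
  if (length(act) > 0L && cfg$use_reduction) {
    red <- reduce_constraints(constraint_set("ubcm", k = k_res))
    sys <- reduced_system(red)
  } else if (length(act) > 0L) {
    sys <- sys_ubcm(k_res)
  } else sys <- NULL
  list(model = "ubcm", sys = sys, red = red, n_active = length(act),
       fixed_p = fixed_p,
       c_r = if (is.null(red)) NA_real_ else red$c_r,
       cls_obs = if (is.null(red)) list(k = k_res)
                 else list(k = red$keys$k),
       totals = list(L = sum(k_res) / 2, n = length(act)),
       expand = function(th_cls) {
         out <- fixed
         if (!is.null(sys)) {
           th_nodes <- if (is.null(red)) th_cls
                       else expand_parameters(red, th_cls)
           out[act] <- th_nodes
         }
         out
       })
}

prep_bicm <- function(observed, cfg) {
  kb <- observed$k_bottom; dt <- observed$d_top
  nb <- length(kb); nt <- length(dt)
  fb <- rep(NA_real_, nb); ft <- rep(NA_real_, nt)
  fixed_p <- matrix(NA_real_, nb, nt)
  repeat {
    ab <- is.na(fb); at <- is.na(ft)
    zb <- ab & kb == 0
    if (any(zb)) { fixed_p[zb, at] <- 0; fb[zb] <- Inf; next }
    zt <- at & dt == 0
    if (any(zt)) { fixed_p[ab, zt] <- 0; ft[zt] <- Inf; next }
    satb <- ab & kb == sum(at) & sum(at) > 0
    if (any(satb)) {
      i <- which(satb)[1L]
      fixed_p[i, at] <- 1
      fb[i] <- -Inf
      dt[is.na(ft)] <- dt[is.na(ft)] - 1
      kb[i] <- 0
      next
    }
    satt <- at & dt == sum(ab) & sum(ab) > 0
    if (any(satt)) {
      j <- which(satt)[1L]
      fixed_p[ab, j] <- 1
      ft[j] <- -Inf
      kb[is.na(fb)] <- kb[is.na(fb)] - 1
      dt[j] <- 0
      next
    }
    break
  }
  if (all(is.na(fb)) && all(is.na(ft))) fixed_p <- NULL
  actb <- which(is.na(fb)); actt <- which(is.na(ft))
  red <- NULL; sys <- NULL
  if (length(actb) && length(actt)) {
    cs <- constraint_set("bicm", k_bottom = kb[actb], d_top = dt[actt])
    if (cfg$use_reduction) {
      red <- reduce_constraints(cs)
      sys <- reduced_system(red)
    } else sys <- sys_bicm(kb[actb], dt[actt])
  }
  list(model = "bicm", sys = sys, red = red,
       n_active = length(actb) + length(actt),
       fixed_p = fixed_p,
       c_r = if (is.null(red)) NA_real_ else red$c_r,
       cls_obs = if (is.null(red)) list(k = kb[actb], d = dt[actt])
                 else list(k = red$keys$bottom$k, d = red$keys$top$d),
       totals = list(L = sum(kb[actb]), n = length(actb) + length(actt),
                     n_bottom = length(actb), n_top = length(actt)),
       expand = function(th_cls) {
         out <- c(fb, ft)
         if (!is.null(sys)) {
           th_nodes <- if (is.null(red)) th_cls
                       else expand_parameters(red, th_cls)
           out[actb] <- th_nodes[seq_along(actb)]
           out[nb + actt] <- th_nodes[length(actb) + seq_along(actt)]
         }
         out
       })
}

# Directed/weighted models: nodes degenerate on one side only are dropped
# from that side (their probability row/column is analytically zero and does
# not touch the other equations); saturation is not supported.
masked_pairs <- function(Sset, Tset) {
  E <- matrix(1, length(Sset), length(Tset))
  E[outer(Sset, Tset, "==")] <- 0
  E
}

prep_dbcm <- function(observed, cfg) {
  kout <- observed$k_out; kin <- observed$k_in
  n <- length(kout)
  Sset <- which(kout > 0); Tset <- which(kin > 0)
  for (i in Sset) if (kout[i] >= sum(Tset != i)) {
    stop("saturated out-degree (node ", i, "): not supported for dbcm",
         call. = FALSE)
  }
  for (j in Tset) if (kin[j] >= sum(Sset != j)) {
    stop("saturated in-degree (node ", j, "): not supported for dbcm",
         call. = FALSE)
  }
  full <- length(Sset) == n && length(Tset) == n
  red <- NULL
  if (full && cfg$use_reduction) {
    red <- reduce_constraints(observed)
    sys <- reduced_system(red)
    cls_obs <- list(k = red$keys$k_out, h = red$keys$k_in)
  } else {
    sys <- sys_dir_binary("dbcm", kout[Sset], kin[Tset],
                          rep(1, length(Sset)), rep(1, length(Tset)),
                          masked_pairs(Sset, Tset))
    cls_obs <- list(k = kout[Sset], h = kin[Tset])
  }
  list(model = "dbcm", sys = sys, red = red,
       n_active = length(Sset) + length(Tset),
       c_r = if (is.null(red)) NA_real_ else red$c_r,
       cls_obs = cls_obs,
       totals = list(L = sum(kout[Sset]), n = n),
       expand = function(th_cls) {
         if (!is.null(red)) {
           th_nodes <- expand_parameters(red, th_cls)
           return(th_nodes)
         }
         a <- rep(Inf, n); b <- rep(Inf, n)
         a[Sset] <- th_cls[seq_along(Sset)]
         b[Tset] <- th_cls[length(Sset) + seq_along(Tset)]
         c(a, b)
       })
}

prep_uecm <- function(observed, cfg) {
  k <- observed$k; s <- observed$s
  n <- length(k)
  act <- which(k > 0)
  for (i in act) if (k[i] >= sum(act != i)) {
    stop("saturated degree (node ", i, "): not supported for uecm",
         call. = FALSE)
  }
  red <- NULL
  if (length(act) == n && cfg$use_reduction) {
    red <- reduce_constraints(observed)
    sys <- reduced_system(red)
    cls_obs <- list(k = red$keys$k, s = red$keys$s)
  } else {
    sys <- sys_uecm(k[act], s[act])
    cls_obs <- list(k = k[act], s = s[act])
  }
  list(model = "uecm", sys = sys, red = red, n_active = length(act),
       c_r = if (is.null(red)) NA_real_ else red$c_r,
       cls_obs = cls_obs,
       totals = list(L = sum(k[act]) / 2, W = sum(s[act]) / 2,
                     n = length(act)),
       expand = function(th_cls) {
         if (!is.null(red)) return(expand_parameters(red, th_cls))
         a <- rep(Inf, n); b <- rep(Inf, n)
         nc <- length(act)
         a[act] <- th_cls[seq_len(nc)]
         b[act] <- th_cls[nc + seq_len(nc)]
         c(a, b)
       })
}

prep_decm <- function(observed, cfg) {
  kout <- observed$k_out; kin <- observed$k_in
  sout <- observed$s_out; sin <- observed$s_in
  n <- length(kout)
  Sset <- which(kout > 0); Tset <- which(kin > 0)
  for (i in Sset) if (kout[i] >= sum(Tset != i)) {
    stop("saturated out-degree (node ", i, "): not supported for decm",
         call. = FALSE)
  }
  for (j in Tset) if (kin[j] >= sum(Sset != j)) {
    stop("saturated in-degree (node ", j, "): not supported for decm",
         call. = FALSE)
  }
  full <- length(Sset) == n && length(Tset) == n
  red <- NULL
  if (full && cfg$use_reduction) {
    red <- reduce_constraints(observed)
    sys <- reduced_system(red)
    cls_obs <- list(k = red$keys$k_out, h = red$keys$k_in,
                    s = red$keys$s_out, t = red$keys$s_in)
  } else {
    sys <- sys_decm(kout[Sset], kin[Tset], sout[Sset], sin[Tset],
                    mS = rep(1, length(Sset)), mT = rep(1, length(Tset)),
                    Epair = masked_pairs(Sset, Tset))
    cls_obs <- list(k = kout[Sset], h = kin[Tset],
                    s = sout[Sset], t = sin[Tset])
  }
  list(model = "decm", sys = sys, red = red,
       n_active = length(Sset) + length(Tset),
       c_r = if (is.null(red)) NA_real_ else red$c_r,
       cls_obs = cls_obs,
       totals = list(L = sum(kout[Sset]), W = sum(sout[Sset]), n = n),
       expand = function(th_cls) {
         if (!is.null(red)) return(expand_parameters(red, th_cls))
         nS <- length(Sset); nT <- length(Tset)
         a <- rep(Inf, n); b <- rep(Inf, n)
         g <- rep(Inf, n); d <- rep(Inf, n)
         a[Sset] <- th_cls[seq_len(nS)]
         b[Tset] <- th_cls[nS + seq_len(nT)]
         g[Sset] <- th_cls[nS + nT + seq_len(nS)]
         d[Tset] <- th_cls[2L * nS + nT + seq_len(nT)]
         c(a, b, g, d)
       })
}

prep_crem_und <- function(observed, marginals) {
  s <- observed$s
  n <- length(s)
  if (is.null(marginals)) stop("CReM requires a marginal matrix f",
                               call. = FALSE)
  f <- as.matrix(marginals)
  stopifnot(nrow(f) == n, ncol(f) == n)
  act <- which(s > 0)
  sys <- if (length(act)) sys_crem_und(s[act], f[act, act, drop = FALSE])
         else NULL
  list(model = "crem_und", sys = sys, red = NULL, n_active = length(act),
       c_r = NA_real_,
       cls_obs = list(s = s[act]),
       totals = list(W = sum(s[act]) / 2, n = length(act)),
       expand = function(th_cls) {
         out <- rep(Inf, n)
         out[act] <- th_cls
         out
       })
}

prep_crem_dir <- function(observed, marginals) {
  sout <- observed$s_out; sin <- observed$s_in
  n <- length(sout)
  if (is.null(marginals)) stop("CReM requires a marginal matrix f",
                               call. = FALSE)
  f <- as.matrix(marginals)
  stopifnot(nrow(f) == n, ncol(f) == n)
  Sset <- which(sout > 0); Tset <- which(sin > 0)
  fsub <- f[Sset, Tset, drop = FALSE]
  fsub[outer(Sset, Tset, "==")] <- 0
  sys <- if (length(Sset) && length(Tset)) {
    sys_crem_dir_masked(sout[Sset], sin[Tset], fsub)
  } else NULL
  list(model = "crem_dir", sys = sys, red = NULL,
       n_active = length(Sset) + length(Tset), c_r = NA_real_,
       cls_obs = list(s = sout[Sset], t = sin[Tset]),
       totals = list(W = sum(sout[Sset]), n = n),
       expand = function(th_cls) {
         a <- rep(Inf, n); b <- rep(Inf, n)
         a[Sset] <- th_cls[seq_along(Sset)]
         b[Tset] <- th_cls[length(Sset) + seq_along(Tset)]
         c(a, b)
       })
}

# Rectangular variant of the directed CReM system (source/target subsets).
sys_crem_dir_masked <- function(s_out, s_in, f) {
  nS <- length(s_out); nT <- length(s_in)
  R <- function(th) outer(th[1:nS], th[nS + (1:nT)], "+")
  list(
    model = "crem_dir", npar = nS + nT, families = c(alpha = nS, beta = nT),
    mult = list(alpha = rep(1, nS), beta = rep(1, nT)),
    improper = function(th) any(R(th)[f > 0] <= 0),
    loglik = function(th) {
      r <- R(th)
      if (any(r[f > 0] <= 0)) return(-Inf)
      lr <- suppressWarnings(log(r)); lr[f == 0] <- 0
      -sum(th[1:nS] * s_out) - sum(th[nS + (1:nT)] * s_in) + sum(f * lr)
    },
    grad = function(th) {
      M <- f / R(th)
      c(-s_out + rowSums(M), -s_in + colSums(M))
    },
    hessian = function(th) {
      M <- f / R(th)^2
      rbind(cbind(diag(-rowSums(M), nS), -M),
            cbind(-t(M), diag(-colSums(M), nT)))
    },
    hess_diag = function(th) {
      M <- f / R(th)^2
      c(-rowSums(M), -colSums(M))
    },
    fpmap = function(th) {
      a <- th[1:nS]; b <- th[nS + (1:nT)]
      M <- f / R(th)
      c(a * rowSums(M) / s_out, b * colSums(M) / s_in)
    },
    expected = function(th) {
      M <- f / R(th)
      list(s_out = rowSums(M), s_in = colSums(M))
    },
    pmat = function(th) f,
    wmat = function(th) f / R(th)
  )
}

# ---------------------------------------------------------------------------

# CReM admissibility is pairwise (theta_i + theta_j > 0, resp.
# alpha_i + beta_j > 0, on feasible pairs): individual multipliers of
# high-strength nodes can be negative at the maximum, so no per-parameter
# positivity clip is applied -- it would pin the iterate at the boundary with
# a non-zero gradient. Inadmissible trial points are rejected by the Armijo
# search (-Inf objective) or reported as divergence by the fixed-point loop.
crem_project <- function(model, th) th

sqp_iterate <- function(sys, th, cfg, diagonal = FALSE) {
  trace <- if (cfg$trace) list() else NULL
  iter <- 0L
  g <- sys$grad(th)
  gn <- sqrt(sum(g^2))
  sn <- NA_real_
  by <- "max_iter"
  while (iter < cfg$max_iter) {
    if (gn <= cfg$tol_grad) { by <- "grad_norm"; break }
    step <- if (diagonal) quasi_newton_step(g, sys$hess_diag(th))
            else newton_step(g, sys$hessian(th))
    slope <- sum(g * step)
    if (!is.finite(slope) || slope <= 0) { # fall back to steepest ascent
      step <- g
      slope <- sum(g^2)
    }
    alpha <- armijo_backtracking(sys$loglik, th, step, slope,
                                 cfg$armijo_gamma, cfg$armijo_beta,
                                 noise_alpha = if (diagonal) 0.5 else 1)
    th <- crem_project(sys$model, th + alpha * step)
    iter <- iter + 1L
    g <- sys$grad(th)
    if (!all(is.finite(g))) {
      stop("non-finite gradient at iteration ", iter, call. = FALSE)
    }
    gn <- sqrt(sum(g^2))
    sn <- alpha * sqrt(sum(step^2))
    if (cfg$trace) {
      trace[[iter]] <- c(iter = iter, loglik = sys$loglik(th),
                         grad_norm = gn, alpha = alpha)
    }
    if (gn <= cfg$tol_grad) { by <- "grad_norm"; break }
    if (sn <= cfg$tol_step) { by <- "step_norm"; break }
  }
  if (gn <= cfg$tol_grad) by <- "grad_norm"
  list(theta = th, converged_by = by, iterations = iter,
       final_grad_norm = gn, final_step_norm = sn,
       trace = if (cfg$trace) do.call(rbind, trace) else NULL)
}

fp_iterate <- function(sys, th, cfg) {
  trace <- if (cfg$trace) list() else NULL
  iter <- 0L
  g <- sys$grad(th)
  gn <- sqrt(sum(g^2))
  sn <- NA_real_
  by <- "max_iter"
  while (iter < cfg$max_iter) {
    if (gn <= cfg$tol_grad) { by <- "grad_norm"; break }
    th_new <- sys$fpmap(th)
    if (cfg$relax > 0) th_new <- (1 - cfg$relax) * th_new + cfg$relax * th
    th_new <- crem_project(sys$model, th_new)
    if (all(is.finite(th_new)) && sys$improper(th_new)) {
      # the plain map has left the admissible region (the enhanced models do
      # not guarantee feasible iterates); report divergence honestly
      return(list(theta = th, converged_by = "diverged", iterations = iter,
                  final_grad_norm = gn, final_step_norm = sn,
                  trace = if (cfg$trace) do.call(rbind, trace) else NULL))
    }
    if (!all(is.finite(th_new)) || sqrt(sum(th_new^2)) > 1e10) {
      return(list(theta = th, converged_by = "diverged", iterations = iter,
                  final_grad_norm = gn, final_step_norm = sn,
                  trace = if (cfg$trace) do.call(rbind, trace) else NULL))
    }
    sn <- sqrt(sum((th_new - th)^2))
    th <- th_new
    iter <- iter + 1L
    g <- sys$grad(th)
    gn <- sqrt(sum(g^2))
    if (cfg$trace) {
      trace[[iter]] <- c(iter = iter, loglik = sys$loglik(th),
                         grad_norm = gn, alpha = 1)
    }
    if (gn <= cfg$tol_grad) { by <- "grad_norm"; break }
    if (sn <= cfg$tol_step) { by <- "step_norm"; break }
  }
  if (gn <= cfg$tol_grad) by <- "grad_norm"
  list(theta = th, converged_by = by, iterations = iter,
       final_grad_norm = gn, final_step_norm = sn,
       trace = if (cfg$trace) do.call(rbind, trace) else NULL)
}

# Class-level initial values using the model's closed-form schemes.
init_class <- function(prep, cfg) {
  sc <- cfg$init
  if (sc == "uniform") {
    if (is.null(cfg$seed)) stop("uniform initialization requires a seed",
                                call. = FALSE)
    set.seed(as.integer(cfg$seed))
    th0 <- stats::runif(prep$sys$npar)
    return(crem_project(prep$model, th0))
  }
  tt <- prep$totals
  co <- prep$cls_obs
  ilog <- function(v, d) -log(v / d)
  th0 <- switch(prep$model,
    ubcm = ilog(co$k, if (sc == "sparse") sqrt(2 * tt$L) else sqrt(tt$n)),
    bicm = {
      d <- if (sc == "sparse") sqrt(tt$L) else sqrt(tt$n)
      c(ilog(co$k, d), ilog(co$d, d))
    },
    dbcm = {
      d <- if (sc == "sparse") sqrt(tt$L) else sqrt(tt$n)
      c(ilog(co$k, d), ilog(co$h, d))
    },
    uecm = {
      dk <- if (sc == "sparse") sqrt(2 * tt$L) else sqrt(tt$n)
      ds <- if (sc == "sparse") sqrt(2 * tt$W) else sqrt(tt$n)
      b <- shift_admissible(ilog(co$s, ds))
      c(ilog(co$k, dk), b)
    },
    decm = {
      dk <- if (sc == "sparse") sqrt(tt$L) else sqrt(tt$n)
      ds <- if (sc == "sparse") sqrt(tt$W) else sqrt(tt$n)
      gd <- shift_admissible(ilog(co$s, ds), ilog(co$t, ds))
      c(ilog(co$k, dk), ilog(co$h, dk), gd)
    },
    crem_und = pmax(ilog(co$s, if (sc == "sparse") sqrt(2 * tt$W)
                               else sqrt(tt$n)), 1e-8),
    crem_dir = {
      d <- if (sc == "sparse") sqrt(tt$W) else sqrt(tt$n)
      pmax(c(ilog(co$s, d), ilog(co$t, d)), 1e-8)
    })
  th0
}

# The closed-form initial values of the enhanced models can violate the
# admissibility requirement beta_i + beta_j > 0 (gamma_i + delta_j > 0) for
# high-strength pairs; shift the strength multipliers uniformly so the
# smallest pair sum clears a small positive margin. The shift only moves the
# starting point, never the solution.
shift_admissible <- function(b, d = NULL, margin = 1e-2) {
  if (is.null(d)) {
    t2 <- if (length(b) == 1L) 2 * b else sum(sort(b)[1:2])
    if (t2 <= margin) b <- b + (margin - t2) / 2
    return(b)
  }
  t2 <- min(b) + min(d)
  if (t2 <= margin) {
    h <- (margin - t2) / 2
    b <- b + h
    d <- d + h
  }
  c(b, d)
}

#' Maximum-likelihood fit of a configuration model
#'
#' Solves the stationarity system of the chosen model on an observed graph or
#' constraint set: after analytic pre-resolution of degenerate nodes and
#' (where supported) collapse of identical-constraint nodes into classes, the
#' selected algorithm iterates until the gradient-norm or step-norm tolerance
#' is met or the iteration cap is reached. For the CReM models the
#' edge-marginal matrix `marginals` of the binary model in use must be
#' supplied; an optional strength rescaling `rescale_kappa` is applied and
#' inverted exactly.
#'
#' @param model model id, see [model_ids()].
#' @param x a `maxent_graph` or a `constraint_set`.
#' @param config a [solver_config()].
#' @param marginals edge-marginal matrix f (CReM only).
#' @return an object of class `solver_result`: node-level `params` (with
#'   `+Inf`/`-Inf` sentinels on analytically resolved nodes), `converged_by`
#'   (`"grad_norm"`, `"step_norm"`, `"max_iter"` or `"diverged"`),
#'   `iterations`, `final_grad_norm`, `final_step_norm`, the maximized
#'   `loglik`, the reduction coefficient `c_r`, and the optional `trace`.
#' @export
solve_model <- function(model, x, config = solver_config(),
                        marginals = NULL) {
  model <- check_model(model)
  if (model == "dcgm") {
    stop("use dcgm_solve_z() for the gravity model", call. = FALSE)
  }
  observed <- if (inherits(x, "maxent_graph")) constraints(x, model) else x
  stopifnot(inherits(observed, "constraint_set"))
  if (observed$model != model) {
    stop("constraint set was built for model '", observed$model, "'",
         call. = FALSE)
  }
  cfg <- model_defaults(model, config)
  kappa <- cfg$rescale_kappa
  if (!is.null(kappa) && !model %in% c("crem_und", "crem_dir")) {
    stop("rescale_kappa applies to the CReM models only", call. = FALSE)
  }
  if (!is.null(kappa)) {
    observed <- if (model == "crem_und") {
      constraint_set("crem_und", s = observed$s / kappa)
    } else {
      constraint_set("crem_dir", s_out = observed$s_out / kappa,
                     s_in = observed$s_in / kappa)
    }
    # the rescaled system's gradient is the original one divided by kappa and
    # its multipliers are kappa times larger; scale the tolerances so the
    # stopping criteria keep their meaning in the original problem's units
    cfg$tol_grad <- cfg$tol_grad / kappa
    cfg$tol_step <- cfg$tol_step * kappa
  }
  prep <- prepare_problem(model, observed, marginals, cfg)
  if (is.null(prep$sys)) {   # fully degenerate: everything resolved
    res <- list(theta = numeric(0), converged_by = "grad_norm",
                iterations = 0L, final_grad_norm = 0,
                final_step_norm = 0, trace = NULL)
  } else {
    th0 <- init_class(prep, cfg)
    res <- run_method(prep$sys, th0, cfg)
  }
  params <- prep$expand(res$theta)
  if (!is.null(kappa)) params <- params / kappa
  structure(list(model = model, params = params,
                 converged_by = res$converged_by,
                 iterations = res$iterations,
                 final_grad_norm = res$final_grad_norm,
                 final_step_norm = res$final_step_norm,
                 loglik = if (is.null(prep$sys)) 0
                          else prep$sys$loglik(res$theta),
                 c_r = prep$c_r, n_active = prep$n_active,
                 fixed_p = prep$fixed_p,
                 method = cfg$method, trace = res$trace),
            class = "solver_result")
}

run_method <- function(sys, th0, cfg) {
  switch(cfg$method,
    newton = sqp_iterate(sys, th0, cfg, diagonal = FALSE),
    quasinewton = sqp_iterate(sys, th0, cfg, diagonal = TRUE),
    fixedpoint = fp_iterate(sys, th0, cfg),
    coupled = {
      ph1 <- fp_iterate(sys, th0, cfg)
      ph2 <- sqp_iterate(sys, ph1$theta, cfg, diagonal = TRUE)
      list(theta = ph2$theta, converged_by = ph2$converged_by,
           iterations = ph1$iterations + ph2$iterations,
           final_grad_norm = ph2$final_grad_norm,
           final_step_norm = ph2$final_step_norm,
           trace = rbind(ph1$trace, ph2$trace))
    })
}

#' @export
print.solver_result <- function(x, ...) {
  cat(sprintf(paste0("<solver_result> %s via %s: %s after %d iterations\n",
                     "  ||grad|| = %.3g, loglik = %.6g%s\n"),
              x$model, x$method, x$converged_by, x$iterations,
              x$final_grad_norm, x$loglik,
              if (is.na(x$c_r)) "" else sprintf(", c_r = %.3g", x$c_r)))
  invisible(x)
}

#' Fitted link probabilities, expected weights and expected constraints
#'
#' Reconstructs the pairwise probability (and, for weighted models, expected
#' weight) matrices implied by a solver result, including the entries of
#' analytically resolved degenerate nodes, whose hard 0/1 probabilities are
#' recorded during pre-resolution (the bare multiplier sentinels alone cannot
#' distinguish a forced link from a forbidden one). Expected constraints are
#' recomputed from these matrices.
#'
#' @param fit a `solver_result`.
#' @param observed the `constraint_set` that was fitted.
#' @param marginals edge-marginal matrix (CReM only).
#' @return list with `p` (link probabilities), `w` (expected weights, weighted
#'   models only) and `expected` (named list of expected constraint vectors).
#' @export
fitted_values <- function(fit, observed, marginals = NULL) {
  stopifnot(inherits(fit, "solver_result"))
  model <- fit$model
  p <- link_probabilities(model, fit$params, observed, marginals)
  if (!is.null(fit$fixed_p)) {
    idx <- !is.na(fit$fixed_p)
    p[idx] <- fit$fixed_p[idx]
  }
  w <- if (model %in% c("uecm", "decm", "crem_und", "crem_dir")) {
    expected_weights(model, fit$params, observed, marginals)
  } else NULL
  expected <- switch(model,
    ubcm = list(k = rowSums(p)),
    dbcm = list(k_out = rowSums(p), k_in = colSums(p)),
    bicm = list(k_bottom = rowSums(p), d_top = colSums(p)),
    uecm = list(k = rowSums(p), s = rowSums(w)),
    decm = list(k_out = rowSums(p), k_in = colSums(p),
                s_out = rowSums(w), s_in = colSums(w)),
    crem_und = list(s = rowSums(w)),
    crem_dir = list(s_out = rowSums(w), s_in = colSums(w)))
  list(p = p, w = w, expected = expected)
}

#' Fixed-point and coupled solvers, and CReM rescaling
#'
#' Convenience wrappers around [solve_model()]: `fixed_point_solve()` iterates
#' the model's consistency map with no line search, `coupled_solve()` runs the
#' fixed-point iteration to its stop and refines the result with the diagonal
#' quasi-Newton method, and `crem_rescaled_solve()` solves the CReM with the
#' strength sequence divided by `kappa`, mapping the multipliers back exactly
#' (the returned solution is independent of `kappa`).
#'
#' @inheritParams solve_model
#' @param kappa positive rescaling factor.
#' @return a `solver_result`.
#' @export
fixed_point_solve <- function(model, x, config = solver_config("fixedpoint"),
                              marginals = NULL) {
  config$method <- "fixedpoint"
  solve_model(model, x, config, marginals)
}

#' @rdname fixed_point_solve
#' @export
coupled_solve <- function(model, x, config = solver_config("coupled"),
                          marginals = NULL) {
  config$method <- "coupled"
  solve_model(model, x, config, marginals)
}

#' @rdname fixed_point_solve
#' @export
crem_rescaled_solve <- function(model, x, kappa,
                                config = solver_config(), marginals = NULL) {
  stopifnot(model %in% c("crem_und", "crem_dir"))
  config$rescale_kappa <- kappa
  solve_model(model, x, config, marginals)
}
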