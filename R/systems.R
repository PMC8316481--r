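# Internal class-level likelihood systems.
#
# Every model is expressed over *classes* of identical-constraint nodes: a
# class K carries a multiplicity m_K and one multiplier per parameter family.
# The full (unreduced) problem is the special case m == 1 with one class per
# node, so the reduced and full systems share one implementation and agree
# algebraically by construction. Pair structure is encoded in an ordered
# pair-count matrix Epair: Epair[K, K'] is the number of ordered node pairs
# (i, j), i != j, with i in K and j in K' (for undirected models it is
# symmetric and each unordered pair is counted twice, whence the 1/2 factors).
#
# Hessians are obtained from the fluctuation-response identity: the Hessian of
# the log-likelihood equals minus the covariance matrix of the constraints.
# Pair-level covariances (Bernoulli, Bernoulli-geometric, conditional
# exponential) are in closed form; class-level blocks follow by summing over
# the pairs each pair-level term touches:
#   undirected, families A,B:  H^{AB} = -(Epair*c + diag(rowSums(Epair*c)))
#   directed row-row:          H      = -diag(rowSums(Epair*c))
#   directed row-col:          H      = -(Epair*c)
#   directed col-col:          H      = -diag(colSums(Epair*c))
# with c the pair-level covariance matrix of the two families' pair terms.

log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- !lo
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

pair_counts <- function(m) {
  E <- outer(m, m)
  diag(E) <- diag(E) - m
  E
}

und_block <- function(Epair, cmat) {
  B <- -(Epair * cmat)
  diag(B) <- diag(B) - rowSums(Epair * cmat)
  B
}

# ---------------------------------------------------------------- UBCM ----

sys_ubcm <- function(k, m = rep(1, length(k)), Epair = pair_counts(m)) {
  force(k); force(m); force(Epair)
  pmat <- function(th) {
    a <- outer(th, th, "+")
    p <- 1 / (1 + exp(a))
    p[is.nan(p)] <- 0  # +Inf - Inf sentinels never pair off-diagonal
    p
  }
  list(
    model = "ubcm", npar = length(k), families = c(theta = length(k)),
    mult = list(theta = m),
    improper = function(th) FALSE,
    loglik = function(th) {
      a <- outer(th, th, "+")
      -sum(m * th * k) - 0.5 * sum(Epair * log1pexp(-a))
    },
    grad = function(th) -m * k + rowSums(Epair * pmat(th)),
    hessian = function(th) und_block(Epair, {p <- pmat(th); p * (1 - p)}),
    hess_diag = function(th) {
      caa <- {p <- pmat(th); p * (1 - p)}
      -rowSums(Epair * caa) - diag(Epair) * diag(caa)
    },
    fpmap = function(th) {
      if (any(k <= 0)) stop("fixed-point map undefined for zero degrees",
                            call. = FALSE)
      x <- exp(-th)
      A <- outer(rep(1, length(x)), x) / (1 + outer(x, x))
      -log(k / (rowSums(Epair * A) / m))
    },
    expected = function(th) list(k = rowSums(Epair * pmat(th)) / m),
    pmat = pmat
  )
}

# ------------------------------------------------- DBCM and BiCM ----------
# Both are Bernoulli models on ordered (source, target) pairs; they differ
# only in the pair-count matrix (BiCM has no within-layer or self pairs).

sys_dir_binary <- function(model, c_row, c_col, mS, mT, Epair) {
  force(c_row); force(c_col); force(mS); force(mT); force(Epair)
  nS <- length(c_row); nT <- length(c_col)
  pm <- function(th) {
    a <- outer(th[1:nS], th[nS + (1:nT)], "+")
    p <- 1 / (1 + exp(a))
    p[is.nan(p)] <- 0
    p
  }
  list(
    model = model, npar = nS + nT,
    families = c(alpha = nS, beta = nT),
    mult = list(alpha = mS, beta = mT),
    improper = function(th) FALSE,
    loglik = function(th) {
      a <- outer(th[1:nS], th[nS + (1:nT)], "+")
      -sum(mS * th[1:nS] * c_row) - sum(mT * th[nS + (1:nT)] * c_col) -
        sum(Epair * log1pexp(-a))
    },
    grad = function(th) {
      p <- pm(th)
      c(-mS * c_row + rowSums(Epair * p), -mT * c_col + colSums(Epair * p))
    },
    hessian = function(th) {
      p <- pm(th); caa <- p * (1 - p)
      Hab <- -(Epair * caa)
      rbind(cbind(diag(-rowSums(Epair * caa), nS), Hab),
            cbind(t(Hab), diag(-colSums(Epair * caa), nT)))
    },
    hess_diag = function(th) {
      p <- pm(th); caa <- p * (1 - p)
      c(-rowSums(Epair * caa), -colSums(Epair * caa))
    },
    fpmap = function(th) {
      if (any(c_row <= 0) || any(c_col <= 0)) {
        stop("fixed-point map undefined for zero degrees", call. = FALSE)
      }
      x <- exp(-th[1:nS]); b <- exp(-th[nS + (1:nT)])
      X <- outer(x, b)
      Brow <- outer(rep(1, nS), b) / (1 + X)
      Bcol <- outer(x, rep(1, nT)) / (1 + X)
      c(-log(c_row / (rowSums(Epair * Brow) / mS)),
        -log(c_col / (colSums(Epair * Bcol) / mT)))
    },
    expected = function(th) {
      p <- pm(th)
      list(row = rowSums(Epair * p) / mS, col = colSums(Epair * p) / mT)
    },
    pmat = pm
  )
}

sys_dbcm <- function(k_out, k_in, m = rep(1, length(k_out)),
                     Epair = pair_counts(m)) {
  sys_dir_binary("dbcm", k_out, k_in, m, m, Epair)
}

sys_bicm <- function(k_bottom, d_top, mb = rep(1, length(k_bottom)),
                     mt = rep(1, length(d_top)), Epair = outer(mb, mt)) {
  sys_dir_binary("bicm", k_bottom, d_top, mb, mt, Epair)
}

# ---------------------------------------------------------------- UECM ----
# Pair law: Bernoulli(p) link, conditional geometric weight >= 1 with
# parameter v = exp(-beta_i - beta_j); p has the Bernoulli-geometric form.
# Pair moments: <w> = p/(1-v), <w^2> = p(1+v)/(1-v)^2.

uecm_pair <- function(alpha, beta, mask = NULL) {
  v <- exp(-outer(beta, beta, "+"))
  # excluded pairs (mask FALSE) carry no constraint: neutralize them so an
  # inadmissible value there cannot poison the sums through 0 * NaN
  if (!is.null(mask)) v[!mask] <- 0
  # p = uv/(1-v+uv) with u = e^{-a_i-a_j}, v = e^{-b_i-b_j}: p = 1/(1+e^E)
  E <- outer(alpha, alpha, "+") + outer(beta, beta, "+") + log1p(-v)
  p <- 1 / (1 + exp(E))
  list(v = v, E = E, p = p, w = p / (1 - v))
}

sys_uecm <- function(k, s, m = rep(1, length(k)), Epair = pair_counts(m)) {
  force(k); force(s); force(m); force(Epair)
  n <- length(k)
  msk <- Epair > 0
  improper <- function(th) {
    v <- exp(-outer(th[n + (1:n)], th[n + (1:n)], "+"))
    any(v[msk] >= 1)
  }
  pair <- function(th) uecm_pair(th[1:n], th[n + (1:n)], msk)
  list(
    model = "uecm", npar = 2L * n, families = c(alpha = n, beta = n),
    mult = list(alpha = m, beta = m),
    improper = improper,
    loglik = function(th) {
      if (improper(th)) return(-Inf)
      q <- pair(th)
      -sum(m * (th[1:n] * k + th[n + (1:n)] * s)) -
        0.5 * sum(Epair * log1pexp(-q$E))
    },
    grad = function(th) {
      if (improper(th)) stop("improper UECM parameters: beta_i + beta_j <= 0",
                             call. = FALSE)
      q <- pair(th)
      c(-m * k + rowSums(Epair * q$p), -m * s + rowSums(Epair * q$w))
    },
    hessian = function(th) {
      q <- pair(th)
      caa <- q$p * (1 - q$p)
      caw <- q$w * (1 - q$p)
      cww <- (q$p * (1 + q$v) - q$p^2) / (1 - q$v)^2
      Hab <- und_block(Epair, caw)
      rbind(cbind(und_block(Epair, caa), Hab),
            cbind(Hab, und_block(Epair, cww)))
    },
    hess_diag = function(th) {
      q <- pair(th)
      caa <- q$p * (1 - q$p)
      cww <- (q$p * (1 + q$v) - q$p^2) / (1 - q$v)^2
      dg <- function(cmat) -rowSums(Epair * cmat) - diag(Epair) * diag(cmat)
      c(dg(caa), dg(cww))
    },
    fpmap = function(th) {
      if (any(k <= 0) || any(s <= 0)) {
        stop("fixed-point map undefined for zero constraints", call. = FALSE)
      }
      alpha <- th[1:n]; beta <- th[n + (1:n)]
      x <- exp(-alpha); y <- exp(-beta)
      u <- outer(x, x); v <- outer(y, y)
      D <- 1 - v + u * v
      Aterm <- outer(rep(1, n), x) * v / D
      Bterm <- u * outer(rep(1, n), y) / ((1 - v) * D)
      c(-log(k / (rowSums(Epair * Aterm) / m)),
        -log(s / (rowSums(Epair * Bterm) / m)))
    },
    expected = function(th) {
      q <- pair(th)
      list(k = rowSums(Epair * q$p) / m, s = rowSums(Epair * q$w) / m)
    },
    pmat = function(th) pair(th)$p,
    wmat = function(th) pair(th)$w
  )
}

# ---------------------------------------------------------------- DECM ----

decm_pair <- function(alpha, beta, gamma, delta, mask = NULL) {
  v <- exp(-outer(gamma, delta, "+"))
  if (!is.null(mask)) v[!mask] <- 0
  E <- outer(alpha, beta, "+") + outer(gamma, delta, "+") + log1p(-v)
  p <- 1 / (1 + exp(E))
  list(v = v, E = E, p = p, w = p / (1 - v))
}

sys_decm <- function(k_out, k_in, s_out, s_in, mS = rep(1, length(k_out)),
                     mT = mS, Epair = pair_counts(mS)) {
  force(k_out); force(k_in); force(s_out); force(s_in)
  force(mS); force(mT); force(Epair)
  nS <- length(k_out); nT <- length(k_in)
  blk <- function(th) list(a = th[1:nS], b = th[nS + (1:nT)],
                           g = th[nS + nT + (1:nS)],
                           d = th[2L * nS + nT + (1:nT)])
  msk <- Epair > 0
  improper <- function(th) {
    z <- blk(th)
    any(exp(-outer(z$g, z$d, "+"))[msk] >= 1)
  }
  pair <- function(th) { z <- blk(th); decm_pair(z$a, z$b, z$g, z$d, msk) }
  list(
    model = "decm", npar = 2L * (nS + nT),
    families = c(alpha = nS, beta = nT, gamma = nS, delta = nT),
    mult = list(alpha = mS, beta = mT, gamma = mS, delta = mT),
    improper = improper,
    loglik = function(th) {
      if (improper(th)) return(-Inf)
      z <- blk(th); q <- pair(th)
      -sum(mS * (z$a * k_out + z$g * s_out)) -
        sum(mT * (z$b * k_in + z$d * s_in)) -
        sum(Epair * log1pexp(-q$E))
    },
    grad = function(th) {
      if (improper(th)) stop("improper DECM parameters: gamma_i + delta_j <= 0",
                             call. = FALSE)
      q <- pair(th)
      c(-mS * k_out + rowSums(Epair * q$p), -mT * k_in + colSums(Epair * q$p),
        -mS * s_out + rowSums(Epair * q$w), -mT * s_in + colSums(Epair * q$w))
    },
    hessian = function(th) {
      q <- pair(th)
      caa <- q$p * (1 - q$p)
      caw <- q$w * (1 - q$p)
      cww <- (q$p * (1 + q$v) - q$p^2) / (1 - q$v)^2
      rd <- function(cmat) diag(-rowSums(Epair * cmat), nS)
      cd <- function(cmat) diag(-colSums(Epair * cmat), nT)
      cr <- function(cmat) -(Epair * cmat)
      rbind(
        cbind(rd(caa), cr(caa), rd(caw), cr(caw)),
        cbind(t(cr(caa)), cd(caa), t(cr(caw)), cd(caw)),
        cbind(rd(caw), cr(caw), rd(cww), cr(cww)),
        cbind(t(cr(caw)), cd(caw), t(cr(cww)), cd(cww))
      )
    },
    hess_diag = function(th) {
      q <- pair(th)
      caa <- q$p * (1 - q$p)
      cww <- (q$p * (1 + q$v) - q$p^2) / (1 - q$v)^2
      c(-rowSums(Epair * caa), -colSums(Epair * caa),
        -rowSums(Epair * cww), -colSums(Epair * cww))
    },
    fpmap = function(th) {
      if (any(c(k_out, k_in, s_out, s_in) <= 0)) {
        stop("fixed-point map undefined for zero constraints", call. = FALSE)
      }
      z <- blk(th)
      x <- exp(-z$a); b <- exp(-z$b); g <- exp(-z$g); d <- exp(-z$d)
      u <- outer(x, b); v <- outer(g, d)
      v[!msk] <- 0
      D <- 1 - v + u * v
      A <- outer(rep(1, nS), b) * v / D    # e^{-beta_j-gamma_i-delta_j}/D
      B <- outer(x, rep(1, nT)) * v / D    # e^{-alpha_j-gamma_j-delta_i}/D
      G <- u * outer(rep(1, nS), d) / ((1 - v) * D)
      Dm <- g * u / ((1 - v) * D)          # e^{-alpha_j-beta_i-gamma_j}/...
      c(-log(k_out / (rowSums(Epair * A) / mS)),
        -log(k_in / (colSums(Epair * B) / mT)),
        -log(s_out / (rowSums(Epair * G) / mS)),
        -log(s_in / (colSums(Epair * Dm) / mT)))
    },
    expected = function(th) {
      q <- pair(th)
      list(k_out = rowSums(Epair * q$p) / mS, k_in = colSums(Epair * q$p) / mT,
           s_out = rowSums(Epair * q$w) / mS, s_in = colSums(Epair * q$w) / mT)
    },
    pmat = function(th) pair(th)$p,
    wmat = function(th) pair(th)$w
  )
}

# ---------------------------------------------------------------- CReM ----
# Conditional exponential weights on a given edge-marginal matrix f; no
# reduction is defined (f is node-pair specific), so these systems are always
# at node level. The objective is the conditional likelihood G(theta).

sys_crem_und <- function(s, f) {
  force(s)
  f <- unname(as.matrix(f)); diag(f) <- 0
  n <- length(s)
  list(
    model = "crem_und", npar = n, families = c(theta = n),
    mult = list(theta = rep(1, n)),
    improper = function(th) {
      R <- outer(th, th, "+")
      any(R[f > 0] <= 0)
    },
    loglik = function(th) {
      R <- outer(th, th, "+")
      if (any(R[f > 0] <= 0)) return(-Inf)
      lr <- suppressWarnings(log(R)); lr[f == 0] <- 0
      -sum(th * s) + 0.5 * sum(f * lr)
    },
    grad = function(th) -s + rowSums(f / outer(th, th, "+")),
    hessian = function(th) {
      M <- f / outer(th, th, "+")^2
      H <- -M
      diag(H) <- -rowSums(M)
      H
    },
    hess_diag = function(th) -rowSums(f / outer(th, th, "+")^2),
    fpmap = function(th) {
      if (any(s <= 0)) stop("fixed-point map undefined for zero strengths",
                            call. = FALSE)
      th * rowSums(f / outer(th, th, "+")) / s
    },
    expected = function(th) list(s = rowSums(f / outer(th, th, "+"))),
    pmat = function(th) f,
    wmat = function(th) {
      W <- f / outer(th, th, "+")
      diag(W) <- 0
      W
    }
  )
}

sys_crem_dir <- function(s_out, s_in, f) {
  force(s_out); force(s_in)
  f <- unname(as.matrix(f)); diag(f) <- 0
  n <- length(s_out)
  R <- function(th) outer(th[1:n], th[n + (1:n)], "+")
  list(
    model = "crem_dir", npar = 2L * n, families = c(alpha = n, beta = n),
    mult = list(alpha = rep(1, n), beta = rep(1, n)),
    improper = function(th) any(R(th)[f > 0] <= 0),
    loglik = function(th) {
      r <- R(th)
      if (any(r[f > 0] <= 0)) return(-Inf)
      lr <- suppressWarnings(log(r)); lr[f == 0] <- 0
      -sum(th[1:n] * s_out) - sum(th[n + (1:n)] * s_in) + sum(f * lr)
    },
    grad = function(th) {
      M <- f / R(th)
      c(-s_out + rowSums(M), -s_in + colSums(M))
    },
    hessian = function(th) {
      M <- f / R(th)^2
      rbind(cbind(diag(-rowSums(M), n), -M),
            cbind(-t(M), diag(-colSums(M), n)))
    },
    hess_diag = function(th) {
      M <- f / R(th)^2
      c(-rowSums(M), -colSums(M))
    },
    fpmap = function(th) {
      if (any(c(s_out, s_in) <= 0)) {
        stop("fixed-point map undefined for zero strengths", call. = FALSE)
      }
      a <- th[1:n]; b <- th[n + (1:n)]
      M <- f / R(th)
      c(a * rowSums(M) / s_out, b * colSums(M) / s_in)
    },
    expected = function(th) {
      M <- f / R(th)
      list(s_out = rowSums(M), s_in = colSums(M))
    },
    pmat = function(th) f,
    wmat = function(th) {
      W <- f / R(th)
      diag(W) <- 0
      W
    }
  )
}

# Dispatch a node-level (identity-class) system for a model.
build_system <- function(model, observed, marginals = NULL) {
  model <- check_model(model)
  if (model %in% c("crem_und", "crem_dir") && is.null(marginals)) {
    stop("CReM requires a marginal-probability matrix f", call. = FALSE)
  }
  switch(model,
    ubcm = sys_ubcm(observed$k),
    dbcm = sys_dbcm(observed$k_out, observed$k_in),
    bicm = sys_bicm(observed$k_bottom, observed$d_top),
    uecm = sys_uecm(observed$k, observed$s),
    decm = sys_decm(observed$k_out, observed$k_in,
                    observed$s_out, observed$s_in),
    crem_und = sys_crem_und(observed$s, marginals),
    crem_dir = sys_crem_dir(observed$s_out, observed$s_in, marginals),
    dcgm = stop("dcgm is solved by dcgm_solve_z(), not a multiplier system",
                call. = FALSE)
  )
}
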