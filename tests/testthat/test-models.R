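test_that("degree-model closed forms match hand values at theta = 0", {
  obs3 <- constraint_set("ubcm", k = c(2, 2, 2))
  th0 <- rep(0, 3)
  p <- link_probabilities("ubcm", th0, obs3)
  expect_equal(p[upper.tri(p)], rep(0.5, 3))
  expect_equal(diag(p), rep(0, 3))

  obs2 <- constraint_set("ubcm", k = c(1, 1))
  expect_equal(log_likelihood("ubcm", c(0, 0), obs2), -log(2))

  expect_equal(gradient("ubcm", th0, obs3), rep(-1, 3))
  expect_equal(unname(expected_constraints("ubcm", th0, obs3)$k), rep(1, 3))

  H <- hessian("ubcm", th0, obs3)
  expect_equal(diag(H), rep(-0.5, 3))
  expect_equal(H[1, 2], -0.25)
  expect_equal(hessian_diagonal("ubcm", th0, obs3), diag(H))

  s <- rep(2, 5)
  pd <- link_probabilities("dcgm", 1 / 4, constraint_set("dcgm", s = s, L = 5))
  expect_equal(pd[1, 2], 0.5)
})

test_that("UBCM log-likelihood at theta = 0 equals the enumeration value", {
  obs <- constraint_set("ubcm", k = c(2, 2, 2))   # the complete 3-graph
  en <- enumerate_ensemble("ubcm", rep(0, 3), obs)
  expect_equal(en$Z, 8)
  # at theta = 0 every graph has probability 1/8, the complete one included
  expect_equal(log_likelihood("ubcm", rep(0, 3), obs), log(1 / 8))
})

test_that("analytic gradients match central finite differences", {
  for (model in c("ubcm", "dbcm", "bicm", "uecm", "decm",
                  "crem_und", "crem_dir")) {
    inst <- small_instance(model)
    th <- random_params(model, inst$obs, seed = 3)
    f <- function(x) log_likelihood(model, x, inst$obs, inst$marginals)
    g <- gradient(model, th, inst$obs, inst$marginals)
    expect_lt(rel_err(fd_gradient(f, th), g), 1e-6)
  }
})

test_that("analytic Hessians match finite differences of the gradient", {
  for (model in c("ubcm", "dbcm", "bicm", "uecm", "decm",
                  "crem_und", "crem_dir")) {
    inst <- small_instance(model)
    th <- random_params(model, inst$obs, seed = 4)
    gf <- function(x) gradient(model, x, inst$obs, inst$marginals)
    H <- hessian(model, th, inst$obs, inst$marginals)
    expect_lt(rel_err(fd_jacobian(gf, th), H), 1e-5)
    expect_equal(hessian_diagonal(model, th, inst$obs, inst$marginals),
                 diag(H))
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(ev), 1e-10)
  }
})

test_that("enumeration oracle: normalization, expectations, covariance", {
  cases <- list(
    list(model = "ubcm", obs = constraint_set("ubcm", k = c(2, 2, 1, 1))),
    list(model = "dbcm", obs = constraint_set("dbcm", k_out = c(1, 1, 1),
                                              k_in = c(1, 1, 1))),
    list(model = "bicm", obs = constraint_set("bicm", k_bottom = c(2, 1),
                                              d_top = c(1, 1, 1))))
  for (cs in cases) {
    th <- random_params(cs$model, cs$obs, seed = 9)
    en <- enumerate_ensemble(cs$model, th, cs$obs)
    expect_lt(abs(sum(en$probs) - 1), 1e-12)
    ex <- unlist(expected_constraints(cs$model, th, cs$obs),
                 use.names = FALSE)
    expect_lt(max(abs(en$expected - ex)), 1e-12)
    H <- hessian(cs$model, th, cs$obs)
    expect_lt(max(abs(H + en$cov)), 1e-12)  # fluctuation-response identity
  }
})

test_that("expected weights decompose expected strengths", {
  for (model in c("uecm", "decm", "crem_und", "crem_dir")) {
    inst <- small_instance(model)
    th <- random_params(model, inst$obs, seed = 5)
    w <- expected_weights(model, th, inst$obs, inst$marginals)
    ex <- expected_constraints(model, th, inst$obs, inst$marginals)
    sname <- if (model %in% c("uecm", "crem_und")) "s" else "s_out"
    expect_equal(unname(rowSums(w)), unname(ex[[sname]]))
  }
  # CReM pair: f = 1, rate 2 -> expected weight 1/2
  obs <- constraint_set("crem_und", s = c(1, 1))
  f <- matrix(c(0, 1, 1, 0), 2)
  w <- expected_weights("crem_und", c(1, 1), obs, f)
  expect_equal(w[1, 2], 0.5)
  # UECM: <w> = p/(1-q); q -> 0 recovers p
  obs2 <- constraint_set("uecm", k = c(1, 1), s = c(2, 2))
  thq <- c(0.3, 0.4, 10, 10)  # q = e^{-20} ~ 0
  expect_equal(expected_weights("uecm", thq, obs2)[1, 2],
               link_probabilities("uecm", thq, obs2)[1, 2],
               tolerance = 1e-8)
})

test_that("fixed-point maps fix the stationarity conditions", {
  c5 <- constraints(worked_instances()$c5, "ubcm")
  expect_equal(fixed_point_map("ubcm", rep(0, 5), c5), rep(0, 5))

  tested <- 0L
  for (model in c("ubcm", "dbcm", "bicm", "uecm", "crem_und")) {
    inst <- small_instance(model)
    fit <- solve_model(model, inst$obs, solver_config("newton"),
                       marginals = inst$marginals)
    th <- fit$params
    if (!all(is.finite(th))) next  # map undefined on degenerate nodes
    mapped <- fixed_point_map(model, th, inst$obs, inst$marginals)
    expect_lt(max(abs(mapped - th)), 1e-6)
    tested <- tested + 1L
  }
  expect_gte(tested, 3L)

  # zero constraints are rejected by the map
  obs0 <- constraint_set("ubcm", k = c(0, 1, 1))
  expect_error(fixed_point_map("ubcm", rep(0, 3), obs0), "zero")
})

test_that("initialization schemes follow their closed forms", {
  obs <- constraint_set("ubcm", k = rep(2, 5))
  expect_equal(initial_parameters("ubcm", obs, "sparse"),
               rep(-log(2 / sqrt(10)), 5))
  expect_equal(initial_parameters("ubcm", obs, "sqrtN"),
               rep(-log(2 / sqrt(5)), 5))
  u1 <- initial_parameters("ubcm", obs, "uniform", seed = 11)
  u2 <- initial_parameters("ubcm", obs, "uniform", seed = 11)
  expect_identical(u1, u2)
  expect_error(initial_parameters("ubcm", obs, "uniform"), "seed")
  # CReM floor keeps multipliers positive when the formula goes nonpositive
  obsc <- constraint_set("crem_und", s = c(100, 1, 1))
  init <- initial_parameters("crem_und", obsc, "sparse")
  expect_true(all(init >= 1e-8))
  expect_error(initial_parameters("ubcm",
                                  constraint_set("ubcm", k = c(0, 1, 1)),
                                  "sparse"), "degenerate")
})

test_that("node relabelling permutes all outputs consistently", {
  inst <- small_instance("ubcm")
  th <- random_params("ubcm", inst$obs, seed = 6)
  perm <- sample(seq_len(inst$obs$n))
  obs_p <- constraint_set("ubcm", k = inst$obs$k[perm])
  p1 <- link_probabilities("ubcm", th, inst$obs)
  p2 <- link_probabilities("ubcm", th[perm], obs_p)
  expect_equal(p2, p1[perm, perm])
  expect_equal(gradient("ubcm", th[perm], obs_p),
               gradient("ubcm", th, inst$obs)[perm])
})

test_that("gravity-model calibration reproduces the target link count", {
  # symmetric case: equal strengths s, half-density target -> z = 1/s^2
  sol <- dcgm_solve_z(rep(3, 6), 6 * 5 / 4)
  expect_equal(sol$z, 1 / 9, tolerance = 1e-8)
  expect_lt(abs(sol$expected_links - 7.5), 1e-10)

  set.seed(21)
  s <- stats::rlnorm(15, 0, 0.8)
  target <- 20
  sol <- dcgm_solve_z(s, target)
  expect_lt(abs(sol$expected_links - target), 1e-10)
  # independent plain-bisection oracle
  ss <- outer(s, s); diag(ss) <- 0
  fL <- function(z) sum(z * ss / (1 + z * ss)) / 2 - target
  lo <- 1e-12; hi <- 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (fL(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(sol$z, sqrt(lo * hi), tolerance = 1e-8)
  # a vanishing target drives z to zero; out-of-range targets are rejected
  expect_lt(dcgm_solve_z(s, 1e-6)$z, 1e-8)
  expect_error(dcgm_solve_z(s, 15 * 14 / 2), "between")
})

test_that("inadmissible enhanced-model parameters are rejected", {
  obs <- constraint_set("uecm", k = c(1, 1), s = c(2, 2))
  bad <- c(0, 0, 0.5, -0.5)  # beta_1 + beta_2 = 0
  expect_error(gradient("uecm", bad, obs), "improper|beta")
  expect_identical(log_likelihood("uecm", bad, obs), -Inf)
  expect_error(link_probabilities("uecm", bad, obs), "improper")
})
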