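test_that("step directions behave on canonical linear algebra cases", {
  g <- c(1, -2, 3)
  expect_equal(newton_step(g, -diag(3)), g)           # steepest-ascent case
  expect_equal(quasi_newton_step(4, -2), 2)

  # one Newton step maximizes a strictly concave quadratic exactly
  set.seed(1)
  A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  H <- -A
  xstar <- c(1, 2, 3)
  x0 <- c(0, 0, 0)
  grad0 <- -A %*% (x0 - xstar)
  expect_equal(x0 + newton_step(as.vector(grad0), H), xstar,
               tolerance = 1e-10)

  # quasi-Newton equals Newton when the Hessian is diagonal
  Hd <- diag(c(-2, -5, -1))
  expect_equal(quasi_newton_step(g, diag(Hd)), newton_step(g, Hd),
               tolerance = 1e-8)

  # regularized direction stays an ascent direction near singularity
  for (seed in 1:5) {
    set.seed(seed)
    B <- matrix(rnorm(16), 4)
    Hs <- -crossprod(B)
    Hs[, 4] <- Hs[, 3]; Hs[4, ] <- Hs[3, ]  # exactly singular
    gg <- rnorm(4)
    expect_gt(sum(gg * newton_step(gg, Hs)), 0)
    expect_gt(sum(gg * quasi_newton_step(gg, diag(Hs))), 0)
  }
})

test_that("Armijo backtracking accepts and shrinks as prescribed", {
  quad <- function(x) -sum(x^2) / 2
  x <- c(2, -1)
  g <- -x
  # exact Newton direction on the quadratic: unit step accepted
  expect_equal(armijo_backtracking(quad, x, g, sum(g * g)), 1)
  # a 100x overshoot must be cut at least once
  expect_lt(armijo_backtracking(quad, x, 100 * g, 100 * sum(g * g)), 1)
  expect_error(armijo_backtracking(quad, x, -g, -1), "ascent")
})

test_that("accepted steps increase the likelihood monotonically", {
  inst <- small_instance("ubcm", seed = 13)
  fit <- solve_model("ubcm", inst$obs, solver_config("newton", trace = TRUE,
                                                     use_reduction = FALSE))
  ll <- fit$trace[, "loglik"]
  expect_true(all(diff(ll) > -1e-10))
  fitq <- solve_model("uecm", small_instance("uecm", 13)$obs,
                      solver_config("quasinewton", trace = TRUE,
                                    max_iter = 200))
  expect_true(all(diff(fitq$trace[, "loglik"]) > -1e-10))
})

test_that("all methods solve the symmetric 5-cycle to theta = 0", {
  c5 <- constraints(worked_instances()$c5, "ubcm")
  for (m in c("newton", "quasinewton", "fixedpoint", "coupled")) {
    fit <- solve_model("ubcm", c5, solver_config(m))
    expect_lt(max(abs(fit$params)), 1e-6)
    expect_true(fit$converged_by %in% c("grad_norm", "step_norm"))
  }
})

test_that("methods agree on the 4-node (2,2,1,1) instance and satisfy MLE", {
  # every realization of degrees (2,2,1,1) contains the link between the two
  # degree-2 nodes, so that pair probability tends to 1 and the likelihood
  # supremum sits at the boundary: the linear methods approach it only
  # logarithmically and need a larger iteration budget than Newton
  obs <- constraints(worked_instances()$k4minus, "ubcm")
  ps <- lapply(c("newton", "quasinewton", "fixedpoint"), function(m) {
    fit <- solve_model("ubcm", obs, solver_config(m, max_iter = 200000))
    fitted_values(fit, obs)$p
  })
  expect_lt(max(abs(ps[[1]] - ps[[2]])), 1e-5)
  expect_lt(max(abs(ps[[1]] - ps[[3]])), 1e-5)
  expect_lt(max(abs(rowSums(ps[[1]]) - obs$k)), 1e-8)
  # the enumeration oracle confirms expectations at the Newton solution
  fit <- solve_model("ubcm", obs)
  en <- enumerate_ensemble("ubcm", fit$params, obs)
  expect_lt(max(abs(en$expected - obs$k)), 1e-8)
})

test_that("degenerate nodes are resolved analytically", {
  wi <- worked_instances()
  hub <- constraints(wi$hub4, "ubcm")
  fit <- solve_model("ubcm", hub)
  fv <- fitted_values(fit, hub)
  expect_equal(unname(fv$expected$k), c(3, 1, 1, 1))
  expect_equal(fv$p[1, 2:4], rep(1, 3))
  expect_equal(fv$p[2, 3], 0)

  iso <- constraints(wi$iso3, "ubcm")
  fiti <- solve_model("ubcm", iso)
  expect_equal(unname(fitted_values(fiti, iso)$expected$k), c(1, 1, 0))
  expect_true(is.infinite(fiti$params[3]))

  # directed 2-cycle: both out-degrees saturated -> explicit error
  a <- matrix(c(0, 1, 1, 0), 2)
  expect_error(solve_model("dbcm", constraints(
    binary_graph(a, directed = TRUE), "dbcm")), "saturated")

  # a node degenerate on one side only is dropped from that side
  kd <- constraint_set("dbcm", k_out = c(2, 1, 0, 1), k_in = c(1, 1, 1, 1))
  fitd <- solve_model("dbcm", kd)
  expect_true(is.infinite(fitd$params[3]))          # alpha_3 = +Inf
  expect_true(all(is.finite(fitd$params[5:8])))     # all beta finite
  fvd <- fitted_values(fitd, kd)
  expect_lt(max(abs(unlist(fvd$expected) - c(kd$k_out, kd$k_in))), 1e-6)
})

test_that("MLE self-consistency holds after sampling from known parameters", {
  # fit a model, sample one graph from it, refit on the realization: the
  # refitted expectations must match the realized constraints
  inst <- small_instance("ubcm", seed = 17)
  fit <- solve_model("ubcm", inst$obs)
  g <- sample_ensemble(ensemble_spec("ubcm", fit$params, inst$obs,
                                     n_samples = 1, seed = 99))[[1]]
  obs2 <- constraints(g, "ubcm")
  fit2 <- solve_model("ubcm", obs2)
  fv <- fitted_values(fit2, obs2)
  expect_lt(max(abs(fv$expected$k - obs2$k)), 1e-6)
})

test_that("CReM rescaling is exact and kappa = 1 is the identity", {
  inst <- small_instance("crem_und", seed = 18)
  base <- solve_model("crem_und", inst$obs, marginals = inst$marginals)
  k1 <- crem_rescaled_solve("crem_und", inst$obs, 1,
                            marginals = inst$marginals)
  k10 <- crem_rescaled_solve("crem_und", inst$obs, 10,
                             marginals = inst$marginals)
  expect_equal(base$params, k1$params, tolerance = 1e-12)
  expect_lt(max(abs(k10$params - k1$params)), 1e-8)
  ex <- fitted_values(k10, inst$obs, inst$marginals)$expected$s
  expect_lt(max(abs(ex - inst$obs$s)), 1e-6)
})

test_that("the fixed-point recipe reports honest status on enhanced models", {
  inst <- small_instance("uecm", seed = 19)
  fit <- solve_model("uecm", inst$obs,
                     solver_config("fixedpoint", max_iter = 500))
  expect_true(fit$converged_by %in%
                c("grad_norm", "step_norm", "max_iter", "diverged"))
  # whatever happened is recorded, never silently wrong
  expect_true(is.finite(fit$final_grad_norm))
})

test_that("coupled solver terminates immediately after a converged phase 1", {
  c5 <- constraints(worked_instances()$c5, "ubcm")
  fit <- coupled_solve("ubcm", c5)
  fp <- fixed_point_solve("ubcm", c5)
  expect_lte(fit$iterations, fp$iterations + 1L)
  expect_true(fit$converged_by %in% c("grad_norm", "step_norm"))
})

test_that("fully degenerate inputs return a fully resolved result", {
  obs <- constraint_set("ubcm", k = c(0, 0, 0))
  fit <- solve_model("ubcm", obs)
  expect_identical(fit$iterations, 0L)
  expect_true(all(is.infinite(fit$params)))
  expect_equal(unname(fitted_values(fit, obs)$expected$k), c(0, 0, 0))
})
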