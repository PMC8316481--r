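test_that("sampling is bit-reproducible given a spec", {
  inst <- small_instance("ubcm")
  fit <- solve_model("ubcm", inst$obs)
  spec <- ensemble_spec("ubcm", fit$params, inst$obs, n_samples = 3,
                        seed = 42)
  s1 <- sample_ensemble(spec)
  s2 <- sample_ensemble(spec)
  for (i in 1:3) expect_identical(s1[[i]]$mat, s2[[i]]$mat)
})

test_that("degenerate probabilities produce deterministic samples", {
  # theta = -Inf on every node -> all pair probabilities exactly 1
  obs <- constraint_set("ubcm", k = c(3, 3, 3, 3))
  full <- sample_ensemble(ensemble_spec("ubcm", rep(-Inf, 4), obs,
                                        n_samples = 2, seed = 1))
  for (g in full) expect_equal(degrees(g), rep(3, 4))
  empty <- sample_ensemble(ensemble_spec("ubcm", rep(Inf, 4),
                                         constraint_set("ubcm", k = rep(0, 4)),
                                         n_samples = 2, seed = 1))
  for (g in empty) expect_equal(degrees(g), rep(0, 4))
})

test_that("binary sampling reproduces binomial moments", {
  # all p = 1/2 on 10 nodes: 45 pairs, mean link count 22.5, sd sqrt(45)/2
  obs <- constraint_set("ubcm", k = rep(4, 10))
  samples <- sample_ensemble(ensemble_spec("ubcm", rep(0, 10), obs,
                                           n_samples = 10000, seed = 7))
  counts <- vapply(samples, function(g) sum(g$mat) / 2, numeric(1))
  se <- sqrt(45 / 4) / sqrt(10000)
  expect_lt(abs(mean(counts) - 22.5), 4 * se)
})

test_that("enhanced sampling follows the Bernoulli-geometric pair law", {
  # q -> 0 (huge strength multipliers): every realized link has weight 1
  obs <- constraint_set("uecm", k = c(2, 2, 2), s = c(4, 4, 4))
  th <- c(rep(-3, 3), rep(8, 3))
  s <- sample_ensemble(ensemble_spec("uecm", th, obs, n_samples = 5,
                                     seed = 3))
  for (g in s) expect_true(all(g$mat %in% c(0, 1)))

  # moderate q: empirical pair mean within 4 SE of p/(1-q)
  th2 <- c(rep(0.5, 3), rep(0.6, 3))
  p <- link_probabilities("uecm", th2, obs)[1, 2]
  q <- exp(-1.2)
  nsamp <- 10000
  s2 <- sample_ensemble(ensemble_spec("uecm", th2, obs, n_samples = nsamp,
                                      seed = 4))
  w12 <- vapply(s2, function(g) g$mat[1, 2], numeric(1))
  mean_w <- p / (1 - q)
  var_w <- (p * (1 + q) - p^2) / (1 - q)^2
  expect_lt(abs(mean(w12) - mean_w), 4 * sqrt(var_w / nsamp))
  # weights vanish exactly off the sampled support
  for (g in s2[1:50]) {
    expect_true(all((g$mat > 0) == (binarize(g)$mat == 1)))
  }
})

test_that("conditional exponential sampling matches its moments", {
  obs <- constraint_set("crem_und", s = c(1, 1))
  f <- matrix(c(0, 1, 1, 0), 2)
  th <- c(1, 1)  # rate 2 on the only pair
  nsamp <- 10000
  s <- sample_ensemble(ensemble_spec("crem_und", th, obs, n_samples = nsamp,
                                     seed = 5, marginals = f))
  w <- vapply(s, function(g) g$mat[1, 2], numeric(1))
  expect_true(all(w > 0))  # f = 1: the link always exists
  expect_lt(abs(mean(w) - 0.5), 4 * sqrt(0.25 / nsamp))

  f0 <- matrix(0, 2, 2)
  s0 <- sample_ensemble(ensemble_spec("crem_und", th, obs, n_samples = 3,
                                      seed = 5, marginals = f0))
  for (g in s0) expect_true(all(g$mat == 0))
})

test_that("ensemble validation flags agreement via analytic z-scores", {
  inst <- small_instance("ubcm", seed = 23)
  fit <- solve_model("ubcm", inst$obs)
  samples <- sample_ensemble(ensemble_spec("ubcm", fit$params, inst$obs,
                                           n_samples = 3000, seed = 11))
  rep <- validate_ensemble(samples, "ubcm", fit$params, inst$obs)
  z <- rep$z[!is.na(rep$z)]
  expect_gte(mean(abs(z) <= 4), 0.99)
  expect_identical(rep, validate_ensemble(samples, "ubcm", fit$params,
                                          inst$obs))
})
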