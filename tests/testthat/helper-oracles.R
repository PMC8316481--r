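# Shared helpers: finite-difference oracles and small seeded instances.

fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

fd_jacobian <- function(g, x, h = 1e-6) {
  cols <- lapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (g(x + e) - g(x - e)) / (2 * h)
  })
  do.call(cbind, cols)
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1, max(abs(b)))
}

# Small non-degenerate instances per model: constraint set (+ marginals for
# the CReM models), built from seeded generated graphs.
small_instance <- function(model, seed = 7) {
  switch(model,
    ubcm = list(obs = constraints(
      generate_binary(12, density = 0.3, heterogeneity = 0.6, seed = seed),
      "ubcm")),
    dbcm = list(obs = constraints(
      generate_binary(12, directed = TRUE, density = 0.35,
                      heterogeneity = 0.4, seed = seed), "dbcm")),
    bicm = list(obs = constraints(
      generate_binary(8, bipartite = TRUE, n_top = 10, density = 0.35,
                      heterogeneity = 0.4, seed = seed), "bicm")),
    uecm = list(obs = constraints(
      generate_weighted(12, density = 0.35, mean_weight = 3, seed = seed),
      "uecm")),
    decm = list(obs = constraints(
      generate_weighted(12, directed = TRUE, density = 0.35, mean_weight = 3,
                        seed = seed), "decm")),
    crem_und = {
      g <- generate_weighted(12, domain = "real", density = 0.35,
                             mean_weight = 2, seed = seed)
      sup <- constraints(binarize(g), "ubcm")
      fit <- solve_model("ubcm", sup)
      list(obs = constraints(g, "crem_und"),
           marginals = fitted_values(fit, sup)$p)
    },
    crem_dir = {
      g <- generate_weighted(12, directed = TRUE, domain = "real",
                             density = 0.35, mean_weight = 2, seed = seed)
      sup <- constraints(binarize(g), "dbcm")
      fit <- solve_model("dbcm", sup)
      list(obs = constraints(g, "crem_dir"),
           marginals = fitted_values(fit, sup)$p)
    })
}

# Admissible random parameter vectors for evaluating analytic derivatives.
random_params <- function(model, obs, seed = 1) {
  set.seed(seed)
  n <- switch(model, bicm = obs$n_bottom + obs$n_top, obs$n)
  switch(model,
    ubcm = stats::runif(n, -0.5, 1.5),
    dbcm = stats::runif(2 * n, -0.5, 1.5),
    bicm = stats::runif(n, -0.5, 1.5),
    uecm = c(stats::runif(n, -0.5, 1.5), stats::runif(n, 0.2, 1.5)),
    decm = c(stats::runif(2 * n, -0.5, 1.5), stats::runif(2 * n, 0.2, 1.5)),
    crem_und = stats::runif(n, 0.3, 2),
    crem_dir = stats::runif(2 * n, 0.3, 2))
}
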