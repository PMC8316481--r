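#' Seeded synthetic graph generators
#'
#' Every solver in this package is exercised on graphs produced here, so the
#' fitted constraint sequences are always graphical by construction. The
#' binary generator draws from a gravity-model link law
#' `p_ij = z x_i x_j / (1 + z x_i x_j)` with deterministic power-spread
#' latent fitnesses `x_i = (i / (n+1))^(-heterogeneity)`, guaranteeing proper
#' probabilities for any heterogeneity; `z` is calibrated so the expected
#' link count matches `density` times the number of pairs. Heterogeneity 0
#' collapses to an Erdos-Renyi-like graph with all pair probabilities equal.
#' Directed and bipartite variants use independent (seed-permuted) fitness
#' vectors per side/layer.
#'
#' @param n number of nodes (bottom-layer nodes for bipartite).
#' @param n_top top-layer size (bipartite only).
#' @param directed generate a directed graph.
#' @param bipartite generate a bipartite graph.
#' @param density target connectance in (0, 1).
#' @param heterogeneity non-negative spread exponent of the latent fitnesses.
#' @param seed integer seed; generation is bit-reproducible.
#' @return a `maxent_graph`.
#' @export
generate_binary <- function(n, directed = FALSE, bipartite = FALSE,
                            n_top = n, density = 0.1, heterogeneity = 0.5,
                            seed = 1L) {
  stopifnot(density > 0, density < 1, heterogeneity >= 0, n >= 2L)
  set.seed(as.integer(seed))
  fit <- function(m) (seq_len(m) / (m + 1))^(-heterogeneity)
  if (bipartite) {
    x <- sample(fit(n)); y <- sample(fit(n_top))
    p <- calibrated_p(outer(x, y), density * n * n_top)
    u <- draw_uniform(n, n_top)
    return(bipartite_graph((u < p) + 0))
  }
  if (directed) {
    x <- sample(fit(n)); y <- sample(fit(n))
    ss <- outer(x, y); diag(ss) <- 0
    p <- calibrated_p(ss, density * n * (n - 1))
    u <- draw_uniform(n, n)
    a <- (u < p) + 0
    diag(a) <- 0
    return(binary_graph(a, directed = TRUE))
  }
  x <- fit(n)
  ss <- outer(x, x); diag(ss) <- 0
  p <- calibrated_p(ss, density * n * (n - 1))  # ordered-pair target
  u <- draw_uniform(n, n)
  a <- (u < p) + 0
  a[lower.tri(a, diag = TRUE)] <- 0
  binary_graph(a + t(a), directed = FALSE)
}

# Scale the gravity kernel so that sum(p) hits the target pair count.
calibrated_p <- function(ss, target) {
  stopifnot(target > 0, target < sum(ss > 0))
  g <- function(z) sum(z * ss / (1 + z * ss))
  lo <- 1e-12; hi <- 1
  while (g(hi) < target) hi <- hi * 10
  while (g(lo) > target) lo <- lo / 10
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (g(mid) < target) lo <- mid else hi <- mid
  }
  z <- sqrt(lo * hi)
  z * ss / (1 + z * ss)
}

#' @rdname generate_binary
#' @param domain `"integer"` (geometric weight layer on the sampled links) or
#'   `"real"` (exponential weight layer).
#' @param mean_weight target mean weight per realized link (> 1 for the
#'   integer domain, whose weights start at 1).
#' @return `generate_weighted()`: a weighted `maxent_graph` whose weights are
#'   positive exactly on the sampled binary support.
#' @export
generate_weighted <- function(n, directed = FALSE,
                              domain = c("integer", "real"),
                              density = 0.1, heterogeneity = 0.5,
                              mean_weight = 3, seed = 1L) {
  domain <- match.arg(domain)
  g <- generate_binary(n, directed = directed, density = density,
                       heterogeneity = heterogeneity, seed = seed)
  a <- g$mat
  u <- draw_uniform(n, n)  # continues the seeded stream
  if (domain == "integer") {
    stopifnot(mean_weight >= 1)
    q <- 1 - 1 / mean_weight
    extra <- if (q > 0) floor(log(1 - u) / log(q)) else 0 * u
    w <- a * (1 + extra)
  } else {
    w <- a * (-log(1 - u) * mean_weight)
  }
  if (!directed) {
    w[lower.tri(w, diag = TRUE)] <- 0
    w <- w + t(w)
  }
  diag(w) <- 0
  weighted_graph(w, directed = directed, domain = domain)
}

#' Catalogue of tiny named worked instances
#'
#' Deterministic miniature graphs used throughout the test suite and the
#' examples: `c5` (the 5-cycle, whose degree-model solution is exactly
#' theta = 0), `path4` (the 4-node path), `bip23` (a 2 x 3 bipartite graph
#' with one missing link), `k4minus` (4 nodes with degrees 2, 2, 1, 1),
#' `hub4` (a star, exercising the saturated-hub analytic resolution),
#' `iso3` (an edge plus an isolated node, exercising the zero-degree
#' resolution), and `wtri` (a weighted triangle with integer weights).
#'
#' @return named list of `maxent_graph` objects.
#' @export
worked_instances <- function() {
  cyc <- function(n) {
    a <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i %% n + 1L
      a[i, j] <- 1; a[j, i] <- 1
    }
    a
  }
  path4 <- matrix(0, 4, 4)
  path4[cbind(1:3, 2:4)] <- 1
  path4 <- path4 + t(path4)
  k4minus <- matrix(0, 4, 4)
  k4minus[cbind(c(1, 1, 2), c(2, 3, 4))] <- 1
  k4minus <- k4minus + t(k4minus)
  hub4 <- matrix(0, 4, 4)
  hub4[1, 2:4] <- 1
  hub4 <- hub4 + t(hub4)
  iso3 <- matrix(0, 3, 3)
  iso3[1, 2] <- iso3[2, 1] <- 1
  wtri <- matrix(c(0, 2, 1, 2, 0, 3, 1, 3, 0), 3)
  list(
    c5 = binary_graph(cyc(5)),
    path4 = binary_graph(path4),
    bip23 = bipartite_graph(rbind(c(1, 1, 0), c(0, 1, 1))),
    k4minus = binary_graph(k4minus),
    hub4 = binary_graph(hub4),
    iso3 = binary_graph(iso3),
    wtri = weighted_graph(wtri, domain = "integer")
  )
}
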