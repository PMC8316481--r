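test_that("degree and strength extraction match hand-computed values", {
  tri <- binary_graph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  expect_equal(degrees(tri), c(2, 2, 2))

  path <- worked_instances()$path4
  expect_equal(degrees(path), c(1, 2, 2, 1))
  expect_equal(degrees(binary_graph(matrix(0, 3, 3))), c(0, 0, 0))

  a <- matrix(0, 2, 2); a[1, 2] <- 1; a[2, 1] <- 1
  d <- directed_degrees(binary_graph(a, directed = TRUE))
  expect_equal(d$out, c(1, 1))
  expect_equal(d$`in`, c(1, 1))
  a2 <- matrix(0, 2, 2); a2[1, 2] <- 1
  d2 <- directed_degrees(binary_graph(a2, directed = TRUE))
  expect_equal(d2$out, c(1, 0))
  expect_equal(d2$`in`, c(0, 1))

  bd <- bipartite_degrees(bipartite_graph(matrix(1, 2, 3)))
  expect_equal(bd$bottom, c(3, 3))
  expect_equal(bd$top, c(2, 2, 2))
  b1 <- matrix(0, 2, 3); b1[1, 1] <- 1
  bd1 <- bipartite_degrees(bipartite_graph(b1))
  expect_equal(bd1$bottom, c(1, 0))
  expect_equal(bd1$top, c(1, 0, 0))

  wt <- weighted_graph(matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3),
                       domain = "integer")
  expect_equal(strengths(wt), c(4, 4, 4))
  w1 <- matrix(0, 3, 3); w1[1, 2] <- w1[2, 1] <- 3.5
  expect_equal(strengths(weighted_graph(w1, domain = "real")), c(3.5, 3.5, 0))
})

test_that("graph containers validate their invariants", {
  expect_error(binary_graph(diag(3)), "self-loop")
  expect_error(binary_graph(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(binary_graph(matrix(c(0, 2, 2, 0), 2)), "0 or 1")
  expect_error(weighted_graph(matrix(c(0, -1, -1, 0), 2)), "negative")
  expect_error(weighted_graph(matrix(c(0, 1.5, 1.5, 0), 2),
                              domain = "integer"), "integer")
})

test_that("binarize takes the Heaviside support and is idempotent", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.3
  g <- binarize(weighted_graph(w, domain = "real"))
  expect_equal(g$mat[1, 2], 1)
  expect_equal(g$mat[1, 3], 0)
  expect_identical(binarize(g)$mat, g$mat)
  gw <- generate_weighted(15, density = 0.3, seed = 2)
  expect_equal(degrees(binarize(gw)), degrees(gw))
})

test_that("round_weights rounds half away from zero and drops null edges", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 2.4
  w[1, 3] <- w[3, 1] <- 2.6
  w[1, 4] <- w[4, 1] <- 0.4
  w[2, 3] <- w[3, 2] <- 2.5
  r <- round_weights(weighted_graph(w, domain = "real"))
  expect_equal(r$mat[1, 2], 2)
  expect_equal(r$mat[1, 3], 3)
  expect_equal(r$mat[1, 4], 0)   # edge dropped
  expect_equal(r$mat[2, 3], 3)   # tie away from zero
  r2 <- round_weights(weighted_graph(w, domain = "real"), ties = "even")
  expect_equal(r2$mat[2, 3], 2)  # banker's rounding under the alternate rule
  expect_identical(r$domain, "integer")
})

test_that("edge-list round trips preserve graphs and dialect is tolerant", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)

  writeLines(c("# comment", "a b", "", "b,c"), tmp)
  g <- read_edge_list(tmp)
  expect_equal(degrees(g), c(1, 2, 1))
  expect_equal(g$labels, c("a", "b", "c"))

  writeLines("a b 2.5", tmp)
  gw <- read_edge_list(tmp, weighted = TRUE)
  expect_equal(gw$mat[1, 2], 2.5)

  writeLines(c("a b", "a a"), tmp)
  expect_error(read_edge_list(tmp), "self-loop at line 2")
  writeLines(c("a b", "c"), tmp)
  expect_error(read_edge_list(tmp), "line 2")

  # duplicates merge: weights sum, binary ORs (including reversed pairs)
  writeLines(c("a b 1.5", "b a 2"), tmp)
  expect_equal(read_edge_list(tmp, weighted = TRUE)$mat[1, 2], 3.5)
  writeLines(c("a b", "b a", "a b"), tmp)
  expect_equal(read_edge_list(tmp)$mat[1, 2], 1)

  for (spec in list(list(g = generate_binary(10, density = 0.3, seed = 5),
                         dir = FALSE, wt = FALSE),
                    list(g = generate_binary(10, directed = TRUE,
                                             density = 0.3, seed = 5),
                         dir = TRUE, wt = FALSE),
                    list(g = generate_weighted(10, density = 0.3,
                                               domain = "real", seed = 5),
                         dir = FALSE, wt = TRUE))) {
    write_edge_list(spec$g, tmp)
    back <- read_edge_list(tmp, directed = spec$dir, weighted = spec$wt)
    ord <- match(spec$g$labels, back$labels)
    keep <- !is.na(ord)  # fully isolated nodes have no edges to carry them
    expect_equal(back$mat[ord[keep], ord[keep]],
                 spec$g$mat[keep, keep, drop = FALSE])
  }

  bg <- generate_binary(5, bipartite = TRUE, n_top = 7, density = 0.4,
                        seed = 6)
  write_edge_list(bg, tmp)
  back <- read_edge_list(tmp, bipartite = TRUE)
  ob <- match(bg$labels$bottom, back$labels$bottom)
  ot <- match(bg$labels$top, back$labels$top)
  kb <- !is.na(ob); kt <- !is.na(ot)
  expect_equal(back$mat[ob[kb], ot[kt]], bg$mat[kb, kt, drop = FALSE])
})

test_that("dense matrix text round trip is exact", {
  m <- matrix(c(0, 0.12345678901234, 2, 0), 2)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  write_dense_matrix(m, tmp)
  expect_equal(read_dense_matrix(tmp), m)
})

test_that("constraint sets satisfy the sum identities on generated graphs", {
  for (seed in 1:3) {
    g <- generate_binary(20, density = 0.2, seed = seed)
    cs <- constraints(g, "ubcm")
    expect_equal(sum(cs$k), 2 * cs$L)

    gd <- generate_binary(20, directed = TRUE, density = 0.2, seed = seed)
    csd <- constraints(gd, "dbcm")
    expect_equal(sum(csd$k_out), sum(csd$k_in))

    gw <- generate_weighted(20, density = 0.2, seed = seed)
    csw <- constraints(gw, "uecm")
    expect_equal(sum(csw$s), 2 * csw$W)

    gb <- generate_binary(8, bipartite = TRUE, n_top = 12, density = 0.3,
                          seed = seed)
    csb <- constraints(gb, "bicm")
    expect_equal(sum(csb$k_bottom), sum(csb$d_top))
  }
})
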