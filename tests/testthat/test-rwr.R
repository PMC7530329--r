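test_that("column normalization produces 1/degree columns summing to one", {
  edge <- igraph::graph_from_edgelist(cbind("a", "b"), directed = FALSE)
  W <- column_normalize(edge)
  expect_equal(as.matrix(W), matrix(c(0, 1, 1, 0), 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b"))))
  star <- igraph::graph_from_edgelist(
    cbind("hub", c("l1", "l2", "l3")), directed = FALSE)
  W <- column_normalize(star)
  expect_equal(unname(W["l1", "hub"]), 1 / 3)
  expect_equal(unname(W["hub", "l1"]), 1)
  expect_equal(unname(Matrix::colSums(W)), rep(1, 4))

  g <- star + igraph::vertices("z")
  expect_warning(W2 <- column_normalize(g), "isolated")
  expect_false("z" %in% colnames(W2))
})

test_that("the single-edge walk seeded at one node reaches (2/3, 1/3)", {
  edge <- igraph::graph_from_edgelist(cbind("a", "b"), directed = FALSE)
  p <- rwr_propagate(column_normalize(edge), "a", r = 0.5)
  expect_equal(unname(p), c(2 / 3, 1 / 3), tolerance = 1e-8)
})

test_that("seeding every node of a regular graph gives the uniform fixed point", {
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- sprintf("v%d", 1:6)
  p <- rwr_propagate(column_normalize(ring), sprintf("v%d", 1:6))
  expect_equal(unname(p), rep(1 / 6, 6), tolerance = 1e-9)
})

test_that("as the restart probability approaches 1 the walk stays at the seeds", {
  set.seed(9)
  g <- random_connected_graph(12)
  W <- column_normalize(g)
  p <- rwr_propagate(W, c("V001", "V002"), r = 0.999999)
  p0 <- setNames(numeric(12), colnames(W))
  p0[c("V001", "V002")] <- 0.5
  expect_equal(unname(p), unname(p0[names(p)]), tolerance = 1e-4)
})

test_that("iteration agrees with the direct linear solve and conserves mass", {
  set.seed(10)
  for (i in 1:5) {
    g <- random_connected_graph(sample(10:60, 1))
    W <- column_normalize(g)
    seeds <- sample(colnames(W), 3)
    p <- rwr_propagate(W, seeds, r = 0.5)
    expect_equal(sum(p), 1, tolerance = 1e-8)
    expect_equal(unname(p), unname(rwr_solve_oracle(W, seeds, 0.5)),
                 tolerance = 1e-8)
  }
})

test_that("steady probability decays with distance from the seed on a path", {
  path <- igraph::graph_from_edgelist(
    cbind(sprintf("p%d", 1:7), sprintf("p%d", 2:8)), directed = FALSE)
  p <- rwr_propagate(column_normalize(path), "p1")
  expect_true(all(diff(unname(p[sprintf("p%d", 1:8)])) <= 1e-12))
})

test_that("seed validation warns on dropped seeds and errors when none remain", {
  edge <- igraph::graph_from_edgelist(cbind("a", "b"), directed = FALSE)
  W <- column_normalize(edge)
  expect_warning(p <- rwr_propagate(W, c("a", "nope")), "dropped")
  expect_equal(unname(p), c(2 / 3, 1 / 3), tolerance = 1e-8)
  expect_error(suppressWarnings(rwr_propagate(W, "nope")), "no seed gene")
})

test_that("permutation p-values are reproducible and respect exchangeability", {
  set.seed(12)
  g <- random_connected_bipartite(6, 12, p = 0.3)
  seeds <- c("G01", "G02", "G03")
  a <- suppressWarnings(
    rwr_significance(g, seeds, n_perm = 100, rng_seed = 42))
  b <- suppressWarnings(
    rwr_significance(g, seeds, n_perm = 100, rng_seed = 42))
  expect_identical(a$candidates, b$candidates)
  expect_true(all(a$candidates$perm_p >= 0 & a$candidates$perm_p <= 1))
  expect_equal(a$candidates$perm_p, a$candidates$m_exceed / 100)
  # ascending order by permutation p
  expect_true(all(diff(a$candidates$perm_p) >= 0))

  # two lncRNAs with identical neighborhoods are exchangeable
  sym <- toy_lclmn(lnc = c("L1", "L1", "L2", "L2"),
                   mrna = c("G1", "G2", "G1", "G2"))
  res <- rwr_significance(sym, "G1", n_perm = 50, rng_seed = 7)
  expect_equal(res$candidates$perm_p[res$candidates$node == "L1"],
               res$candidates$perm_p[res$candidates$node == "L2"])
})

test_that("a candidate above every permuted score gets p = 0", {
  # G1 touches only HUB, every other mRNA splits its mass with L2, so
  # seeding G1 maximizes HUB's score over every possible pseudo-seed;
  # redrawing G1 itself reproduces the identical walk (a tie, not an excess)
  net <- toy_lclmn(lnc = c(rep("HUB", 4), rep("L2", 3)),
                   mrna = c(sprintf("G%d", 1:4), sprintf("G%d", 2:4)))
  res <- rwr_significance(net, "G1", n_perm = 60, rng_seed = 3)
  expect_equal(res$candidates$perm_p[res$candidates$node == "HUB"], 0)
})

test_that("infeasible permutations and missing class attributes error", {
  net <- toy_lclmn(lnc = c("L1", "L2"), mrna = c("G1", "G1"))
  expect_error(rwr_significance(net, "G1", n_perm = 10), NA)
  # more seeds than eligible mRNA nodes
  g <- as_igraph(net)
  expect_error(
    suppressWarnings(
      rwr_significance(g, c("G1", "L1"), n_perm = 10)),
    "infeasible")
  g2 <- igraph::delete_vertex_attr(g, "class")
  expect_error(rwr_significance(g2, "G1", n_perm = 10), "class")
})

test_that("degree-preserving rewiring is available as an alternative null", {
  set.seed(14)
  g <- random_connected_bipartite(5, 10, p = 0.35)
  res <- rwr_significance(g, c("G01", "G02"), n_perm = 20, rng_seed = 5,
                          scheme = "rewire")
  expect_equal(nrow(res$candidates), 5L)
  expect_true(all(res$candidates$perm_p >= 0 & res$candidates$perm_p <= 1))
})
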