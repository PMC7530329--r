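etab <- function(genes, mirs) data.frame(gene_id = genes, mirna_id = mirs,
                                         stringsAsFactors = FALSE)

test_that("merging two single-edge tables yields the minimal triple network", {
  g <- build_global_network(etab("L1", "mi1"), etab("G1", "mi2"))
  expect_equal(g$lnc_nodes, "L1")
  expect_equal(g$mrna_nodes, "G1")
  expect_setequal(g$mirna_nodes, c("mi1", "mi2"))
  expect_equal(nrow(g$lnc_mi) + nrow(g$mrna_mi), 2L)
})

test_that("duplicate input rows do not change edge counts (set semantics)", {
  g <- build_global_network(etab(c("L1", "L1", "L1"), c("mi1", "mi1", "mi2")),
                            etab("G1", "mi1"))
  expect_equal(nrow(g$lnc_mi), 2L)
})

test_that("class collisions and malformed ids are rejected", {
  expect_error(build_global_network(etab("X1", "mi1"), etab("X1", "mi2")),
               "both lncRNA and mRNA")
  expect_error(build_global_network(etab("L1", "L1"), etab("G1", "mi1")),
               "self-pairs")
  expect_error(build_global_network(etab("L1", ""), etab("G1", "mi1")),
               "empty or missing")
  expect_error(build_global_network(etab("mi1", "x"), etab("G1", "mi1")),
               "both gene and miRNA")
})

test_that("node and edge counts match the generator's records", {
  cfg <- sim_config(n_lnc = 15, n_mrna = 60, n_mirna = 40,
                    n_pairs_samples = 4, n_planted_cerna = 4, seed = 13)
  sim <- simulate_expression(cfg)
  inter <- simulate_interactions(cfg, sim$truth)
  g <- build_global_network(inter$lnc_mi, inter$mrna_mi)
  expect_equal(nrow(g$lnc_mi), nrow(inter$lnc_mi))
  expect_equal(nrow(g$mrna_mi), nrow(inter$mrna_mi))
  expect_setequal(g$lnc_nodes, unique(inter$lnc_mi$gene_id))
  expect_setequal(g$mrna_nodes, unique(inter$mrna_mi$gene_id))
})

test_that("DE restriction keeps incident edges and live miRNAs only", {
  g <- build_global_network(
    etab(rep("L1", 3), c("mi1", "mi2", "mi3")),
    etab(c("G1", "G2"), c("mi1", "mi4")))

  all_in <- extract_de_subnetwork(g, "L1", c("G1", "G2"))
  expect_equal(all_in[names(all_in)], g[names(g)])

  none <- extract_de_subnetwork(g, character(0), character(0))
  expect_length(none$lnc_nodes, 0L)
  expect_length(none$mirna_nodes, 0L)
  expect_equal(nrow(none$lnc_mi), 0L)

  lnc_only <- extract_de_subnetwork(g, "L1", character(0))
  expect_equal(lnc_only$lnc_nodes, "L1")
  expect_setequal(lnc_only$mirna_nodes, c("mi1", "mi2", "mi3"))
  expect_length(lnc_only$mrna_nodes, 0L)
  expect_equal(nrow(lnc_only$lnc_mi), 3L)
})

test_that("hypergeometric tail matches hand enumeration and boundary identities", {
  # 3 of the C(5,2) = 10 two-subsets contain >= 2 of the mRNA's 3 partners
  expect_equal(hypergeom_pvalue(t = 3, n = 2, r = 2, m = 5), 0.3,
               tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(t = 4, n = 3, r = 0, m = 10), 1)
  expect_equal(hypergeom_pvalue(t = 7, n = 3, r = 3, m = 7), 1)
  expect_error(hypergeom_pvalue(t = 5, n = 2, r = 3, m = 10), "min\\(t, n\\)")
  expect_error(hypergeom_pvalue(t = 11, n = 2, r = 1, m = 10), "universe")
})

test_that("the tail is monotone in r and t and complements the CDF", {
  for (m in c(8, 20)) {
    t <- 5; n <- 4
    p_r <- hypergeom_pvalue(t, n, 0:min(t, n), m)
    expect_true(all(diff(p_r) <= 1e-14))
    p_t <- hypergeom_pvalue(2:m, n, 2, m)
    expect_true(all(diff(p_t) >= -1e-14))
    expect_equal(hypergeom_pvalue(t, n, 3, m) + phyper(2, t, m - t, n), 1,
                 tolerance = 1e-12)
  }
})

test_that("pair scoring excludes disjoint pairs and BH-corrects the rest", {
  g <- build_global_network(
    etab(rep(c("L1", "L2"), c(3, 2)), c("mi1", "mi2", "mi3", "mi4", "mi5")),
    etab(rep("G1", 2), c("mi1", "mi2")))
  de <- extract_de_subnetwork(g, c("L1", "L2"), "G1")
  pairs <- score_cerna_pairs(de, g)
  # L2 shares nothing with G1
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$lnc, "L1")
  expect_equal(c(pairs$t, pairs$n, pairs$r, pairs$m), c(2L, 3L, 2L, 5L))
  # a single scored pair: BH leaves p unchanged
  expect_equal(pairs$adjusted_p, pairs$p)
  expect_equal(pairs$p, hypergeom_pvalue(2, 3, 2, 5))
})

test_that("planted ceRNA pairs score lower than background pairs", {
  cfg <- sim_config(n_lnc = 30, n_mrna = 120, n_mirna = 200,
                    n_pairs_samples = 4, n_planted_cerna = 10,
                    shared_mirna_boost = 8, background_degree = 5, seed = 17)
  sim <- simulate_expression(cfg)
  inter <- simulate_interactions(cfg, sim$truth)
  g <- build_global_network(inter$lnc_mi, inter$mrna_mi)
  de <- extract_de_subnetwork(g, sim$truth$de_lnc_ids, sim$truth$de_mrna_ids)
  pairs <- score_cerna_pairs(de, g)
  planted <- paste(sim$truth$planted_pairs$lnc, sim$truth$planted_pairs$mrna)
  is_planted <- paste(pairs$lnc, pairs$mrna) %in% planted
  expect_lt(mean(pairs$adjusted_p[is_planted]),
            mean(pairs$adjusted_p[!is_planted]))
})

test_that("the ceRNA network honors the adjusted-p threshold", {
  pairs <- data.frame(
    lnc = c("L1", "L2"), mrna = c("G1", "G2"), t = 2L, n = 2L, r = 1L,
    m = 10L, p = c(0.001, 0.5), adjusted_p = c(0.002, 0.5))
  none <- build_lclmn(pairs, alpha = 0.001)
  expect_equal(nrow(none$pairs), 0L)
  expect_length(none$lnc_nodes, 0L)
  all_of_them <- build_lclmn(pairs, alpha = 1.0000001)
  expect_equal(nrow(all_of_them$pairs), 2L)
  some <- build_lclmn(pairs, alpha = 0.01)
  expect_equal(some$pairs$lnc, "L1")
  # no isolated nodes by construction
  expect_setequal(some$lnc_nodes, unique(some$pairs$lnc))
  expect_setequal(some$mrna_nodes, unique(some$pairs$mrna))
})
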