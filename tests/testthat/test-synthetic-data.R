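test_that("generators are reproducible from the seed and sensitive to it", {
  cfg <- sim_config(n_lnc = 20, n_mrna = 80, n_mirna = 50,
                    n_pairs_samples = 5, n_planted_cerna = 5, seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  ia <- simulate_interactions(cfg, a$truth)
  ib <- simulate_interactions(cfg, a$truth)
  expect_identical(ia, ib)
  expect_identical(simulate_probe_hits(cfg), simulate_probe_hits(cfg))

  cfg2 <- sim_config(n_lnc = 20, n_mrna = 80, n_mirna = 50,
                     n_pairs_samples = 5, n_planted_cerna = 5, seed = 12)
  expect_false(identical(simulate_expression(cfg2)$matrix, a$matrix))
})

test_that("the differential truth set has exactly round(frac_de * rows) members", {
  cfg <- sim_config(n_lnc = 200, n_mrna = 800, frac_de = 0.1,
                    n_pairs_samples = 4, n_planted_cerna = 10, seed = 3)
  sim <- simulate_expression(cfg)
  expect_length(c(sim$truth$de_lnc_ids, sim$truth$de_mrna_ids), 100L)
  expect_equal(nrow(sim$matrix), 1000L)
  expect_equal(ncol(sim$matrix), 8L)
})

test_that("zero effect size means empty truth sets and no planted pairs", {
  cfg <- sim_config(n_lnc = 20, n_mrna = 60, de_effect = 0,
                    n_pairs_samples = 4, seed = 5)
  sim <- simulate_expression(cfg)
  expect_length(sim$truth$de_lnc_ids, 0L)
  expect_length(sim$truth$de_mrna_ids, 0L)
  expect_equal(nrow(sim$truth$planted_pairs), 0L)
})

test_that("invalid simulation settings are rejected", {
  expect_error(sim_config(frac_de = 1.2), "frac_de")
  expect_error(sim_config(frac_de = -0.1), "frac_de")
  expect_error(sim_config(coexpr_r = 1), "coexpr_r")
  expect_error(sim_config(n_lnc = 2, n_mrna = 2, n_planted_cerna = 5),
               "possible")
  expect_error(sim_config(shared_mirna_boost = 300, n_mirna = 200),
               "n_mirna")
  expect_error(
    simulate_expression(sim_config(n_pairs_samples = 1)),
    "must be a single integer >= 1|at least 2")
})

test_that("planted pairs share at least the boost and exceed background sharing", {
  cfg <- sim_config(n_lnc = 30, n_mrna = 120, n_mirna = 100,
                    n_pairs_samples = 4, n_planted_cerna = 10,
                    shared_mirna_boost = 6, background_degree = 4, seed = 21)
  sim <- simulate_expression(cfg)
  inter <- simulate_interactions(cfg, sim$truth)
  partners <- function(tab) split(tab$mirna_id, tab$gene_id)
  pl <- partners(inter$lnc_mi)
  pm <- partners(inter$mrna_mi)
  planted <- sim$truth$planted_pairs
  shared_planted <- mapply(function(a, b)
    length(intersect(pl[[a]], pm[[b]])), planted$lnc, planted$mrna)
  expect_true(all(shared_planted >= 6L))

  set.seed(1)
  rand <- data.frame(lnc = sample(names(pl), 50, replace = TRUE),
                     mrna = sample(names(pm), 50, replace = TRUE))
  rand <- rand[!paste(rand$lnc, rand$mrna) %in%
                 paste(planted$lnc, planted$mrna), ]
  shared_rand <- mapply(function(a, b)
    length(intersect(pl[[a]], pm[[b]])), rand$lnc, rand$mrna)
  expect_gt(mean(shared_planted), mean(shared_rand))
})

test_that("background edge totals follow the binomial sampling scheme", {
  cfg <- sim_config(n_lnc = 100, n_mrna = 100, n_mirna = 100,
                    n_pairs_samples = 4, n_planted_cerna = 0,
                    background_degree = 10, shared_mirna_boost = 0,
                    seed = 31)
  sim <- simulate_expression(cfg)
  inter <- simulate_interactions(cfg, sim$truth)
  total <- nrow(inter$lnc_mi) + nrow(inter$mrna_mi)
  expected <- 200 * 100 * 0.1
  sd3 <- 3 * sqrt(200 * 100 * 0.1 * 0.9)
  expect_lt(abs(total - expected), sd3)
  # no duplicate edges in either table
  expect_false(any(duplicated(inter$lnc_mi)))
  expect_false(any(duplicated(inter$mrna_mi)))
})

test_that("planted pairs reach the target co-expression on log2 values", {
  cfg <- sim_config(seed = 1)
  sim <- simulate_expression(cfg)
  pp <- sim$truth$planted_pairs
  rs <- vapply(seq_len(nrow(pp)), function(i)
    cor(sim$matrix[pp$lnc[i], ], sim$matrix[pp$mrna[i], ]), numeric(1))
  expect_lt(abs(mean(rs) - cfg$coexpr_r), 0.05)
  expect_true(all(rs > 0.6))
})

test_that("differential recovery is non-decreasing in effect size", {
  recovered <- vapply(c(0.5, 1.5, 3), function(eff) {
    cfg <- sim_config(n_lnc = 40, n_mrna = 160, n_pairs_samples = 10,
                      de_effect = eff, noise_sd = 0.8,
                      n_planted_cerna = 5, seed = 41)
    sim <- simulate_expression(cfg)
    res <- sam_de(sim$matrix, sim$design, n_perm = 200, seed = 41,
                  transcript_class = sim$transcript_class)
    sel <- select_de(res)
    truth <- c(sim$truth$de_lnc_ids, sim$truth$de_mrna_ids)
    sum(truth %in% c(sel$lncRNA, sel$mRNA))
  }, numeric(1))
  expect_true(all(diff(recovered) >= 0))
  expect_gt(recovered[3], recovered[1])
})

test_that("the probe-hit fixture covers the documented boundary cases", {
  hits <- simulate_probe_hits(sim_config(seed = 2))
  truth <- attr(hits, "truth")
  # at least one probe hits both transcript classes
  classes_per_probe <- tapply(hits$transcript_class, hits$probe_id,
                              function(x) length(unique(x)))
  expect_true(any(classes_per_probe == 2L))
  # match lengths at and below the 60-nt cutoff are present
  expect_true(all(c(59L, 60L) %in% hits$match_length))
  # length-59 rows never appear among the kept probes
  short_probes <- unique(hits$probe_id[hits$match_length < 60L])
  expect_false(any(short_probes %in% truth$kept_probes))
  # support boundary: a transcript with 3 clean probes and one with 4+
  ann <- filter_hits(hits)
  support <- table(ann$mapping$transcript_id)
  expect_true(any(support == 4L))
  expect_false("TXC_FEW" %in% ann$transcripts_kept)
})
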