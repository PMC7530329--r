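#' Simulation settings for synthetic ceRNA pipeline inputs
#'
#' Bundles every knob of the synthetic-data generator: a paired tumor/normal
#' expression matrix with a planted fraction of differential transcripts, two
#' bipartite miRNA-interaction tables in which designated lncRNA-mRNA pairs
#' share an enriched miRNA set, and controllable lncRNA-mRNA co-expression.
#' The defaults describe the study conditions the package's validation suite
#' runs under: 20 tumor/normal pairs, 20% differential transcripts at a
#' 2-fold log2 shift over noise of SD 0.5, 30 planted ceRNA pairs that each
#' gain 8 shared miRNAs over a background of ~5 partners per gene drawn from
#' a 200-miRNA universe, and a planted co-expression of r = 0.9.
#'
#' @param n_lnc Number of lncRNA transcripts.
#' @param n_mrna Number of mRNA transcripts.
#' @param n_mirna Size of the miRNA universe.
#' @param n_pairs_samples Number of tumor/normal sample pairs (total samples
#'   is twice this).
#' @param frac_de Fraction of transcripts carrying a differential shift,
#'   in `[0, 1]`.
#' @param de_effect Log2 fold-change magnitude of the planted shift. A value
#'   of 0 means no transcript is differential and the truth sets are empty.
#' @param noise_sd Log2-scale residual standard deviation.
#' @param n_planted_cerna Number of planted ceRNA (lncRNA, mRNA) pairs; their
#'   members are drawn from the differential truth sets so they survive the
#'   DE-mapping stage.
#' @param shared_mirna_boost Extra miRNAs shared by each planted pair beyond
#'   background expectation. Must not exceed `n_mirna`.
#' @param background_degree Mean number of background miRNA partners per gene.
#' @param coexpr_r Target population Pearson correlation (on log2 values)
#'   between members of a planted pair, in `[0, 1)`.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_expression()], [simulate_interactions()],
#'   [simulate_probe_hits()]
#' @export
sim_config <- function(n_lnc = 50L, n_mrna = 300L, n_mirna = 200L,
                       n_pairs_samples = 20L, frac_de = 0.2, de_effect = 2,
                       noise_sd = 0.5, n_planted_cerna = 30L,
                       shared_mirna_boost = 8L, background_degree = 5,
                       coexpr_r = 0.9, seed = 1L) {
  cfg <- list(
    n_lnc = assert_count(n_lnc, "n_lnc"),
    n_mrna = assert_count(n_mrna, "n_mrna"),
    n_mirna = assert_count(n_mirna, "n_mirna"),
    n_pairs_samples = assert_count(n_pairs_samples, "n_pairs_samples"),
    frac_de = assert_fraction(frac_de, "frac_de"),
    de_effect = assert_fraction(de_effect, "de_effect", 0, Inf),
    noise_sd = assert_fraction(noise_sd, "noise_sd", 0, Inf),
    n_planted_cerna = assert_count(n_planted_cerna, "n_planted_cerna",
                                   min = 0L),
    shared_mirna_boost = assert_count(shared_mirna_boost,
                                      "shared_mirna_boost", min = 0L),
    background_degree = assert_fraction(background_degree,
                                        "background_degree", 0, Inf),
    coexpr_r = assert_fraction(coexpr_r, "coexpr_r"),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$n_planted_cerna > cfg$n_lnc * cfg$n_mrna) {
    stop("n_planted_cerna exceeds the number of possible lncRNA-mRNA pairs",
         call. = FALSE)
  }
  if (cfg$shared_mirna_boost > cfg$n_mirna) {
    stop("shared_mirna_boost cannot exceed n_mirna", call. = FALSE)
  }
  if (cfg$background_degree > cfg$n_mirna) {
    stop("background_degree cannot exceed n_mirna", call. = FALSE)
  }
  if (cfg$coexpr_r >= 1) {
    stop("coexpr_r must be strictly below 1", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a paired tumor/normal expression matrix with planted truth
#'
#' Draws log-normal microarray-like intensities: on the log2 scale each value
#' is baseline + condition shift + per-pair random intercept + noise, with
#' baseline ~ Normal(6, 1). Exactly `round(frac_de * n_transcripts)`
#' transcripts (when `de_effect > 0`) receive a tumor-vs-normal mean shift of
#' `+/- de_effect`, split evenly between up- and down-regulation. Planted
#' ceRNA pairs are drawn from the differential truth sets; their members share
#' the direction of their differential shift plus a pair-level latent
#' component (identical within a tumor/normal pair, so the paired test is
#' unaffected) scaled so the population Pearson correlation of their log2
#' values across all samples equals `coexpr_r` — or the shift-induced floor
#' `v_shift / (v_shift + v_indep)` when that already exceeds the target.
#'
#' @param config A [sim_config()] object.
#' @param scale `"log2"` (default) returns the log2-scale matrix the rest of
#'   the pipeline consumes; `"intensity"` returns `2^value`.
#'
#' @return A list with elements
#'   \describe{
#'     \item{matrix}{numeric transcripts x samples matrix,}
#'     \item{design}{data frame with columns `sample`, `condition`
#'       (`"tumor"`/`"normal"`) and `pair`,}
#'     \item{transcript_class}{named character vector, `"lncRNA"` or
#'       `"mRNA"` per row,}
#'     \item{truth}{list with `de_lnc_ids`, `de_mrna_ids`, `de_direction`
#'       (named +1/-1) and `planted_pairs` (data frame `lnc`, `mrna`).}
#'   }
#' @export
simulate_expression <- function(config, scale = c("log2", "intensity")) {
  stopifnot(inherits(config, "sim_config"))
  scale <- match.arg(scale)
  if (config$n_pairs_samples < 2L) {
    stop("n_pairs_samples must be at least 2", call. = FALSE)
  }
  lnc <- lnc_id_set(config$n_lnc)
  mrna <- mrna_id_set(config$n_mrna)
  ids <- c(lnc, mrna)
  G <- length(ids)
  k <- config$n_pairs_samples

  n_de <- if (config$de_effect > 0) round(config$frac_de * G) else 0L
  n_de_lnc <- round(n_de * config$n_lnc / G)
  n_de_mrna <- n_de - n_de_lnc
  n_planted <- if (n_de > 0) config$n_planted_cerna else 0L
  if (n_planted > 0 && (n_de_lnc < 1L || n_de_mrna < n_planted)) {
    stop("differential truth sets too small to host the planted ceRNA ",
         "pairs; increase frac_de or decrease n_planted_cerna",
         call. = FALSE)
  }

  with_seed(config$seed, {
    de_lnc <- sort(sample(lnc, n_de_lnc))
    de_mrna <- sort(sample(mrna, n_de_mrna))
    de_ids <- c(de_lnc, de_mrna)
    direction <- stats::setNames(
      sample(rep_len(c(1, -1), n_de)), de_ids)

    planted <- if (n_planted > 0) {
      data.frame(
        lnc = rep_len(sample(de_lnc), n_planted),
        mrna = sample(de_mrna, n_planted),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(lnc = character(0), mrna = character(0))
    }
    # pair members share the shift direction (shared latent condition
    # component), so the planted correlation is not diluted
    if (n_planted > 0) {
      direction[planted$mrna] <- direction[planted$lnc]
    }

    samples_t <- sprintf("T%02d", seq_len(k))
    samples_n <- sprintf("N%02d", seq_len(k))
    design <- data.frame(
      sample = c(samples_t, samples_n),
      condition = rep(c("tumor", "normal"), each = k),
      pair = rep(sprintf("P%02d", seq_len(k)), 2L),
      stringsAsFactors = FALSE
    )

    baseline <- stats::rnorm(G, mean = 6, sd = 1)
    pairfx <- matrix(stats::rnorm(G * k, sd = 0.5 * config$noise_sd), G, k)
    noise <- matrix(stats::rnorm(G * 2L * k, sd = config$noise_sd), G, 2L * k)

    m <- baseline + cbind(pairfx, pairfx) + noise
    shift <- stats::setNames(numeric(G), ids)
    shift[de_ids] <- direction * config$de_effect
    m[, seq_len(k)] <- m[, seq_len(k)] + shift

    # planted co-expression: pair members share a per-sample-pair latent a*z
    # (identical in tumor and normal, so paired differences are untouched).
    # Across pooled samples the shared condition shift already contributes
    # covariance de_effect^2/4, so a is calibrated to top the total up to
    # coexpr_r: (a^2 + v_shift) / (a^2 + v_shift + v_indep) = coexpr_r.
    if (n_planted > 0 && config$coexpr_r > 0) {
      var_indep <- (0.5 * config$noise_sd)^2 + config$noise_sd^2
      var_shift <- config$de_effect^2 / 4
      a2 <- config$coexpr_r / (1 - config$coexpr_r) * var_indep - var_shift
      a <- sqrt(max(a2, 0))
      for (L in unique(planted$lnc)) {
        z <- stats::rnorm(k)
        members <- c(L, planted$mrna[planted$lnc == L])
        m[match(members, ids), ] <-
          m[match(members, ids), , drop = FALSE] +
          matrix(a * c(z, z), nrow = length(members), ncol = 2L * k,
                 byrow = TRUE)
      }
    }

    dimnames(m) <- list(ids, design$sample)
    if (scale == "intensity") m <- 2^m

    list(
      matrix = m,
      design = design,
      transcript_class = stats::setNames(
        rep(c("lncRNA", "mRNA"), c(config$n_lnc, config$n_mrna)), ids),
      truth = list(
        de_lnc_ids = de_lnc,
        de_mrna_ids = de_mrna,
        de_direction = direction,
        planted_pairs = planted
      )
    )
  })
}

#' Simulate bipartite miRNA-interaction tables with planted ceRNA pairs
#'
#' Every gene (lncRNA or mRNA) gains each miRNA as a background partner
#' independently with probability `background_degree / n_mirna`, so expected
#' edge totals follow the binomial. Each planted pair then receives
#' `shared_mirna_boost` common miRNAs added to both members, guaranteeing
#' at least that many shared partners. No duplicate edges are produced.
#'
#' @param config A [sim_config()] object.
#' @param truth The `truth` element returned by [simulate_expression()]
#'   (its `planted_pairs` decide which pairs are boosted).
#'
#' @return A list with `lnc_mi` and `mrna_mi`, each a data frame with
#'   columns `gene_id`, `mirna_id` and a `gene_class` attribute.
#' @export
simulate_interactions <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$shared_mirna_boost > config$n_mirna) {
    stop("shared_mirna_boost cannot exceed n_mirna", call. = FALSE)
  }
  lnc <- lnc_id_set(config$n_lnc)
  mrna <- mrna_id_set(config$n_mrna)
  mirs <- mirna_id_set(config$n_mirna)
  p_bg <- config$background_degree / config$n_mirna
  planted <- truth$planted_pairs

  with_seed(config$seed + 1L, {
    draw <- function(genes) {
      hits <- matrix(stats::runif(length(genes) * config$n_mirna) < p_bg,
                     nrow = length(genes))
      idx <- which(hits, arr.ind = TRUE)
      split(mirs[idx[, 2L]], factor(genes[idx[, 1L]], levels = genes))
    }
    partners <- c(draw(lnc), draw(mrna))

    if (nrow(planted) > 0 && config$shared_mirna_boost > 0) {
      for (i in seq_len(nrow(planted))) {
        shared <- sample(mirs, config$shared_mirna_boost)
        for (g in c(planted$lnc[i], planted$mrna[i])) {
          partners[[g]] <- union(partners[[g]], shared)
        }
      }
    }

    as_table <- function(genes, class) {
      sub <- partners[genes]
      df <- data.frame(
        gene_id = rep(genes, lengths(sub)),
        mirna_id = unlist(sub, use.names = FALSE),
        stringsAsFactors = FALSE
      )
      attr(df, "gene_class") <- class
      df
    }
    list(lnc_mi = as_table(lnc, "lncRNA"), mrna_mi = as_table(mrna, "mRNA"))
  })
}

#' Simulate a probe-to-transcript alignment hit table with known outcome
#'
#' Builds a BLAST-tabular-style hit table that exercises every branch of the
#' probe re-annotation filter: probes matching a single transcript, probes
#' matching both a coding and a lncRNA transcript, probes matching two
#' transcripts of one class, transcripts supported by exactly 3 versus 4
#' surviving probes, and match lengths at and below the 60-nt perfect-match
#' cutoff (plus a sub-100% identity hit). The generator's intended outcome is
#' attached as the `truth` attribute so the filter can be checked exactly.
#'
#' @param config A [sim_config()] object (only the seed is used, to shuffle
#'   row order).
#'
#' @return A data frame with columns `probe_id`, `transcript_id`,
#'   `transcript_class`, `match_length`, `identity_pct`, carrying a `truth`
#'   attribute: a list with `kept_probes`, `kept_transcripts` and the
#'   intended `mapping` data frame.
#' @export
simulate_probe_hits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  hit <- function(probe, tx, class, len = 60L, ident = 100) {
    data.frame(probe_id = probe, transcript_id = tx, transcript_class = class,
               match_length = len, identity_pct = ident,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    # kept coding transcript: 5 clean single-target probes
    do.call(rbind, lapply(1:5, function(i)
      hit(sprintf("PRC%02d", i), "TXC_KEEP", "coding"))),
    # kept lncRNA transcript: exactly 4 clean probes (boundary: > 3 kept)
    do.call(rbind, lapply(1:4, function(i)
      hit(sprintf("PRL%02d", i), "TXL_KEEP", "lncRNA"))),
    # dropped: only 3 supporting probes (boundary: 3 is not > 3)
    do.call(rbind, lapply(1:3, function(i)
      hit(sprintf("PRF%02d", i), "TXC_FEW", "coding"))),
    # dropped: 4 probes but one only matches 59 nt, leaving 3
    do.call(rbind, lapply(1:3, function(i)
      hit(sprintf("PRS%02d", i), "TXL_SHORT", "lncRNA"))),
    hit("PRS04", "TXL_SHORT", "lncRNA", len = 59L),
    # cross-class probe: matches a coding and a lncRNA transcript
    hit("PRX01", "TXC_KEEP", "coding"),
    hit("PRX01", "TXL_KEEP", "lncRNA"),
    # within-class multi-target probe
    hit("PRM01", "TXC_KEEP", "coding"),
    hit("PRM01", "TXC_FEW", "coding"),
    # imperfect identity at full length
    hit("PRI01", "TXC_KEEP", "coding", ident = 98)
  )
  kept_probes <- c(sprintf("PRC%02d", 1:5), sprintf("PRL%02d", 1:4))
  mapping <- data.frame(
    probe_id = kept_probes,
    transcript_id = rep(c("TXC_KEEP", "TXL_KEEP"), c(5L, 4L)),
    transcript_class = rep(c("coding", "lncRNA"), c(5L, 4L)),
    stringsAsFactors = FALSE
  )
  out <- with_seed(config$seed + 2L, rows[sample(nrow(rows)), , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    kept_probes = kept_probes,
    kept_transcripts = c("TXC_KEEP", "TXL_KEEP"),
    mapping = mapping
  )
  out
}
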