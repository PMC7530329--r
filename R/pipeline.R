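#' Configuration for an end-to-end ceRNA-network run
#'
#' Collects every input and threshold of the pipeline. Inputs may be given as
#' file paths (read with the package's readers) or as the in-memory objects
#' the corresponding readers return; paths are checked at validation time.
#'
#' @param expression Expression matrix (log2 transcripts x samples) or TSV
#'   path. When `probe_hits` is supplied this is the probe-level matrix.
#' @param design Paired design data frame (`sample`, `condition`, `pair`) or
#'   TSV path.
#' @param transcript_class Named character vector (`"lncRNA"`/`"mRNA"` per
#'   transcript) or TSV path with columns `transcript_id`, `class`. Optional
#'   when `probe_hits` carries the classes.
#' @param lnc_mi,mrna_mi Interaction tables (`gene_id`, `mirna_id`) or TSV
#'   paths.
#' @param seeds Character vector of RWR seed gene ids or a one-per-line file.
#' @param probe_hits Optional probe-hit table (or TSV path) triggering the
#'   re-annotation stage; `expression` is then collapsed probe-to-transcript.
#' @param out_dir Output directory (created if missing).
#' @param de_alpha Adjusted-p threshold for differential expression.
#' @param pair_alpha Adjusted-p threshold for the hypergeometric pair test.
#' @param r_min,p_max Co-expression thresholds.
#' @param k Top-k per centrality dimension.
#' @param rwr_restart,rwr_tol,rwr_n_perm RWR parameters.
#' @param sam_n_perm Number of SAM sign-flip permutations.
#' @param m_universe Optional miRNA universe override.
#' @param sam_seed,rwr_rng_seed RNG seeds for the two stochastic stages.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, design, transcript_class = NULL,
                            lnc_mi, mrna_mi, seeds, probe_hits = NULL,
                            out_dir = tempfile("cerna_run_"),
                            de_alpha = 0.01, pair_alpha = 0.01,
                            r_min = 0.6, p_max = 0.05, k = 10L,
                            rwr_restart = 0.5, rwr_tol = 1e-10,
                            rwr_n_perm = 5000L, sam_n_perm = 1000L,
                            m_universe = NULL, sam_seed = 1L,
                            rwr_rng_seed = 1L) {
  assert_fraction(de_alpha, "de_alpha", 0, 1)
  assert_fraction(pair_alpha, "pair_alpha", 0, 1)
  assert_fraction(r_min, "r_min", -1, 1)
  assert_fraction(p_max, "p_max", 0, 1)
  assert_count(k, "k")
  assert_fraction(rwr_restart, "rwr_restart", 0, 1)
  if (rwr_restart <= 0 || rwr_restart >= 1) {
    stop("rwr_restart must be strictly inside (0, 1)", call. = FALSE)
  }
  if (rwr_tol <= 0) stop("rwr_tol must be positive", call. = FALSE)
  assert_count(rwr_n_perm, "rwr_n_perm")
  assert_count(sam_n_perm, "sam_n_perm", min = 100L)

  for (nm in c("expression", "design", "transcript_class", "lnc_mi",
               "mrna_mi", "seeds", "probe_hits")) {
    val <- get(nm)
    if (is.character(val) && length(val) == 1L && is.null(names(val)) &&
        !file.exists(val)) {
      stop(sprintf("input file for '%s' not found: %s", nm, val),
           call. = FALSE)
    }
  }
  structure(
    list(expression = expression, design = design,
         transcript_class = transcript_class, lnc_mi = lnc_mi,
         mrna_mi = mrna_mi, seeds = seeds, probe_hits = probe_hits,
         out_dir = out_dir, de_alpha = de_alpha, pair_alpha = pair_alpha,
         r_min = r_min, p_max = p_max, k = as.integer(k),
         rwr_restart = rwr_restart, rwr_tol = rwr_tol,
         rwr_n_perm = as.integer(rwr_n_perm),
         sam_n_perm = as.integer(sam_n_perm), m_universe = m_universe,
         sam_seed = as.integer(sam_seed),
         rwr_rng_seed = as.integer(rwr_rng_seed)),
    class = "pipeline_config"
  )
}

load_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    reader(x, ...)
  } else {
    x
  }
}

stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full ceRNA-network pipeline
#'
#' Executes, in order: optional probe re-annotation and collapsing, paired
#' SAM differential expression, global and DE triple-network construction,
#' hypergeometric pair scoring with FDR control, centrality analysis with
#' top-k overlap, random walk with restart prioritization, and co-expression
#' screening with ceRNA module extraction. Each stage's table or graph is
#' written under `config$out_dir`, together with `report.json` recording all
#' counts, thresholds and seeds; reruns with an identical configuration
#' produce a byte-identical report.
#'
#' @param config A [pipeline_config()] object.
#'
#' @return The run report (a named list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  expr <- stage("load_expression",
                load_input(config$expression, read_expression))
  design <- stage("load_design", load_input(config$design, read_design))
  lnc_mi <- stage("load_interactions",
                  load_input(config$lnc_mi, read_interactions,
                             gene_class = "lncRNA"))
  mrna_mi <- stage("load_interactions",
                   load_input(config$mrna_mi, read_interactions,
                              gene_class = "mRNA"))
  seeds <- stage("load_seeds", load_input(config$seeds, read_id_list))

  tclass <- config$transcript_class
  if (is.character(tclass) && length(tclass) == 1L && is.null(names(tclass))) {
    ct <- read_tsv_checked(tclass, required = c("transcript_id", "class"))
    tclass <- stats::setNames(ct$class, ct$transcript_id)
  }

  report <- list(
    thresholds = list(
      de_alpha = config$de_alpha, pair_alpha = config$pair_alpha,
      r_min = config$r_min, p_max = config$p_max, k = config$k,
      rwr_restart = config$rwr_restart, rwr_tol = config$rwr_tol),
    seeds_used = list(sam_seed = config$sam_seed,
                      rwr_rng_seed = config$rwr_rng_seed,
                      sam_n_perm = config$sam_n_perm,
                      rwr_n_perm = config$rwr_n_perm)
  )

  # optional probe re-annotation
  if (!is.null(config$probe_hits)) {
    hits <- stage("annotate", load_input(
      config$probe_hits,
      function(p) read_tsv_checked(p, required = c(
        "probe_id", "transcript_id", "transcript_class", "match_length",
        "identity_pct"))))
    ann <- stage("annotate", filter_hits(hits))
    expr <- stage("annotate", collapse_to_transcripts(expr, ann))
    tclass <- attr(expr, "transcript_class")
    report$annotation <- list(probes_kept = nrow(ann$mapping),
                              transcripts_kept =
                                length(ann$transcripts_kept))
  }
  if (is.null(tclass)) {
    stop("pipeline stage 'annotate' failed: transcript classes are needed ",
         "(supply transcript_class or probe_hits)", call. = FALSE)
  }

  # differential expression
  sam <- stage("diffexpr", sam_de(expr, design, n_perm = config$sam_n_perm,
                                  seed = config$sam_seed,
                                  transcript_class = tclass))
  de <- select_de(sam, alpha = config$de_alpha)
  utils::write.table(
    cbind(sam$table, selected = sam$table$adjusted_p < config$de_alpha),
    out("diffexpr.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  report$diffexpr <- list(n_transcripts = nrow(sam$table), s0 = sam$s0,
                          de_lncRNA = length(de$lncRNA),
                          de_mRNA = length(de$mRNA))

  # triple network and ceRNA pair scoring
  global <- stage("triple_network", build_global_network(lnc_mi, mrna_mi))
  de_net <- stage("triple_network",
                  extract_de_subnetwork(global, de$lncRNA, de$mRNA))
  pairs <- stage("triple_network",
                 score_cerna_pairs(de_net, global,
                                   m_universe = config$m_universe))
  lclmn <- build_lclmn(pairs, alpha = config$pair_alpha)
  utils::write.table(pairs, out("cerna_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sif(lclmn, out("lclmn.sif"))
  if (nrow(lclmn$pairs) > 0L) write_graphml(lclmn, out("lclmn.graphml"))
  report$network <- list(
    global = list(lnc = length(global$lnc_nodes),
                  mirna = length(global$mirna_nodes),
                  mrna = length(global$mrna_nodes)),
    de = list(lnc = length(de_net$lnc_nodes),
              mirna = length(de_net$mirna_nodes),
              mrna = length(de_net$mrna_nodes)),
    pairs_scored = nrow(pairs),
    lclmn = list(lnc = length(lclmn$lnc_nodes),
                 mrna = length(lclmn$mrna_nodes),
                 edges = nrow(lclmn$pairs))
  )

  if (nrow(lclmn$pairs) == 0L) {
    report$note <- "no significant ceRNA pair; downstream stages skipped"
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), out("report.json"))
    return(invisible(report))
  }

  # topology
  cent <- stage("topology", compute_centralities(lclmn))
  overlap <- stage("topology", top_k_overlap(cent, k = config$k))
  utils::write.table(cent, out("centrality.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_id_list(overlap, out("topology_overlap.txt"))
  report$topology <- list(k = config$k, overlap_lncRNAs = overlap)

  # random walk with restart
  rwr <- stage("rwr", rwr_significance(
    lclmn, seeds, r = config$rwr_restart, tol = config$rwr_tol,
    n_perm = config$rwr_n_perm, rng_seed = config$rwr_rng_seed))
  utils::write.table(rwr$candidates, out("rwr_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$rwr <- list(
    seeds_in_network = length(rwr$seed_genes),
    significant_lncRNAs =
      rwr$candidates$node[rwr$candidates$perm_p < 0.05])

  # co-expression and modules
  copairs <- stage("coexpression",
                   coexpressed_pairs(lclmn, expr, r_min = config$r_min,
                                     p_max = config$p_max))
  utils::write.table(copairs, out("coexpressed_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  module_lncs <- intersect(overlap, unique(copairs$lnc))
  for (L in module_lncs) {
    mod <- stage("coexpression", extract_module(L, copairs, global))
    write_sif(mod, out(sprintf("module_%s.sif", L)))
  }
  report$coexpression <- list(pairs_retained = nrow(copairs),
                              modules = module_lncs)

  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), out("report.json"))
  invisible(report)
}
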