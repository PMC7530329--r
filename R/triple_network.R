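clean_edges <- function(tab, what) {
  if (!is.data.frame(tab) || ncol(tab) < 2L) {
    stop(what, " must be a data frame with columns gene_id, mirna_id",
         call. = FALSE)
  }
  df <- data.frame(gene_id = as.character(tab[[1L]]),
                   mirna_id = as.character(tab[[2L]]),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$gene_id)) || any(!nzchar(df$mirna_id)) ||
      anyNA(df$gene_id) || anyNA(df$mirna_id)) {
    stop(what, " contains empty or missing ids", call. = FALSE)
  }
  if (any(df$gene_id == df$mirna_id)) {
    stop(what, " contains self-pairs", call. = FALSE)
  }
  unique(df)
}

#' Merge lncRNA-miRNA and mRNA-miRNA tables into a global triple network
#'
#' The two bipartite interaction tables are deduplicated and merged into a
#' tripartite graph over the lncRNA, miRNA and mRNA node sets. Edge
#' multiplicity is 1 and the three node sets must be disjoint.
#'
#' @param lnc_mi Data frame (`gene_id`, `mirna_id`) of lncRNA-miRNA edges.
#' @param mrna_mi Data frame (`gene_id`, `mirna_id`) of mRNA-miRNA edges.
#'
#' @return An object of class `triple_network`: list with node sets
#'   `lnc_nodes`, `mirna_nodes`, `mrna_nodes` and edge tables `lnc_mi`,
#'   `mrna_mi`.
#' @export
build_global_network <- function(lnc_mi, mrna_mi) {
  lnc_mi <- clean_edges(lnc_mi, "lnc_mi")
  mrna_mi <- clean_edges(mrna_mi, "mrna_mi")
  lnc_nodes <- sort(unique(lnc_mi$gene_id))
  mrna_nodes <- sort(unique(mrna_mi$gene_id))
  mirna_nodes <- sort(unique(c(lnc_mi$mirna_id, mrna_mi$mirna_id)))
  clash <- intersect(lnc_nodes, mrna_nodes)
  if (length(clash) > 0L) {
    stop("id(s) appear as both lncRNA and mRNA: ",
         paste(utils::head(clash, 5L), collapse = ", "), call. = FALSE)
  }
  clash <- intersect(c(lnc_nodes, mrna_nodes), mirna_nodes)
  if (length(clash) > 0L) {
    stop("id(s) appear as both gene and miRNA: ",
         paste(utils::head(clash, 5L), collapse = ", "), call. = FALSE)
  }
  structure(
    list(lnc_nodes = lnc_nodes, mirna_nodes = mirna_nodes,
         mrna_nodes = mrna_nodes, lnc_mi = lnc_mi, mrna_mi = mrna_mi),
    class = "triple_network"
  )
}

#' @export
print.triple_network <- function(x, ...) {
  cat(sprintf(
    "triple network: %d lncRNA, %d miRNA, %d mRNA nodes; %d + %d edges\n",
    length(x$lnc_nodes), length(x$mirna_nodes), length(x$mrna_nodes),
    nrow(x$lnc_mi), nrow(x$mrna_mi)))
  invisible(x)
}

#' Restrict a triple network to differentially expressed genes
#'
#' Keeps only lncRNA/mRNA nodes in the supplied DE sets, their incident
#' edges, and miRNAs that retain at least one edge. Ids not present in the
#' network simply drop out.
#'
#' @param g A [build_global_network()] result.
#' @param de_lnc,de_mrna Character vectors of DE lncRNA and mRNA ids.
#'
#' @return A `triple_network` restricted to the DE genes.
#' @export
extract_de_subnetwork <- function(g, de_lnc, de_mrna) {
  stopifnot(inherits(g, "triple_network"))
  lnc_mi <- g$lnc_mi[g$lnc_mi$gene_id %in% de_lnc, , drop = FALSE]
  mrna_mi <- g$mrna_mi[g$mrna_mi$gene_id %in% de_mrna, , drop = FALSE]
  structure(
    list(
      lnc_nodes = sort(unique(lnc_mi$gene_id)),
      mirna_nodes = sort(unique(c(lnc_mi$mirna_id, mrna_mi$mirna_id))),
      mrna_nodes = sort(unique(mrna_mi$gene_id)),
      lnc_mi = lnc_mi, mrna_mi = mrna_mi
    ),
    class = "triple_network"
  )
}

#' Upper-tail hypergeometric p-value for shared miRNAs
#'
#' Probability that a lncRNA with `n` miRNA partners and an mRNA with `t`
#' partners, drawn from a universe of `m` miRNAs, share at least `r` partners
#' by chance: `P = 1 - sum_{i=0}^{r-1} C(t, i) C(m - t, n - i) / C(m, n)`,
#' i.e. `P(X >= r)` for `X ~ Hypergeometric(m, t, n)`. Evaluated through the
#' numerically stable hypergeometric tail rather than naive summation.
#'
#' @param t Number of miRNAs interacting with the mRNA.
#' @param n Number of miRNAs interacting with the lncRNA.
#' @param r Number of shared miRNAs; `0 <= r <= min(t, n)`.
#' @param m Total miRNA universe size; `t, n <= m`.
#'
#' @return Numeric vector of p-values in `[0, 1]` (arguments recycle).
#' @export
hypergeom_pvalue <- function(t, n, r, m) {
  arg <- unname(cbind(t, n, r, m))  # recycles
  t <- arg[, 1L]; n <- arg[, 2L]; r <- arg[, 3L]; m <- arg[, 4L]
  if (any(arg < 0) || anyNA(arg)) {
    stop("t, n, r, m must be non-negative", call. = FALSE)
  }
  if (any(t > m) || any(n > m)) {
    stop("partner counts t and n cannot exceed the universe size m",
         call. = FALSE)
  }
  if (any(r > pmin(t, n))) {
    stop("shared count r cannot exceed min(t, n)", call. = FALSE)
  }
  stats::phyper(r - 1, t, m - t, n, lower.tail = FALSE)
}

#' Score candidate ceRNA pairs by the shared-miRNA hypergeometric test
#'
#' Enumerates every (lncRNA, mRNA) combination of the DE triple network that
#' shares at least one miRNA, computes the upper-tail hypergeometric p-value
#' from partner counts, and applies Benjamini-Hochberg correction across all
#' scored pairs. Pairs sharing no miRNA cannot be ceRNA partners (their
#' p-value is 1) and are excluded before testing.
#'
#' @param de_net `triple_network` restricted to DE genes (pairs are drawn
#'   from its lncRNA and mRNA node sets).
#' @param global_net `triple_network` on which partner sets (`t`, `n`) and
#'   shared counts (`r`) are counted; defaults to `de_net`. Using the full
#'   background network keeps the counts on the same footing as the
#'   universe `m`.
#' @param m_universe miRNA universe size; defaults to the number of distinct
#'   miRNAs in `global_net`.
#'
#' @return A data frame of class `cerna_pairs` with columns `lnc`, `mrna`,
#'   `t`, `n`, `r`, `m`, `p`, `adjusted_p`, ordered by `(p, lnc, mrna)`.
#' @export
score_cerna_pairs <- function(de_net, global_net = de_net,
                              m_universe = NULL) {
  stopifnot(inherits(de_net, "triple_network"),
            inherits(global_net, "triple_network"))
  if (length(de_net$lnc_nodes) == 0L && length(de_net$mrna_nodes) == 0L) {
    stop("de_net is empty", call. = FALSE)
  }
  m <- as.integer(m_universe %||% length(global_net$mirna_nodes))
  mirs <- global_net$mirna_nodes
  lncs <- de_net$lnc_nodes
  mrnas <- de_net$mrna_nodes

  lnc_tab <- global_net$lnc_mi[global_net$lnc_mi$gene_id %in% lncs, ]
  mrna_tab <- global_net$mrna_mi[global_net$mrna_mi$gene_id %in% mrnas, ]
  empty <- data.frame(lnc = character(0), mrna = character(0),
                      t = integer(0), n = integer(0), r = integer(0),
                      m = integer(0), p = numeric(0), adjusted_p = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(lnc_tab) == 0L || nrow(mrna_tab) == 0L) {
    return(structure(empty, class = c("cerna_pairs", "data.frame")))
  }

  L <- Matrix::sparseMatrix(
    i = match(lnc_tab$gene_id, lncs), j = match(lnc_tab$mirna_id, mirs),
    x = 1, dims = c(length(lncs), length(mirs)))
  Mx <- Matrix::sparseMatrix(
    i = match(mrna_tab$gene_id, mrnas), j = match(mrna_tab$mirna_id, mirs),
    x = 1, dims = c(length(mrnas), length(mirs)))
  n_lnc <- Matrix::rowSums(L)
  t_mrna <- Matrix::rowSums(Mx)
  if (any(c(n_lnc, t_mrna) > m)) {
    stop("a partner count exceeds the miRNA universe size m", call. = FALSE)
  }

  shared <- Matrix::summary(Matrix::tcrossprod(L, Mx))
  shared <- shared[shared$x >= 1, , drop = FALSE]
  if (nrow(shared) == 0L) {
    return(structure(empty, class = c("cerna_pairs", "data.frame")))
  }
  out <- data.frame(
    lnc = lncs[shared$i], mrna = mrnas[shared$j],
    t = as.integer(t_mrna[shared$j]), n = as.integer(n_lnc[shared$i]),
    r = as.integer(shared$x), m = m, stringsAsFactors = FALSE)
  out$p <- hypergeom_pvalue(out$t, out$n, out$r, out$m)
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$lnc, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cerna_pairs", "data.frame"))
}

#' Build the lncRNA-mRNA ceRNA network from scored pairs
#'
#' Retains pairs whose FDR-adjusted hypergeometric p-value falls below
#' `alpha` and assembles them into a bipartite network; every node in the
#' result touches at least one significant edge.
#'
#' @param pairs A [score_cerna_pairs()] result.
#' @param alpha Adjusted-p threshold (strict `<`), default 0.01.
#'
#' @return An object of class `lclmn`: list with `pairs` (the significant
#'   rows), `lnc_nodes`, `mrna_nodes` and `alpha`.
#' @export
build_lclmn <- function(pairs, alpha = 0.01) {
  stopifnot(inherits(pairs, "data.frame"),
            all(c("lnc", "mrna", "adjusted_p") %in% names(pairs)))
  sig <- pairs[pairs$adjusted_p < alpha, , drop = FALSE]
  rownames(sig) <- NULL
  structure(
    list(pairs = as.data.frame(sig),
         lnc_nodes = sort(unique(sig$lnc)),
         mrna_nodes = sort(unique(sig$mrna)),
         alpha = alpha),
    class = "lclmn"
  )
}

#' @export
print.lclmn <- function(x, ...) {
  cat(sprintf(
    "ceRNA network: %d lncRNA nodes, %d mRNA nodes, %d edges (adjusted p < %g)\n",
    length(x$lnc_nodes), length(x$mrna_nodes), nrow(x$pairs), x$alpha))
  invisible(x)
}

#' Convert a network object to igraph
#'
#' @param x An `lclmn` or `triple_network` object.
#' @return An undirected `igraph` graph with a `class` vertex attribute
#'   (`"lncRNA"`, `"mRNA"`, `"miRNA"`); `lclmn` edges carry `r`, `p` and
#'   `adjusted_p` attributes.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "lclmn")) {
    vertices <- data.frame(
      name = c(x$lnc_nodes, x$mrna_nodes),
      class = rep(c("lncRNA", "mRNA"),
                  c(length(x$lnc_nodes), length(x$mrna_nodes))),
      stringsAsFactors = FALSE)
    edges <- x$pairs[, c("lnc", "mrna", "r", "p", "adjusted_p"),
                     drop = FALSE]
    return(igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = vertices))
  }
  if (inherits(x, "triple_network")) {
    vertices <- data.frame(
      name = c(x$lnc_nodes, x$mirna_nodes, x$mrna_nodes),
      class = rep(c("lncRNA", "miRNA", "mRNA"),
                  c(length(x$lnc_nodes), length(x$mirna_nodes),
                    length(x$mrna_nodes))),
      stringsAsFactors = FALSE)
    edges <- rbind(
      stats::setNames(x$lnc_mi, c("from", "to")),
      stats::setNames(x$mrna_mi, c("from", "to")))
    return(igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = vertices))
  }
  stop("as_igraph() supports 'lclmn' and 'triple_network' objects",
       call. = FALSE)
}
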