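#' Pearson correlation with a two-sided t-based p-value
#'
#' Sample Pearson correlation between two vectors, with the two-sided
#' p-value from the exact null transform `t = r * sqrt((n - 2) / (1 - r^2))`
#' on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, at least 3, neither constant.
#'
#' @return List with elements `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("at least 3 observations are required", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values are not supported", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Screen ceRNA-network edges by expression correlation
#'
#' Computes the Pearson correlation (with t-based p-value) for every
#' lncRNA-mRNA edge of the network over the supplied expression matrix, and
#' retains the strongly positively co-expressed pairs: `r > r_min` and
#' `p < p_max`, both strict. Edges whose endpoints are missing from the
#' matrix are skipped with a warning.
#'
#' @param lclmn A [build_lclmn()] result.
#' @param expr Numeric transcripts x samples matrix on the log2 scale. By
#'   default all samples (tumor and normal) are used.
#' @param r_min Correlation threshold (strict `>`), default 0.6.
#' @param p_max p-value threshold (strict `<`), default 0.05.
#' @param samples Optional character vector restricting the columns used
#'   (e.g. tumor samples only).
#'
#' @return Data frame with columns `lnc`, `mrna`, `r`, `p`, one row per
#'   retained pair (zero rows for an empty network).
#' @export
coexpressed_pairs <- function(lclmn, expr, r_min = 0.6, p_max = 0.05,
                              samples = NULL) {
  stopifnot(inherits(lclmn, "lclmn"), is.matrix(expr))
  if (!is.null(samples)) expr <- expr[, samples, drop = FALSE]
  pairs <- lclmn$pairs
  empty <- data.frame(lnc = character(0), mrna = character(0),
                      r = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)

  missing <- setdiff(unique(c(pairs$lnc, pairs$mrna)), rownames(expr))
  if (length(missing) > 0L) {
    warning(sprintf(
      "%d network node(s) missing from the expression matrix were skipped",
      length(missing)))
    pairs <- pairs[!(pairs$lnc %in% missing | pairs$mrna %in% missing), ,
                   drop = FALSE]
  }
  if (nrow(pairs) == 0L) return(empty)

  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pw <- pearson_with_p(expr[pairs$lnc[i], ], expr[pairs$mrna[i], ])
    data.frame(lnc = pairs$lnc[i], mrna = pairs$mrna[i],
               r = pw$r, p = pw$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  out <- res[res$r > r_min & res$p < p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a lncRNA-centric ceRNA module
#'
#' Builds the sub-network around one lncRNA: its co-expressed mRNA partners,
#' the miRNAs adjacent (in the global triple network) to both the lncRNA and
#' at least one member mRNA, and the two edge layers connecting them.
#'
#' @param lnc_id The central lncRNA id; must have at least one retained
#'   co-expressed pair.
#' @param pairs A [coexpressed_pairs()] result.
#' @param g The global `triple_network` providing the miRNA adjacency.
#'
#' @return An object of class `cerna_module`: list with `lnc`, `mrnas`,
#'   `mirnas`, and edge tables `lnc_mi`, `mrna_mi`.
#' @export
extract_module <- function(lnc_id, pairs, g) {
  stopifnot(inherits(g, "triple_network"), is.data.frame(pairs))
  if (!lnc_id %in% g$lnc_nodes) {
    stop(sprintf("lncRNA '%s' is not in the triple network", lnc_id),
         call. = FALSE)
  }
  members <- sort(unique(pairs$mrna[pairs$lnc == lnc_id]))
  if (length(members) == 0L) {
    stop(sprintf("lncRNA '%s' has no retained co-expressed pair", lnc_id),
         call. = FALSE)
  }
  lnc_partners <- g$lnc_mi$mirna_id[g$lnc_mi$gene_id == lnc_id]
  mrna_partners <- lapply(members, function(mm)
    g$mrna_mi$mirna_id[g$mrna_mi$gene_id == mm])
  names(mrna_partners) <- members

  connecting <- sort(unique(unlist(
    lapply(mrna_partners, intersect, x = lnc_partners))))
  lnc_mi <- data.frame(gene_id = lnc_id, mirna_id = connecting,
                       stringsAsFactors = FALSE)
  mrna_mi <- do.call(rbind, lapply(members, function(mm) {
    mi <- intersect(mrna_partners[[mm]], connecting)
    if (length(mi) == 0L) return(NULL)
    data.frame(gene_id = mm, mirna_id = sort(mi), stringsAsFactors = FALSE)
  }))
  structure(
    list(lnc = lnc_id, mrnas = members, mirnas = connecting,
         lnc_mi = lnc_mi,
         mrna_mi = mrna_mi %||%
           data.frame(gene_id = character(0), mirna_id = character(0))),
    class = "cerna_module"
  )
}

#' @export
print.cerna_module <- function(x, ...) {
  cat(sprintf("ceRNA module around %s: %d mRNAs, %d connecting miRNAs\n",
              x$lnc, length(x$mrnas), length(x$mirnas)))
  invisible(x)
}
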