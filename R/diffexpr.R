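validate_design <- function(mat, design) {
  if (!is.matrix(mat) || nrow(mat) == 0L) {
    stop("expression matrix must be a non-empty numeric matrix",
         call. = FALSE)
  }
  need <- c("sample", "condition", "pair")
  if (!is.data.frame(design) || !all(need %in% names(design))) {
    stop("design must be a data frame with columns sample, condition, pair",
         call. = FALSE)
  }
  bad <- setdiff(unique(design$condition), c("tumor", "normal"))
  if (length(bad) > 0L) {
    stop("condition must be 'tumor' or 'normal'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(design$sample %in% colnames(mat))) {
    stop("design sample(s) missing from the matrix columns", call. = FALSE)
  }
  tab <- table(design$pair, design$condition)
  if (!all(dim(tab) == c(length(unique(design$pair)), 2L)) ||
      any(tab != 1L)) {
    stop("each pair must contain exactly one tumor and one normal sample",
         call. = FALSE)
  }
  if (nrow(tab) < 2L) {
    stop("at least 2 sample pairs are required", call. = FALSE)
  }
  invisible(design)
}

# per-transcript tumor - normal differences, one column per pair
paired_differences <- function(mat, design) {
  validate_design(mat, design)
  pairs <- sort(unique(design$pair))
  tum <- vapply(pairs, function(p)
    design$sample[design$pair == p & design$condition == "tumor"], "")
  nor <- vapply(pairs, function(p)
    design$sample[design$pair == p & design$condition == "normal"], "")
  d <- mat[, tum, drop = FALSE] - mat[, nor, drop = FALSE]
  colnames(d) <- pairs
  d
}

d_from_diffs <- function(diffs, s0) {
  k <- ncol(diffs)
  m <- rowMeans(diffs)
  sdv <- sqrt(pmax(rowSums(diffs^2) - k * m^2, 0) / (k - 1))
  se <- sdv / sqrt(k)
  d <- m / (se + s0)
  d[se + s0 == 0 & m == 0] <- 0
  d
}

#' Paired SAM score per transcript
#'
#' Scores each transcript by the change between paired tumor and normal
#' values relative to the variability of those paired differences:
#' `d = mean(diff) / (se(diff) + s0)` where `se = sd(diff) / sqrt(k)` over
#' the `k` pairs and `s0` is a small positive fudge constant that keeps
#' low-variance transcripts from dominating.
#'
#' @param mat Numeric transcripts x samples matrix (log2 scale).
#' @param design Data frame with columns `sample`, `condition`
#'   (`"tumor"`/`"normal"`) and `pair`; every sample belongs to exactly one
#'   complete pair and there are at least two pairs.
#' @param s0 Fudge constant added to the per-transcript standard error.
#'
#' @return Named numeric vector of d scores. Swapping the condition labels
#'   negates every score.
#' @export
sam_statistic <- function(mat, design, s0 = 0) {
  stopifnot(is.numeric(s0), length(s0) == 1L, s0 >= 0)
  d_from_diffs(paired_differences(mat, design), s0)
}

#' Estimate the SAM fudge constant
#'
#' Returns a low percentile (default the 5th) of the per-transcript standard
#' errors of the paired differences. Linear interpolation (the default
#' quantile definition) is used between order statistics.
#'
#' @inheritParams sam_statistic
#' @param prob Percentile of the standard-error distribution, in `(0, 1)`.
#'
#' @return A single non-negative number; 0 (with a warning) when the matrix
#'   is constant within every pair.
#' @export
estimate_s0 <- function(mat, design, prob = 0.05) {
  diffs <- paired_differences(mat, design)
  k <- ncol(diffs)
  m <- rowMeans(diffs)
  se <- sqrt(pmax(rowSums(diffs^2) - k * m^2, 0) / (k - 1)) / sqrt(k)
  if (all(se == 0)) {
    warning("all per-transcript standard errors are zero; s0 = 0")
    return(0)
  }
  stats::quantile(se, prob, names = FALSE)
}

#' Paired SAM test with sign-flip permutation p-values
#'
#' Builds the null distribution of the SAM score by randomly flipping the
#' sign of each pair's difference, pooling the permuted scores across all
#' transcripts (standard SAM practice, which stabilizes the tails). The raw
#' p-value of a transcript is the fraction of pooled null `|d|` values at or
#' above its observed `|d|`; Benjamini-Hochberg correction gives the adjusted
#' p-value.
#'
#' @inheritParams sam_statistic
#' @param n_perm Number of sign-flip permutations (at least 100).
#' @param s0 Fudge constant; estimated with [estimate_s0()] when `NULL`.
#' @param seed RNG seed for the permutations.
#' @param transcript_class Optional named character vector (`"lncRNA"` /
#'   `"mRNA"`) used by [select_de()] to split the selection.
#' @param keep_null Keep the full matrix of permuted scores (transcripts x
#'   permutations) in the result, for diagnostics.
#'
#' @return An object of class `sam_result`: list with `table` (data frame
#'   `id`, `class`, `d`, `p`, `adjusted_p`), `s0`, `n_perm`, `seed`, and
#'   `null_d` when requested.
#' @export
sam_de <- function(mat, design, n_perm = 1000L, s0 = NULL, seed = 1L,
                   transcript_class = NULL, keep_null = FALSE) {
  diffs <- paired_differences(mat, design)
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 100L) {
    stop("n_perm must be at least 100", call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  if (is.null(s0)) s0 <- estimate_s0(mat, design)
  k <- ncol(diffs)
  d <- d_from_diffs(diffs, s0)

  # sign flips leave the per-transcript sum of squares unchanged, so the
  # permuted scores need only the flipped means
  flips <- with_seed(seed,
    matrix(sample(c(-1, 1), k * n_perm, replace = TRUE), nrow = k))
  m_perm <- (diffs %*% flips) / k
  ss <- rowSums(diffs^2)
  sd_perm <- sqrt(pmax(ss - k * m_perm^2, 0) / (k - 1))
  d_perm <- m_perm / (sd_perm / sqrt(k) + s0)
  d_perm[sd_perm / sqrt(k) + s0 == 0 & m_perm == 0] <- 0

  null_abs <- sort(abs(as.numeric(d_perm)))
  n_null <- length(null_abs)
  p <- (n_null - findInterval(abs(d), null_abs, left.open = TRUE)) / n_null
  adjusted <- stats::p.adjust(p, method = "BH")

  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  cls <- if (is.null(transcript_class)) NA_character_ else
    unname(transcript_class[ids])
  structure(
    list(
      table = data.frame(id = ids, class = cls, d = unname(d), p = p,
                         adjusted_p = adjusted, stringsAsFactors = FALSE),
      s0 = s0, n_perm = n_perm, seed = seed,
      null_d = if (keep_null) d_perm else NULL
    ),
    class = "sam_result"
  )
}

#' @export
print.sam_result <- function(x, alpha = 0.01, ...) {
  cat(sprintf(
    "paired SAM result: %d transcripts, s0 = %.4g, %d permutations\n",
    nrow(x$table), x$s0, x$n_perm))
  cat(sprintf("  %d transcripts at adjusted p < %g\n",
              sum(x$table$adjusted_p < alpha), alpha))
  invisible(x)
}

#' Select differentially expressed transcripts
#'
#' @param result A [sam_de()] result.
#' @param alpha Adjusted-p threshold (strict `<`), default 0.01.
#'
#' @return List with `lncRNA` and `mRNA` character vectors of selected ids
#'   (ids with missing class are returned under `unclassified`).
#' @export
select_de <- function(result, alpha = 0.01) {
  stopifnot(inherits(result, "sam_result"))
  tab <- result$table[result$table$adjusted_p < alpha, , drop = FALSE]
  cls <- ifelse(is.na(tab$class), "unclassified", tab$class)
  out <- list(
    lncRNA = sort(tab$id[cls == "lncRNA"]),
    mRNA = sort(tab$id[cls == "mRNA"])
  )
  if (any(cls == "unclassified")) {
    out$unclassified <- sort(tab$id[cls == "unclassified"])
  }
  out
}
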