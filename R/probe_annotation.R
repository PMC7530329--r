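#' Filter probe-transcript alignment hits to unambiguous annotations
#'
#' Applies the three re-annotation criteria to a table of precomputed
#' alignment hits. First only perfect matches are retained (alignment length
#' equal to `perfect_match_length` and 100% identity). Then, in order:
#' (1) probes matching both a protein-coding and a lncRNA transcript are
#' removed; (2) within each class, probes matching more than one transcript
#' are removed; (3) only transcripts supported by more than three surviving
#' probes are kept.
#'
#' @param hits Data frame with columns `probe_id`, `transcript_id`,
#'   `transcript_class` (`"coding"` or `"lncRNA"`), `match_length`,
#'   `identity_pct`.
#' @param perfect_match_length Alignment length counted as a perfect match;
#'   probe length on the array, 60 nt by default.
#'
#' @return An object of class `probe_annotation`: a list with `mapping`
#'   (data frame `probe_id`, `transcript_id`, `transcript_class`; one row
#'   per probe) and `transcripts_kept` (character vector).
#' @export
filter_hits <- function(hits, perfect_match_length = 60L) {
  required <- c("probe_id", "transcript_id", "transcript_class",
                "match_length", "identity_pct")
  if (!is.data.frame(hits) || nrow(hits) == 0L) {
    stop("'hits' must be a non-empty data frame of probe alignment hits",
         call. = FALSE)
  }
  missing <- setdiff(required, names(hits))
  if (length(missing) > 0L) {
    stop("'hits' lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(hits$transcript_class), c("coding", "lncRNA"))
  if (length(bad) > 0L) {
    stop("unknown transcript_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  h <- hits[hits$match_length == perfect_match_length &
              hits$identity_pct == 100, required[1:3], drop = FALSE]
  h <- unique(h)
  h <- h[order(h$probe_id, h$transcript_id), , drop = FALSE]

  # (1) drop probes hitting both transcript classes
  n_class <- tapply(h$transcript_class, h$probe_id,
                    function(x) length(unique(x)))
  h <- h[n_class[h$probe_id] == 1L, , drop = FALSE]

  # (2) within the remaining single-class probes, drop multi-target probes
  n_tx <- tapply(h$transcript_id, h$probe_id,
                 function(x) length(unique(x)))
  h <- h[n_tx[h$probe_id] == 1L, , drop = FALSE]

  # (3) keep transcripts supported by more than three probes
  support <- table(h$transcript_id)
  kept_tx <- sort(names(support)[support > 3L])
  h <- h[h$transcript_id %in% kept_tx, , drop = FALSE]
  rownames(h) <- NULL

  structure(
    list(mapping = h, transcripts_kept = kept_tx),
    class = "probe_annotation"
  )
}

#' @export
print.probe_annotation <- function(x, ...) {
  cls <- x$mapping$transcript_class[match(x$transcripts_kept,
                                          x$mapping$transcript_id)]
  cat(sprintf(
    "probe annotation: %d probes -> %d transcripts (%d coding, %d lncRNA)\n",
    nrow(x$mapping), length(x$transcripts_kept),
    sum(cls == "coding"), sum(cls == "lncRNA")))
  invisible(x)
}

#' Collapse a probe-level expression matrix to transcript level
#'
#' Each kept transcript is summarized as the per-sample median of its
#' supporting probes, which is robust to a single aberrant probe.
#'
#' @param probe_matrix Numeric matrix, rows = probes (rownames required),
#'   columns = samples.
#' @param annotation A [filter_hits()] result.
#'
#' @return Numeric matrix with one row per kept transcript (zero rows when
#'   the annotation is empty), same columns as the input, and a
#'   `transcript_class` attribute (named character vector).
#' @export
collapse_to_transcripts <- function(probe_matrix, annotation) {
  stopifnot(inherits(annotation, "probe_annotation"),
            is.matrix(probe_matrix))
  map <- annotation$mapping
  out <- matrix(numeric(0), nrow = 0L, ncol = ncol(probe_matrix),
                dimnames = list(NULL, colnames(probe_matrix)))
  classes <- character(0)
  if (nrow(map) > 0L) {
    absent <- setdiff(map$probe_id, rownames(probe_matrix))
    if (length(absent) > 0L) {
      stop("annotated probe(s) missing from the probe matrix: ",
           paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
    }
    rows <- lapply(annotation$transcripts_kept, function(tx) {
      probes <- map$probe_id[map$transcript_id == tx]
      apply(probe_matrix[probes, , drop = FALSE], 2L, stats::median)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- annotation$transcripts_kept
    classes <- stats::setNames(
      map$transcript_class[match(annotation$transcripts_kept,
                                 map$transcript_id)],
      annotation$transcripts_kept)
  }
  attr(out, "transcript_class") <- classes
  out
}
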