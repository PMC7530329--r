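read_tsv_checked <- function(path, required = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L) {
      stop(sprintf("%s: missing column(s): %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Read an expression matrix from TSV
#'
#' Expects a header of sample ids and a first column of transcript ids.
#' Duplicate ids and non-numeric cells are reported with their location.
#'
#' @param path TSV file path.
#' @return Numeric matrix with transcript rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) {
    stop(sprintf("%s: expected an id column plus at least one sample", path),
         call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicate transcript id(s): %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    num <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(num) & !is.na(vals[[j]]))
    if (length(bad) > 0L) {
      stop(sprintf(
        "%s: non-numeric value '%s' at data row %d, column '%s'",
        path, vals[[j]][bad[1L]], bad[1L], names(vals)[j]), call. = FALSE)
    }
    vals[[j]] <- num
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix with transcript rownames.
#' @param path Output path.
#' @param id_column Name of the id column, default `"transcript_id"`.
#' @export
write_expression <- function(mat, path, id_column = "transcript_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a paired-sample design table
#'
#' @param path TSV with columns `sample`, `condition` (`tumor`/`normal`),
#'   `pair`.
#' @return Data frame.
#' @export
read_design <- function(path) {
  df <- read_tsv_checked(path, required = c("sample", "condition", "pair"))
  bad <- setdiff(unique(df$condition), c("tumor", "normal"))
  if (length(bad) > 0L) {
    stop(sprintf("%s: condition must be tumor/normal; found: %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a bipartite miRNA-interaction table
#'
#' @param path TSV with columns `gene_id`, `mirna_id`.
#' @param gene_class `"lncRNA"` or `"mRNA"`, attached as an attribute.
#' @return Data frame with a `gene_class` attribute.
#' @export
read_interactions <- function(path, gene_class = c("lncRNA", "mRNA")) {
  gene_class <- match.arg(gene_class)
  df <- read_tsv_checked(path, required = c("gene_id", "mirna_id"))
  df <- clean_edges(df, path)
  attr(df, "gene_class") <- gene_class
  df
}

#' Write a bipartite miRNA-interaction table
#' @param tab Data frame with columns `gene_id`, `mirna_id`.
#' @param path Output path.
#' @export
write_interactions <- function(tab, path) {
  utils::write.table(tab[, c("gene_id", "mirna_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-id-per-line list (e.g. seed genes)
#' @param path File path.
#' @return Character vector (blank lines dropped).
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}

#' Write a one-id-per-line list
#' @param ids Character vector.
#' @param path Output path.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Export a network in Cytoscape SIF format
#'
#' Each line is a tab-separated `source interaction target` triple: `ceRNA`
#' for lncRNA-mRNA edges, `lnc_mirna` / `mrna_mirna` for the interaction
#' layers of a triple network or module.
#'
#' @param x An `lclmn`, `triple_network` or `cerna_module` object.
#' @param path Output path.
#' @export
write_sif <- function(x, path) {
  lines <- if (inherits(x, "lclmn")) {
    paste(x$pairs$lnc, "ceRNA", x$pairs$mrna, sep = "\t")
  } else if (inherits(x, c("triple_network", "cerna_module"))) {
    c(paste(x$lnc_mi$gene_id, "lnc_mirna", x$lnc_mi$mirna_id, sep = "\t"),
      paste(x$mrna_mi$gene_id, "mrna_mirna", x$mrna_mi$mirna_id, sep = "\t"))
  } else {
    stop("write_sif() supports lclmn, triple_network and cerna_module",
         call. = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a SIF file
#' @param path SIF path.
#' @return Data frame with columns `source`, `interaction`, `target`.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d is not a tab-separated triple", path, bad[1L]),
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(source = m[, 1L], interaction = m[, 2L], target = m[, 3L],
             stringsAsFactors = FALSE)
}

#' Export a network as GraphML (for Cytoscape)
#'
#' GraphML keeps node classes and edge statistics as attributes, so it is the
#' lossless interchange format; SIF is the lightweight alternative.
#'
#' @param x An `lclmn`, `triple_network` or igraph object.
#' @param path Output path.
#' @export
write_graphml <- function(x, path) {
  ig <- to_igraph_input(x)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file
#' @param path GraphML path.
#' @return An igraph object.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  igraph::read_graph(path, format = "graphml")
}
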