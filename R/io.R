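# Readers and writers for the delimited-text formats the pipeline consumes:
# labeled feature tables (TSV/CSV) and Newick phylogenies.

#' Read a labeled feature table
#'
#' Reads a delimited text file (TSV or CSV, auto-detected from the file
#' extension) with one header row of sample/feature labels and one leading
#' label column, and returns a numeric matrix with dimnames. Typical inputs
#' are taxa x samples abundance tables or fiber x monosaccharide
#' composition tables.
#'
#' @param path path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param rows_are_features if `TRUE` (default) rows are features and
#'   columns samples; set `FALSE` to transpose on read so that rows are
#'   samples.
#' @return numeric matrix with row and column labels in file order.
#' @export
read_feature_table <- function(path, rows_are_features = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty file: ", path)
  if (length(lines) < 2L) stop("no data rows in ", path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1L]]
  col_labels <- header[-1L]
  if (anyDuplicated(col_labels)) {
    stop("duplicate column label(s): ",
         paste(unique(col_labels[duplicated(col_labels)]), collapse = ", "))
  }
  n_col <- length(header)
  widths <- lengths(cells[-1L])
  if (any(widths != n_col)) {
    stop(sprintf("ragged rows: expected %d fields, found %s", n_col,
                 paste(unique(widths[widths != n_col]), collapse = "/")))
  }
  body <- do.call(rbind, cells[-1L])
  row_labels <- body[, 1L]
  if (anyDuplicated(row_labels)) {
    stop("duplicate row label(s): ",
         paste(unique(row_labels[duplicated(row_labels)]), collapse = ", "))
  }
  payload <- suppressWarnings(
    matrix(as.numeric(body[, -1L, drop = FALSE]), nrow = nrow(body))
  )
  if (anyNA(payload)) {
    bad <- which(is.na(payload), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at row '%s', column '%s'",
                 row_labels[bad[1L]], col_labels[bad[2L]]))
  }
  dimnames(payload) <- list(row_labels, col_labels)
  if (!rows_are_features) payload <- t(payload)
  payload
}

#' Write a labeled feature table
#'
#' Inverse of [read_feature_table()]: writes a numeric matrix with dimnames
#' as TSV (or CSV by extension) with full precision, so a write/read
#' round-trip reproduces values to better than 1e-12.
#'
#' @param m numeric matrix with row and column names.
#' @param path output path; `.csv` selects comma separation, anything else tab.
#' @param label_header name of the leading label column (default `"id"`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(m, path, label_header = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- paste(c(label_header, colnames(m)), collapse = sep)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 17, trim = TRUE,
                                   scientific = TRUE)), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a Newick phylogeny
#'
#' Parses a rooted Newick tree (via \pkg{ape}) for use in weighted UniFrac.
#' Missing branch lengths are set to 0 with a warning; negative branch
#' lengths are an error.
#'
#' @param path path to a Newick file.
#' @return an [ape::read.tree()] `phylo` object with an `edge.length` vector.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) stop("empty Newick file: ", path)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in tree")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

#' Write a Newick phylogeny
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
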