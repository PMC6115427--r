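# Plain-TSV readers and writers for every table the pipeline
# exchanges, plus read-only GCT 1.2 support for expression. All
# writers emit headers the matching reader re-parses bit-identically.

.write_tsv <- function(x, path, row_label = NULL) {
  if (!is.null(row_label)) {
    x <- cbind(stats::setNames(data.frame(rownames(x),
                                          stringsAsFactors = FALSE),
                               row_label),
               as.data.frame(x, check.names = FALSE))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write / read a replicate-level viability panel
#'
#' Columns: `cell_line`, `condition`, `replicate`, `signal`.
#' @param panel panel data frame.
#' @param path file path.
#' @return `read_panel` returns the validated panel data frame.
#' @export
write_panel <- function(panel, path) .write_tsv(panel, path)

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  .validate_panel(p)
}

#' Write / read a dependency-profile table
#'
#' Columns: `cell_line`, `condition`, `score`, `n`, `class`.
#' @param profiles profile data frame from [build_profiles()].
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) .write_tsv(profiles, path)

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a numeric matrix as TSV with a leading id column
#'
#' @param m matrix with row and column names.
#' @param path file path.
#' @param row_label header of the leading id column.
#' @export
write_matrix <- function(m, path, row_label = "gene") {
  .write_tsv(m, path, row_label = row_label)
}

#' Read a gene x cell-line expression matrix (TSV or GCT 1.2)
#'
#' TSV: first column = gene symbol, remaining columns = cell lines.
#' GCT 1.2: `#1.2` header line, a dimensions line, then `Name`,
#' `Description` and sample columns. Row symbols pass through
#' [resolve_gene_alias()]; duplicated symbols and non-numeric cells
#' are errors that name the offender.
#'
#' @param path file path.
#' @param dialect `"auto"` (default; sniffs the `#1.2` magic),
#'   `"tsv"` or `"gct"`.
#' @return numeric matrix, genes x cell lines.
#' @export
read_matrix <- function(path, dialect = c("auto", "tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1)
    dialect <- if (identical(first, "#1.2")) "gct" else "tsv"
  }
  if (dialect == "gct") {
    hdr <- readLines(path, n = 2)
    if (!identical(hdr[1], "#1.2"))
      stop("read_matrix: '", path, "' lacks the #1.2 GCT header")
    dims <- as.integer(strsplit(hdr[2], "\t")[[1]][1:2])
    d <- utils::read.delim(path, skip = 2, stringsAsFactors = FALSE,
                           check.names = FALSE)
    if (nrow(d) != dims[1] || ncol(d) - 2 != dims[2])
      stop("read_matrix: GCT dimension line disagrees with the table")
    ids <- d[[1]]
    vals <- d[, -(1:2), drop = FALSE]
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    ids <- d[[1]]
    vals <- d[, -1, drop = FALSE]
  }
  ids <- resolve_gene_alias(ids)
  if (anyDuplicated(ids))
    stop("read_matrix: duplicated gene symbol(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop("read_matrix: non-numeric column(s): ",
         paste(colnames(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write sgRNA counts with library annotation
#'
#' Columns: `sgrna_id`, `gene`, `is_control`, then one column per
#' sample.
#' @param counts integer matrix, sgRNA x samples.
#' @param library data frame `sgrna_id`, `gene`, `is_control`.
#' @param path file path.
#' @export
write_counts <- function(counts, library, path) {
  stopifnot(all(library$sgrna_id == rownames(counts)))
  .write_tsv(cbind(library, as.data.frame(counts, check.names = FALSE)),
             path)
}

#' @rdname write_counts
#' @return `read_counts` returns a list with `counts` (integer
#'   matrix) and `library`.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  lib <- d[, c("sgrna_id", "gene", "is_control")]
  lib$is_control <- as.logical(lib$is_control)
  m <- as.matrix(d[, setdiff(names(d), names(lib)), drop = FALSE])
  rownames(m) <- lib$sgrna_id
  list(counts = m, library = lib)
}
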