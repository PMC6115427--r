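#' Canonical EMT marker signatures
#'
#' Fixed marker lists used for the epithelial and mesenchymal
#' marker-sum scores: epithelial = MUC1, CDH1 (E-cadherin), EPCAM,
#' CLDN3; mesenchymal = SNAI1 (Snail), SNAI2 (Slug), TWIST1, TWIST2,
#' VIM, CDH2 (N-cadherin).
#'
#' @param name `"epithelial"` or `"mesenchymal"`.
#' @return list with `name` and `genes`.
#' @export
#' @examples
#' signature_definition("mesenchymal")$genes
signature_definition <- function(name = c("epithelial", "mesenchymal")) {
  name <- match.arg(name)
  genes <- switch(name,
    epithelial = c("MUC1", "CDH1", "EPCAM", "CLDN3"),
    mesenchymal = c("SNAI1", "SNAI2", "TWIST1", "TWIST2", "VIM", "CDH2"))
  list(name = name, genes = genes)
}

# legacy protein names accepted for marker genes; anything else that
# fails to match a signature gene is reported, never guessed at
.gene_aliases <- c(SNAIL = "SNAI1", SLUG = "SNAI2",
                   "E-CADHERIN" = "CDH1", "N-CADHERIN" = "CDH2")

#' Resolve marker-gene aliases to canonical symbols
#'
#' @param genes character vector of gene symbols or known aliases
#'   (SNAIL, SLUG, E-cadherin, N-cadherin).
#' @return character vector of canonical symbols; unknown aliases pass
#'   through unchanged (they simply will not match a signature).
#' @export
resolve_gene_alias <- function(genes) {
  key <- toupper(genes)
  hit <- key %in% names(.gene_aliases)
  genes[hit] <- .gene_aliases[key[hit]]
  genes
}

#' Marker-sum signature score per cell line
#'
#' Sums the log2 expression of the signature's member genes for each
#' cell line. Member genes absent from the matrix are recorded and
#' excluded from the sum — never imputed — and the per-line gene count
#' is carried so cross-matrix comparisons can be restricted to
#' complete cases. With `standardize = TRUE` each member gene is
#' z-scored across lines before summing (for cross-dataset use; the
#' default raw sum is the study's definition).
#'
#' @param expression log2 expression matrix, genes x cell lines. Row
#'   names are passed through [resolve_gene_alias()].
#' @param definition a signature from [signature_definition()].
#' @param standardize z-score member genes before summing (default
#'   FALSE).
#' @return data frame with `cell_line`, `signature`, `score`,
#'   `n_genes`; attribute `"missing_genes"` lists absent members.
#' @export
signature_score <- function(expression, definition, standardize = FALSE) {
  rn <- resolve_gene_alias(rownames(expression))
  present <- definition$genes[definition$genes %in% rn]
  missing <- setdiff(definition$genes, present)
  if (length(present) == 0L)
    stop("signature_score: no '", definition$name,
         "' signature genes present in the matrix")
  sub <- expression[match(present, rn), , drop = FALSE]
  if (standardize) sub <- t(scale(t(sub)))
  out <- data.frame(cell_line = colnames(expression),
                    signature = definition$name,
                    score = colSums(sub),
                    n_genes = length(present),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "missing_genes") <- missing
  out
}

#' Per-tissue averages of a per-line quantity
#'
#' Arithmetic mean per tissue over lines with non-missing values; all
#' lines weigh equally. Works for signature scores, dependency scores
#' or synergy values alike.
#'
#' @param values named numeric vector (names = cell lines).
#' @param tissue_labels data frame with `cell_line`, `tissue`.
#' @return named numeric vector of tissue means; tissues with no
#'   usable line are dropped with a message.
#' @export
tissue_average <- function(values, tissue_labels) {
  tis <- tissue_labels$tissue[match(names(values), tissue_labels$cell_line)]
  keep <- !is.na(tis)
  if (!all(keep)) {
    message("tissue_average: dropping ", sum(!keep),
            " line(s) without a tissue label")
  }
  out <- tapply(values[keep], tis[keep], mean, na.rm = TRUE)
  empty <- is.nan(out)
  if (any(empty)) {
    message("tissue_average: dropping empty tissue(s): ",
            paste(names(out)[empty], collapse = ", "))
    out <- out[!empty]
  }
  c(out)
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson r and the two-sided p-value from the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of
#' freedom (via [stats::cor.test()]). Pairs with missing values are
#' dropped first.
#'
#' @param x,y numeric vectors of equal length; each must have at
#'   least 3 complete pairs and be non-constant.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  nx <- deparse(substitute(x)); ny <- deparse(substitute(y))
  if (length(x) != length(y)) stop("pearson: length mismatch")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pearson: fewer than 3 complete pairs")
  if (stats::var(x) == 0) stop("pearson: constant input '", nx, "'")
  if (stats::var(y) == 0) stop("pearson: constant input '", ny, "'")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Densitometry normalization of a protein band
#'
#' Ratio of a target band intensity (e.g. SLUG) to the loading-control
#' band (e.g. beta-actin) from the same lane, the standard western
#' blot quantitation; the normalized values feed [pearson()] against
#' dependency scores.
#'
#' @param target_band target band intensity (>= 0).
#' @param loading_band loading-control band intensity (> 0).
#' @return target/loading ratio.
#' @export
densitometry_normalize <- function(target_band, loading_band) {
  if (any(loading_band <= 0))
    stop("densitometry_normalize: loading band must be > 0")
  if (any(target_band < 0))
    stop("densitometry_normalize: negative target band")
  target_band / loading_band
}
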