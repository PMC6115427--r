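#' Reads-per-million normalization of sgRNA counts
#'
#' Per sample: `(count + pseudocount) / (sample total + pseudocount *
#' n_sgRNA) * 1e6`. The pseudocount (default 1) guards the log step
#' downstream against zero counts; at pseudocount 0 the transform is
#' exactly scale invariant.
#'
#' @param counts integer matrix, sgRNAs x samples (named rows/cols).
#' @param pseudocount added to every count (default 1).
#' @return numeric RPM matrix of the same shape.
#' @export
normalize_counts <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("normalize_counts: negative counts")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    stop("normalize_counts: all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts + pseudocount, 2, tot + pseudocount * nrow(counts), "/") * 1e6
}

#' Per-sgRNA log2 fold change, treated vs vehicle
#'
#' Replicates are averaged on the RPM scale within each condition and
#' the log is taken afterwards:
#' `log2(mean treated RPM) - log2(mean DMSO RPM)`. Averaging before
#' the log stabilizes sgRNAs with zeros in one replicate.
#'
#' @param normalized RPM matrix from [normalize_counts()].
#' @param treated,control column names of the treated and vehicle
#'   (DMSO) samples.
#' @return named numeric vector of per-sgRNA log2 fold changes.
#' @export
sgrna_lfc <- function(normalized, treated, control) {
  miss <- setdiff(c(treated, control), colnames(normalized))
  if (length(miss))
    stop("sgrna_lfc: sample(s) missing from table: ",
         paste(miss, collapse = ", "))
  if (length(treated) < 1 || length(control) < 1)
    stop("sgrna_lfc: need at least one replicate per condition")
  mt <- rowMeans(normalized[, treated, drop = FALSE])
  mc <- rowMeans(normalized[, control, drop = FALSE])
  log2(mt) - log2(mc)
}

#' Best-3 depletion score for one gene
#'
#' Mean of the gene's 3 most-depleted (smallest) sgRNA log2 fold
#' changes. The screen is negative selection, so "best" means most
#' depleted; a gene whose sgRNAs all gained can still have a positive
#' three-score.
#'
#' @param lfcs numeric vector of one gene's sgRNA log2 fold changes
#'   (length >= 3).
#' @return mean of the 3 smallest values.
#' @export
#' @examples
#' three_score(c(-3, -2, -1, 0, 0))  # -2
three_score <- function(lfcs) {
  lfcs <- lfcs[!is.na(lfcs)]
  if (length(lfcs) < 3)
    stop("three_score: fewer than 3 sgRNA fold changes")
  mean(sort(lfcs)[1:3])
}

.validate_library <- function(library) {
  need <- c("sgrna_id", "gene", "is_control")
  miss <- setdiff(need, names(library))
  if (length(miss))
    stop("library is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(library$sgrna_id))
    stop("library has duplicated sgrna_id values")
  tab <- table(library$gene[!library$is_control])
  short <- names(tab)[tab < 3]
  if (length(short))
    stop("gene(s) with fewer than 3 sgRNAs (three-score undefined): ",
         paste(short, collapse = ", "))
  library
}

#' Score a negative-selection pooled CRISPR screen
#'
#' Full pipeline: RPM-normalize the counts, compute per-sgRNA log2
#' fold changes of treated vs DMSO, aggregate each gene's best 3
#' depleted sgRNAs into its depletion metric (DM = three-score, log2
#' scale), and rank genes ascending (most depleted first). Control
#' sgRNAs are chunked, in sorted id order, into pseudo-genes of the
#' modal library size; a gene is flagged as a sensitizer hit when its
#' DM falls below the 5th percentile of the control pseudo-gene DM
#' distribution (a package convention — the original analysis called
#' hits by inspection).
#'
#' @param counts integer matrix, sgRNAs x samples (row names =
#'   sgrna_id).
#' @param library data frame with `sgrna_id`, `gene`, `is_control`.
#' @param treated,control column names of treated and DMSO samples.
#' @param pseudocount see [normalize_counts()].
#' @return list of class `bh3_screen_result`:
#'   * `genes`: data frame `gene`, `dm`, `z` (DM standardized against
#'     the control pseudo-gene distribution), `rank`, `hit`, ranked
#'     ascending by DM;
#'   * `sgrnas`: data frame `sgrna_id`, `gene`, `is_control`, `lfc`;
#'   * `controls`: numeric vector of control pseudo-gene DMs;
#'   * `hit_cutoff`: the 5th-percentile DM cutoff.
#' @export
score_screen <- function(counts, library, treated, control,
                         pseudocount = 1) {
  library <- .validate_library(library)
  counts <- as.matrix(counts)
  miss <- setdiff(library$sgrna_id, rownames(counts))
  if (length(miss))
    stop("score_screen: library sgRNA(s) missing from counts: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  counts <- counts[library$sgrna_id, , drop = FALSE]
  rpm <- normalize_counts(counts, pseudocount)
  lfc <- sgrna_lfc(rpm, treated, control)
  sg <- data.frame(sgrna_id = library$sgrna_id, gene = library$gene,
                   is_control = library$is_control, lfc = unname(lfc),
                   stringsAsFactors = FALSE)
  tgt <- sg[!sg$is_control, ]
  dm <- tapply(tgt$lfc, tgt$gene, three_score)
  # deterministic control pseudo-genes: chunk sorted control ids into
  # groups the size of a typical library gene
  ctl <- sg[sg$is_control, ]
  ctl <- ctl[order(ctl$sgrna_id), ]
  per_gene <- as.integer(stats::median(table(tgt$gene)))
  ctrl_dm <- numeric(0)
  if (nrow(ctl) >= 3) {
    grp <- ceiling(seq_len(nrow(ctl)) / per_gene)
    full <- names(table(grp))[table(grp) >= 3]
    ctrl_dm <- vapply(full, function(g) three_score(ctl$lfc[grp == g]),
                      numeric(1))
    names(ctrl_dm) <- paste0("control_", full)
  }
  cutoff <- if (length(ctrl_dm) >= 2)
    unname(stats::quantile(ctrl_dm, 0.05)) else NA_real_
  genes <- data.frame(gene = names(dm), dm = unname(dm),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$dm, genes$gene), ]
  genes$rank <- seq_len(nrow(genes))
  genes$z <- if (length(ctrl_dm) >= 2)
    (genes$dm - mean(ctrl_dm)) / stats::sd(ctrl_dm) else NA_real_
  genes$hit <- if (is.na(cutoff)) NA else genes$dm < cutoff
  rownames(genes) <- NULL
  structure(list(genes = genes, sgrnas = sg, controls = ctrl_dm,
                 hit_cutoff = cutoff),
            class = "bh3_screen_result")
}

#' @export
print.bh3_screen_result <- function(x, ...) {
  cat("CRISPR screen:", nrow(x$genes), "genes,",
      sum(x$sgrnas$is_control), "control sgRNAs\n")
  cat("Most depleted:\n")
  print(utils::head(x$genes, 5), row.names = FALSE)
  invisible(x)
}
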