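#' Ordinary least squares fit of sensitivity scores on a design matrix
#'
#' Fits `y = X beta + eps` with `eps ~ N(0, sigma^2 I)` by OLS via
#' [stats::lm()], after checking that `X` carries an intercept column
#' and is full rank. Per-column two-sided p-values come from the t
#' distribution with `n - p` degrees of freedom.
#'
#' @param y numeric vector of sensitivity (dependency) scores.
#' @param X numeric design matrix with named columns, including an
#'   intercept column of ones.
#' @param phenotype optional name for the response, carried in the
#'   result.
#' @return an object of class `bh3_linear_fit`: list with `phenotype`,
#'   `coefficients`, `p_values` (non-intercept columns), `sigma2`,
#'   `r_squared`, `n`, `fitted`, `residuals`, `y`.
#' @export
fit_linear <- function(y, X, phenotype = "phenotype") {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y))
    stop("fit_linear: nrow(X) != length(y)")
  if (length(y) <= ncol(X))
    stop("fit_linear: need more observations than columns")
  const_cols <- apply(X, 2, function(v) length(unique(v)) == 1L)
  intercept <- which(const_cols & X[1, ] == 1)
  if (length(intercept) == 0L)
    stop("fit_linear: X must include an intercept column of ones")
  if (any(const_cols & X[1, ] != 1))
    stop("fit_linear: constant non-intercept column: ",
         paste(colnames(X)[const_cols & X[1, ] != 1], collapse = ", "))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("fit_linear: design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(y ~ X - 1)
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  sm <- summary(fit)
  pv <- sm$coefficients[, 4]
  names(pv) <- colnames(X)
  pv <- pv[setdiff(colnames(X), colnames(X)[intercept[1]])]
  res <- stats::residuals(fit)
  structure(list(
    phenotype = phenotype,
    coefficients = beta,
    p_values = pv,
    sigma2 = sum(res^2) / (length(y) - ncol(X)),
    r_squared = .r2(y, res),
    n = length(y),
    fitted = stats::fitted(fit),
    residuals = res,
    y = y
  ), class = "bh3_linear_fit")
}

.r2 <- function(y, residuals) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant response: R-squared defined as 0")
    return(0)
  }
  1 - sum(residuals^2) / ss_tot
}

#' Goodness of fit of a linear model
#'
#' `R^2 = 1 - SS_res / SS_tot`, with `SS_tot` taken about the mean of
#' the observed response. A constant response gives `SS_tot = 0`; the
#' statistic is then defined as 0 with a warning.
#'
#' @param fit a `bh3_linear_fit` from [fit_linear()].
#' @return `R^2` in `[0, 1]` for models with an intercept.
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "bh3_linear_fit"))
  .r2(fit$y, fit$residuals)
}

#' @export
print.bh3_linear_fit <- function(x, ...) {
  cat("Linear fit:", x$phenotype, " n =", x$n,
      " R^2 =", format(x$r_squared, digits = 4), "\n")
  invisible(x)
}

#' Compare tissue of origin vs mutation status as dependency predictors
#'
#' For each dependency phenotype, fits a tissue-only model (tissue
#' indicator columns) and a mutation-only model (one 0/1 column per
#' gene) and reports both goodness-of-fit values plus the winner. A
#' gene mutated in every line or no line carries no information and is
#' dropped from the design; a phenotype with all-missing scores is
#' skipped.
#'
#' @param profiles output of [build_profiles()].
#' @param tissue_labels data frame with columns `cell_line`, `tissue`.
#' @param mutation_table 0/1 matrix, genes x cell lines ("mutant"
#'   covers point mutations, amplifications and deletions as a single
#'   state).
#' @param phenotypes panel conditions to model (default: all 7).
#' @return data frame with columns `phenotype`, `r2_tissue`,
#'   `r2_mutation`, `winner`, `n`.
#' @export
compare_predictors <- function(profiles, tissue_labels, mutation_table,
                               phenotypes = setdiff(PANEL_CONDITIONS, "VEH")) {
  m <- profiles_to_matrix(profiles)
  shared <- intersect(rownames(m),
                      intersect(tissue_labels$cell_line, colnames(mutation_table)))
  tis <- tissue_labels$tissue[match(shared, tissue_labels$cell_line)]
  mut <- t(mutation_table[, shared, drop = FALSE])
  informative <- apply(mut, 2, function(v) length(unique(v)) > 1L)
  mut <- mut[, informative, drop = FALSE]
  X_tis <- stats::model.matrix(~tissue, data.frame(tissue = factor(tis)))
  X_mut <- cbind(`(Intercept)` = 1, mut)
  max_p <- max(ncol(X_tis), ncol(X_mut))
  if (length(shared) < 3 + max_p)
    stop("compare_predictors: too few shared cell lines (", length(shared),
         ") for ", max_p, " predictor columns")
  rows <- lapply(phenotypes, function(ph) {
    y <- m[shared, ph]
    if (all(is.na(y))) {
      message("compare_predictors: skipping '", ph, "' (all scores missing)")
      return(NULL)
    }
    ok <- !is.na(y)
    r2t <- r_squared(fit_linear(y[ok], X_tis[ok, , drop = FALSE], ph))
    r2m <- r_squared(fit_linear(y[ok], X_mut[ok, , drop = FALSE], ph))
    data.frame(phenotype = ph, r2_tissue = r2t, r2_mutation = r2m,
               winner = if (r2t > r2m) "tissue" else if (r2m > r2t)
                 "mutation" else "tie",
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-gene expression-dependency association
#'
#' Simple linear regression of each phenotype's dependency score on
#' each gene's log2 expression, one gene at a time. Reports the slope
#' sign, the two-sided p-value of the slope, and `1/p` for the
#' inverse-p plots used to visualise the best correlate per phenotype.
#' Raw p-values are reported by default; Benjamini-Hochberg adjusted
#' values are added when `adjust = "BH"`.
#'
#' @param profiles output of [build_profiles()].
#' @param expression log2 expression matrix, genes x cell lines.
#' @param genes gene symbols to test (default: all rows of
#'   `expression`).
#' @param phenotypes panel conditions to test (default: all 7).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame with columns `phenotype`, `gene`, `slope`,
#'   `p_value`, `inverse_p`, `n` (and `p_adj` when adjusted);
#'   zero-variance genes are skipped with a message.
#' @export
expression_association <- function(profiles, expression,
                                   genes = rownames(expression),
                                   phenotypes = setdiff(PANEL_CONDITIONS, "VEH"),
                                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- profiles_to_matrix(profiles)
  shared <- intersect(rownames(m), colnames(expression))
  if (length(shared) < 4)
    stop("expression_association: fewer than 4 shared cell lines")
  genes <- intersect(genes, rownames(expression))
  rows <- list()
  for (ph in phenotypes) {
    y <- m[shared, ph]
    for (g in genes) {
      x <- expression[g, shared]
      ok <- !is.na(y) & !is.na(x)
      if (sum(ok) < 4) next
      if (stats::var(x[ok]) == 0) {
        message("expression_association: skipping zero-variance gene '", g, "'")
        next
      }
      fit <- stats::lm(y[ok] ~ x[ok])
      co <- summary(fit)$coefficients
      p <- co[2, 4]
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph, gene = g, slope = co[2, 1],
        p_value = p, inverse_p = 1 / p, n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH" && !is.null(out)) {
    out$p_adj <- stats::ave(out$p_value, out$phenotype,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  }
  out
}

# pooled / Welch two-sample t over every admissible split of scores
# sorted by expression, vectorised with cumulative sums. Returns one
# row per candidate split (midpoints between consecutive distinct
# expression values satisfying the group-size floor).
.split_scan <- function(expr, scores, min_group_size, welch = FALSE) {
  ord <- order(expr)
  e <- expr[ord]; s <- scores[ord]
  n <- length(s)
  # last index of each run of tied expression values = admissible cut
  cut_idx <- which(diff(e) > 0)
  cut_idx <- cut_idx[cut_idx >= min_group_size & (n - cut_idx) >= min_group_size]
  if (length(cut_idx) == 0L) return(NULL)
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  n1 <- cut_idx; n2 <- n - cut_idx
  m1 <- cs[cut_idx] / n1
  m2 <- (cs[n] - cs[cut_idx]) / n2
  ss1 <- cs2[cut_idx] - n1 * m1^2
  ss2 <- (cs2[n] - cs2[cut_idx]) - n2 * m2^2
  if (welch) {
    v1 <- ss1 / (n1 - 1); v2 <- ss2 / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- (ss1 + ss2) / (n - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n - 2, length(cut_idx))
  }
  tt <- (m2 - m1) / sqrt(se2)
  # zero within-group variance: perfect separation (p = 0) unless the
  # group means coincide too (p = 1)
  zero <- se2 == 0
  tt[zero] <- sign(m2[zero] - m1[zero]) * Inf
  tt[zero & m2 == m1] <- 0
  p <- 2 * stats::pt(-abs(tt), df)
  data.frame(threshold = (e[cut_idx] + e[cut_idx + 1]) / 2,
             n_below = n1, n_above = n2,
             mean_below = m1, mean_above = m2,
             t = tt, p_value = p)
}

#' Sliding-scale expression threshold search
#'
#' Finds the expression cutpoint that best segregates cell lines into
#' high- and low-score groups. Every midpoint between consecutive
#' distinct sorted expression values whose split leaves at least
#' `min_group_size` lines on each side is evaluated with a two-sample
#' t-test on the scores; the split with the smallest p-value wins.
#' Ties on p are broken by the larger between-group mean difference,
#' then the lower threshold, so the result is deterministic.
#'
#' Because the minimum is taken over many correlated tests, the
#' reported `p_value` is selection-biased and is not uniform under the
#' null; set `n_perm > 0` for a permutation-adjusted p-value
#' (`p_perm`) that is calibrated.
#'
#' @param expression per-line log2 expression values (named or
#'   parallel to `scores`).
#' @param scores per-line phenotype (dependency) scores.
#' @param min_group_size smallest admissible group (default 3).
#' @param ttest `"pooled"` (Student, default) or `"welch"`.
#' @param n_perm number of score permutations for the adjusted
#'   p-value; 0 (default) skips it.
#' @return an object of class `bh3_threshold`: list with `threshold`,
#'   `direction` (`"above-sensitive"` or `"below-sensitive"`),
#'   `p_value`, `n_above`, `n_below`, `mean_above`, `mean_below`,
#'   `min_group_size`, `ttest`, and `p_perm` when requested.
#' @export
find_threshold <- function(expression, scores, min_group_size = 3,
                           ttest = c("pooled", "welch"), n_perm = 0) {
  ttest <- match.arg(ttest)
  ok <- !is.na(expression) & !is.na(scores)
  expression <- expression[ok]; scores <- scores[ok]
  n <- length(scores)
  if (n < 2 * min_group_size)
    stop("find_threshold: need at least 2*min_group_size observations")
  if (length(unique(expression)) < 2)
    stop("find_threshold: expression has fewer than 2 distinct values")
  scan <- .split_scan(expression, scores, min_group_size,
                      welch = ttest == "welch")
  if (is.null(scan)) stop("find_threshold: no admissible split")
  best <- scan[order(scan$p_value, -abs(scan$mean_above - scan$mean_below),
                     scan$threshold), ][1, ]
  res <- structure(list(
    threshold = best$threshold,
    direction = if (best$mean_above >= best$mean_below)
      "above-sensitive" else "below-sensitive",
    p_value = best$p_value,
    n_above = best$n_above, n_below = best$n_below,
    mean_above = best$mean_above, mean_below = best$mean_below,
    min_group_size = min_group_size, ttest = ttest
  ), class = "bh3_threshold")
  if (n_perm > 0) {
    obs <- best$p_value
    hits <- 0L
    for (b in seq_len(n_perm)) {
      sc <- .split_scan(expression, sample(scores), min_group_size,
                        welch = ttest == "welch")
      if (min(sc$p_value) <= obs) hits <- hits + 1L
    }
    res$p_perm <- (hits + 1) / (n_perm + 1)
  }
  res
}

#' @export
print.bh3_threshold <- function(x, ...) {
  cat("Expression threshold", format(x$threshold, digits = 4),
      "(", x$direction, ")  p =", format(x$p_value, digits = 3),
      " n =", x$n_below, "below /", x$n_above, "above\n")
  if (!is.null(x$p_perm))
    cat("  permutation-adjusted p =", format(x$p_perm, digits = 3), "\n")
  invisible(x)
}

#' Validate a fixed expression threshold on an independent cohort
#'
#' Splits an external cohort at a previously identified threshold
#' (not re-fit) and compares the two groups' sensitivity values
#' (e.g. log2 IC50) with a two-sample t-test.
#'
#' @param threshold a `bh3_threshold` or a single numeric cutpoint.
#' @param external_expression named per-line expression values.
#' @param external_sensitivity named per-line sensitivity values.
#' @param ttest `"pooled"` or `"welch"`.
#' @return list with `threshold`, `n_below`, `n_above`, `mean_below`,
#'   `mean_above`, `p_value`.
#' @export
validate_threshold <- function(threshold, external_expression,
                               external_sensitivity,
                               ttest = c("pooled", "welch")) {
  ttest <- match.arg(ttest)
  thr <- if (inherits(threshold, "bh3_threshold")) threshold$threshold
         else as.numeric(threshold)
  shared <- intersect(names(external_expression), names(external_sensitivity))
  if (length(shared)) {
    external_expression <- external_expression[shared]
    external_sensitivity <- external_sensitivity[shared]
  }
  ok <- !is.na(external_expression) & !is.na(external_sensitivity)
  e <- external_expression[ok]; s <- external_sensitivity[ok]
  below <- s[e < thr]; above <- s[e >= thr]
  if (length(below) < 2 || length(above) < 2)
    stop("validate_threshold: threshold leaves fewer than 2 lines on a side")
  tt <- stats::t.test(above, below, var.equal = ttest == "pooled")
  list(threshold = thr, n_below = length(below), n_above = length(above),
       mean_below = mean(below), mean_above = mean(above),
       p_value = tt$p.value)
}

#' Tissue-average outlier analysis
#'
#' For each cell line, the percentage difference of each phenotype's
#' dependency score and each gene's expression relative to the average
#' of its tissue of origin. Dependency deltas are
#' `100 * (score - tissue mean) / tissue mean` (defined as 0 when both
#' are 0); expression deltas are computed analogously on the linear
#' scale (after un-logging) so "percentage" stays meaningful.
#' When an `associations` table is given, a concordance flag marks
#' lines whose dependency and driver-gene expression deviate in the
#' direction the association predicts.
#'
#' @param profiles output of [build_profiles()].
#' @param expression log2 expression matrix, genes x cell lines.
#' @param tissue_labels data frame with `cell_line`, `tissue`.
#' @param phenotypes panel conditions to report.
#' @param genes genes to report expression deltas for.
#' @param associations optional data frame with columns `phenotype`,
#'   `gene`, `sign` (+1/-1) describing expected
#'   expression-to-dependency directions.
#' @return data frame with one row per line x phenotype x gene:
#'   `cell_line`, `tissue`, `phenotype`, `gene`, `dep_delta`,
#'   `expr_delta`, `concordant` (NA without an association entry).
#'   Lines in singleton tissues are skipped with a message.
#' @export
outlier_analysis <- function(profiles, expression, tissue_labels,
                             phenotypes = c("A199", "W539", "A121"),
                             genes = rownames(expression),
                             associations = NULL) {
  m <- profiles_to_matrix(profiles)
  shared <- intersect(rownames(m), colnames(expression))
  shared <- intersect(shared, tissue_labels$cell_line)
  tis <- tissue_labels$tissue[match(shared, tissue_labels$cell_line)]
  counts <- table(tis)
  single <- names(counts)[counts < 2]
  if (length(single)) {
    message("outlier_analysis: skipping singleton tissue(s): ",
            paste(single, collapse = ", "))
    keep <- !(tis %in% single)
    shared <- shared[keep]; tis <- tis[keep]
  }
  genes <- intersect(genes, rownames(expression))
  pct_delta <- function(v, mu) {
    ifelse(mu == 0, ifelse(v == 0, 0, NA_real_), 100 * (v - mu) / mu)
  }
  rows <- list()
  for (tt in unique(tis)) {
    lines <- shared[tis == tt]
    dep_mu <- colMeans(m[lines, phenotypes, drop = FALSE], na.rm = TRUE)
    lin_expr <- 2^expression[genes, lines, drop = FALSE]
    expr_mu <- rowMeans(lin_expr, na.rm = TRUE)
    for (cl in lines) for (ph in phenotypes) for (g in genes) {
      dd <- pct_delta(m[cl, ph], dep_mu[[ph]])
      ed <- pct_delta(lin_expr[g, cl], expr_mu[[g]])
      conc <- NA
      if (!is.null(associations)) {
        a <- associations[associations$phenotype == ph &
                            associations$gene == g, ]
        if (nrow(a) == 1 && !is.na(dd) && !is.na(ed) && dd != 0 && ed != 0)
          conc <- sign(dd) == sign(ed) * a$sign[1]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cl, tissue = tt, phenotype = ph, gene = g,
        dep_delta = dd, expr_delta = ed, concordant = conc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
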