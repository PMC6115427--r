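# Shared fixtures and independent oracles used across the suite.

# A small hand-set panel: 2 lines x 3 conditions x 2 replicates.
tiny_panel <- function() {
  data.frame(
    cell_line = rep(c("L1", "L2"), each = 6),
    condition = rep(rep(c("VEH", "W539", "A121"), each = 2), 2),
    replicate = rep(1:2, 6),
    signal = c(1000, 1000, 500, 500, 800, 800,    # L1: 50, 20
               2000, 2000, 1800, 1800, 400, 400), # L2: 10, 80
    stringsAsFactors = FALSE)
}

# random replicate-level panel over all 8 conditions
random_panel <- function(n_lines = 4, reps = 3) {
  g <- expand.grid(replicate = seq_len(reps),
                   condition = bh3map::PANEL_CONDITIONS,
                   cell_line = paste0("L", seq_len(n_lines)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$signal <- stats::runif(nrow(g), 100, 2000)
  g[, c("cell_line", "condition", "replicate", "signal")]
}

# brute-force threshold oracle: every midpoint between consecutive
# distinct sorted expression values, two-sample t-test via stats::t.test,
# identical tie-breaking to the implementation but computed independently.
brute_threshold <- function(expr, scores, min_group_size = 3,
                            welch = FALSE) {
  ord <- order(expr)
  e <- expr[ord]; s <- scores[ord]
  u <- sort(unique(e))
  cand <- (u[-length(u)] + u[-1]) / 2
  rows <- lapply(cand, function(th) {
    lo <- s[e < th]; hi <- s[e > th]
    if (length(lo) < min_group_size || length(hi) < min_group_size)
      return(NULL)
    se2 <- if (welch) {
      stats::var(lo) / length(lo) + stats::var(hi) / length(hi)
    } else {
      vp <- (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
        (length(lo) + length(hi) - 2)
      vp * (1 / length(lo) + 1 / length(hi))
    }
    p <- if (se2 == 0) {
      if (mean(lo) == mean(hi)) 1 else 0
    } else {
      stats::t.test(hi, lo, var.equal = !welch)$p.value
    }
    data.frame(threshold = th, p = p, diff = abs(mean(hi) - mean(lo)),
               dir = if (mean(hi) >= mean(lo)) "above-sensitive"
                     else "below-sensitive")
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(NULL)
  tab[order(tab$p, -tab$diff, tab$threshold), ][1, ]
}

# index of the inter-point gap (among sorted distinct expression
# values) that a threshold falls into; used for recovery checks
gap_index <- function(threshold, expr) {
  findInterval(threshold, sort(unique(expr)))
}
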