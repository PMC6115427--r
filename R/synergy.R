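#' Bliss synergy, printed-formula variant
#'
#' The study's printed synergy formula on the 0-1 dependence scale:
#' `(1 - x)(1 - m) - combo`, where `x` and `m` are the single-agent
#' BCL-XL and MCL-1 dependence scores divided by 100 and `combo` is
#' the observed co-dependence. Note this variant assigns +1 to a line
#' with no response to anything; see [bliss_synergy_excess()] for the
#' canonical Bliss excess, which is the package default for grouping.
#'
#' @param x_dep,m_dep,combo_dep dependence scores on the 0-1 scale
#'   (dependency scores divided by 100).
#' @return numeric synergy value.
#' @export
bliss_synergy_printed <- function(x_dep, m_dep, combo_dep) {
  .check_unit(x_dep, "x_dep"); .check_unit(m_dep, "m_dep")
  .check_unit(combo_dep, "combo_dep")
  (1 - x_dep) * (1 - m_dep) - combo_dep
}

#' Bliss synergy, excess-over-independence variant
#'
#' Canonical Bliss excess on the dependence (viability-loss fraction)
#' scale: `combo - (1 - (1 - x)(1 - m))`. Under Bliss independence the
#' combined survival fraction is the product of single-agent survival
#' fractions, so the expected combined loss is `1 - (1-x)(1-m)`; the
#' excess is the observed combined loss minus that expectation. Zero
#' means exact additivity, positive means synergy.
#'
#' @inheritParams bliss_synergy_printed
#' @return numeric synergy value in `[-1, 1]`.
#' @export
#' @examples
#' bliss_synergy_excess(0.5, 0.5, 0.75)  # exactly additive: 0
bliss_synergy_excess <- function(x_dep, m_dep, combo_dep) {
  .check_unit(x_dep, "x_dep"); .check_unit(m_dep, "m_dep")
  .check_unit(combo_dep, "combo_dep")
  combo_dep - (1 - (1 - x_dep) * (1 - m_dep))
}

.check_unit <- function(v, name) {
  if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1))
    stop(name, " must be in [0, 1]")
  invisible(v)
}

#' Assign a cell line to a synergy response group
#'
#' Three groups: `"single-dependent"` if either single-agent
#' dependence exceeds `single_cutoff`; otherwise
#' `"synergistic co-dependent"` if the synergy value exceeds
#' `synergy_cutoff` and the combination score passes the
#' `dependent>25` cutoff; otherwise `"insensitive"`.
#'
#' @inheritParams bliss_synergy_printed
#' @param synergy synergy value for the line (excess scale by
#'   default; see [compute_synergy()]).
#' @param single_cutoff single-agent dependence cutoff on the 0-1
#'   scale (default 0.25, i.e. the 25-point viability-loss cutoff).
#' @param synergy_cutoff synergy cutoff (default 0.25 on the excess
#'   scale; the study states none, so it is configurable).
#' @return one of `"single-dependent"`, `"synergistic co-dependent"`,
#'   `"insensitive"`.
#' @export
assign_group <- function(x_dep, m_dep, combo_dep, synergy,
                         single_cutoff = 0.25, synergy_cutoff = 0.25) {
  if (is.na(combo_dep)) stop("assign_group: missing combination score")
  if (is.na(x_dep) || is.na(m_dep))
    stop("assign_group: missing single-agent score")
  if (x_dep > single_cutoff || m_dep > single_cutoff)
    "single-dependent"
  else if (!is.na(synergy) && synergy > synergy_cutoff &&
           classify(combo_dep * 100, "dependent>25"))
    "synergistic co-dependent"
  else
    "insensitive"
}

#' Per-cell-line BCL-XL + MCL-1 synergy table
#'
#' Extracts the BCL-XL (`W539`), MCL-1 (`A121`) and combination
#' (`W539+A121`) dependency scores from a profile table, rescales them
#' to 0-1, computes both Bliss synergy variants, and assigns each line
#' to a response group.
#'
#' @param profiles output of [build_profiles()].
#' @param formula which synergy variant drives the group assignment:
#'   `"excess"` (default) or `"printed"`.
#' @inheritParams assign_group
#' @return data frame with columns `cell_line`, `x_dep`, `m_dep`,
#'   `combo_dep` (0-1 scale), `synergy_printed`, `synergy_excess`,
#'   `group`.
#' @export
compute_synergy <- function(profiles, formula = c("excess", "printed"),
                            single_cutoff = 0.25, synergy_cutoff = 0.25) {
  formula <- match.arg(formula)
  m <- profiles_to_matrix(profiles)
  need <- c("W539", "A121", "W539+A121")
  if (!all(need %in% colnames(m)))
    stop("profiles lack required conditions: ",
         paste(setdiff(need, colnames(m)), collapse = ", "))
  x <- m[, "W539"] / 100
  mm <- m[, "A121"] / 100
  cb <- m[, "W539+A121"] / 100
  printed <- bliss_synergy_printed(x, mm, cb)
  excess <- bliss_synergy_excess(x, mm, cb)
  drv <- if (formula == "excess") excess else printed
  grp <- vapply(seq_along(x), function(i)
    assign_group(x[i], mm[i], cb[i], drv[i], single_cutoff, synergy_cutoff),
    character(1))
  data.frame(cell_line = rownames(m), x_dep = unname(x), m_dep = unname(mm),
             combo_dep = unname(cb), synergy_printed = unname(printed),
             synergy_excess = unname(excess), group = grp,
             stringsAsFactors = FALSE, row.names = NULL)
}
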