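#' @details
#' The eight-condition panel vocabulary. `VEH` is the vehicle (DMSO)
#' control; the three single agents are `A199` (ABT-199 / venetoclax,
#' BCL-2), `W539` (WEHI-539, BCL-XL) and `A121` (A-1210477, MCL-1);
#' the pairwise combinations and the `TRIPLE` combination complete the
#' panel.
#' @rdname panel_conditions
#' @export
PANEL_CONDITIONS <- c("VEH", "A199", "W539", "A121",
                      "A199+W539", "A199+A121", "W539+A121", "TRIPLE")

# drug-name aliases accepted at read time; everything else fails loudly
.condition_aliases <- c(
  "VEH"                        = "VEH",
  "VEHICLE"                    = "VEH",
  "DMSO"                       = "VEH",
  "A199"                       = "A199",
  "ABT-199"                    = "A199",
  "ABT199"                     = "A199",
  "VENETOCLAX"                 = "A199",
  "W539"                       = "W539",
  "WEHI-539"                   = "W539",
  "WEHI539"                    = "W539",
  "A121"                       = "A121",
  "A-1210477"                  = "A121",
  "A1210477"                   = "A121",
  "A199+W539"                  = "A199+W539",
  "ABT-199+WEHI-539"           = "A199+W539",
  "A199+A121"                  = "A199+A121",
  "ABT-199+A-1210477"          = "A199+A121",
  "W539+A121"                  = "W539+A121",
  "WEHI-539+A-1210477"         = "W539+A121",
  "TRIPLE"                     = "TRIPLE",
  "A199+W539+A121"             = "TRIPLE",
  "ABT-199+WEHI-539+A-1210477" = "TRIPLE"
)

#' Canonical panel condition labels
#'
#' Maps condition labels (including common drug-name aliases such as
#' `"ABT-199"` or `"venetoclax"`) onto the fixed eight-condition panel
#' vocabulary in [PANEL_CONDITIONS]. Unknown labels are an error, never
#' silently passed through.
#'
#' @param x character vector of condition labels.
#' @return character vector of canonical labels.
#' @export
#' @examples
#' normalize_condition(c("DMSO", "venetoclax", "W539+A121"))
normalize_condition <- function(x) {
  key <- toupper(trimws(as.character(x)))
  out <- .condition_aliases[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown panel condition label(s): ", paste(bad, collapse = ", "))
  }
  unname(out)
}

#' Percentage viability loss (dependency score)
#'
#' Converts replicate luminescence signals for one cell line under one
#' treatment into a viability-loss score,
#' `100 * (1 - mean(treated) / mean(untreated))`, clamped to `[0, 99]`
#' so that 0 means no apparent viability loss and the score never
#' reaches 100. Replicates are averaged before the ratio is taken.
#'
#' @param treated_signals numeric vector of treated-well signals
#'   (arbitrary luminescence units, >= 0).
#' @param untreated_signals numeric vector of vehicle-well signals.
#' @return a single score in `[0, 99]`.
#' @export
#' @examples
#' viability_loss(c(500, 500, 500), c(1000, 1000, 1000))  # 50
#' viability_loss(c(1100, 1050), c(1000, 1000))           # clamps to 0
viability_loss <- function(treated_signals, untreated_signals) {
  if (length(treated_signals) == 0L || length(untreated_signals) == 0L)
    stop("viability_loss: empty replicate vector")
  if (anyNA(treated_signals) || anyNA(untreated_signals))
    stop("viability_loss: NA signal")
  if (any(treated_signals < 0) || any(untreated_signals < 0))
    stop("viability_loss: negative signal")
  u <- mean(untreated_signals)
  if (u <= 0) stop("viability_loss: untreated mean is not positive")
  raw <- 100 * (1 - mean(treated_signals) / u)
  min(max(raw, 0), 99)
}

# printed sensitivity cutoffs; all comparisons are strict
.class_rules <- list(
  "sensitive>50"   = function(s) s > 50,
  "dependent>25"   = function(s) s > 25,
  "nonresponse<20" = function(s) s < 20,
  "resistant<10"   = function(s) s < 10
)

#' Test a dependency score against a named sensitivity cutoff
#'
#' All cutoffs are strict: a score of exactly 50 is not `sensitive>50`
#' and a score of exactly 25 is not `dependent>25`.
#'
#' @param score dependency score in `[0, 99]`.
#' @param rule one of `"sensitive>50"`, `"dependent>25"`,
#'   `"nonresponse<20"`, `"resistant<10"`.
#' @return logical.
#' @export
classify <- function(score, rule) {
  if (!is.numeric(score) || anyNA(score) || any(score < 0) || any(score > 99))
    stop("classify: score must be in [0, 99]")
  f <- .class_rules[[rule]]
  if (is.null(f)) stop("classify: unknown rule '", rule, "'")
  f(score)
}

#' Label a score with its most specific sensitivity class
#'
#' Assigns one label per score with precedence `sensitive>50` >
#' `dependent>25` > `resistant<10` > `nonresponse<20` > `intermediate`.
#' Scores in the unnamed 20-25 band fall through to `"intermediate"`.
#'
#' @param score numeric vector of dependency scores.
#' @return character vector of class labels.
#' @export
classify_label <- function(score) {
  vapply(score, function(s) {
    if (is.na(s)) return(NA_character_)
    if (s > 50) "sensitive>50"
    else if (s > 25) "dependent>25"
    else if (s < 10) "resistant<10"
    else if (s < 20) "nonresponse<20"
    else "intermediate"
  }, character(1))
}

.validate_panel <- function(panel) {
  need <- c("cell_line", "condition", "replicate", "signal")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  panel$condition <- normalize_condition(panel$condition)
  if (any(panel$signal < 0, na.rm = TRUE)) stop("panel has negative signals")
  veh <- unique(panel$cell_line[panel$condition == "VEH" & !is.na(panel$signal)])
  no_veh <- setdiff(unique(panel$cell_line), veh)
  if (length(no_veh))
    stop("cell line(s) without vehicle replicates: ",
         paste(no_veh, collapse = ", "))
  panel
}

#' Build dependency profiles from a raw viability panel
#'
#' Scores every cell line under every non-vehicle condition against
#' that line's own vehicle replicates with [viability_loss()], and
#' attaches sensitivity class labels. A condition with no replicates
#' for a line yields a missing score (never imputed).
#'
#' @param panel data frame with columns `cell_line`, `condition`,
#'   `replicate`, `signal` (the format written by
#'   [write_panel()] / simulated by [simulate_screen()]).
#' @return data frame with columns `cell_line`, `condition`, `score`,
#'   `n` (replicates used) and `class`, one row per line x non-vehicle
#'   condition.
#' @seealso [profiles_to_matrix()] for the heatmap-ready wide form.
#' @export
build_profiles <- function(panel) {
  panel <- .validate_panel(panel)
  lines <- unique(panel$cell_line)
  conds <- setdiff(PANEL_CONDITIONS, "VEH")
  out <- expand.grid(cell_line = lines, condition = conds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$cell_line, lines), match(out$condition, conds)), ]
  score <- numeric(nrow(out)); n_rep <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    sel_v <- panel$cell_line == out$cell_line[i] & panel$condition == "VEH"
    sel_t <- panel$cell_line == out$cell_line[i] &
      panel$condition == out$condition[i]
    trt <- panel$signal[sel_t]
    trt <- trt[!is.na(trt)]
    n_rep[i] <- length(trt)
    score[i] <- if (length(trt) == 0L) NA_real_ else
      viability_loss(trt, panel$signal[sel_v][!is.na(panel$signal[sel_v])])
  }
  out$score <- score
  out$n <- n_rep
  out$class <- classify_label(score)
  rownames(out) <- NULL
  out
}

#' Reshape dependency profiles to a wide line x condition matrix
#'
#' @param profiles output of [build_profiles()].
#' @return numeric matrix, rows = cell lines, columns = the 7 treated
#'   panel conditions.
#' @export
profiles_to_matrix <- function(profiles) {
  conds <- setdiff(PANEL_CONDITIONS, "VEH")
  lines <- unique(profiles$cell_line)
  m <- matrix(NA_real_, length(lines), length(conds),
              dimnames = list(lines, conds))
  m[cbind(match(profiles$cell_line, lines),
          match(profiles$condition, conds))] <- profiles$score
  m
}

#' Subcutaneous tumor volume from caliper diameters
#'
#' `V = (L^2 * W) / 2` with `L` the longest and `W` the shortest
#' diameter, both in mm.
#'
#' @param L longest diameter (mm).
#' @param W shortest diameter (mm); must not exceed `L`.
#' @return volume in mm^3.
#' @export
#' @examples
#' tumor_volume(10, 5)  # 250
tumor_volume <- function(L, W) {
  if (any(W <= 0) || any(L <= 0)) stop("tumor_volume: diameters must be > 0")
  if (any(W > L)) stop("tumor_volume: W exceeds L; diameter roles swapped?")
  (L^2 * W) / 2
}
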