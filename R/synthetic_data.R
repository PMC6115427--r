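#' Default tissue composition of the simulated cohort
#'
#' Ten solid/liquid tumor types (TCGA abbreviations) with line counts
#' summing to 78, mirroring the profiled panel's design.
#' @return named integer vector, tissue -> number of cell lines.
#' @export
default_tissues <- function() {
  c(LAML = 8L, OV = 8L, COAD = 8L, PAAD = 10L, LUAD = 9L,
    SKCM = 8L, LIHC = 7L, BLCA = 6L, BRCA = 8L, GBM = 6L)
}

# per-tissue baseline single-agent viability-loss fractions (A199 =
# BCL-2, W539 = BCL-XL, A121 = MCL-1). Leukemia lines lean BCL-2/MCL-1,
# solid tumors carry modest heterogeneous baselines.
.default_base_rates <- function(tissues) {
  known <- rbind(
    LAML = c(0.35, 0.03, 0.45),
    OV   = c(0.05, 0.08, 0.08),
    COAD = c(0.05, 0.08, 0.08),
    PAAD = c(0.05, 0.12, 0.10),
    LUAD = c(0.05, 0.08, 0.08),
    SKCM = c(0.12, 0.12, 0.12),
    LIHC = c(0.08, 0.10, 0.10),
    BLCA = c(0.05, 0.15, 0.08),
    BRCA = c(0.05, 0.08, 0.15),
    GBM  = c(0.05, 0.10, 0.08))
  colnames(known) <- c("A199", "W539", "A121")
  out <- matrix(rep(c(0.05, 0.10, 0.10), each = length(tissues)),
                nrow = length(tissues),
                dimnames = list(names(tissues), colnames(known)))
  hit <- intersect(names(tissues), rownames(known))
  out[hit, ] <- known[hit, ]
  out
}

# default expression panel: BCL-2 family drivers plus the EMT markers
.default_expr_genes <- function() {
  data.frame(
    gene = c("PMAIP1", "BCL2L1", "MCL1", "BCL2", "BAX",
             "MUC1", "CDH1", "EPCAM", "CLDN3",
             "SNAI1", "SNAI2", "TWIST1", "TWIST2", "VIM", "CDH2"),
    mean = c(9.5, 7.5, 9.0, 6.0, 8.0,
             8, 8, 8, 8,
             7, 7, 7, 7, 7, 7),
    sd = c(1.2, 1.0, 0.8, 1.0, 0.7,
           1, 1, 1, 1,
           1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Default planted expression-to-dependency rules
#'
#' Two rules mirroring the study's biomarker logic: NOXA (PMAIP1)
#' expression above 10 log2 units adds 45 viability-loss points of
#' BCL-XL dependence (NOXA neutralizes MCL-1, shifting the line onto
#' BCL-XL); BCL-XL (BCL2L1) expression below 7 adds 45 points of
#' MCL-1 dependence.
#' @return list of rules, each with `gene`, `condition`, `direction`
#'   (`"above"`/`"below"`), `threshold` (log2 units), `effect`
#'   (viability-loss points).
#' @export
default_dependency_rules <- function() {
  list(
    list(gene = "PMAIP1", condition = "W539", direction = "above",
         threshold = 10.0, effect = 45),
    list(gene = "BCL2L1", condition = "A121", direction = "below",
         threshold = 7.0, effect = 45))
}

#' CRISPR screen sub-configuration
#'
#' @param n_genes library genes (default 398).
#' @param sgrna_per_gene sgRNAs per gene (default 5; must be >= 3 or
#'   the three-score is undefined).
#' @param n_controls non-targeting control sgRNAs (default 50).
#' @param dispersion negative-binomial dispersion of counts (variance
#'   `mu + dispersion * mu^2`); 0 means the deterministic noiseless
#'   limit. Default 0.01, typical of a high-coverage pooled screen.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of
#'   per-construct baseline abundance; defaults give ~1000x coverage.
#' @param sensitizers gene symbols planted as sensitizers (default
#'   BCL2L2 (BCL-w) and BCL2A1 (BFL-1)).
#' @param effect planted log2 depletion applied to `n_effective`
#'   randomly chosen sgRNAs of each sensitizer (default -2).
#' @param n_effective sgRNAs per sensitizer that carry the effect
#'   (default 3).
#' @return list of class `crispr_config`.
#' @export
crispr_config <- function(n_genes = 398, sgrna_per_gene = 5,
                          n_controls = 50, dispersion = 0.01,
                          baseline_meanlog = log(1000),
                          baseline_sdlog = 0.5,
                          sensitizers = c("BCL2L2", "BCL2A1"),
                          effect = -2, n_effective = 3) {
  if (sgrna_per_gene < 3)
    stop("crispr_config: sgrna_per_gene must be >= 3 (three-score undefined)")
  if (n_genes < 1 || n_controls < 0 || dispersion < 0)
    stop("crispr_config: invalid counts or dispersion")
  if (n_effective > sgrna_per_gene)
    stop("crispr_config: n_effective exceeds sgrna_per_gene")
  if (!is.finite(effect)) stop("crispr_config: effect must be finite")
  structure(list(n_genes = n_genes, sgrna_per_gene = sgrna_per_gene,
                 n_controls = n_controls, dispersion = dispersion,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 sensitizers = sensitizers, effect = effect,
                 n_effective = n_effective),
            class = "crispr_config")
}

#' Simulation configuration
#'
#' Defines the synthetic study: cohort composition, replicate noise,
#' expression distributions, planted expression- and mutation-driven
#' dependency rules, EMT coupling, and the CRISPR screen. Defaults
#' emulate the profiled study design: 78 lines over 10 tissues,
#' triplicate wells, the 8-condition panel, and a 398-gene screen.
#'
#' @param tissues named integer vector, tissue -> line count.
#' @param replicates wells per condition (default 3).
#' @param noise_sd_viability replicate noise s.d. as a fraction of the
#'   untreated signal (default 0.05).
#' @param untreated_meanlog,untreated_sdlog log-normal parameters of
#'   each line's untreated luminescence signal (defaults around 1e6
#'   arbitrary units; the scale cancels in scoring).
#' @param base_rates tissue x agent matrix of baseline single-agent
#'   viability-loss fractions; default [.default_base_rates] values.
#' @param dependency_rules list of planted expression rules, see
#'   [default_dependency_rules()]; each adds `effect` viability-loss
#'   points to `condition` when the line's `gene` expression is
#'   above/below `threshold`.
#' @param mutation_rules like `dependency_rules` but keyed on the 0/1
#'   mutation state of `gene` (fields `gene`, `condition`, `effect`).
#' @param mutation_genes genes in the binary mutation table.
#' @param mutation_rate Bernoulli rate of mutation per gene per line.
#' @param expr_genes data frame `gene`, `mean`, `sd` of per-gene log2
#'   expression distributions (tissue-shared means; EMT markers are
#'   shifted per class).
#' @param emt list with `p_epithelial` (per-line Bernoulli rate of the
#'   epithelial class), `marker_shift` (log2 shift added to the class'
#'   own markers), `xl_coupling` (viability-loss fraction added to
#'   BCL-XL dependence of mesenchymal lines), `synergy` (viability-
#'   loss fraction added beyond Bliss independence to the W539+A121
#'   and TRIPLE conditions of epithelial lines). Set the couplings to
#'   0 for an EMT-free cohort.
#' @param crispr a [crispr_config()], or NULL to skip the screen.
#' @param seed integer seed; a fixed seed makes the bundle
#'   byte-identical across calls.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(tissues = default_tissues(),
                       replicates = 3,
                       noise_sd_viability = 0.05,
                       untreated_meanlog = log(1e6),
                       untreated_sdlog = 0.2,
                       base_rates = NULL,
                       dependency_rules = default_dependency_rules(),
                       mutation_rules = list(),
                       mutation_genes = c("TP53", "PIK3CA", "PTEN", "KRAS",
                                          "EGFR", "NF1", "BRAF", "RB1",
                                          "ATM", "BRCA2", "BRCA1"),
                       mutation_rate = 0.3,
                       expr_genes = NULL,
                       emt = list(p_epithelial = 0.5, marker_shift = 1.5,
                                  xl_coupling = 0.15, synergy = 0.3),
                       crispr = crispr_config(),
                       seed = 1L) {
  if (length(tissues) < 1 || any(tissues < 1))
    stop("sim_config: every tissue needs at least one line")
  if (is.null(names(tissues)))
    stop("sim_config: tissues must be a named vector")
  if (replicates < 1) stop("sim_config: replicates must be >= 1")
  if (noise_sd_viability < 0)
    stop("sim_config: noise_sd_viability must be >= 0")
  if (is.null(base_rates)) base_rates <- .default_base_rates(tissues)
  if (!all(names(tissues) %in% rownames(base_rates)))
    stop("sim_config: base_rates missing tissue(s): ",
         paste(setdiff(names(tissues), rownames(base_rates)), collapse = ", "))
  if (is.null(expr_genes)) expr_genes <- .default_expr_genes()
  for (r in c(dependency_rules, mutation_rules)) {
    if (!is.finite(r$effect)) stop("sim_config: non-finite planted effect")
    if (!r$condition %in% setdiff(PANEL_CONDITIONS, "VEH"))
      stop("sim_config: rule targets unknown condition '", r$condition, "'")
  }
  defaults <- list(p_epithelial = 0.5, marker_shift = 1.5,
                   xl_coupling = 0.15, synergy = 0.3)
  emt <- utils::modifyList(defaults, emt)
  structure(list(
    tissues = tissues, n_cell_lines = sum(tissues),
    replicates = as.integer(replicates),
    noise_sd_viability = noise_sd_viability,
    untreated_meanlog = untreated_meanlog,
    untreated_sdlog = untreated_sdlog,
    base_rates = base_rates,
    dependency_rules = dependency_rules,
    mutation_rules = mutation_rules,
    mutation_genes = mutation_genes, mutation_rate = mutation_rate,
    expr_genes = expr_genes, emt = emt, crispr = crispr,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# which single agents each panel condition combines
.condition_agents <- list(
  "A199" = "A199", "W539" = "W539", "A121" = "A121",
  "A199+W539" = c("A199", "W539"), "A199+A121" = c("A199", "A121"),
  "W539+A121" = c("W539", "A121"),
  "TRIPLE" = c("A199", "W539", "A121"))

#' Simulate a full synthetic study bundle
#'
#' Generates, from one seed, every input the pipeline consumes:
#' a replicate-level viability panel, a log2 expression matrix, a
#' binary mutation table, tissue labels, and (unless disabled) an
#' sgRNA count table — together with a `truth` record of every
#' planted parameter, sufficient to score recovery.
#'
#' The generative model: each line's single-agent true viability-loss
#' fractions start at its tissue's base rates; planted expression and
#' mutation rules add their effects; mesenchymal-class lines gain
#' `emt$xl_coupling` of BCL-XL dependence. Combination losses follow
#' Bliss independence (combined survival = product of single-agent
#' survivals); epithelial-class lines additionally gain `emt$synergy`
#' on the two conditions combining BCL-XL and MCL-1 inhibition.
#' Losses are clamped to `[0, 0.99]`. Observed replicate signals are
#' `untreated_signal * (1 - true_loss) * (1 + N(0, noise_sd))`,
#' truncated at 0.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_bundle` with elements
#'   `viability_panel`, `expression`, `mutations`, `tissue_labels`,
#'   `crispr` (list `counts`, `library`, `samples`, or NULL) and
#'   `truth`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tissues <- rep(names(config$tissues), config$tissues)
  n <- length(tissues)
  lines <- sprintf("%s_%02d", tissues, stats::ave(seq_len(n), tissues,
                                                  FUN = seq_along))
  # expression: shared per-gene normal, EMT markers shifted by class
  eg <- config$expr_genes
  expr <- matrix(stats::rnorm(nrow(eg) * n, eg$mean, eg$sd),
                 nrow = nrow(eg), dimnames = list(eg$gene, lines))
  epithelial <- stats::rbinom(n, 1, config$emt$p_epithelial)
  epi_genes <- intersect(signature_definition("epithelial")$genes, eg$gene)
  mes_genes <- intersect(signature_definition("mesenchymal")$genes, eg$gene)
  shift <- config$emt$marker_shift
  expr[epi_genes, epithelial == 1] <- expr[epi_genes, epithelial == 1] + shift
  expr[mes_genes, epithelial == 0] <- expr[mes_genes, epithelial == 0] + shift
  # mutations
  mut <- matrix(stats::rbinom(length(config$mutation_genes) * n, 1,
                              config$mutation_rate),
                nrow = length(config$mutation_genes),
                dimnames = list(config$mutation_genes, lines))
  # latent single-agent losses
  agents <- c("A199", "W539", "A121")
  single <- config$base_rates[tissues, agents, drop = FALSE]
  rownames(single) <- lines
  for (r in config$dependency_rules) {
    if (!r$gene %in% rownames(expr)) next
    hit <- if (r$direction == "above") expr[r$gene, ] > r$threshold
           else expr[r$gene, ] < r$threshold
    single[hit, r$condition] <- single[hit, r$condition] + r$effect / 100
  }
  for (r in config$mutation_rules) {
    if (!r$gene %in% rownames(mut)) next
    hit <- mut[r$gene, ] == 1
    single[hit, r$condition] <- single[hit, r$condition] + r$effect / 100
  }
  single[, "W539"] <- single[, "W539"] +
    config$emt$xl_coupling * (1 - epithelial)
  single <- pmin(pmax(single, 0), 0.99)
  # combination losses under Bliss independence + planted synergy
  conds <- setdiff(PANEL_CONDITIONS, "VEH")
  true_loss <- matrix(NA_real_, n, length(conds),
                      dimnames = list(lines, conds))
  for (cd in conds) {
    surv <- rep(1, n)
    for (a in .condition_agents[[cd]]) surv <- surv * (1 - single[, a])
    loss <- 1 - surv
    if (all(c("W539", "A121") %in% .condition_agents[[cd]]))
      loss <- loss + config$emt$synergy * epithelial
    true_loss[, cd] <- pmin(pmax(loss, 0), 0.99)
  }
  # observed replicate signals
  untreated <- stats::rlnorm(n, config$untreated_meanlog,
                             config$untreated_sdlog)
  reps <- config$replicates
  all_conds <- PANEL_CONDITIONS
  panel <- expand.grid(replicate = seq_len(reps), condition = all_conds,
                       cell_line = lines, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)[, c("cell_line", "condition",
                                                     "replicate")]
  li <- match(panel$cell_line, lines)
  loss_vec <- ifelse(panel$condition == "VEH", 0,
                     true_loss[cbind(li, match(panel$condition, conds))])
  noise <- stats::rnorm(nrow(panel), 0, config$noise_sd_viability)
  panel$signal <- pmax(untreated[li] * (1 - loss_vec) * (1 + noise), 0)
  tissue_labels <- data.frame(cell_line = lines, tissue = tissues,
                              stringsAsFactors = FALSE)
  crispr <- if (!is.null(config$crispr))
    simulate_crispr_counts(config, .reseed = FALSE) else NULL
  truth <- list(
    single_losses = single, true_loss = true_loss,
    epithelial = stats::setNames(epithelial, lines),
    dependency_rules = config$dependency_rules,
    mutation_rules = config$mutation_rules,
    emt = config$emt, base_rates = config$base_rates,
    untreated = stats::setNames(untreated, lines),
    crispr = if (is.null(crispr)) NULL else crispr$truth)
  structure(list(viability_panel = panel, expression = expr,
                 mutations = mut, tissue_labels = tissue_labels,
                 crispr = crispr, truth = truth),
            class = "synthetic_bundle")
}

#' Simulate sgRNA counts for a negative-selection screen
#'
#' Per-construct baseline abundances are drawn log-normal; DMSO
#' duplicate counts are negative binomial around the baseline, and
#' treated duplicates around `baseline * 2^effect`, where each planted
#' sensitizer gene carries the depletion effect on `n_effective`
#' randomly chosen sgRNAs and control sgRNAs carry no effect. With
#' `dispersion = 0` counts are the deterministic rounded means (the
#' noiseless limit).
#'
#' @param config a [sim_config()] whose `crispr` slot is set.
#' @param .reseed set the RNG from `config$seed` (default TRUE; used
#'   internally to keep [simulate_screen()]'s stream intact).
#' @return list with `counts` (integer matrix sgRNA x samples DMSO_1,
#'   DMSO_2, TREATED_1, TREATED_2), `library` (data frame `sgrna_id`,
#'   `gene`, `is_control`), `samples` (sample -> condition map) and
#'   `truth` (`sensitizers`, `effect`, per-sgRNA effect vector).
#' @export
simulate_crispr_counts <- function(config, .reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cc <- config$crispr
  if (is.null(cc)) stop("simulate_crispr_counts: config has no crispr block")
  if (.reseed) set.seed(config$seed)
  genes <- cc$sensitizers
  if (length(genes) > cc$n_genes)
    stop("simulate_crispr_counts: more sensitizers than library genes")
  genes <- c(genes, sprintf("GENE%04d", seq_len(cc$n_genes - length(genes))))
  lib <- data.frame(
    sgrna_id = c(sprintf("%s_sg%d", rep(genes, each = cc$sgrna_per_gene),
                         seq_len(cc$sgrna_per_gene)),
                 sprintf("CTRL_sg%03d", seq_len(cc$n_controls))),
    gene = c(rep(genes, each = cc$sgrna_per_gene),
             rep("control", cc$n_controls)),
    is_control = c(rep(FALSE, cc$n_genes * cc$sgrna_per_gene),
                   rep(TRUE, cc$n_controls)),
    stringsAsFactors = FALSE)
  m <- nrow(lib)
  baseline <- stats::rlnorm(m, cc$baseline_meanlog, cc$baseline_sdlog)
  effect <- stats::setNames(rep(0, m), lib$sgrna_id)
  for (g in cc$sensitizers) {
    ids <- lib$sgrna_id[lib$gene == g]
    effect[sample(ids, cc$n_effective)] <- cc$effect
  }
  draw <- function(mu) {
    if (cc$dispersion == 0) as.integer(round(mu))
    else stats::rnbinom(length(mu), mu = mu, size = 1 / cc$dispersion)
  }
  counts <- cbind(DMSO_1 = draw(baseline), DMSO_2 = draw(baseline),
                  TREATED_1 = draw(baseline * 2^effect),
                  TREATED_2 = draw(baseline * 2^effect))
  rownames(counts) <- lib$sgrna_id
  samples <- data.frame(
    sample = colnames(counts),
    condition = c("DMSO", "DMSO", "TREATED", "TREATED"),
    stringsAsFactors = FALSE)
  list(counts = counts, library = lib, samples = samples,
       truth = list(sensitizers = cc$sensitizers, effect = cc$effect,
                    per_sgrna_effect = effect))
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic bundle:", nrow(x$tissue_labels), "cell lines,",
      length(unique(x$tissue_labels$tissue)), "tissues,",
      nrow(x$expression), "expression genes",
      if (!is.null(x$crispr))
        paste0(", CRISPR screen (", nrow(x$crispr$library), " sgRNAs)"),
      "\n")
  invisible(x)
}
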