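#' Run the full analysis pipeline on a synthetic or loaded study
#'
#' Executes, in dependency order, every enabled stage: simulation (or
#' loading), viability scoring, synergy, EMT signatures and their
#' correlations, biomarker statistics (predictor comparison,
#' expression association, threshold search, outliers) and CRISPR
#' screen scoring. Every intermediate table is written as TSV/JSON
#' under `out_dir`, along with `summary.txt` and a `manifest.json`
#' recording inputs, parameters, package version, seed and output
#' hashes — enough to reproduce the run bit-identically.
#'
#' @param config a [sim_config()] describing the synthetic study, or
#'   a list of pre-built inputs with elements `viability_panel`,
#'   `expression`, `mutations`, `tissue_labels` and optionally
#'   `crispr` (as produced by [simulate_screen()]).
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run; any subset of
#'   `c("viability", "synergy", "signatures", "biomarkers",
#'   "screen")`. Disabled stages are noted in the manifest.
#' @param threshold_rules which (gene, phenotype) pairs to run the
#'   threshold finder on; defaults to the pairs named by the planted
#'   dependency rules when `config` is a `sim_config`, else the two
#'   default biomarker pairs (PMAIP1/W539, BCL2L1/A121).
#' @param min_group_size,ttest,synergy_formula,pseudocount stage
#'   parameter overrides, passed through to the module functions.
#' @return the manifest, invisibly.
#' @export
run_all <- function(config, out_dir,
                    stages = c("viability", "synergy", "signatures",
                               "biomarkers", "screen"),
                    threshold_rules = NULL,
                    min_group_size = 3,
                    ttest = "pooled",
                    synergy_formula = "excess",
                    pseudocount = 1) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("viability", "synergy", "signatures", "biomarkers",
                  "screen")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  notes <- if (length(setdiff(all_stages, stages)))
    paste0("stage '", setdiff(all_stages, stages), "' skipped")
  else character(0)
  log_stage <- function(...) message("[bh3map] ", ...)

  if (inherits(config, "sim_config")) {
    log_stage("simulate: ", config$n_cell_lines, " cell lines, seed ",
              config$seed)
    bundle <- simulate_screen(config)
    params <- unclass(config)
    params$base_rates <- as.data.frame(params$base_rates)
    if (!is.null(params$crispr)) params$crispr <- unclass(params$crispr)
    if (is.null(threshold_rules))
      threshold_rules <- lapply(config$dependency_rules, function(r)
        list(gene = r$gene, phenotype = r$condition))
  } else {
    bundle <- config
    params <- list(inputs = "pre-built")
    if (is.null(threshold_rules))
      threshold_rules <- list(list(gene = "PMAIP1", phenotype = "W539"),
                              list(gene = "BCL2L1", phenotype = "A121"))
  }

  write_panel(bundle$viability_panel, file.path(out_dir, "panel.tsv"))
  write_matrix(bundle$expression, file.path(out_dir, "expression.tsv"))
  write_matrix(bundle$mutations, file.path(out_dir, "mutations.tsv"),
               row_label = "gene")
  .write_tsv(bundle$tissue_labels, file.path(out_dir, "tissues.tsv"))
  if (!is.null(bundle$crispr))
    write_counts(bundle$crispr$counts, bundle$crispr$library,
                 file.path(out_dir, "crispr_counts.tsv"))
  if (!is.null(bundle$truth))
    jsonlite::write_json(
      list(epithelial = bundle$truth$epithelial,
           dependency_rules = bundle$truth$dependency_rules,
           emt = bundle$truth$emt,
           crispr = bundle$truth$crispr[c("sensitizers", "effect")]),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  profiles <- synergy_tab <- sig <- NULL
  summary_lines <- character(0)

  run_stage <- function(name, fn) {
    if (!name %in% stages) {
      log_stage(name, ": skipped")
      return(NULL)
    }
    log_stage(name)
    fn()
  }

  profiles <- run_stage("viability", function() {
    p <- build_profiles(bundle$viability_panel)
    write_profiles(p, file.path(out_dir, "profiles.tsv"))
    write_matrix(profiles_to_matrix(p),
                 file.path(out_dir, "profiles_wide.tsv"),
                 row_label = "cell_line")
    summary_lines <<- c(summary_lines,
      sprintf("cell lines scored: %d", length(unique(p$cell_line))),
      sprintf("sensitive (>50) to W539+A121 combination: %d",
              sum(p$condition == "W539+A121" & p$class == "sensitive>50",
                  na.rm = TRUE)))
    p
  })

  if (!is.null(profiles)) {
    synergy_tab <- run_stage("synergy", function() {
      s <- compute_synergy(profiles, formula = synergy_formula)
      .write_tsv(s, file.path(out_dir, "synergy.tsv"))
      summary_lines <<- c(summary_lines,
        sprintf("synergy groups: %s",
                paste(names(table(s$group)), table(s$group),
                      sep = "=", collapse = ", ")))
      s
    })

    sig <- run_stage("signatures", function() {
      epi <- signature_score(bundle$expression,
                             signature_definition("epithelial"))
      mes <- signature_score(bundle$expression,
                             signature_definition("mesenchymal"))
      both <- rbind(epi, mes)
      .write_tsv(both, file.path(out_dir, "signatures.tsv"))
      cors <- NULL
      if (!is.null(synergy_tab)) {
        mes_score <- stats::setNames(mes$score, mes$cell_line)
        idx <- match(synergy_tab$cell_line, names(mes_score))
        pm <- pearson(mes_score[idx], synergy_tab$x_dep)
        ps <- pearson(mes_score[idx], synergy_tab$synergy_excess)
        cors <- list(
          mesenchymal_vs_xl_dependence = pm,
          mesenchymal_vs_synergy_excess = ps)
        jsonlite::write_json(cors, file.path(out_dir, "correlations.json"),
                             auto_unbox = TRUE, digits = NA)
        summary_lines <<- c(summary_lines,
          sprintf("r(mesenchymal, BCL-XL dep) = %.3f; r(mesenchymal, synergy) = %.3f",
                  pm$r, ps$r))
      }
      list(scores = both, correlations = cors)
    })

    run_stage("biomarkers", function() {
      cmp <- compare_predictors(profiles, bundle$tissue_labels,
                                bundle$mutations)
      .write_tsv(cmp, file.path(out_dir, "predictor_comparison.tsv"))
      assoc <- expression_association(profiles, bundle$expression)
      .write_tsv(assoc, file.path(out_dir, "associations.tsv"))
      thr <- lapply(threshold_rules, function(tr) {
        m <- profiles_to_matrix(profiles)
        shared <- intersect(rownames(m), colnames(bundle$expression))
        res <- find_threshold(bundle$expression[tr$gene, shared],
                              m[shared, tr$phenotype],
                              min_group_size = min_group_size,
                              ttest = ttest)
        c(gene = tr$gene, phenotype = tr$phenotype, unclass(res))
      })
      jsonlite::write_json(thr, file.path(out_dir, "thresholds.json"),
                           auto_unbox = TRUE, digits = NA)
      out <- outlier_analysis(profiles, bundle$expression,
                              bundle$tissue_labels)
      .write_tsv(out, file.path(out_dir, "outliers.tsv"))
      summary_lines <<- c(summary_lines,
        sprintf("tissue beats mutation for %d/%d phenotypes",
                sum(cmp$winner == "tissue"), nrow(cmp)),
        vapply(thr, function(x)
          sprintf("threshold %s/%s: %.3f (%s, p=%.2g)", x$gene,
                  x$phenotype, x$threshold, x$direction, x$p_value),
          character(1)))
      NULL
    })
  }

  if (!is.null(bundle$crispr)) {
    run_stage("screen", function() {
      sm <- bundle$crispr$samples
      res <- score_screen(bundle$crispr$counts, bundle$crispr$library,
                          treated = sm$sample[sm$condition == "TREATED"],
                          control = sm$sample[sm$condition == "DMSO"],
                          pseudocount = pseudocount)
      .write_tsv(res$genes, file.path(out_dir, "screen_genes.tsv"))
      .write_tsv(res$sgrnas, file.path(out_dir, "screen_sgrnas.tsv"))
      summary_lines <<- c(summary_lines,
        sprintf("screen: %d genes, most depleted: %s (DM=%.2f)",
                nrow(res$genes), res$genes$gene[1], res$genes$dm[1]))
      NULL
    })
  } else if ("screen" %in% stages) {
    notes <- c(notes, "stage 'screen' skipped: no count table in inputs")
  }

  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, outputs))
  names(hashes) <- outputs
  manifest <- list(
    package = "bh3map",
    version = as.character(utils::packageVersion("bh3map")),
    seed = if (inherits(config, "sim_config")) config$seed else NULL,
    stages = stages, notes = notes,
    parameters = list(min_group_size = min_group_size, ttest = ttest,
                      synergy_formula = synergy_formula,
                      pseudocount = pseudocount,
                      sim = if (inherits(config, "sim_config"))
                        params else NULL),
    outputs = as.list(hashes),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
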