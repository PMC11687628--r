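#' Pipeline configuration
#'
#' Thresholds default to the study's stated values: branch-level P < 0.05,
#' codon-level P < 0.1, evidence-ratio threshold 3.0, 100 parametric
#' bootstrap replications.
#'
#' @param alpha_branch,alpha_codon selection-test significance thresholds.
#' @param evidence_threshold evidence-ratio cut for the selected model set.
#' @param n_bootstrap parametric bootstrap replicates.
#' @param criterion `"AICc"` or `"AIC"` model-ranking basis.
#' @param root_mode `"fixed"` or `"stationary"` OU root handling.
#' @param lambda,ml_lambda PGLS branch-length scaling (fixed value or ML).
#' @param sqrt_transform square-root transform of the PGLS responses.
#' @param min_species minimum clade size for the rate statistic.
#' @param seed master seed for the stochastic stages.
#' @param output_dir optional directory; when set, [run_pipeline()] writes
#'   per-stage TSV/JSON outputs and a run manifest there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(alpha_branch = 0.05, alpha_codon = 0.1,
                            evidence_threshold = 3, n_bootstrap = 100,
                            criterion = c("AICc", "AIC"),
                            root_mode = c("fixed", "stationary"),
                            lambda = 1, ml_lambda = FALSE,
                            sqrt_transform = TRUE,
                            min_species = 3, seed = 1,
                            output_dir = NULL) {
  stopifnot(alpha_branch > 0, alpha_branch < 1,
            alpha_codon > 0, alpha_codon < 1,
            evidence_threshold > 0, n_bootstrap >= 1,
            lambda >= 0, lambda <= 1, min_species >= 3)
  structure(list(alpha_branch = alpha_branch, alpha_codon = alpha_codon,
                 evidence_threshold = evidence_threshold,
                 n_bootstrap = n_bootstrap,
                 criterion = match.arg(criterion),
                 root_mode = match.arg(root_mode),
                 lambda = lambda, ml_lambda = ml_lambda,
                 sqrt_transform = sqrt_transform,
                 min_species = min_species, seed = seed,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys error.
#'
#' @param file path to a YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  vals <- yaml::read_yaml(file)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full comparative pipeline
#'
#' Mirrors the study workflow on one set of inputs: per-clade rates of
#' chromosome-size evolution (2C/2n -> within-clade z-scores -> contrasts ->
#' median |PIC|), per-clade composite selection frequencies, seven-model
#' comparison of each clade-level response on the painted clade tree,
#' parametric bootstrap + Mann-Whitney comparison of the regime optima under
#' each response's best model, and PGLS of each response on the regime.
#'
#' @param system inputs as produced by [simulate_clade_system()], or an
#'   equivalently shaped list assembled from real data (`clade_tree`,
#'   `regimes`, `clade_regime`, `species_trees`, `karyotypes`,
#'   `branch_tab`, `codon_tab`, `length_tab`).
#' @param config a [pipeline_config()].
#' @return a `pipeline_report`: list with `rates`, `selection`,
#'   `clade_summary`, per-response `model_comparison`, `bootstrap`,
#'   `theta_test`, `pgls`, and the `config` (with hash). When
#'   `config$output_dir` is set the stages are also written to disk.
#' @export
run_pipeline <- function(system, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  rates <- clade_rates(system$species_trees, system$karyotypes,
                       min_species = config$min_species)
  selection <- selection_frequency_table(system$branch_tab, system$codon_tab,
                                         system$length_tab,
                                         alpha_branch = config$alpha_branch,
                                         alpha_codon = config$alpha_codon)

  regions <- unique(selection$region)
  responses <- list(rate = stats::setNames(rates$rate, rates$clade))
  for (rg in regions) {
    sel <- selection[selection$region == rg, , drop = FALSE]
    responses[[paste0("selection_", rg)]] <-
      stats::setNames(sel$F, sel$clade)
  }

  fit_cfg <- ou_fit_config(root_mode = config$root_mode,
                           criterion = config$criterion)
  comparisons <- list()
  boots <- list()
  theta_tests <- list()
  pgls <- list()
  clade_regime <- system$clade_regime[system$clade_tree$tip.label]

  for (resp_name in names(responses)) {
    y <- responses[[resp_name]]
    y <- y[!is.na(y)]
    keep <- intersect(system$clade_tree$tip.label, names(y))
    tree_r <- prune_to_taxa(system$clade_tree, keep)
    regimes_r <- paint_regimes(tree_r, clade_regime[keep],
                               root_regime = system$regimes$root_regime,
                               levels = system$regimes$levels)
    cmp <- compare_models(tree_r, regimes_r, y[keep], config = fit_cfg,
                          evidence_threshold = config$evidence_threshold)
    comparisons[[resp_name]] <- cmp
    best_fit <- cmp$fits[[cmp$best]]
    if (length(best_fit$theta) > 1) {
      bt <- parametric_bootstrap(tree_r, regimes_r, best_fit,
                                 n_reps = config$n_bootstrap,
                                 seed = config$seed)
      boots[[resp_name]] <- bt
      theta_tests[[resp_name]] <- compare_bootstrap_theta(bt)
    }
    pgls[[resp_name]] <- pgls_fit(tree_r, y[keep], clade_regime[keep],
                                  lambda = config$lambda,
                                  ml_lambda = config$ml_lambda,
                                  sqrt_transform = config$sqrt_transform)
  }

  clade_summary <- merge(
    rates[, c("clade", "regime", "n_species", "rate")],
    stats::setNames(
      selection[selection$region == "full", c("clade", "F")],
      c("clade", "selection_frequency")),
    by = "clade", all = TRUE)

  report <- structure(
    list(rates = rates, selection = selection,
         clade_summary = clade_summary,
         model_comparisons = comparisons,
         bootstrap = boots, theta_tests = theta_tests, pgls = pgls,
         config = config, config_hash = rlang::hash(unclass(config))),
    class = "pipeline_report")
  if (!is.null(config$output_dir)) write_pipeline_report(report)
  report
}

write_pipeline_report <- function(report) {
  dir <- report$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) { df$config_hash <- report$config_hash; df }
  utils::write.table(stamp(report$rates), file.path(dir, "clade_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(stamp(report$selection),
                     file.path(dir, "selection_frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$model_comparisons)) {
    utils::write.table(stamp(report$model_comparisons[[nm]]$table),
                       file.path(dir, paste0("model_comparison_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tests <- lapply(names(report$theta_tests), function(nm) {
    tt <- report$theta_tests[[nm]]
    bt <- report$bootstrap[[nm]]
    list(response = nm, model = bt$model, U = tt$U, p_value = tt$p_value,
         n_reps = bt$n_reps,
         theta_means = as.list(colMeans(bt$theta)))
  })
  pgls_tab <- lapply(names(report$pgls), function(nm) {
    co <- report$pgls[[nm]]$coefficients
    list(response = nm, slope = co$estimate[2], p_value = co$p_value[2],
         lambda = report$pgls[[nm]]$lambda)
  })
  jsonlite::write_json(
    list(config_hash = report$config_hash,
         config = unclass(report$config),
         theta_tests = tests, pgls = pgls_tab),
    file.path(dir, "hypothesis_tests.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (config", substr(x$config_hash, 1, 8), ")\n")
  cat(" responses analysed:", paste(names(x$model_comparisons), collapse = ", "),
      "\n")
  for (nm in names(x$model_comparisons)) {
    cmp <- x$model_comparisons[[nm]]
    line <- sprintf("  %-22s best %-5s (AICw %.3f)", nm, cmp$best,
                    cmp$table$AICw[1])
    if (!is.null(x$theta_tests[[nm]])) {
      line <- paste0(line, sprintf("; theta MW P = %.3g",
                                   x$theta_tests[[nm]]$p_value))
    }
    p <- x$pgls[[nm]]$coefficients$p_value[2]
    cat(line, sprintf("; PGLS P = %.3g", p), "\n")
  }
  invisible(x)
}
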