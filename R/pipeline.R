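#' Configuration of a full pipeline run
#'
#' Exactly one of `generator` (a [panel_config()]) or `inputs` (paths to
#' the four tables) must be given. All analysis switches live here; the
#' master `seed` drives every source of randomness and is recorded in the
#' provenance header of every written output.
#'
#' @param generator a [panel_config()]; its seed is replaced by `seed`.
#' @param inputs named list of file paths: `intake`, `composition`
#'   (group-level: `food_group`, `n_conc`, `p_conc`, `n_sources`),
#'   `heights`, `covariates`.
#' @param cohorts cohort labels analysed.
#' @param level_covariates selectable covariates of the levels model.
#' @param difference_covariates selectable covariates of the differences
#'   model (see [build_difference_design()] naming).
#' @param with_hdi if `TRUE`, appends the HDI and low-birth-weight columns
#'   to both covariate sets.
#' @param absolute_diffs fit the pairwise model on absolute differences.
#' @param glm_predictors panel variables whose pairwise differences enter
#'   the pairwise linear model (default `c("N", "GDP")`).
#' @param mc3_draws if positive, the BMA stages use the MC3 sampler with
#'   this many draws instead of exact enumeration.
#' @param enumeration_cap passed to [bma_fit()].
#' @param seed master seed.
#' @param outdir if non-`NULL`, [run_pipeline()] writes every table there.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(generator = NULL, inputs = NULL,
                       cohorts = c("1960s", "1970s", "1980s"),
                       level_covariates = c("N", "P", "NP", "GDP", "GDPg",
                                            "Cal", "Urban", "aN_pN", "aP_pP"),
                       difference_covariates = c("N_level", "P_level", "d_GDP",
                                                 "d_GDPg", "d_Cal", "d_N", "d_P",
                                                 "d_NP", "d_aP_pP", "d_aN_pN",
                                                 "d_Urban"),
                       with_hdi = FALSE, absolute_diffs = FALSE,
                       glm_predictors = c("N", "GDP"),
                       mc3_draws = 0, enumeration_cap = 20,
                       seed = 1L, outdir = NULL) {
  if (is.null(generator) == is.null(inputs))
    np_error("exactly one of 'generator' or 'inputs' must be provided",
             "configuration_error")
  if (!is.null(generator) && !inherits(generator, "panel_config"))
    np_error("generator must be a panel_config", "configuration_error")
  if (!is.null(inputs)) {
    miss <- setdiff(c("intake", "composition", "heights", "covariates"),
                    names(inputs))
    if (length(miss))
      np_error(sprintf("inputs lacks path(s): %s", paste(miss, collapse = ", ")),
               "configuration_error")
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    np_error("seed must be a single finite number", "configuration_error")
  if (with_hdi) {
    level_covariates <- unique(c(level_covariates, "HDI", "lowbw"))
    difference_covariates <- unique(c(difference_covariates, "d_HDI", "d_lowbw"))
  }
  if (!is.null(generator)) generator$seed <- as.integer(seed)
  structure(list(generator = generator, inputs = inputs, cohorts = cohorts,
                 level_covariates = level_covariates,
                 difference_covariates = difference_covariates,
                 with_hdi = with_hdi, absolute_diffs = absolute_diffs,
                 glm_predictors = glm_predictors, mc3_draws = mc3_draws,
                 enumeration_cap = enumeration_cap,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages on one panel: data acquisition (synthetic
#' generation or file input), intake-panel construction, reduced major
#' axis fits of height on N, P and N:P, the all-pairwise country
#' difference model for the last cohort, the first-to-last cohort change
#' table with change RMA fits, and Bayesian model averaging of the levels
#' and differences models. Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return A `report_bundle`: the intake and analysis panels, RMA and
#'   change-RMA summary tables, the pairwise model summary, cohort-change
#'   table, the two `bma` fits with their posterior summary tables, the
#'   ground truth (generator runs only) and a run log with per-stage row
#'   accounting (`rows_in = rows_used + rows_dropped`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    np_error("config must be a run_config", "configuration_error")
  seeds <- split_seeds(config$seed, 3)
  log_rows <- list()
  note <- function(stage, rows_in, rows_used, secs) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, rows_in = rows_in, rows_used = rows_used,
      rows_dropped = rows_in - rows_used, seconds = round(secs, 3))
  }

  # -- data --------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  truth <- NULL
  if (!is.null(config$generator)) {
    sim <- simulate_panel(config$generator)
    composition <- average_food_group_concentration(sim$composition_tables,
                                                    sim$group_map)
    intake_table <- sim$intake
    heights <- sim$heights
    covariates <- sim$covariates
    truth <- sim$truth
  } else {
    intake_table <- read_table(config$inputs$intake,
                               schema = c(country = "character", year = "numeric",
                                          food_group = "character",
                                          origin = "character",
                                          kg_per_capita = "numeric"))
    composition <- read_table(config$inputs$composition,
                              schema = c(food_group = "character",
                                         n_conc = "numeric", p_conc = "numeric"),
                              key = "food_group")
    class(composition) <- c("food_composition", "data.frame")
    heights <- read_table(config$inputs$heights,
                          schema = c(country = "character", cohort = "character",
                                     height = "numeric"),
                          key = c("country", "cohort"))
    covariates <- read_table(config$inputs$covariates,
                             schema = c(country = "character", cohort = "character"),
                             key = c("country", "cohort"))
  }
  note("data", nrow(intake_table), nrow(intake_table),
       proc.time()[["elapsed"]] - t0)

  # -- intake ------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  intake_panel <- build_intake_panel(intake_table, composition, config$cohorts)
  panel <- assemble_analysis_panel(intake_panel, heights, covariates)
  note("intake", nrow(intake_panel), nrow(panel),
       proc.time()[["elapsed"]] - t0)

  # -- association -------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  rma_vars <- intersect(c("N", "P", "NP", "Cal"), names(panel))
  rma_summary <- do.call(rbind, lapply(rma_vars, function(v) {
    f <- rma_fit(panel[[v]], panel$height)
    data.frame(predictor = v, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, n = f$n)
  }))

  last <- config$cohorts[length(config$cohorts)]
  first <- config$cohorts[1]
  pair_vars <- unique(c(config$glm_predictors, "N", "P", "NP", "GDP", "Cal"))
  pair_vars <- intersect(pair_vars, names(panel))
  pairs <- pairwise_differences(panel, last, vars = pair_vars)
  pair_fit <- glm_pairwise_fit(pairs,
                               predictors = paste0("d_", config$glm_predictors),
                               absolute = config$absolute_diffs)
  pair_summary <- data.frame(predictor = names(pair_fit$coefficients),
                             coefficient = unname(pair_fit$coefficients),
                             partial_F = unname(pair_fit$partial_F),
                             r_squared = pair_fit$r_squared,
                             df_residual = pair_fit$df_residual)

  change <- NULL
  change_rma <- NULL
  if (length(config$cohorts) >= 2) {
    change <- cohort_change_table(panel, from = first, to = last)
    change_rma <- do.call(rbind, lapply(intersect(c("d_N", "d_P", "d_NP"),
                                                  names(change)), function(v) {
      f <- rma_fit(change[[v]], change$d_height)
      data.frame(predictor = v, slope = f$slope, intercept = f$intercept,
                 r_squared = f$r_squared, n = f$n)
    }))
  }
  note("association", nrow(panel),
       nrow(panel) - length(attr(pairs, "dropped")),
       proc.time()[["elapsed"]] - t0)

  # -- bma ---------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  bma_method <- if (config$mc3_draws > 0) "mc3" else "enumerate"
  lev_design <- build_levels_design(panel, covariates = config$level_covariates)
  bma_levels <- bma_fit(lev_design, method = bma_method,
                        enumeration_cap = config$enumeration_cap,
                        n_draws = max(config$mc3_draws, 1000), seed = seeds[1])
  bma_differences <- NULL
  if (length(config$cohorts) >= 2) {
    dif_design <- build_difference_design(panel,
                                          covariates = config$difference_covariates)
    bma_differences <- bma_fit(dif_design, method = bma_method,
                               enumeration_cap = config$enumeration_cap,
                               n_draws = max(config$mc3_draws, 1000),
                               seed = seeds[2])
  }
  note("bma", nrow(panel), lev_design$n, proc.time()[["elapsed"]] - t0)

  bundle <- structure(list(
    intake_panel = intake_panel, analysis_panel = panel,
    composition = composition,
    rma = rma_summary, pairwise = pair_summary, pairwise_fit = pair_fit,
    cohort_change = change, change_rma = change_rma,
    bma_levels = bma_levels, bma_differences = bma_differences,
    truth = truth,
    log = list(seed = config$seed,
               stages = do.call(rbind, log_rows),
               r_version = R.version.string,
               package_version = as.character(packageVersion("npheight")))),
    class = "report_bundle")
  if (!is.null(config$outdir)) write_report_bundle(bundle, config$outdir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("npheight report bundle (seed", x$log$seed, ")\n\n")
  cat("Stage row accounting:\n")
  print(x$log$stages, row.names = FALSE)
  cat("\nRMA of height on intake:\n")
  print(transform(x$rma, slope = round(slope, 3), intercept = round(intercept, 1),
                  r_squared = round(r_squared, 3)), row.names = FALSE)
  cat("\nTop levels-model PIPs:\n")
  print(round(head(sort(x$bma_levels$pip, decreasing = TRUE), 5), 3))
  if (!is.null(x$bma_differences)) {
    cat("\nTop differences-model PIPs:\n")
    print(round(head(sort(x$bma_differences$pip, decreasing = TRUE), 5), 3))
  }
  invisible(x)
}

#' Write every table of a report bundle to an output directory
#'
#' @param bundle a [run_pipeline()] result.
#' @param outdir directory to write into (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, outdir) {
  if (!inherits(bundle, "report_bundle"))
    np_error("bundle must be a report_bundle", "validation_error")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- bundle$log$seed
  paths <- character(0)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible())
    paths <<- c(paths, write_table(as.data.frame(df),
                                   file.path(outdir, name), seed = seed))
  }
  wt(bundle$intake_panel, "intake_panel.csv")
  wt(bundle$analysis_panel, "analysis_panel.csv")
  wt(bundle$composition, "composition.csv")
  wt(bundle$rma, "rma_summary.csv")
  wt(bundle$pairwise, "pairwise_glm.csv")
  wt(bundle$cohort_change, "cohort_change.csv")
  wt(bundle$change_rma, "change_rma.csv")
  wt(bundle$bma_levels$cond, "bma_levels_posterior.csv")
  if (!is.null(bundle$bma_differences))
    wt(bundle$bma_differences$cond, "bma_differences_posterior.csv")
  # run log: seed and row accounting only (no wall times, so identical
  # seeds give byte-identical output directories)
  stages <- bundle$log$stages
  stages$seconds <- NULL
  yaml::write_yaml(list(seed = seed,
                        package_version = bundle$log$package_version,
                        stages = lapply(seq_len(nrow(stages)), function(i)
                          as.list(stages[i, ]))),
                   file.path(outdir, "run_log.yml"))
  invisible(c(paths, file.path(outdir, "run_log.yml")))
}
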