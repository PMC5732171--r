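#!/usr/bin/env Rscript
# Thin command-line wrapper over the npheight package.
#
# Usage:
#   Rscript scripts/npheight.R <simulate|intake|associate|bma|run> [options]
#
# Common options:
#   --seed <int>            master seed (default 1)
#   --outdir <dir>          output directory (default "npheight_out")
#   --countries <int>       simulate: number of countries (default 80)
#   --indir <dir>           intake/associate/bma: directory holding
#                           intake.csv, composition.csv, heights.csv,
#                           covariates.csv (as written by `simulate`)
#   --absolute-diffs        fit the pairwise model on absolute differences
#   --mc3-draws <int>       use the MC3 sampler with this many draws
#   --enumeration-cap <int> largest covariate count enumerated exactly
#   --with-hdi              include HDI and low-birth-weight covariates

suppressPackageStartupMessages(library(npheight))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) stop("usage: npheight.R <simulate|intake|associate|bma|run> [options]")
cmd <- args[1]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
has <- function(flag) flag %in% args

seed <- as.integer(opt("--seed", "1"))
outdir <- opt("--outdir", "npheight_out")
indir <- opt("--indir", outdir)

input_paths <- function(dir) list(
  intake = file.path(dir, "intake.csv"),
  composition = file.path(dir, "composition.csv"),
  heights = file.path(dir, "heights.csv"),
  covariates = file.path(dir, "covariates.csv"))

make_config <- function(generator = NULL, inputs = NULL) {
  run_config(generator = generator, inputs = inputs,
             with_hdi = has("--with-hdi"),
             absolute_diffs = has("--absolute-diffs"),
             mc3_draws = as.integer(opt("--mc3-draws", "0")),
             enumeration_cap = as.integer(opt("--enumeration-cap", "20")),
             seed = seed, outdir = outdir)
}

read_panel <- function(dir) {
  paths <- input_paths(dir)
  intake <- read_table(paths$intake)
  composition <- read_table(paths$composition, key = "food_group")
  class(composition) <- c("food_composition", "data.frame")
  heights <- read_table(paths$heights, key = c("country", "cohort"))
  covariates <- read_table(paths$covariates, key = c("country", "cohort"))
  ip <- build_intake_panel(intake, composition)
  list(intake_panel = ip,
       panel = assemble_analysis_panel(ip, heights, covariates))
}

switch(cmd,
  simulate = {
    n <- as.integer(opt("--countries", "80"))
    sim <- simulate_panel(panel_config(n_countries = n, seed = seed))
    write_synthetic_panel(sim, outdir)
    comp <- average_food_group_concentration(sim$composition_tables,
                                             sim$group_map)
    write_table(comp, file.path(outdir, "composition.csv"), seed = seed)
    cat("wrote synthetic panel for", n, "countries to", outdir, "\n")
  },
  intake = {
    got <- read_panel(indir)
    write_table(got$intake_panel, file.path(outdir, "intake_panel.csv"),
                seed = seed)
    cat("wrote", file.path(outdir, "intake_panel.csv"), "\n")
  },
  associate = {
    got <- read_panel(indir)
    panel <- got$panel
    rma_tab <- do.call(rbind, lapply(intersect(c("N", "P", "NP"), names(panel)),
                                     function(v) {
      f <- rma_fit(panel[[v]], panel$height)
      data.frame(predictor = v, slope = f$slope, intercept = f$intercept,
                 r_squared = f$r_squared, n = f$n)
    }))
    write_table(rma_tab, file.path(outdir, "rma_summary.csv"), seed = seed)
    pairs <- pairwise_differences(panel, "1980s", vars = c("N", "GDP"))
    fit <- glm_pairwise_fit(pairs, predictors = c("d_N", "d_GDP"),
                            absolute = has("--absolute-diffs"))
    write_table(data.frame(predictor = names(fit$coefficients),
                           coefficient = unname(fit$coefficients),
                           partial_F = unname(fit$partial_F),
                           r_squared = fit$r_squared),
                file.path(outdir, "pairwise_glm.csv"), seed = seed)
    write_table(cohort_change_table(panel),
                file.path(outdir, "cohort_change.csv"), seed = seed)
    cat("wrote association tables to", outdir, "\n")
  },
  bma = {
    got <- read_panel(indir)
    cfg <- make_config(inputs = input_paths(indir))
    design <- build_levels_design(got$panel,
                                  covariates = cfg$level_covariates)
    fit <- bma_fit(design,
                   method = if (cfg$mc3_draws > 0) "mc3" else "enumerate",
                   enumeration_cap = cfg$enumeration_cap,
                   n_draws = max(cfg$mc3_draws, 1000), seed = seed)
    write_table(fit$cond, file.path(outdir, "bma_levels_posterior.csv"),
                seed = seed)
    print(fit)
  },
  run = {
    if (dir.exists(indir) && file.exists(file.path(indir, "intake.csv")) &&
        indir != outdir) {
      bundle <- run_pipeline(make_config(inputs = input_paths(indir)))
    } else {
      n <- as.integer(opt("--countries", "80"))
      bundle <- run_pipeline(make_config(
        generator = panel_config(n_countries = n, seed = seed)))
    }
    write_report_bundle(bundle, outdir)
    print(bundle)
  },
  stop(sprintf("unknown subcommand '%s'", cmd))
)
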