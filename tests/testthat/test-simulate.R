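test_that("generator configuration is validated", {
  expect_error(panel_config(n_countries = 0), class = "npheight_configuration_error")
  expect_error(panel_config(cohorts = character(0)),
               class = "npheight_configuration_error")
  expect_error(panel_config(true_coefficients = list(
    "animal-dominated" = c(bogus = 1))), "bogus",
    class = "npheight_configuration_error")
  expect_error(panel_config(noise_sd = -1), class = "npheight_configuration_error")
  # defaults carry the printed intake ranges
  cfg <- panel_config()
  expect_equal(cfg$intake_ranges$N, c(3.3, 23.7))
  expect_equal(cfg$intake_ranges$P, c(0.41, 2.76))
  expect_equal(cfg$intake_ranges$Cal, c(1879, 3721))
})

test_that("identical config and seed give identical outputs", {
  cfg <- panel_config(n_countries = 6, seed = 123)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$intake, b$intake)
  expect_identical(a$heights, b$heights)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$composition_tables, b$composition_tables)
  # and written tables are byte-identical
  d1 <- file.path(tempdir(), "sima"); d2 <- file.path(tempdir(), "simb")
  write_synthetic_panel(a, d1); write_synthetic_panel(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the draws
  expect_false(identical(simulate_panel(panel_config(n_countries = 6,
                                                     seed = 124))$heights,
                         a$heights))
})

test_that("generated intakes respect the configured ranges and group structure", {
  cfg <- panel_config(n_countries = 30, seed = 17)
  sim <- simulate_panel(cfg)
  ti <- sim$truth$intake
  expect_true(all(ti$N >= 3.3 & ti$N <= 23.7))
  expect_true(all(ti$P >= 0.41 & ti$P <= 2.76))
  expect_true(all(sim$covariates$Cal >= 1879 & sim$covariates$Cal <= 3721))
  expect_true(all(sim$intake$kg_per_capita >= 0))
  # the classification rule reproduces the generated group assignment
  cls <- classify_diet_group(ti$aN_pN, ti$aP_pP)
  expect_equal(as.character(cls), unname(sim$truth$groups[ti$country]))
  # animal-dominated countries occupy the upper half of the N range
  gi <- sim$truth$groups[ti$country]
  first <- ti[ti$cohort == "1960s", ]
  gf <- sim$truth$groups[first$country]
  expect_true(all(first$N[gf == "animal-dominated"] >= mean(c(3.3, 23.7))))
  expect_true(all(first$N[gf == "plant-dominated"] <= mean(c(3.3, 23.7))))
})

test_that("cohort intake trends follow the configured group asymmetry", {
  cfg <- panel_config(n_countries = 24, seed = 29)
  sim <- simulate_panel(cfg)
  ti <- sim$truth$intake
  g <- sim$truth$groups[ti$country]
  for (grp in unique(g)) {
    sub <- ti[g == grp, ]
    n1 <- sub$N[sub$cohort == "1960s"]
    n3 <- sub$N[sub$cohort == "1980s"]
    expect_equal(n3 / n1, rep(1 + cfg$trends$N[[grp]], length(n1)),
                 tolerance = 1e-10)
  }
})

test_that("noiseless heights with a single N coefficient are affine in N intake", {
  cfg <- panel_config(n_countries = 10, seed = 13, noise_sd = 0,
                      true_coefficients = list(
                        "animal-dominated" = c(N = 0.5),
                        "plant-dominated" = c(N = 0.5)),
                      cohort_effects = list(
                        "animal-dominated" = c(0, 0, 0),
                        "plant-dominated" = c(0, 0, 0)))
  sim <- simulate_panel(cfg)
  m <- merge(sim$heights, sim$truth$intake, by = c("country", "cohort"))
  g <- sim$truth$groups[m$country]
  for (grp in unique(g)) {
    sub <- m[g == grp, ]
    fit <- lm(height ~ N, data = sub)
    expect_lt(max(abs(residuals(fit))), 1e-8)
    expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 1e-8)
  }
})

test_that("per-group OLS on generated panels recovers the true coefficients", {
  # Monte-Carlo recovery: refit each generated panel by least squares per
  # group and count estimates within 3 standard errors of the truth
  hits <- 0L; total <- 0L
  for (s in 1:200) {
    cfg <- panel_config(n_countries = 24, seed = 4000 + s,
                        true_coefficients = list(
                          "animal-dominated" = c(NP = 1.0, N = 0.2),
                          "plant-dominated" = c(NP = 0.7, N = 0.2)))
    sim <- simulate_panel(cfg)
    m <- merge(sim$heights, sim$truth$intake, by = c("country", "cohort"))
    g <- sim$truth$groups[m$country]
    for (grp in c("animal-dominated", "plant-dominated")) {
      sub <- cbind(m[g == grp, ], cohort_f = factor(m$cohort[g == grp]))
      fit <- lm(height ~ cohort_f + NP + N, data = sub)
      est <- summary(fit)$coefficients
      for (cv in c("NP", "N")) {
        total <- total + 1L
        truth <- cfg$true_coefficients[[grp]][[cv]]
        if (abs(est[cv, "Estimate"] - truth) < 3 * est[cv, "Std. Error"])
          hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("composition tables average back to the true group concentrations", {
  cfg <- panel_config(n_countries = 4, seed = 37)
  comp_src <- simulate_composition_tables(cfg)
  expect_gte(length(comp_src$tables), 2)
  recovered <- average_food_group_concentration(comp_src$tables,
                                                comp_src$group_map)
  truth <- comp_src$truth[order(comp_src$truth$food_group), ]
  expect_equal(recovered$n_conc, truth$n_conc, tolerance = 1e-12)
  expect_equal(recovered$p_conc, truth$p_conc, tolerance = 1e-12)
  # single-item, single-table edge: the item value becomes the group mean
  single <- list(data.frame(food_item = "meat_1", n_conc = 0.03, p_conc = 0.002))
  one <- average_food_group_concentration(single, c(meat_1 = "meat"))
  expect_equal(one$n_conc, 0.03)
})

test_that("truth record separates included and excluded covariates", {
  cfg <- panel_config(n_countries = 5, seed = 41,
                      true_coefficients = list(
                        "animal-dominated" = c(NP = 1, GDP = 0),
                        "plant-dominated" = c(NP = 0.5)))
  sim <- simulate_panel(cfg)
  expect_setequal(sim$truth$inclusion, "NP")
  for (g in names(sim$truth$coefficients)) {
    b <- sim$truth$coefficients[[g]]
    expect_true(all(b[setdiff(names(b), sim$truth$inclusion)] == 0))
  }
})

test_that("a configured +1.5 cm rich-group trend shows up in the cohort changes", {
  # isolate the cohort effect: no covariate feeds height, so the group-mean
  # height change equals the configured trend up to Monte-Carlo error
  cfg <- panel_config(n_countries = 60, seed = 19, noise_sd = 2,
                      true_coefficients = list(
                        "animal-dominated" = c(N = 0),
                        "plant-dominated" = c(N = 0)))
  sim <- simulate_panel(cfg)
  comp <- average_food_group_concentration(sim$composition_tables, sim$group_map)
  panel <- assemble_analysis_panel(build_intake_panel(sim$intake, comp),
                                   sim$heights, sim$covariates)
  ch <- cohort_change_table(panel)
  g <- sim$truth$groups[ch$country]
  for (grp in c("animal-dominated", "plant-dominated")) {
    d <- ch$d_height[g == grp]
    trend <- cfg$cohort_effects[[grp]][3] - cfg$cohort_effects[[grp]][1]
    # per-country change noise has sd sqrt(2) * noise_sd
    expect_lt(abs(mean(d) - trend), 3 * sqrt(2) * cfg$noise_sd / sqrt(length(d)))
  }
})
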