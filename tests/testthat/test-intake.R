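test_that("growth windows match the cohort definitions", {
  expect_identical(growth_window("1960s"), c(start = 1961L, end = 1989L))
  expect_identical(growth_window("1970s"), c(start = 1971L, end = 1999L))
  expect_identical(growth_window("1980s"), c(start = 1981L, end = 2009L))
  expect_error(growth_window("1990s"), class = "npheight_domain_error")
  expect_error(growth_window(1960), class = "npheight_domain_error")
})

test_that("group concentrations are two-stage means over items and databases", {
  # identity: one item, one table
  one <- data.frame(food_item = "wheat", n_conc = 0.03, p_conc = 0.004)
  comp <- average_food_group_concentration(one, c(wheat = "cereals"))
  expect_equal(comp$n_conc, 0.03)
  expect_equal(comp$n_sources, 1L)

  # forced cross-database mean: one item in two tables
  t1 <- data.frame(food_item = "wheat", n_conc = 0.02, p_conc = 0.003)
  t2 <- data.frame(food_item = "wheat", n_conc = 0.04, p_conc = 0.005)
  comp <- average_food_group_concentration(list(t1, t2), c(wheat = "cereals"))
  expect_equal(comp$n_conc, 0.03)
  expect_equal(comp$p_conc, 0.004)

  # 5 items, 2 groups, 2 partially overlapping tables vs a hand-computed
  # two-stage mean
  ta <- data.frame(food_item = c("wheat", "rice", "beef", "pork"),
                   n_conc = c(0.020, 0.016, 0.032, 0.028),
                   p_conc = c(0.0030, 0.0012, 0.0020, 0.0022))
  tb <- data.frame(food_item = c("rice", "beef", "lamb"),
                   n_conc = c(0.018, 0.036, 0.030),
                   p_conc = c(0.0014, 0.0024, 0.0018))
  map <- c(wheat = "cereals", rice = "cereals",
           beef = "meat", pork = "meat", lamb = "meat")
  comp <- average_food_group_concentration(list(ta, tb), map)
  rice <- mean(c(0.016, 0.018)); beef <- mean(c(0.032, 0.036))
  expect_equal(comp$n_conc[comp$food_group == "cereals"], mean(c(0.020, rice)))
  expect_equal(comp$n_conc[comp$food_group == "meat"],
               mean(c(beef, 0.028, 0.030)))
  expect_equal(comp$n_sources, c(2L, 2L))

  # item mapped but absent everywhere -> error naming the item
  expect_error(average_food_group_concentration(ta, c(tofu = "soy")),
               "tofu", class = "npheight_missing_data_error")
})

test_that("annual N and P intake is the window mean of group intake x concentration", {
  comp <- average_food_group_concentration(
    data.frame(food_item = c("beef", "wheat"),
               n_conc = c(0.03, 0.01), p_conc = c(0.002, 0.001)),
    c(beef = "meat", wheat = "cereals"))
  tab <- data.frame(country = "X", year = c(2000, 2000),
                    food_group = c("meat", "cereals"),
                    origin = c("animal", "plant"),
                    kg_per_capita = c(100, 50))

  # hand arithmetic: 100 kg at 3% N + 50 kg at 1% N = 3.5 kg N / y
  out <- annual_np_intake(tab, comp, "X", c(2000, 2000))
  expect_equal(out$N, 3.5)
  expect_equal(out$P, 100 * 0.002 + 50 * 0.001)
  expect_equal(out$N, out$N_animal + out$N_plant)

  # zero intake -> zero
  tab0 <- transform(tab, kg_per_capita = 0)
  out0 <- annual_np_intake(tab0, comp, "X", c(2000, 2000))
  expect_equal(c(out0$N, out0$P), c(0, 0))

  # two years with yearly N totals 3.0 and 4.0 -> 3.5
  tab2 <- data.frame(country = "X", year = c(2000, 2001),
                     food_group = "meat", origin = "animal",
                     kg_per_capita = c(100, 100 * 4 / 3))
  expect_equal(annual_np_intake(tab2, comp, "X", c(2000, 2001))$N, 3.5)

  # a gap year inside the window averages over available years, with warning
  expect_warning(out_gap <- annual_np_intake(tab2, comp, "X", c(2000, 2003)),
                 "years")
  expect_equal(out_gap$N, 3.5)

  # food group absent from composition -> missing data error
  tabx <- transform(tab, food_group = c("meat", "fruit"))
  expect_error(annual_np_intake(tabx, comp, "X", c(2000, 2000)),
               "fruit", class = "npheight_missing_data_error")
  expect_error(annual_np_intake(tab, comp, "Y", c(2000, 2000)),
               class = "npheight_missing_data_error")
})

test_that("intake is additive over origins and scale-equivariant", {
  cfg <- panel_config(n_countries = 6, seed = 11)
  sim <- simulate_panel(cfg)
  comp <- average_food_group_concentration(sim$composition_tables, sim$group_map)
  for (cc in unique(sim$intake$country)[1:3]) {
    base <- annual_np_intake(sim$intake, comp, cc, growth_window("1970s"))
    expect_equal(base$N, base$N_animal + base$N_plant)
    expect_equal(base$P, base$P_animal + base$P_plant)
    # multiplying all food intakes by c scales N and P by c and leaves the
    # N:P ratio and classification unchanged
    scaled_tab <- transform(sim$intake, kg_per_capita = kg_per_capita * 3)
    scaled <- annual_np_intake(scaled_tab, comp, cc, growth_window("1970s"))
    expect_equal(scaled$N, 3 * base$N)
    expect_equal(scaled$P, 3 * base$P)
    expect_equal(scaled$N / scaled$P, base$N / base$P)
    expect_equal(classify_diet_group(scaled$N_animal / scaled$N_plant,
                                     scaled$P_animal / scaled$P_plant),
                 classify_diet_group(base$N_animal / base$N_plant,
                                     base$P_animal / base$P_plant))
  }
})

test_that("a constant yearly series has window mean equal to any single year", {
  comp <- average_food_group_concentration(
    data.frame(food_item = "beef", n_conc = 0.03, p_conc = 0.002),
    c(beef = "meat"))
  tab <- data.frame(country = "X", year = 1981:2009, food_group = "meat",
                    origin = "animal", kg_per_capita = 80)
  full <- annual_np_intake(tab, comp, "X", c(1981, 2009))
  one <- annual_np_intake(tab, comp, "X", c(1990, 1990))
  expect_equal(full$N, one$N)
  expect_equal(full$P, one$P)
})

test_that("N:P mass ratio divides and rejects zero P", {
  expect_equal(np_mass_ratio(5, 5), 1)
  # printed group means: rich 19.5/2.17, poor 9.66/1.35 kg per year
  expect_equal(np_mass_ratio(19.5, 2.17), 8.99, tolerance = 0.001)
  expect_equal(np_mass_ratio(9.66, 1.35), 7.16, tolerance = 0.001)
  expect_error(np_mass_ratio(5, 0), class = "npheight_undefined_ratio_error")
  expect_error(np_mass_ratio(-1, 2), class = "npheight_domain_error")
})

test_that("diet classification uses a strict > 2 threshold on the ratio sum", {
  expect_equal(as.character(classify_diet_group(1.6, 1.5)), "animal-dominated")
  expect_equal(as.character(classify_diet_group(1.0, 1.0)), "plant-dominated")
  expect_equal(as.character(classify_diet_group(0, 0)), "plant-dominated")
  expect_error(classify_diet_group(Inf, 1), class = "npheight_undefined_ratio_error")
  expect_error(classify_diet_group(-0.1, 1), class = "npheight_undefined_ratio_error")
})

test_that("the intake panel has one complete row per country and cohort", {
  cfg <- panel_config(n_countries = 3, seed = 5)
  sim <- simulate_panel(cfg)
  comp <- average_food_group_concentration(sim$composition_tables, sim$group_map)
  panel <- build_intake_panel(sim$intake, comp)
  expect_equal(nrow(panel), 3 * 3)
  num <- panel[c("N", "P", "NP", "aN_pN", "aP_pP")]
  expect_true(all(vapply(num, function(v) all(is.finite(v) & v >= 0), TRUE)))
  # classification stored in the panel agrees with the rule applied to the
  # stored ratios
  expect_equal(panel$diet_group,
               as.character(classify_diet_group(panel$aN_pN, panel$aP_pP)))
  # generator round trip: the panel reproduces the true group assignment
  expect_equal(panel$diet_group, unname(sim$truth$groups[panel$country]))
})

test_that("height range spans the tallest and shortest country means", {
  expect_equal(height_range(c(183, 175.2, 160)), 23)
  expect_equal(height_range(data.frame(height = c(170, 180))), 10)
  expect_error(height_range(165), class = "npheight_insufficient_data_error")
})
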