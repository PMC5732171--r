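# Synthetic country x cohort panel generator with known ground truth.

# Fixed food-group taxonomy used by the generator. Concentrations are mass
# fractions (kg N or P per kg food), chosen so that the column N:P ratios
# bracket the realised per-origin N:P range of the draws; the 2x2 solve for
# food-group quantities then always has a positive solution.
.food_groups <- data.frame(
  food_group = c("meat", "dairy", "pulses", "vegetables"),
  origin     = c("animal", "animal", "plant", "plant"),
  n_conc     = c(0.034, 0.0050, 0.038, 0.0040),
  p_conc     = c(0.0020, 0.00115, 0.0030, 0.0008),
  stringsAsFactors = FALSE)

.generator_covariates <- c("N", "P", "NP", "GDP", "GDPg", "Cal", "Urban",
                           "aN_pN", "aP_pP", "HDI", "lowbw")

#' Configuration of the synthetic panel generator
#'
#' Fixes the study conditions emulated by [simulate_panel()]: panel
#' dimensions, the two diet groups, the true height model, and the
#' printed intake ranges. Intakes are drawn uniformly within range with
#' group-specific sub-ranges (the animal-dominated group occupying the
#' upper half); out-of-range draws are resampled, never clipped.
#'
#' @param n_countries number of countries (default 80).
#' @param cohorts ordered cohort labels, a subset of
#'   `c("1960s", "1970s", "1980s")`.
#' @param frac_animal_group proportion of countries in the
#'   animal-dominated group.
#' @param true_coefficients list with one named numeric vector per group
#'   (`"animal-dominated"`, `"plant-dominated"`) of true covariate effects
#'   on height (cm per covariate unit); names must be covariates the
#'   generator produces. Covariates absent from the vectors have a true
#'   effect of exactly zero.
#' @param intercepts named per-group baseline heights, cm.
#' @param cohort_effects list of per-group cohort effects (cm), one value
#'   per cohort; the default gives the animal-dominated group a +1.5 cm
#'   gain from the first to the last cohort and the plant-dominated group
#'   none.
#' @param noise_sd Gaussian height noise, cm (may be 0 for noiseless
#'   checks).
#' @param intake_ranges per-variable `(min, max)` bounds; the defaults are
#'   the printed ranges N 3.3--23.7 kg/y, P 0.41--2.76 kg/y, calories
#'   1879--3721 kcal/d, plus the N:P draw range (a generator choice).
#' @param trends per-group relative increase of N and P intake from the
#'   first to the last cohort; defaults +12.1%/+7.0% (N) and
#'   +7.6%/+6.01% (P) for the animal/plant groups.
#' @param seed master seed; one pseudo-random stream per output table is
#'   split from it via [split_seeds()].
#' @return A validated object of class `"panel_config"`.
#' @export
panel_config <- function(n_countries = 80,
                         cohorts = c("1960s", "1970s", "1980s"),
                         frac_animal_group = 0.5,
                         true_coefficients = list(
                           "animal-dominated" = c(NP = 1.0, N = 0.20),
                           "plant-dominated"  = c(NP = 0.7, N = 0.20)),
                         intercepts = c("animal-dominated" = 164,
                                        "plant-dominated" = 158),
                         cohort_effects = list(
                           "animal-dominated" = c(0, 0.75, 1.5),
                           "plant-dominated"  = c(0, 0, 0)),
                         noise_sd = 2,
                         intake_ranges = list(N = c(3.3, 23.7),
                                              P = c(0.41, 2.76),
                                              Cal = c(1879, 3721),
                                              NP = c(6.5, 10.5)),
                         trends = list(
                           N = c("animal-dominated" = 0.121,
                                 "plant-dominated" = 0.070),
                           P = c("animal-dominated" = 0.076,
                                 "plant-dominated" = 0.0601)),
                         seed = 1L) {
  if (!is_count(n_countries))
    np_error("n_countries must be a positive integer", "configuration_error")
  if (!length(cohorts) || !all(cohorts %in% names(.growth_windows)))
    np_error("cohorts must be a non-empty subset of the known cohort labels",
             "configuration_error")
  if (!is.numeric(frac_animal_group) || frac_animal_group < 0 || frac_animal_group > 1)
    np_error("frac_animal_group must lie in [0, 1]", "configuration_error")
  grp_names <- c("animal-dominated", "plant-dominated")
  if (!is.list(true_coefficients) || !all(names(true_coefficients) %in% grp_names))
    np_error("true_coefficients must be a list named by diet group", "configuration_error")
  for (g in names(true_coefficients)) {
    bad <- setdiff(names(true_coefficients[[g]]), .generator_covariates)
    if (length(bad))
      np_error(sprintf("true_coefficients name unknown covariate(s): %s",
                       paste(bad, collapse = ", ")), "configuration_error")
  }
  if (!all(grp_names %in% names(intercepts)))
    np_error("intercepts must name both diet groups", "configuration_error")
  if (!all(vapply(cohort_effects[grp_names], length, 0L) == length(cohorts)))
    np_error("cohort_effects must give one value per cohort for each group",
             "configuration_error")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    np_error("noise_sd must be a single nonnegative number (cm)", "configuration_error")
  for (v in c("N", "P", "Cal", "NP")) {
    r <- intake_ranges[[v]]
    if (is.null(r) || length(r) != 2 || !is.numeric(r) || r[1] >= r[2] || r[1] < 0)
      np_error(sprintf("intake_ranges$%s must be (min, max) with 0 <= min < max", v),
               "configuration_error")
  }
  for (v in c("N", "P")) {
    tr <- trends[[v]]
    if (is.null(tr) || !all(grp_names %in% names(tr)))
      np_error(sprintf("trends$%s must name both diet groups", v), "configuration_error")
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    np_error("seed must be a single finite number", "configuration_error")
  structure(list(n_countries = as.integer(n_countries), cohorts = cohorts,
                 frac_animal_group = frac_animal_group,
                 true_coefficients = true_coefficients,
                 intercepts = intercepts, cohort_effects = cohort_effects,
                 noise_sd = noise_sd, intake_ranges = intake_ranges,
                 trends = trends, seed = as.integer(seed)),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("Synthetic panel config: %d countries x %d cohorts, %.0f%% animal-dominated, noise sd %.2g cm, seed %d\n",
              x$n_countries, length(x$cohorts), 100 * x$frac_animal_group,
              x$noise_sd, x$seed))
  invisible(x)
}

#' Generate item-level food-composition source tables
#'
#' Emulates several composition databases reporting N and P concentrations
#' per food item: each food group owns a few items whose concentrations
#' scatter around the group's true value, and an item may appear in more
#' than one source table with slightly different values. Deviations are
#' recentred so that the two-stage mean computed by
#' [average_food_group_concentration()] recovers the generator's true
#' group concentrations exactly.
#'
#' @param config a [panel_config()].
#' @param n_tables number of source tables (at least 1; the first table
#'   carries every item, so any two tables share food groups).
#' @param items_per_group items per food group.
#' @param jitter relative scatter of item and cross-table deviations.
#' @return List with `tables` (list of data frames `food_item`, `n_conc`,
#'   `p_conc`), `group_map` (named vector item -> group), `origin_map`
#'   (named vector group -> origin) and `truth` (the true group-level
#'   composition).
#' @export
simulate_composition_tables <- function(config, n_tables = 3,
                                        items_per_group = 3, jitter = 0.15) {
  if (!inherits(config, "panel_config"))
    np_error("config must be a panel_config", "configuration_error")
  if (!is_count(n_tables))
    np_error("at least one source table must be requested", "configuration_error")
  set.seed(split_seeds(config$seed, 4)[1])

  fg <- .food_groups
  items <- data.frame(
    food_item = unlist(lapply(fg$food_group, function(g)
      paste0(g, "_", seq_len(items_per_group)))),
    food_group = rep(fg$food_group, each = items_per_group),
    stringsAsFactors = FALSE)
  # item-level target means: recentred within group so the group mean is exact
  for (conc in c("n_conc", "p_conc")) {
    truth <- fg[[conc]][match(items$food_group, fg$food_group)]
    dev <- runif(nrow(items), -jitter, jitter)
    dev <- dev - ave(dev, items$food_group)
    items[[conc]] <- truth * (1 + dev)
  }

  membership <- matrix(FALSE, nrow(items), n_tables)
  membership[, 1] <- TRUE  # first table carries every item
  if (n_tables > 1)
    membership[, -1] <- runif(nrow(items) * (n_tables - 1)) < 0.6
  tables <- vector("list", n_tables)
  for (tb in seq_len(n_tables)) {
    idx <- which(membership[, tb])
    tables[[tb]] <- data.frame(food_item = items$food_item[idx],
                               n_conc = NA_real_, p_conc = NA_real_,
                               stringsAsFactors = FALSE)
  }
  # per-item cross-table deviations, recentred so the cross-table mean is exact
  for (i in seq_len(nrow(items))) {
    tbs <- which(membership[i, ])
    for (conc in c("n_conc", "p_conc")) {
      dev <- runif(length(tbs), -jitter, jitter)
      dev <- dev - mean(dev)
      vals <- items[[conc]][i] * (1 + dev)
      for (j in seq_along(tbs)) {
        tab <- tables[[tbs[j]]]
        tables[[tbs[j]]][[conc]][tab$food_item == items$food_item[i]] <- vals[j]
      }
    }
  }
  truth <- fg
  truth$n_sources <- vapply(fg$food_group, function(g)
    length(unique(which(membership[items$food_group == g, , drop = FALSE],
                        arr.ind = TRUE)[, "col"])), 0L)
  list(tables = tables,
       group_map = setNames(items$food_group, items$food_item),
       origin_map = setNames(fg$origin, fg$food_group),
       truth = truth)
}

# Draw one country's intake profile; resample until every constraint holds.
.draw_country_intake <- function(animal, ranges, trendN, trendP, n_cohorts,
                                 mid_first, mid_last, yr_first, yr_last,
                                 max_tries = 1000L) {
  fg <- .food_groups
  Ma <- rbind(fg$n_conc[fg$origin == "animal"], fg$p_conc[fg$origin == "animal"])
  Mp <- rbind(fg$n_conc[fg$origin == "plant"], fg$p_conc[fg$origin == "plant"])
  half <- mean(ranges$N)
  subN <- if (animal) c(half, ranges$N[2]) else c(ranges$N[1], half)
  for (try in seq_len(max_tries)) {
    N1 <- runif(1, subN[1], subN[2])
    NP1 <- runif(1, ranges$NP[1], ranges$NP[2])
    P1 <- N1 / NP1
    rN1 <- if (animal) runif(1, 1.2, 3.0) else runif(1, 0.15, 0.85)
    u <- runif(1, 0.8, 1.25)
    # the animal share of intake drifts over the panel (upward in the
    # animal-dominated group), so cohort differences of the partition
    # ratios are informative rather than identically zero
    drift <- if (animal) runif(1, 0.02, 0.15) else runif(1, -0.08, 0.08)
    rNT <- if (n_cohorts > 1) rN1 * (1 + drift) else rN1
    rP1 <- rN1 * u
    rPT <- rNT * u
    if (n_cohorts > 1) {
      NT <- N1 * (1 + trendN)
      PT <- P1 * (1 + trendP)
    } else {
      NT <- N1; PT <- P1
    }
    # the ratio of two linear-in-year series is monotone over the span, so
    # checking the classification at the first and last cohorts covers all
    ok <- N1 >= ranges$N[1] && NT <= ranges$N[2] &&
      P1 >= ranges$P[1] && P1 <= ranges$P[2] &&
      PT >= ranges$P[1] && PT <= ranges$P[2] &&
      ((rN1 + rP1 > 2) == animal) && ((rNT + rPT > 2) == animal) &&
      rNT > 0 && rPT > 0
    if (!ok) next
    split2 <- function(total, r) c(animal = total * r / (1 + r), plant = total / (1 + r))
    amounts <- function(Ntot, Ptot, rN, rP) {
      na <- split2(Ntot, rN); pa <- split2(Ptot, rP)
      a_an <- solve(Ma, c(na[["animal"]], pa[["animal"]]))
      a_pl <- solve(Mp, c(na[["plant"]], pa[["plant"]]))
      c(a_an, a_pl)  # meat, dairy, pulses, vegetables
    }
    k1 <- amounts(N1, P1, rN1, rP1)
    kT <- amounts(NT, PT, rNT, rPT)
    if (any(k1 <= 0) || any(kT <= 0)) next
    # linear-in-year series through the first/last window-mean years must
    # stay nonnegative over the full span
    if (n_cohorts > 1) {
      slope <- (kT - k1) / (mid_last - mid_first)
      k_lo <- k1 + slope * (yr_first - mid_first)
      k_hi <- k1 + slope * (yr_last - mid_first)
      if (any(k_lo < 0) || any(k_hi < 0)) next
    }
    return(list(N1 = N1, NT = NT, P1 = P1, PT = PT,
                rN1 = rN1, rNT = rNT, rP1 = rP1, rPT = rPT,
                k1 = k1, kT = kT))
  }
  np_error("could not draw an in-range intake profile; check intake_ranges and trends",
           "configuration_error")
}

#' Generate a synthetic country x cohort panel with known ground truth
#'
#' Produces the four tables the analysis consumes -- a long food-intake
#' table, item-level composition tables, a height panel and a covariate
#' panel -- plus a `truth` record of the generating process. Heights are
#' the group-specific linear predictor of the levels model (per-group
#' intercept, cohort effects and true covariate coefficients) plus
#' Gaussian noise. Food-group quantities are linear in calendar year, so
#' the growth-window means recovered by [build_intake_panel()] equal the
#' generator's per-cohort targets exactly, and every animal-dominated
#' (plant-dominated) country satisfies the classification rule by
#' construction.
#'
#' @param config a [panel_config()].
#' @return An object of class `"synthetic_panel"`: `intake` (long table:
#'   `country`, `year`, `food_group`, `origin`, `kg_per_capita`),
#'   `heights` (`country`, `cohort`, `height`), `covariates` (`country`,
#'   `cohort`, `GDP`, `GDPg`, `Cal`, `Urban`, `HDI`, `lowbw`),
#'   `composition_tables`, `group_map`, `composition` (true group-level
#'   table) and `truth` (a `truth_record`: group assignment, true
#'   coefficients, inclusion set, per-cohort true intake values, seed and
#'   stream seeds).
#' @export
simulate_panel <- function(config) {
  if (!inherits(config, "panel_config"))
    np_error("config must be a panel_config", "configuration_error")
  streams <- split_seeds(config$seed, 4)
  comp <- simulate_composition_tables(config)

  cohorts <- config$cohorts
  Tn <- length(cohorts)
  wins <- lapply(cohorts, growth_window)
  mids <- vapply(wins, function(w) mean(w[1]:w[2]), 0)
  yr_first <- min(vapply(wins, `[[`, 0L, 1))
  yr_last <- max(vapply(wins, `[[`, 0L, 2))
  years <- yr_first:yr_last

  n <- config$n_countries
  countries <- sprintf("C%03d", seq_len(n))

  set.seed(streams[2])
  n_anim <- round(config$frac_animal_group * n)
  grp <- setNames(rep("plant-dominated", n), countries)
  if (n_anim > 0) grp[sample(countries, n_anim)] <- "animal-dominated"

  fg <- .food_groups
  intake_rows <- vector("list", n)
  truth_intake <- vector("list", n)
  for (ci in seq_len(n)) {
    cc <- countries[ci]
    g <- grp[[cc]]
    dr <- .draw_country_intake(g == "animal-dominated", config$intake_ranges,
                               config$trends$N[[g]], config$trends$P[[g]],
                               Tn, mids[1], mids[Tn], yr_first, yr_last)
    if (Tn > 1) {
      slope <- (dr$kT - dr$k1) / (mids[Tn] - mids[1])
    } else slope <- rep(0, 4)
    kg <- outer(slope, years - mids[1]) + dr$k1  # 4 x years
    intake_rows[[ci]] <- data.frame(
      country = cc,
      year = rep(years, each = 4),
      food_group = rep(fg$food_group, length(years)),
      origin = rep(fg$origin, length(years)),
      kg_per_capita = as.vector(kg),
      stringsAsFactors = FALSE)
    # per-cohort true window means (linear series: mean over window = value
    # at the window's mean year); origin components are linear, so ratios
    # are taken after interpolating each component
    lin <- function(v1, vT, t) if (Tn > 1) v1 + (vT - v1) * (mids[t] - mids[1]) / (mids[Tn] - mids[1]) else v1
    part <- function(total, r) total * r / (1 + r)
    N_an <- vapply(seq_len(Tn), function(t)
      lin(part(dr$N1, dr$rN1), part(dr$NT, dr$rNT), t), 0)
    N_pl <- vapply(seq_len(Tn), function(t)
      lin(dr$N1 / (1 + dr$rN1), dr$NT / (1 + dr$rNT), t), 0)
    P_an <- vapply(seq_len(Tn), function(t)
      lin(part(dr$P1, dr$rP1), part(dr$PT, dr$rPT), t), 0)
    P_pl <- vapply(seq_len(Tn), function(t)
      lin(dr$P1 / (1 + dr$rP1), dr$PT / (1 + dr$rPT), t), 0)
    Nt <- N_an + N_pl
    Pt <- P_an + P_pl
    truth_intake[[ci]] <- data.frame(
      country = cc, cohort = cohorts,
      N = Nt, P = Pt, NP = Nt / Pt,
      aN_pN = N_an / N_pl, aP_pP = P_an / P_pl,
      stringsAsFactors = FALSE)
  }
  intake <- do.call(rbind, intake_rows)
  truth_intake <- do.call(rbind, truth_intake)

  # covariate panel: group-separated uniform draws with mild cohort trends
  set.seed(streams[3])
  cov_rows <- vector("list", n)
  cal_rng <- config$intake_ranges$Cal
  cal_mid <- mean(cal_rng)
  for (ci in seq_len(n)) {
    cc <- countries[ci]
    animal <- grp[[cc]] == "animal-dominated"
    gdp1 <- runif(1, if (animal) 12000 else 600, if (animal) 55000 else 12000)
    gdpg <- runif(Tn, if (animal) 0.5 else 0, if (animal) 5 else 8)
    gdp <- numeric(Tn); gdp[1] <- gdp1
    for (t in seq_len(Tn)[-1]) gdp[t] <- gdp[t - 1] * (1 + gdpg[t] / 100)^10
    repeat {
      cal1 <- runif(1, if (animal) cal_mid else cal_rng[1],
                    if (animal) cal_rng[2] else cal_mid)
      calg <- runif(1, 0, 0.04)
      cal <- cal1 * (1 + calg)^(seq_len(Tn) - 1)
      if (all(cal >= cal_rng[1] & cal <= cal_rng[2])) break
    }
    urb1 <- runif(1, if (animal) 50 else 10, if (animal) 95 else 60)
    urb <- pmin(98, urb1 + (seq_len(Tn) - 1) * runif(1, 0, 7))
    hdi1 <- runif(1, if (animal) 0.60 else 0.30, if (animal) 0.95 else 0.65)
    hdi <- pmin(0.97, hdi1 + (seq_len(Tn) - 1) * runif(1, 0, 0.05))
    lbw1 <- runif(1, if (animal) 3 else 8, if (animal) 9 else 20)
    lbw <- pmax(2, lbw1 - (seq_len(Tn) - 1) * runif(1, 0, 1.5))
    cov_rows[[ci]] <- data.frame(country = cc, cohort = cohorts,
                                 GDP = gdp, GDPg = gdpg, Cal = cal,
                                 Urban = urb, HDI = hdi, lowbw = lbw,
                                 stringsAsFactors = FALSE)
  }
  covariates <- do.call(rbind, cov_rows)

  # heights: group-specific linear predictor + Gaussian noise
  set.seed(streams[4])
  xpanel <- merge(truth_intake, covariates, by = c("country", "cohort"),
                  sort = FALSE)
  xpanel <- xpanel[order(xpanel$country, xpanel$cohort), ]
  mu <- numeric(nrow(xpanel))
  for (i in seq_len(nrow(xpanel))) {
    g <- grp[[xpanel$country[i]]]
    t_idx <- match(xpanel$cohort[i], cohorts)
    beta <- config$true_coefficients[[g]] %||% numeric(0)
    mu[i] <- config$intercepts[[g]] + config$cohort_effects[[g]][t_idx] +
      sum(beta * unlist(xpanel[i, names(beta)]))
  }
  noise <- rnorm(nrow(xpanel), 0, config$noise_sd)
  heights <- data.frame(country = xpanel$country, cohort = xpanel$cohort,
                        height = mu + noise, stringsAsFactors = FALSE)

  inclusion <- unique(unlist(lapply(config$true_coefficients, function(b)
    names(b)[b != 0])))
  truth <- structure(list(
    groups = grp,
    coefficients = config$true_coefficients,
    intercepts = config$intercepts,
    cohort_effects = config$cohort_effects,
    inclusion = inclusion,
    intake = truth_intake,
    noise_sd = config$noise_sd,
    seed = config$seed,
    streams = streams), class = "truth_record")

  rownames(intake) <- rownames(heights) <- rownames(covariates) <- NULL
  structure(list(intake = intake, heights = heights, covariates = covariates,
                 composition_tables = comp$tables, group_map = comp$group_map,
                 composition = comp$truth, truth = truth, config = config),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("Synthetic panel: %d countries x %d cohorts (%d intake rows), seed %d\n",
              x$config$n_countries, length(x$config$cohorts), nrow(x$intake),
              x$config$seed))
  invisible(x)
}

#' Join intake, height and covariate panels into one analysis panel
#'
#' Inner-joins the three per-(country, cohort) tables; the result houses
#' every right-hand-side variable of the levels and differences models.
#'
#' @param intake_panel an [intake_panel][build_intake_panel].
#' @param heights data frame `country`, `cohort`, `height`.
#' @param covariates data frame `country`, `cohort` plus covariate columns.
#' @return Data frame with one row per (country, cohort) present in all
#'   three inputs; attribute `"dropped"` counts rows lost in the join.
#' @export
assemble_analysis_panel <- function(intake_panel, heights, covariates) {
  if (!all(c("country", "cohort", "height") %in% names(heights)))
    np_error("heights must contain country, cohort, height", "validation_error")
  if (!all(c("country", "cohort") %in% names(covariates)))
    np_error("covariates must contain country, cohort", "validation_error")
  out <- merge(merge(heights, intake_panel, by = c("country", "cohort")),
               covariates, by = c("country", "cohort"))
  out <- out[order(out$country, out$cohort), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- max(nrow(intake_panel), nrow(heights)) - nrow(out)
  out
}

#' Write a synthetic panel to delimited text files
#'
#' Writes the intake, height and covariate tables plus the composition
#' source tables as comma-delimited UTF-8 files, and the ground-truth
#' record as a YAML sidecar.
#'
#' @param x a [simulate_panel()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_panel <- function(x, dir) {
  if (!inherits(x, "synthetic_panel"))
    np_error("x must be a synthetic_panel", "validation_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- x$config$seed
  paths <- c(
    write_table(x$intake, file.path(dir, "intake.csv"), seed = seed),
    write_table(x$heights, file.path(dir, "heights.csv"), seed = seed),
    write_table(x$covariates, file.path(dir, "covariates.csv"), seed = seed),
    write_table(data.frame(food_item = names(x$group_map),
                           food_group = unname(x$group_map)),
                file.path(dir, "group_map.csv"), seed = seed))
  for (i in seq_along(x$composition_tables))
    paths <- c(paths, write_table(x$composition_tables[[i]],
                                  file.path(dir, sprintf("composition_%d.csv", i)),
                                  seed = seed))
  tr <- x$truth
  yaml::write_yaml(list(seed = tr$seed,
                        streams = as.integer(tr$streams),
                        groups = as.list(tr$groups),
                        inclusion = tr$inclusion,
                        noise_sd = tr$noise_sd,
                        coefficients = lapply(tr$coefficients, as.list),
                        intercepts = as.list(tr$intercepts),
                        cohort_effects = lapply(tr$cohort_effects, as.list)),
                   file.path(dir, "truth.yml"))
  invisible(c(paths, file.path(dir, "truth.yml")))
}
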