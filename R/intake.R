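#' N:P intake ratio on a mass basis
#'
#' @param n annual N intake, kg per person per year.
#' @param p annual P intake, kg per person per year; must be positive.
#' @return `n / p`, dimensionless mass ratio. Vectorised.
#' @examples
#' np_mass_ratio(19.5, 2.17)
#' @export
np_mass_ratio <- function(n, p) {
  if (!is.numeric(n) || !is.numeric(p))
    np_error("n and p must be numeric", "domain_error")
  if (length(n) != length(p) && length(n) != 1 && length(p) != 1)
    np_error("n and p must have compatible lengths", "domain_error")
  if (any(!is.finite(n)) || any(!is.finite(p)) || any(n < 0))
    np_error("n and p must be finite and N intake nonnegative", "domain_error")
  if (any(p <= 0))
    np_error("N:P ratio is undefined where P intake is zero", "undefined_ratio_error")
  n / p
}

#' Classify a country's diet as animal- or plant-dominated
#'
#' A country is animal-dominated when the sum of its animal/plant intake
#' ratios, (animal N / plant N) + (animal P / plant P), strictly exceeds 2;
#' otherwise (including the boundary sum of exactly 2) it is
#' plant-dominated. This binary indicator is the grouping variable of the
#' joint height model.
#'
#' @param animal_n_over_plant_n ratio of animal-origin to plant-origin N intake.
#' @param animal_p_over_plant_p ratio of animal-origin to plant-origin P intake.
#' @return Factor with levels `"animal-dominated"`, `"plant-dominated"`.
#'   Vectorised.
#' @examples
#' classify_diet_group(1.6, 1.5)  # animal-dominated
#' classify_diet_group(1.0, 1.0)  # boundary: plant-dominated
#' @export
classify_diet_group <- function(animal_n_over_plant_n, animal_p_over_plant_p) {
  rn <- animal_n_over_plant_n
  rp <- animal_p_over_plant_p
  if (!is.numeric(rn) || !is.numeric(rp) || length(rn) != length(rp))
    np_error("both ratios must be numeric vectors of equal length", "domain_error")
  if (any(!is.finite(rn)) || any(!is.finite(rp)) || any(rn < 0) || any(rp < 0))
    np_error("animal/plant intake ratios are undefined (zero or missing plant-origin intake?)",
             "undefined_ratio_error")
  factor(ifelse(rn + rp > 2, "animal-dominated", "plant-dominated"),
         levels = c("animal-dominated", "plant-dominated"))
}

#' Annual per-capita N and P intake over a window of years
#'
#' Computes the window mean of yearly sums of (food-group intake times
#' food-group N or P concentration), accumulated separately for
#' animal-origin and plant-origin food groups and totalled:
#' `sum(annual intake of each food group * mean concentration of each food
#' group) / number of years`. Years inside the window with no intake
#' records at all are excluded from the denominator (with a warning listing
#' the gap); food groups absent within an otherwise recorded year
#' contribute zero.
#'
#' @param intake_table data frame with columns `country`, `year`,
#'   `food_group`, `origin` (`"animal"` or `"plant"`) and `kg_per_capita`.
#' @param composition a [food_composition][average_food_group_concentration]
#'   table covering every food group present.
#' @param country country identifier to extract.
#' @param window length-2 numeric `(start, end)`, years inclusive, e.g.
#'   from [growth_window()].
#' @return List with elements `N`, `P` (kg per person per year), the
#'   origin components `N_animal`, `N_plant`, `P_animal`, `P_plant`, and
#'   `years_used`. `N = N_animal + N_plant` exactly, likewise for P.
#' @export
annual_np_intake <- function(intake_table, composition, country, window) {
  need <- c("country", "year", "food_group", "origin", "kg_per_capita")
  miss <- setdiff(need, names(intake_table))
  if (length(miss))
    np_error(sprintf("intake table lacks column(s): %s", paste(miss, collapse = ", ")),
             "validation_error")
  if (!is.numeric(window) || length(window) != 2 || any(!is.finite(window)) ||
      window[1] > window[2])
    np_error("window must be numeric (start, end) with start <= end", "domain_error")

  rows <- intake_table[intake_table$country == country &
                         intake_table$year >= window[1] &
                         intake_table$year <= window[2], , drop = FALSE]
  if (!nrow(rows))
    np_error(sprintf("no intake records for country '%s' in years %d-%d",
                     country, window[1], window[2]), "missing_data_error")
  bad_origin <- setdiff(unique(rows$origin), c("animal", "plant"))
  if (length(bad_origin))
    np_error(sprintf("unknown origin value(s): %s", paste(bad_origin, collapse = ", ")),
             "validation_error")
  if (any(!is.finite(rows$kg_per_capita) | rows$kg_per_capita < 0))
    np_error(sprintf("country '%s': kg_per_capita must be finite and nonnegative", country),
             "validation_error")
  missing_groups <- setdiff(unique(rows$food_group), composition$food_group)
  if (length(missing_groups))
    np_error(sprintf("food group(s) absent from the composition table: %s",
                     paste(missing_groups, collapse = ", ")), "missing_data_error")

  idx <- match(rows$food_group, composition$food_group)
  n_flux <- rows$kg_per_capita * composition$n_conc[idx]
  p_flux <- rows$kg_per_capita * composition$p_conc[idx]

  years <- sort(unique(rows$year))
  span <- seq(window[1], window[2])
  if (length(years) < length(span)) {
    gaps <- setdiff(span, years)
    warning(sprintf("country '%s': no intake records for %d of %d years in window %d-%d (%s%s); averaging over available years",
                    country, length(gaps), length(span), window[1], window[2],
                    paste(head(gaps, 8), collapse = ", "),
                    if (length(gaps) > 8) ", ..." else ""))
  }

  per_origin <- function(flux, org) sum(flux[rows$origin == org]) / length(years)
  out <- list(N_animal = per_origin(n_flux, "animal"),
              N_plant  = per_origin(n_flux, "plant"),
              P_animal = per_origin(p_flux, "animal"),
              P_plant  = per_origin(p_flux, "plant"))
  out$N <- out$N_animal + out$N_plant
  out$P <- out$P_animal + out$P_plant
  out$years_used <- years
  out[c("N", "P", "N_animal", "N_plant", "P_animal", "P_plant", "years_used")]
}

#' Build the per-country, per-cohort intake panel
#'
#' Applies [annual_np_intake()] over each cohort's [growth_window()],
#' derives the N:P mass ratio, the animal/plant partition ratios, and the
#' diet-group classification, yielding one row per (country, cohort).
#' Besides the cohort-specific `diet_group`, a single per-country label
#' `country_group` is carried, taken from the latest available cohort
#' (the 1980s window when present).
#'
#' @inheritParams annual_np_intake
#' @param cohorts cohort labels to build, a subset of
#'   `c("1960s", "1970s", "1980s")`.
#' @return An `intake_panel` data frame with columns `country`, `cohort`,
#'   `N`, `P`, `NP`, `aN_pN`, `aP_pP`, `diet_group`, `country_group`.
#'   `NP` is `NA` where P intake is zero.
#' @export
build_intake_panel <- function(intake_table, composition,
                               cohorts = c("1960s", "1970s", "1980s")) {
  if (!length(cohorts))
    np_error("empty cohort list", "configuration_error")
  for (tt in cohorts) growth_window(tt)  # validates labels
  countries <- sort(unique(intake_table$country))
  if (!length(countries))
    np_error("intake table contains no countries", "missing_data_error")

  with_context <- function(cc, tt, expr) {
    tryCatch(expr, npheight_error = function(e) {
      np_error(sprintf("country %s, cohort %s: %s", cc, tt, conditionMessage(e)),
               sub("^npheight_", "", class(e)[1]))
    })
  }

  rows <- vector("list", length(countries) * length(cohorts))
  i <- 0L
  for (cc in countries) {
    for (tt in cohorts) {
      win <- growth_window(tt)
      amt <- with_context(cc, tt,
                          annual_np_intake(intake_table, composition, cc, win))
      grp <- with_context(cc, tt,
                          classify_diet_group(amt$N_animal / amt$N_plant,
                                              amt$P_animal / amt$P_plant))
      i <- i + 1L
      rows[[i]] <- data.frame(
        country = cc, cohort = tt,
        N = amt$N, P = amt$P,
        NP = if (amt$P > 0) amt$N / amt$P else NA_real_,
        aN_pN = amt$N_animal / amt$N_plant,
        aP_pP = amt$P_animal / amt$P_plant,
        diet_group = as.character(grp))
    }
  }
  out <- do.call(rbind, rows)
  last <- cohorts[length(cohorts)]
  ref <- if ("1980s" %in% cohorts) "1980s" else last
  ref_rows <- out[out$cohort == ref, ]
  out$country_group <- ref_rows$diet_group[match(out$country, ref_rows$country)]
  rownames(out) <- NULL
  class(out) <- c("intake_panel", "data.frame")
  out
}

#' Range of country mean heights
#'
#' The spread between the tallest and shortest country means, in cm.
#'
#' @param height numeric vector of country mean heights, or a data frame
#'   with a `height` column.
#' @return `max(height) - min(height)`.
#' @examples
#' height_range(c(183, 171, 160))
#' @export
height_range <- function(height) {
  if (is.data.frame(height)) height <- height$height
  height <- height[is.finite(height)]
  if (length(height) < 2)
    np_error("need at least two finite heights", "insufficient_data_error")
  max(height) - min(height)
}
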