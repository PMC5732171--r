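#' All pairwise country differences within a cohort
#'
#' Builds the table of signed differences between every unordered pair of
#' countries in one cohort. Orientation is fixed lexicographically:
#' `country_a < country_b` and each difference column is the value for
#' `country_a` minus the value for `country_b`, so reversing a pair's
#' orientation negates every difference. Countries with any missing
#' required column are excluded (complete-case).
#'
#' @param panel analysis panel data frame with columns `country`, `cohort`,
#'   the response and the variables of interest.
#' @param cohort cohort label to subset on.
#' @param vars variables to difference besides the response; default: all
#'   numeric columns.
#' @param response response variable, differenced as `d_<response>`
#'   (default `"height"`).
#' @return A `pair_table` data frame with `n(n-1)/2` rows, columns
#'   `country_a`, `country_b` and one `d_<var>` column per variable.
#' @export
pairwise_differences <- function(panel, cohort, vars = NULL, response = "height") {
  if (!is.data.frame(panel) || !all(c("country", "cohort", response) %in% names(panel)))
    np_error("panel must contain 'country', 'cohort' and the response column",
             "validation_error")
  sub <- panel[panel$cohort == cohort, , drop = FALSE]
  if (is.null(vars))
    vars <- setdiff(names(sub)[vapply(sub, is.numeric, TRUE)], c(response, "year"))
  miss <- setdiff(vars, names(sub))
  if (length(miss))
    np_error(sprintf("variables not in panel: %s", paste(miss, collapse = ", ")),
             "validation_error")
  cols <- c(response, vars)
  cc <- complete.cases(sub[cols])
  dropped <- sub$country[!cc]
  sub <- sub[cc, , drop = FALSE]
  if (anyDuplicated(sub$country))
    np_error(sprintf("duplicated country rows within cohort %s", cohort),
             "validation_error")
  if (nrow(sub) < 2)
    np_error(sprintf("need at least 2 complete countries in cohort %s", cohort),
             "insufficient_data_error")
  sub <- sub[order(sub$country), , drop = FALSE]
  idx <- combn(nrow(sub), 2)
  a <- idx[1, ]; b <- idx[2, ]
  out <- data.frame(country_a = sub$country[a], country_b = sub$country[b],
                    stringsAsFactors = FALSE)
  for (v in cols) out[[paste0("d_", v)]] <- sub[[v]][a] - sub[[v]][b]
  attr(out, "cohort") <- cohort
  attr(out, "dropped") <- dropped
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Linear model on pairwise country differences with partial F statistics
#'
#' Least-squares fit of a difference response on difference predictors,
#' without an intercept: signed pairwise differences are antisymmetric
#' under orientation reversal, so an intercept is not identifiable under
#' the orientation convention. Per-predictor partial F statistics come
#' from drop-one nested model comparisons in the joint model. Pairs
#' sharing a country are not independent; no correction is applied, which
#' is a known caveat of this design.
#'
#' @param pairs a [pair_table][pairwise_differences] (or compatible data
#'   frame).
#' @param predictors names of difference columns to use as predictors,
#'   e.g. `c("d_N", "d_GDP")`.
#' @param response name of the response difference column
#'   (default `"d_height"`).
#' @param absolute if `TRUE`, absolute values of the response and all
#'   predictors are taken before fitting (still without intercept).
#' @return A `pairwise_glm` object: `coefficients`, `partial_F` (named, one
#'   per predictor), `r_squared`, `df_residual`, and the underlying
#'   [stats::lm] fit.
#' @export
glm_pairwise_fit <- function(pairs, predictors, response = "d_height",
                             absolute = FALSE) {
  miss <- setdiff(c(response, predictors), names(pairs))
  if (length(miss))
    np_error(sprintf("columns not in pair table: %s", paste(miss, collapse = ", ")),
             "validation_error")
  dat <- as.data.frame(pairs[c(response, predictors)])
  if (absolute) dat[] <- lapply(dat, abs)
  if (nrow(dat) < length(predictors) + 1)
    np_error("fewer rows than predictors + 1", "insufficient_data_error")
  X <- as.matrix(dat[predictors])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    np_error(sprintf("rank-deficient design; linearly dependent column(s): %s",
                     paste(dep, collapse = ", ")), "collinearity_error")
  }
  fml <- reformulate(c("0", predictors), response = response)
  fit <- lm(fml, data = dat)
  dr <- drop1(fit, test = "F")
  pf <- setNames(dr[predictors, "F value"], predictors)
  structure(list(coefficients = coef(fit), partial_F = pf,
                 r_squared = summary(fit)$r.squared,
                 df_residual = fit$df.residual,
                 absolute = absolute, fit = fit, call = match.call()),
            class = "pairwise_glm")
}

#' @export
print.pairwise_glm <- function(x, ...) {
  cat(sprintf("Pairwise-difference linear model (%s differences, no intercept)\n",
              if (x$absolute) "absolute" else "signed"))
  tab <- data.frame(coefficient = x$coefficients,
                    partial_F = x$partial_F[names(x$coefficients)])
  print(round(tab, 4))
  cat(sprintf("r^2 = %.4f on %d residual df\n", x$r_squared, x$df_residual))
  invisible(x)
}

#' Per-country change between two cohorts
#'
#' For every country present with complete data in both cohorts, computes
#' later-cohort minus earlier-cohort differences of height and intake
#' variables (each cohort's intake refers to its own growth window).
#' Countries missing either cohort are dropped with a note.
#'
#' @param panel analysis panel data frame (`country`, `cohort`, variables).
#' @param from earlier cohort label (default `"1960s"`).
#' @param to later cohort label (default `"1980s"`).
#' @param vars variables to difference.
#' @return A `cohort_change` data frame with columns `country` and
#'   `d_<var>` (value in `to` minus value in `from`).
#' @export
cohort_change_table <- function(panel, from = "1960s", to = "1980s",
                                vars = c("height", "N", "P", "NP")) {
  miss <- setdiff(c("country", "cohort", vars), names(panel))
  if (length(miss))
    np_error(sprintf("panel lacks column(s): %s", paste(miss, collapse = ", ")),
             "validation_error")
  a <- panel[panel$cohort == from, c("country", vars), drop = FALSE]
  b <- panel[panel$cohort == to, c("country", vars), drop = FALSE]
  a <- a[complete.cases(a), , drop = FALSE]
  b <- b[complete.cases(b), , drop = FALSE]
  if (anyDuplicated(a$country) || anyDuplicated(b$country))
    np_error("duplicated country rows within a cohort", "validation_error")
  common <- sort(intersect(a$country, b$country))
  dropped <- setdiff(union(a$country, b$country), common)
  if (!length(common))
    np_error(sprintf("no country has complete data in both the %s and %s cohorts",
                     from, to), "insufficient_data_error")
  if (length(dropped))
    message(sprintf("cohort_change_table: dropped %d countries without both cohorts (%s%s)",
                    length(dropped), paste(head(dropped, 5), collapse = ", "),
                    if (length(dropped) > 5) ", ..." else ""))
  ai <- match(common, a$country)
  bi <- match(common, b$country)
  out <- data.frame(country = common, stringsAsFactors = FALSE)
  for (v in vars) out[[paste0("d_", v)]] <- b[[v]][bi] - a[[v]][ai]
  attr(out, "from") <- from
  attr(out, "to") <- to
  attr(out, "dropped") <- dropped
  class(out) <- c("cohort_change", "data.frame")
  out
}
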