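#' Low-level BMA design constructor
#'
#' Holds the response, the always-included block `W` (never subject to
#' selection: intercepts and cohort dummies), the selectable block `Z`, and
#' the mapping from named covariates to their `Z` columns. In a grouped
#' (levels) design each covariate owns two group-specific columns that are
#' switched in and out of a model together; the two diet groups share the
#' model structure and the error variance but not the coefficient values.
#'
#' @param y numeric response vector.
#' @param W always-included design block (matrix, full column rank).
#' @param Z selectable design block (matrix).
#' @param covariates character vector of selectable covariate names.
#' @param cov_cols named list mapping each covariate to its column indices
#'   in `Z`.
#' @param groups group labels for grouped designs, or `NULL`.
#' @param rows optional data frame of row identifiers (country, cohort, ...).
#' @param response name of the response variable.
#' @param dropped number of incomplete rows excluded upstream.
#' @return An object of class `"bma_design"`.
#' @export
bma_design <- function(y, W, Z, covariates, cov_cols, groups = NULL,
                       rows = NULL, response = "y", dropped = 0L) {
  W <- as.matrix(W); Z <- as.matrix(Z)
  if (!is.numeric(y) || nrow(W) != length(y) || nrow(Z) != length(y))
    np_error("y, W and Z must have matching row counts", "validation_error")
  if (any(!is.finite(y)) || any(!is.finite(W)) || any(!is.finite(Z)))
    np_error("design contains non-finite values; drop incomplete rows first",
             "validation_error")
  if (!setequal(names(cov_cols), covariates) || !length(covariates))
    np_error("cov_cols must map exactly the selectable covariates", "validation_error")
  if (any(unlist(cov_cols) < 1) || any(unlist(cov_cols) > ncol(Z)))
    np_error("cov_cols indexes outside Z", "validation_error")
  if (qr(W)$rank < ncol(W))
    np_error("always-included block W is rank deficient", "collinearity_error")
  structure(list(y = y, W = W, Z = Z, covariates = covariates,
                 cov_cols = cov_cols, groups = groups, rows = rows,
                 response = response, n = length(y), dropped = dropped),
            class = "bma_design")
}

#' @export
print.bma_design <- function(x, ...) {
  cat(sprintf("BMA design: n = %d rows, %d always-included columns, %d selectable covariates (%d columns)\n",
              x$n, ncol(x$W), length(x$covariates), ncol(x$Z)))
  if (!is.null(x$groups))
    cat("  groups:", paste(x$groups, collapse = " / "), "\n")
  invisible(x)
}

#' Design matrix for the height-levels model
#'
#' Encodes the joint two-group levels model: height is regressed on a
#' per-group intercept and per-group cohort dummies (always included) plus
#' group-specific copies of each selectable covariate, `x * I(group)`, so
#' that the two diet groups are fitted in one joint model with one error
#' variance while keeping group-specific coefficients. One inclusion
#' indicator per covariate switches both of its group columns together.
#'
#' @param panel analysis panel data frame: one row per (country, cohort)
#'   with `country`, the cohort and grouping columns, the response and the
#'   covariates. Incomplete rows are dropped (complete-case).
#' @param covariates selectable covariates; defaults to the full
#'   right-hand-side set: N and P intake, the N:P ratio, GDP, GDP growth,
#'   calories, urban share and the two animal/plant partition ratios.
#'   Append `"HDI"` and `"lowbw"` to use the extended covariate set.
#' @param response response column (default `"height"`, cm).
#' @param group binary grouping column (default `"diet_group"`).
#' @param cohort cohort column (default `"cohort"`).
#' @return A [bma_design] with `2 * length(covariates)` selectable columns.
#' @export
build_levels_design <- function(panel,
                                covariates = c("N", "P", "NP", "GDP", "GDPg",
                                               "Cal", "Urban", "aN_pN", "aP_pP"),
                                response = "height", group = "diet_group",
                                cohort = "cohort") {
  need <- unique(c("country", cohort, group, response, covariates))
  miss <- setdiff(need, names(panel))
  if (length(miss))
    np_error(sprintf("panel lacks column(s): %s", paste(miss, collapse = ", ")),
             "validation_error")
  cc <- complete.cases(panel[need])
  dat <- panel[cc, , drop = FALSE]
  groups_lv <- sort(unique(as.character(dat[[group]])))
  if (length(groups_lv) != 2)
    np_error(sprintf("grouping column '%s' must take exactly two values; found %d",
                     group, length(groups_lv)), "validation_error")
  coh <- as.character(dat[[cohort]])
  coh_lv <- sort(unique(coh))
  p_group <- length(coh_lv)  # per-group intercept + (T-1) cohort dummies
  counts <- table(factor(as.character(dat[[group]]), levels = groups_lv))
  if (any(counts < p_group + 1)) {
    g_bad <- names(counts)[which(counts < p_group + 1)[1]]
    np_error(sprintf("group '%s' has %d complete rows, fewer than the %d always-included columns + 1",
                     g_bad, counts[[g_bad]], p_group), "insufficient_data_error")
  }

  W_cols <- list()
  for (g in groups_lv) {
    ind <- as.numeric(dat[[group]] == g)
    W_cols[[paste0("intercept|", g)]] <- ind
    for (t in coh_lv[-1])
      W_cols[[paste0("cohort", t, "|", g)]] <- ind * (coh == t)
  }
  W <- do.call(cbind, W_cols)

  Z_cols <- list()
  cov_cols <- list()
  j <- 0L
  for (v in covariates) {
    for (g in groups_lv) {
      j <- j + 1L
      Z_cols[[paste0(v, "|", g)]] <- dat[[v]] * (dat[[group]] == g)
    }
    cov_cols[[v]] <- c(j - 1L, j)
  }
  Z <- do.call(cbind, Z_cols)

  bma_design(y = dat[[response]], W = W, Z = Z, covariates = covariates,
             cov_cols = cov_cols, groups = groups_lv,
             rows = dat[c("country", cohort, group)],
             response = response, dropped = sum(!cc))
}

#' Design matrix for the cohort-differences model
#'
#' One row per (country, consecutive cohort pair) with complete data in
#' both cohorts; the response is the later-minus-earlier height change.
#' Covariate names are interpreted by suffix/prefix: `<var>_level` takes
#' the variable's level in one cohort of the pair (the earlier cohort by
#' default, switchable via `level_cohort`), and `d_<var>` takes the
#' later-minus-earlier difference. The always-included block is an
#' intercept plus cohort-pair dummies. No diet-group split is applied in
#' the differences model.
#'
#' @inheritParams build_levels_design
#' @param covariates selectable covariates; the default pairs the N and P
#'   intake levels with differences of the remaining right-hand-side terms.
#' @param level_cohort which cohort of a consecutive pair supplies
#'   `<var>_level` columns: `"earlier"` (default) or `"later"`.
#' @return A [bma_design] (ungrouped) with one selectable column per
#'   covariate. With complete data for 3 cohorts in `m` countries the
#'   design has `2 m` rows.
#' @export
build_difference_design <- function(panel,
                                    covariates = c("N_level", "P_level", "d_GDP",
                                                   "d_GDPg", "d_Cal", "d_N", "d_P",
                                                   "d_NP", "d_aP_pP", "d_aN_pN",
                                                   "d_Urban"),
                                    response = "height",
                                    level_cohort = c("earlier", "later"),
                                    cohort = "cohort") {
  level_cohort <- match.arg(level_cohort)
  is_lev <- grepl("_level$", covariates)
  is_dif <- grepl("^d_", covariates)
  if (any(!is_lev & !is_dif))
    np_error(sprintf("covariate names must end in '_level' or start with 'd_': %s",
                     paste(covariates[!is_lev & !is_dif], collapse = ", ")),
             "validation_error")
  lev_vars <- sub("_level$", "", covariates[is_lev])
  dif_vars <- sub("^d_", "", covariates[is_dif])
  base_vars <- unique(c(response, lev_vars, dif_vars))
  miss <- setdiff(c("country", cohort, base_vars), names(panel))
  if (length(miss))
    np_error(sprintf("panel lacks column(s): %s", paste(miss, collapse = ", ")),
             "validation_error")
  if (anyDuplicated(paste(panel$country, panel[[cohort]])))
    np_error("panel must have one row per (country, cohort)", "validation_error")
  coh_lv <- sort(unique(as.character(panel[[cohort]])))
  if (length(coh_lv) < 2)
    np_error("need at least two cohorts to take differences", "insufficient_data_error")

  dropped <- 0L
  blocks <- list()
  for (t in seq_len(length(coh_lv) - 1)) {
    e <- panel[panel[[cohort]] == coh_lv[t], c("country", base_vars), drop = FALSE]
    l <- panel[panel[[cohort]] == coh_lv[t + 1], c("country", base_vars), drop = FALSE]
    e <- e[complete.cases(e), , drop = FALSE]
    l <- l[complete.cases(l), , drop = FALSE]
    common <- sort(intersect(e$country, l$country))
    dropped <- dropped + length(setdiff(union(e$country, l$country), common))
    if (!length(common)) next
    ei <- match(common, e$country)
    li <- match(common, l$country)
    lev <- if (level_cohort == "earlier") e[ei, , drop = FALSE] else l[li, , drop = FALSE]
    blk <- data.frame(country = common,
                      pair = paste0(coh_lv[t], "-", coh_lv[t + 1]),
                      stringsAsFactors = FALSE)
    blk$d_response <- l[[response]][li] - e[[response]][ei]
    for (v in lev_vars) blk[[paste0(v, "_level")]] <- lev[[v]]
    for (v in dif_vars) blk[[paste0("d_", v)]] <- l[[v]][li] - e[[v]][ei]
    blocks[[length(blocks) + 1L]] <- blk
  }
  if (!length(blocks))
    np_error("no country has complete data in any consecutive cohort pair",
             "insufficient_data_error")
  dat <- do.call(rbind, blocks)

  pair_lv <- sort(unique(dat$pair))
  W_cols <- list(intercept = rep(1, nrow(dat)))
  for (p in pair_lv[-1])
    W_cols[[paste0("pair", p)]] <- as.numeric(dat$pair == p)
  W <- do.call(cbind, W_cols)
  Z <- as.matrix(dat[covariates])
  cov_cols <- as.list(setNames(seq_along(covariates), covariates))

  bma_design(y = dat$d_response, W = W, Z = Z, covariates = covariates,
             cov_cols = cov_cols, groups = NULL,
             rows = dat[c("country", "pair")],
             response = paste0("d_", response), dropped = dropped)
}
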