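#' Average food-item N and P concentrations into food-group values
#'
#' Food-composition source databases report nitrogen and phosphorus
#' concentrations per food item, while food-balance intake data are recorded
#' per food group. This collapses item-level tables into one group-level
#' table with a two-stage mean: an item present in more than one source
#' database first receives the cross-database mean of its concentrations,
#' and the food-group value is then the mean over the group's items.
#'
#' @param item_tables a data frame or list of data frames, one per source
#'   database, with columns `food_item`, `n_conc`, `p_conc` (mass fractions,
#'   kg of N or P per kg of food, in `[0, 1)`).
#' @param group_map named character vector mapping food item to food group;
#'   every mapped item must appear in at least one table.
#' @return A `food_composition` data frame with one row per food group and
#'   columns `food_group`, `n_conc`, `p_conc` and `n_sources` (number of
#'   source databases that contributed at least one item of the group).
#' @examples
#' tab <- data.frame(food_item = "wheat", n_conc = 0.02, p_conc = 0.003)
#' average_food_group_concentration(tab, c(wheat = "cereals"))
#' @export
average_food_group_concentration <- function(item_tables, group_map) {
  if (is.data.frame(item_tables)) item_tables <- list(item_tables)
  if (!is.list(item_tables) || !length(item_tables))
    np_error("at least one composition table is required", "validation_error")
  for (i in seq_along(item_tables)) {
    tab <- item_tables[[i]]
    miss <- setdiff(c("food_item", "n_conc", "p_conc"), names(tab))
    if (length(miss))
      np_error(sprintf("composition table %d lacks column(s): %s",
                       i, paste(miss, collapse = ", ")), "validation_error")
    conc <- c(tab$n_conc, tab$p_conc)
    if (any(!is.finite(conc) | conc < 0 | conc >= 1))
      np_error(sprintf("composition table %d: concentrations must be mass fractions in [0, 1)", i),
               "validation_error")
  }
  items <- names(group_map)
  if (is.null(items) || any(items == "") || anyNA(group_map))
    np_error("group_map must be a complete named character vector (item -> group)",
             "validation_error")

  per_item <- lapply(items, function(it) {
    hits <- lapply(seq_along(item_tables), function(i) {
      tab <- item_tables[[i]]
      rows <- tab[tab$food_item == it, , drop = FALSE]
      if (!nrow(rows)) return(NULL)
      data.frame(table = i, n_conc = mean(rows$n_conc), p_conc = mean(rows$p_conc))
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits))
      np_error(sprintf("no N or P concentration found for food item '%s' in any source table", it),
               "missing_data_error")
    # cross-database mean first, then items are averaged within the group
    list(food_group = unname(group_map[[it]]),
         n_conc = mean(hits$n_conc), p_conc = mean(hits$p_conc),
         tables = hits$table)
  })

  groups <- sort(unique(vapply(per_item, `[[`, "", "food_group")))
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- per_item[vapply(per_item, `[[`, "", "food_group") == g]
    data.frame(food_group = g,
               n_conc = mean(vapply(sub, `[[`, 0, "n_conc")),
               p_conc = mean(vapply(sub, `[[`, 0, "p_conc")),
               n_sources = length(unique(unlist(lapply(sub, `[[`, "tables")))))
  }))
  rownames(out) <- NULL
  class(out) <- c("food_composition", "data.frame")
  out
}
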