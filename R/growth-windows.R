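.growth_windows <- list(
  "1960s" = c(1961L, 1989L),
  "1970s" = c(1971L, 1999L),
  "1980s" = c(1981L, 2009L)
)

#' Growth window of a birth cohort
#'
#' Adult height of men born in a given decade reflects nutrition over the
#' roughly 29-year span starting the year after the decade opens: intake is
#' averaged over 1961--1989 for the 1960s cohort, 1971--1999 for the 1970s
#' cohort and 1981--2009 for the 1980s cohort.
#'
#' @param cohort cohort label, one of `"1960s"`, `"1970s"`, `"1980s"`.
#' @return Named integer vector `c(start =, end =)`, both years inclusive.
#' @examples
#' growth_window("1960s")
#' @export
growth_window <- function(cohort) {
  if (!is.character(cohort) || length(cohort) != 1 ||
      is.na(cohort) || !cohort %in% names(.growth_windows))
    np_error(sprintf("unknown cohort label %s; expected one of %s",
                     deparse(cohort),
                     paste(names(.growth_windows), collapse = ", ")),
             "domain_error")
  w <- .growth_windows[[cohort]]
  c(start = w[1], end = w[2])
}

npheight_cohorts <- function() names(.growth_windows)
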