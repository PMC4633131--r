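## Harmonization of heterogeneous panel sources: currency-base deflation,
## regional gap filling, and exclusion of countries without coverage.

#' Convert incomes to a common currency base
#'
#' Multiplies each country's income by the deflation factor for the
#' requested base pair. Country-specific factors take precedence over a
#' `*` wildcard row. Converting a panel already in the target base
#' (`from == to`) is the identity.
#'
#' @param panel a [food_panel()].
#' @param deflators a [deflator_table()].
#' @param from,to currency base labels, e.g. `"US$1990"`, `"US$2005"`.
#' @return the panel with `income` rebased.
#' @export
deflate_income <- function(panel, deflators, from, to) {
  if (identical(from, to)) return(panel)
  deflators <- deflator_table(deflators)
  pair <- paste0(from, "->", to)
  rows <- deflators[deflators$base_pair == pair, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop_data(paste0("no deflator defined for base pair ", pair))
  }
  wildcard <- rows$factor[rows$country == "*"]
  factors <- rows$factor[match(panel$country, rows$country)]
  if (length(wildcard) == 1L) factors[is.na(factors)] <- wildcard
  if (anyNA(factors)) {
    miss <- unique(panel$country[is.na(factors)])
    stop_data(paste0("missing deflator for base pair ", pair,
                     ", countries: ", paste(head(miss, 5L), collapse = ", ")))
  }
  panel$income <- panel$income * factors
  panel
}

#' Fill missing panel cells with regional same-year averages
#'
#' Missing `income`, `total_cal` and `animal_cal` cells are replaced with
#' the regional same-year average of the countries that report the value.
#' The average is population-weighted by default, consistent with the
#' population weighting used in all regional aggregation; an unweighted
#' mean is available for comparison. Originally present cells are never
#' altered.
#'
#' @param panel a [food_panel()].
#' @param map a [region_map()] covering every country in the panel.
#' @param weighted use population-weighted regional means (default) or
#'   unweighted means.
#' @return the filled panel, with attribute `n_filled` counting replaced
#'   cells.
#' @export
fill_missing_regional <- function(panel, map, weighted = TRUE) {
  map <- region_map(map)
  region <- map$region[match(panel$country, map$country)]
  if (anyNA(region)) {
    miss <- unique(panel$country[is.na(region)])
    stop_data(paste0("countries without region mapping: ",
                     paste(head(miss, 5L), collapse = ", ")))
  }
  n_filled <- 0L
  for (col in c("income", "total_cal", "animal_cal")) {
    holes <- which(is.na(panel[[col]]))
    for (i in holes) {
      donors <- which(region == region[i] & panel$year == panel$year[i] &
                        !is.na(panel[[col]]))
      if (weighted) donors <- donors[!is.na(panel$population[donors])]
      if (length(donors) == 0L) {
        stop_data(sprintf(
          "no donor country for %s in region %s, year %d",
          col, region[i], panel$year[i]))
      }
      panel[[col]][i] <- if (weighted) {
        weighted.mean(panel[[col]][donors], panel$population[donors])
      } else {
        mean(panel[[col]][donors])
      }
      n_filled <- n_filled + 1L
    }
  }
  attr(panel, "n_filled") <- n_filled
  panel
}

#' Restrict a panel to a covered country set
#'
#' Drops records for countries outside `coverage` (e.g. countries absent
#' from the calorie source) and reports the share of world population the
#' exclusion represents, computed over all population records.
#'
#' @param panel a [food_panel()].
#' @param coverage character vector of covered country codes.
#' @return the restricted panel, with attributes `excluded_countries` and
#'   `excluded_share` (fraction of total population removed).
#' @export
exclude_uncovered <- function(panel, coverage) {
  keep <- panel$country %in% coverage
  total_pop <- sum(panel$population, na.rm = TRUE)
  covered_pop <- sum(panel$population[keep], na.rm = TRUE)
  share <- if (total_pop > 0) 1 - covered_pop / total_pop else 0
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_countries") <- sort(unique(panel$country[!keep]))
  attr(out, "excluded_share") <- share
  attr(out, "year_range") <- attr(panel, "year_range")
  class(out) <- class(panel)
  out
}
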