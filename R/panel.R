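## Country-year panel container and delimited-text readers/writers.
##
## A food panel is a long-format data.frame with one row per country-year:
##   country    ISO3-style code (character)
##   year       calendar year (integer)
##   income     per-capita income, US$2005 capita^-1 a^-1
##   population capita
##   total_cal  total calorie demand, kcal capita^-1 d^-1
##   animal_cal animal-based calorie demand, kcal capita^-1 d^-1
## Missing observations are NA, never 0: 0 kcal is a (invalid) value, not
## the absence of one.

panel_columns <- function() {
  c("country", "year", "income", "population", "total_cal", "animal_cal")
}

#' Construct a food demand panel
#'
#' Builds and validates the canonical country-year panel used throughout the
#' package. Input columns beyond the canonical six are dropped.
#'
#' @param x data.frame with columns `country`, `year`, `income`,
#'   `population`, `total_cal`, `animal_cal` (missing values as `NA`).
#' @param year_range optional integer vector of length 2 declaring the
#'   admissible year span; rows outside it are an error.
#' @return A `food_panel`, a validated data.frame.
#' @export
food_panel <- function(x, year_range = NULL) {
  if (!is.data.frame(x)) stop_data("panel input must be a data.frame")
  missing_cols <- setdiff(panel_columns(), names(x))
  if (length(missing_cols) > 0L) {
    stop_data(paste0("panel is missing columns: ",
                     paste(missing_cols, collapse = ", ")))
  }
  x <- x[panel_columns()]
  x$country <- as.character(x$country)
  x$year <- as.integer(x$year)
  for (col in c("income", "population", "total_cal", "animal_cal")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  validate_panel(x, year_range = year_range)
  rownames(x) <- NULL
  class(x) <- c("food_panel", "data.frame")
  attr(x, "year_range") <- year_range
  x
}

validate_panel <- function(x, year_range = NULL) {
  offending <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      idx <- which(bad)
      rows <- paste0(x$country[idx], "/", x$year[idx])
      stop_data(paste0(what, " for ", length(idx), " row(s): ",
                       paste(head(rows, 5L), collapse = ", "),
                       if (length(idx) > 5L) ", ..." else ""))
    }
  }
  offending(!is.na(x$income) & x$income <= 0, "income must be > 0")
  offending(!is.na(x$population) & x$population < 0, "population must be >= 0")
  offending(!is.na(x$animal_cal) & x$animal_cal < 0,
            "animal_cal must be >= 0")
  offending(!is.na(x$animal_cal) & !is.na(x$total_cal) &
              x$animal_cal > x$total_cal,
            "animal_cal exceeds total_cal")
  if (!is.null(year_range)) {
    offending(x$year < year_range[1] | x$year > year_range[2],
              "year outside declared range")
  }
  invisible(x)
}

#' Read a country-year panel from delimited text
#'
#' Reads a comma-separated, UTF-8, header-row file in long format (one row
#' per country-year). Because FAOSTAT and World Bank exports label columns
#' differently, the mapping from file columns to canonical names is
#' configurable through `schema`.
#'
#' @param path path to a CSV file.
#' @param schema named character vector mapping canonical names
#'   (`country`, `year`, `income`, `population`, `total_cal`, `animal_cal`)
#'   to the column names used in the file. Defaults to the canonical names
#'   themselves.
#' @param year_range optional admissible year span, passed to [food_panel()].
#' @return A [food_panel()].
#' @export
read_panel <- function(path, schema = NULL, year_range = NULL) {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (is.null(schema)) {
    schema <- setNames(panel_columns(), panel_columns())
  }
  missing_cols <- setdiff(schema, names(raw))
  if (length(missing_cols) > 0L) {
    stop_data(paste0("declared columns absent from file: ",
                     paste(missing_cols, collapse = ", ")))
  }
  out <- data.frame(country = raw[[schema[["country"]]]],
                    stringsAsFactors = FALSE)
  for (col in c("year", "income", "population", "total_cal", "animal_cal")) {
    cell <- raw[[schema[[col]]]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is.na(cell) & is.na(num)
    if (any(bad)) {
      row <- which(bad)[1L]
      stop_data(sprintf(
        "malformed numeric cell in column '%s', row %d: '%s'",
        schema[[col]], row, cell[row]))
    }
    out[[col]] <- num
  }
  food_panel(out, year_range = year_range)
}

#' Write a panel to the canonical CSV dialect
#'
#' Numeric cells are written with 17 significant digits so that a
#' write/read round trip reproduces the records bit-identically.
#'
#' @param panel a [food_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- as.data.frame(panel)
  for (col in c("income", "population", "total_cal", "animal_cal")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), NA_character_,
                         formatC(v, digits = 17, format = "g"))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Number of complete income-calorie observations
#'
#' Counts panel rows where income, total calories and animal calories are
#' all present -- the observations usable by every regression family.
#'
#' @param panel a [food_panel()].
#' @return integer count.
#' @export
n_complete_pairs <- function(panel) {
  sum(!is.na(panel$income) & !is.na(panel$total_cal) &
        !is.na(panel$animal_cal))
}

#' Read or build a country-to-region map
#'
#' @param x path to a two-column CSV (`country,region`) or an equivalent
#'   data.frame. Every country must map to exactly one region.
#' @return data.frame with columns `country` and `region`.
#' @export
region_map <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_config(paste0("file not found: ", x))
    x <- read.csv(x, colClasses = "character")
  }
  if (!all(c("country", "region") %in% names(x))) {
    stop_data("region map needs columns 'country' and 'region'")
  }
  x <- x[c("country", "region")]
  dup <- duplicated(x$country)
  if (any(dup)) {
    stop_data(paste0("countries mapped to more than one region: ",
                     paste(unique(x$country[dup]), collapse = ", ")))
  }
  x
}

#' The default ten world regions
#'
#' Region labels for grouping countries with similar socio-economic
#' conditions: Sub-Saharan Africa (AFR), Centrally Planned Asia (CPA),
#' Europe (EUR), Former Soviet Union (FSU), Latin America (LAM), Middle
#' East (MEA), North America (NAM), Pacific OECD (PAO), Pacific Asia (PAS)
#' and South Asia (SAS).
#'
#' @return character vector of the ten region codes.
#' @export
default_regions <- function() {
  c("AFR", "CPA", "EUR", "FSU", "LAM", "MEA", "NAM", "PAO", "PAS", "SAS")
}

#' Read or build a deflator table
#'
#' Currency-base conversion factors, as a three-column CSV
#' (`country,base_pair,factor`) with `base_pair` written `from->to`
#' (e.g. `US$1990->US$2005`). A `*` wildcard country row supplies a global
#' factor for countries without their own row.
#'
#' @param x path or data.frame.
#' @return data.frame with columns `country`, `base_pair`, `factor`.
#' @export
deflator_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_config(paste0("file not found: ", x))
    x <- read.csv(x, colClasses = c("character", "character", "numeric"))
  }
  if (!all(c("country", "base_pair", "factor") %in% names(x))) {
    stop_data("deflator table needs columns 'country', 'base_pair', 'factor'")
  }
  if (any(!is.na(x$factor) & x$factor <= 0)) {
    stop_data("deflator factors must be > 0")
  }
  x[c("country", "base_pair", "factor")]
}

#' @export
print.food_panel <- function(x, ...) {
  cat(sprintf("<food_panel> %d records, %d countries, years %d-%d\n",
              nrow(x), length(unique(x$country)),
              min(x$year), max(x$year)))
  cat(sprintf("  complete (income, total, animal) observations: %d\n",
              n_complete_pairs(x)))
  invisible(x)
}
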