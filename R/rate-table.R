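#' Period-by-age incidence-rate tables
#'
#' The registry-style input of the pipeline: a matrix of age-specific
#' incidence rates (per 100,000 person-years) indexed by calendar year and
#' 5-year age band. Optionally carries the underlying case counts and
#' person-years, in which case rates must agree with
#' `100000 * count / person_years`.
#'
#' @param years integer vector of calendar years, contiguous and ascending.
#' @param bands age-band `data.frame` from [age_bands()] or
#'   [parse_age_bands()].
#' @param rates numeric matrix, `length(years)` rows by `nrow(bands)`
#'   columns; `NA` marks a missing cell, zero is a real observed rate.
#' @param counts,person_years optional matrices of the same shape.
#' @param sex,population free-text labels carried through to outputs.
#' @return an object of class `rate_table`.
#' @seealso [read_rate_table()], [build_cohort_table()]
#' @export
rate_table <- function(years, bands, rates, counts = NULL,
                       person_years = NULL, sex = "", population = "") {
  years <- as.integer(years)
  if (length(years) == 0L) stop("no years")
  if (is.unsorted(years, strictly = TRUE) ||
      any(diff(years) != 1L))
    stop("non-contiguous years in rate table")
  rates <- as.matrix(rates)
  if (nrow(rates) != length(years) || ncol(rates) != nrow(bands))
    stop("rate matrix shape does not match years x bands")
  if (any(rates < 0, na.rm = TRUE)) stop("negative rate in table")
  dimnames(rates) <- list(years, bands$label)
  for (m in list(counts, person_years)) {
    if (!is.null(m) && !all(dim(as.matrix(m)) == dim(rates)))
      stop("counts/person_years shape does not match rates")
  }
  if (!is.null(person_years) && any(person_years <= 0, na.rm = TRUE))
    stop("person_years must be positive")
  if (!is.null(counts) && !is.null(person_years)) {
    implied <- 1e5 * counts / person_years
    ok <- is.na(rates) | is.na(implied) |
      abs(rates - implied) <= pmax(0.05, 1e-6 * implied)
    if (!all(ok))
      stop("rates inconsistent with 100000 * count / person_years")
  }
  structure(list(years = years, bands = bands, rates = rates,
                 counts = counts, person_years = person_years,
                 sex = sex, population = population),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("Period x age incidence-rate table: %d years (%d-%d), %d age bands\n",
              length(x$years), min(x$years), max(x$years), nrow(x$bands)))
  if (nzchar(x$population) || nzchar(x$sex))
    cat(sprintf("  %s %s\n", x$population, x$sex))
  cat(sprintf("  %d observed cells, %d missing\n",
              sum(!is.na(x$rates)), sum(is.na(x$rates))))
  invisible(x)
}

#' Read a period-by-age rate table from delimited text
#'
#' Reads CSV (default) or TSV (by `.tsv`/`.txt` extension) registry tables.
#' The expected layout has one row per calendar period and one column per
#' age band (or the transpose, see `schema$orientation`). Period labels may
#' be single years (`1980`) or 5-year ranges (`"1980-84"`), which are
#' expanded to their 5 constituent years each carrying the period's rate.
#'
#' @param path file path (or connection) to the delimited table.
#' @param schema list of options: `orientation` is `"year_rows"` (years down
#'   the first column, bands across the header; default) or `"age_rows"`
#'   (the transpose); `values` is `"rate"` (default) or `"count"`; when
#'   `values = "count"`, `person_years` must give a path to an
#'   identically-laid-out table of person-years, and rates are computed as
#'   `100000 * count / person_years`.
#' @param sex,population labels attached to the result.
#' @return a validated [rate_table()].
#' @export
read_rate_table <- function(path, schema = list(), sex = "", population = "") {
  orientation <- schema$orientation %||% "year_rows"
  values <- schema$values %||% "rate"
  raw <- read_delim_auto(path)
  if (orientation == "age_rows") {
    band_labels <- as.character(raw[[1]])
    flipped <- data.frame(period = names(raw)[-1],
                          t(as.matrix(raw[-1])),
                          check.names = FALSE, stringsAsFactors = FALSE)
    names(flipped) <- c("period", band_labels)
    raw <- flipped
  } else if (orientation != "year_rows") {
    stop("schema$orientation must be 'year_rows' or 'age_rows'")
  }
  period_labels <- as.character(raw[[1]])
  bands <- parse_age_bands(names(raw)[-1])
  vals <- as.matrix(as.data.frame(lapply(raw[-1], as.numeric)))
  expanded <- expand_periods(period_labels, vals)
  if (any(expanded$values < 0, na.rm = TRUE))
    stop("negative rate in table")
  if (values == "count") {
    if (is.null(schema$person_years))
      stop("schema$person_years required when values = 'count'")
    py_raw <- read_delim_auto(schema$person_years)
    py <- expand_periods(as.character(py_raw[[1]]),
                         as.matrix(as.data.frame(lapply(py_raw[-1], as.numeric))))
    rates <- 1e5 * expanded$values / py$values
    rate_table(expanded$years, bands, rates, counts = expanded$values,
               person_years = py$values, sex = sex, population = population)
  } else {
    rate_table(expanded$years, bands, expanded$values,
               sex = sex, population = population)
  }
}

# expand period labels (single years or 5-year ranges) into single years,
# replicating each period row across its constituent years
expand_periods <- function(labels, vals) {
  labels <- trimws(gsub("–|—", "-", labels))
  years <- integer(0)
  rows <- integer(0)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (grepl("^[0-9]{4}$", lab)) {
      yrs <- as.integer(lab)
    } else if (grepl("^[0-9]{4}\\s*-\\s*[0-9]{2,4}$", lab)) {
      parts <- strsplit(lab, "\\s*-\\s*")[[1]]
      from <- as.integer(parts[1])
      to <- as.integer(parts[2])
      if (to < 100) to <- (from %/% 100) * 100 + to
      yrs <- from:to
    } else {
      stop(sprintf("unparseable period label '%s' (row %d)", labels[i], i))
    }
    years <- c(years, yrs)
    rows <- c(rows, rep(i, length(yrs)))
  }
  if (anyDuplicated(years)) stop("overlapping period labels")
  o <- order(years)
  list(years = years[o], values = vals[rows[o], , drop = FALSE])
}

#' Write a rate table to delimited text
#'
#' @param x a [rate_table()].
#' @param path output path; `.tsv`/`.txt` extension selects tab separation.
#' @param digits decimal places for rates (default 6 keeps round-trips exact
#'   at typical registry precision).
#' @export
write_rate_table <- function(x, path, digits = 6) {
  df <- data.frame(year = x$years,
                   round(x$rates, digits),
                   check.names = FALSE)
  write_delim_auto(df, path)
  invisible(path)
}

# -- small shared helpers -----------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_auto <- function(path) {
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"), comment.char = "",
                    quote = "\"")
}

write_delim_auto <- function(df, path) {
  utils::write.table(df, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, na = "")
}
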