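#' Birth-cohort specification
#'
#' Defines the grid of 5-year birth cohorts to extract from a registry
#' table, and the minimum age from which rates enter the analysis.
#'
#' @param first_start,last_start start years of the first and last cohorts
#'   (defaults 1895 and 1975, giving 17 cohorts).
#' @param step cohort width in years; 5 throughout this package.
#' @param min_age minimum age-band lower bound to include (default 25;
#'   younger bands are excluded because case counts there are too sparse
#'   for stable rates).
#' @return an object of class `cohort_spec` with an `n_cohorts` element.
#' @export
cohort_spec <- function(first_start = 1895, last_start = 1975, step = 5,
                        min_age = 25) {
  if (last_start < first_start) stop("empty cohort span")
  if ((last_start - first_start) %% step != 0)
    stop("cohort span must be a multiple of the step")
  n <- (last_start - first_start) %/% step + 1L
  structure(list(first_start = as.integer(first_start),
                 last_start = as.integer(last_start),
                 step = as.integer(step),
                 min_age = as.integer(min_age),
                 n_cohorts = as.integer(n)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("%d birth cohorts: %s to %s (step %d), ages %d+\n",
              x$n_cohorts, cohort_label(x$first_start),
              cohort_label(x$last_start), x$step, x$min_age))
  invisible(x)
}

#' Calendar years in which a cohort traverses an age band
#'
#' The Lexis-diagonal convention: the cohort starting in birth year `c`
#' occupies the band with lower bound `a` during calendar years
#' `c + a, ..., c + a + 4`. Equivalently, the registry cell (year `y`,
#' band `[a, a+4]`) belongs to the cohort containing birth year `y - a`.
#' Open-ended terminal bands use their lower bound the same way, so the
#' diagonal support at both registry boundaries matches what 5-year-band
#' registries actually report.
#'
#' @param cohort_start cohort start year.
#' @param band a one-row slice of an age-band `data.frame`, or a numeric
#'   band lower bound.
#' @return integer vector of 5 calendar years.
#' @examples
#' assign_years(1895, 80)  # 1975:1979
#' @export
assign_years <- function(cohort_start, band) {
  lower <- if (is.data.frame(band)) band$lower[1] else as.integer(band)
  as.integer(cohort_start + lower + 0:4)
}

#' Age bands fully observable for a cohort within a registry's year range
#'
#' Predicts the staircase support pattern of a cohort-by-age table: a band
#' is observable for a cohort only if all 5 assigned calendar years fall
#' inside the registry's range and the band is at or above the spec's
#' minimum age.
#'
#' @param table_years integer vector (or range) of registry years.
#' @param cohort_start cohort start year.
#' @param spec a [cohort_spec()].
#' @param bands age-band `data.frame`; defaults to 25-29 ... 85+.
#' @return the subset of `bands` observable for this cohort (possibly
#'   zero rows).
#' @examples
#' sp <- cohort_spec()
#' observable_bands(1975:2014, 1895, sp)$label  # "80-84" "85+"
#' @export
observable_bands <- function(table_years, cohort_start, spec,
                             bands = age_bands(seq(25, 85, 5))) {
  lo <- min(table_years)
  hi <- max(table_years)
  keep <- vapply(seq_len(nrow(bands)), function(i) {
    yrs <- assign_years(cohort_start, bands$lower[i])
    bands$lower[i] >= spec$min_age && min(yrs) >= lo && max(yrs) <= hi
  }, logical(1))
  bands[keep, , drop = FALSE]
}

#' Extract 5-year birth cohorts from a period-by-age rate table
#'
#' Walks each cohort's Lexis diagonal through the registry table and
#' averages the rates over the 5 calendar years assigned to each
#' (cohort, band) cell. Cells below the minimum age, or with fewer than
#' `ceiling(min_coverage * 5)` of their assigned years observed, are
#' missing.
#'
#' @param table a [rate_table()].
#' @param spec a [cohort_spec()].
#' @param min_coverage fraction of the 5 assigned years that must be
#'   present (default 1: complete diagonals only; lower it for registries
#'   whose first or last year truncates a diagonal).
#' @return a [cohort_table()].
#' @export
build_cohort_table <- function(table, spec, min_coverage = 1) {
  stopifnot(inherits(table, "rate_table"), inherits(spec, "cohort_spec"))
  if (min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must be in (0, 1]")
  starts <- seq(spec$first_start, spec$last_start, by = spec$step)
  need <- ceiling(min_coverage * 5)
  bands <- table$bands
  out <- matrix(NA_real_, length(starts), nrow(bands))
  for (ci in seq_along(starts)) {
    for (bi in seq_len(nrow(bands))) {
      if (bands$lower[bi] < spec$min_age) next
      yrs <- assign_years(starts[ci], bands$lower[bi])
      rows <- match(yrs, table$years)
      vals <- table$rates[rows[!is.na(rows)], bi]
      vals <- vals[!is.na(vals)]
      if (length(vals) >= need) out[ci, bi] <- mean(vals)
    }
  }
  cohort_table(starts, bands, out)
}
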