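#' Cohort-by-age tables of 5-year-averaged incidence
#'
#' The intermediate product of the pipeline: rates averaged over the 5
#' calendar years in which each 5-year birth cohort traverses each age band
#' (a Lexis diagonal), one row per cohort, one column per age band. Missing
#' cells (`NA`) mark band/cohort combinations outside the registry's year
#' range or below the minimum age; they are distinct from observed zero
#' rates.
#'
#' @param cohort_starts integer vector of cohort start years, ascending in
#'   steps of 5 (a cohort labelled 1895 is the 1895-99 birth cohort).
#' @param bands age-band `data.frame` from [age_bands()].
#' @param rates numeric matrix, cohorts by bands, `NA` for missing.
#' @return an object of class `cohort_table`.
#' @export
cohort_table <- function(cohort_starts, bands, rates) {
  cohort_starts <- as.integer(cohort_starts)
  if (length(cohort_starts) == 0L) stop("no cohorts")
  if (length(cohort_starts) > 1L && any(diff(cohort_starts) != 5L))
    stop("cohort start years must ascend in 5-year steps")
  rates <- as.matrix(rates)
  if (nrow(rates) != length(cohort_starts) || ncol(rates) != nrow(bands))
    stop("rate matrix shape does not match cohorts x bands")
  if (any(rates < 0, na.rm = TRUE)) stop("negative rate in cohort table")
  dimnames(rates) <- list(cohort_label(cohort_starts), bands$label)
  structure(list(cohort_starts = cohort_starts, bands = bands,
                 rates = rates),
            class = "cohort_table")
}

cohort_label <- function(start) {
  sprintf("%d-%02d", start, (start + 4L) %% 100L)
}

parse_cohort_starts <- function(labels) {
  labels <- trimws(gsub("–|—", "-", as.character(labels)))
  start <- suppressWarnings(as.integer(sub("^([0-9]{4}).*$", "\\1", labels)))
  if (anyNA(start))
    stop(sprintf("unparseable cohort label '%s'", labels[which(is.na(start))[1]]))
  start
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort x age table: %d cohorts (%s to %s), %d age bands, %d observed cells\n",
              length(x$cohort_starts),
              rownames(x$rates)[1], rownames(x$rates)[nrow(x$rates)],
              nrow(x$bands), sum(!is.na(x$rates))))
  invisible(x)
}

#' Read a cohort-by-age table from delimited text
#'
#' Expects the layout of the packaged British-male melanoma fixture: one
#' row per age band, a first column of band labels, and one column per
#' 5-year birth cohort headed by its range label (`"1895-99"`, en-dash
#' accepted). Blank cells are missing.
#'
#' @param path file path; `.tsv`/`.txt` selects tab separation.
#' @return a [cohort_table()].
#' @export
read_cohort_table <- function(path) {
  raw <- read_delim_auto(path)
  if (ncol(raw) < 2L) stop("no cohorts in cohort table")
  bands <- parse_age_bands(raw[[1]])
  starts <- parse_cohort_starts(names(raw)[-1])
  rates <- t(as.matrix(as.data.frame(lapply(raw[-1], as.numeric))))
  cohort_table(starts, bands, rates)
}

#' Write a cohort-by-age table to delimited text
#'
#' Inverse of [read_cohort_table()]; round-trips exactly at the declared
#' decimal precision.
#'
#' @param x a [cohort_table()].
#' @param path output path.
#' @param digits decimal places (default 1, the precision of registry
#'   summary tables).
#' @export
write_cohort_table <- function(x, path, digits = 1) {
  df <- data.frame(age_band = x$bands$label,
                   t(round(x$rates, digits)),
                   check.names = FALSE)
  names(df) <- c("age_band", rownames(x$rates))
  write_delim_auto(df, path)
  invisible(path)
}

#' Age-specific melanoma incidence for British males, by birth cohort
#'
#' The packaged fixture: malignant melanoma incidence per 100,000
#' person-years in British males, averaged over 5-year intervals along
#' Lexis diagonals, for the 17 birth cohorts 1895-99 through 1975-79 and
#' age bands 25-29 through 85+ (registry years 1975-2014). Within each
#' cohort the observed rate rises monotonically with age.
#'
#' @return a [cohort_table()] with 17 cohorts and 13 age bands.
#' @examples
#' gb <- gb_melanoma_males()
#' fit <- accel_fit(gb)
#' summary(fit)
#' @export
gb_melanoma_males <- function() {
  read_cohort_table(system.file("extdata", "table1_gb_males.csv",
                                package = "cohortaccel", mustWork = TRUE))
}
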