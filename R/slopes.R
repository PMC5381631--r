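#' Log-log age-incidence slope (acceleration)
#'
#' Ordinary least-squares slope of log incidence on log age — the
#' acceleration of cancer with age. Under a simple multistage model with k
#' rate-limiting steps the incidence rate is proportional to age^(k-1), so
#' this slope estimates k - 1. The slope is invariant to the log base (both
#' axes are transformed identically) and to any rescaling of the rates.
#'
#' Bands with zero, negative or missing rates are excluded (their log is
#' undefined) with a warning; if fewer than 2 usable points remain the
#' slope is `NA`.
#'
#' @param bands age-band `data.frame` (its `rep_age` column supplies the
#'   regression abscissae) or a numeric vector of ages.
#' @param rates numeric vector of incidence rates, same length.
#' @return a list of class `loglog_slope` with elements `slope`,
#'   `intercept` (natural-log scale), `n_points`, `ages_used` and
#'   `rates_used`.
#' @examples
#' loglog_slope(c(27.5, 32.5, 37.5), c(4.7, 7.4, 10.1))$slope  # ~ 2.47
#' @export
loglog_slope <- function(bands, rates) {
  ages <- if (is.data.frame(bands)) bands$rep_age else as.numeric(bands)
  if (length(ages) != length(rates))
    stop("ages and rates must have equal length")
  bad <- is.na(rates) | rates <= 0 | is.na(ages)
  if (any(bad & !is.na(rates) & rates <= 0))
    warning(sprintf("%d non-positive rate(s) excluded from slope fit",
                    sum(rates <= 0, na.rm = TRUE)))
  ages <- ages[!bad]
  rates <- rates[!bad]
  n <- length(ages)
  if (n < 2L || length(unique(ages)) < 2L) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          n_points = n, ages_used = ages,
                          rates_used = rates),
                     class = "loglog_slope"))
  }
  x <- log(ages)
  y <- log(rates)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  structure(list(slope = b, intercept = a, n_points = n,
                 ages_used = ages, rates_used = rates),
            class = "loglog_slope")
}

#' @export
print.loglog_slope <- function(x, ...) {
  cat(sprintf("log-log age-incidence slope: %.3f (%d points)\n",
              x$slope, x$n_points))
  invisible(x)
}

#' Age bands usable by both of two cohorts
#'
#' The common-age restriction: when two cohorts' slopes are compared, both
#' regressions are fit only over the age bands observed (non-missing,
#' positive rate) in both cohorts, so the ratio is not confounded by their
#' differing age support.
#'
#' @param table a [cohort_table()].
#' @param a,b cohort start years present in `table`.
#' @return the subset of `table$bands` usable by both cohorts.
#' @export
common_bands <- function(table, a, b) {
  ia <- match(as.integer(a), table$cohort_starts)
  ib <- match(as.integer(b), table$cohort_starts)
  if (is.na(ia) || is.na(ib)) stop("cohort not present in table")
  usable <- function(i) !is.na(table$rates[i, ]) & table$rates[i, ] > 0
  table$bands[usable(ia) & usable(ib), , drop = FALSE]
}

#' Adjacent-cohort log2 slope ratio
#'
#' Fits the log-log slope to a cohort and to the adjacent older cohort,
#' each restricted to their common age bands, and returns the log2 of the
#' recent:prior slope ratio. A negative value means the more recent cohort's
#' incidence rises less steeply with age. The ratio is missing (`NA`) when
#' fewer than 2 common bands exist or either slope is non-positive.
#'
#' @param table a [cohort_table()].
#' @param recent start year of the more recent cohort; the prior cohort is
#'   `recent - 5` and must be present.
#' @return a list of class `pair_ratio`: `recent`, `prior`,
#'   `common_bands`, `slope_recent`, `slope_prior`, `log2_ratio`.
#' @export
pair_ratio <- function(table, recent) {
  recent <- as.integer(recent)
  prior <- recent - 5L
  if (!(prior %in% table$cohort_starts))
    stop(sprintf("prior cohort %d absent from table", prior))
  if (!(recent %in% table$cohort_starts))
    stop(sprintf("cohort %d absent from table", recent))
  cb <- common_bands(table, recent, prior)
  res <- structure(list(recent = recent, prior = prior, common_bands = cb,
                        slope_recent = NA_real_, slope_prior = NA_real_,
                        log2_ratio = NA_real_),
                   class = "pair_ratio")
  if (nrow(cb) < 2L) return(res)
  bi <- band_index(table$bands, cb$lower)
  s_new <- loglog_slope(cb, table$rates[match(recent, table$cohort_starts), bi])
  s_old <- loglog_slope(cb, table$rates[match(prior, table$cohort_starts), bi])
  res$slope_recent <- s_new$slope
  res$slope_prior <- s_old$slope
  if (!is.na(s_new$slope) && !is.na(s_old$slope) &&
      s_new$slope > 0 && s_old$slope > 0)
    res$log2_ratio <- log2(s_new$slope / s_old$slope)
  res
}

#' @export
print.pair_ratio <- function(x, ...) {
  cat(sprintf("%s vs %s over %d common bands: log2 slope ratio %s\n",
              cohort_label(x$recent), cohort_label(x$prior),
              nrow(x$common_bands),
              ifelse(is.na(x$log2_ratio), "NA",
                     sprintf("%.2f", x$log2_ratio))))
  invisible(x)
}

#' Summarise adjacent-cohort log2 slope ratios
#'
#' The mean of the non-missing log2 ratios (i.e. the log2 of the geometric
#' mean of the slope ratios, capturing the multiplicative tendency of the
#' slope to change over cohorts), its standard error (sample standard
#' deviation with n-1 denominator over sqrt(n)), and the mean:SE ratio —
#' how many standard errors the trend departs from zero.
#'
#' @param ratios a numeric vector of log2 ratios (`NA` for missing pairs),
#'   a list of [pair_ratio()] objects, or a data.frame with a `log2_ratio`
#'   column. Names or `recent` entries label the pairs.
#' @return a list of class `accel_summary`: `ratios` (named numeric,
#'   missing kept as `NA`), `mean`, `se`, `z`, `n`.
#' @export
summarize_ratios <- function(ratios) {
  if (is.data.frame(ratios)) {
    r <- ratios$log2_ratio
    names(r) <- if (!is.null(ratios$recent)) cohort_label(ratios$recent)
  } else if (is.list(ratios) && !is.null(ratios[[1]]$log2_ratio)) {
    r <- vapply(ratios, function(p) p$log2_ratio, numeric(1))
    names(r) <- vapply(ratios, function(p) cohort_label(p$recent),
                       character(1))
  } else {
    r <- as.numeric(ratios)
    names(r) <- names(ratios)
  }
  ok <- r[!is.na(r)]
  if (length(ok) < 2L) stop("nothing to summarize: fewer than 2 usable ratios")
  m <- mean(ok)
  se <- stats::sd(ok) / sqrt(length(ok))
  if (se == 0) stop("zero standard error: all ratios identical")
  structure(list(ratios = r, mean = m, se = se, z = m / se,
                 n = length(ok)),
            class = "accel_summary")
}

#' @export
print.accel_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Adjacent-cohort log2 slope ratios (n = %d):\n", x$n))
  print(round(x$ratios, digits))
  cat(sprintf("Mean %.*f  SE %.*f  Ratio mean:SE %.*f\n",
              digits, x$mean, digits, x$se, digits, x$z))
  invisible(x)
}

#' Pointwise age-specific acceleration along a cohort
#'
#' Finite-difference acceleration curve: for each pair of consecutive
#' usable (positive-rate) bands, the difference quotient of log rate over
#' log representative age, attached to the geometric-mean age of the pair.
#' For rates following an exact power law age^m every point equals m.
#'
#' @param bands age-band `data.frame` or numeric ages.
#' @param rates numeric vector of rates.
#' @param cohort_start optional cohort label carried in the result.
#' @return a `data.frame` of class `accel_curve` with columns `age` and
#'   `acceleration`, plus a `cohort_start` attribute.
#' @export
pointwise_acceleration <- function(bands, rates, cohort_start = NA) {
  ages <- if (is.data.frame(bands)) bands$rep_age else as.numeric(bands)
  keep <- !is.na(rates) & rates > 0 & !is.na(ages)
  ages <- ages[keep]
  rates <- rates[keep]
  if (length(ages) < 2L)
    stop("need at least 2 usable positive-rate points")
  i <- seq_len(length(ages) - 1L)
  acc <- diff(log(rates)) / diff(log(ages))
  out <- data.frame(age = sqrt(ages[i] * ages[i + 1L]),
                    acceleration = acc)
  attr(out, "cohort_start") <- cohort_start
  class(out) <- c("accel_curve", "data.frame")
  out
}
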