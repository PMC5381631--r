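#' Fit the birth-cohort acceleration model
#'
#' The package's central fitting function. Given a cohort-by-age table of
#' incidence rates (or a registry period-by-age table, which is first
#' collapsed to cohorts along Lexis diagonals), it
#' \enumerate{
#'   \item fits, per cohort, the ordinary least-squares slope of log
#'     incidence on log representative age over all of that cohort's usable
#'     bands (the cohort's acceleration);
#'   \item for each adjacent cohort pair, refits both slopes restricted to
#'     the bands the two cohorts share, and takes the log2 of the
#'     recent:prior slope ratio;
#'   \item summarises the non-missing log2 ratios by their mean, standard
#'     error and mean:SE ratio.
#' }
#' A negative mean says that, on geometric average, incidence has been
#' rising less steeply with age in more recent cohorts even as its overall
#' level rises — the signature, in multistage terms, of fewer effective
#' rate-limiting steps.
#'
#' @param x a [cohort_table()] or a [rate_table()].
#' @param spec a [cohort_spec()]; used (with `min_coverage`) only when `x`
#'   is a rate table.
#' @param min_coverage passed to [build_cohort_table()].
#' @return an object of class `accel_fit` with components `table` (the
#'   cohort table analysed), `slopes` (per-cohort data.frame: `cohort`,
#'   `slope`, `intercept`, `n_points`), `pairs` (per-pair data.frame:
#'   `recent`, `prior`, `n_common`, `slope_recent`, `slope_prior`,
#'   `log2_ratio`), `summary` (an `accel_summary`, or `NULL` if fewer than
#'   2 usable pairs) and `call`.
#' @seealso [summary.accel_fit()], [plot.accel_fit()], [pair_ratio()]
#' @examples
#' fit <- accel_fit(gb_melanoma_males())
#' coef(fit)                 # the 16 log2 slope ratios
#' coef(fit, "slopes")       # per-cohort accelerations
#' summary(fit)
#' @export
accel_fit <- function(x, spec = cohort_spec(), min_coverage = 1) {
  cl <- match.call()
  if (inherits(x, "rate_table"))
    x <- build_cohort_table(x, spec, min_coverage)
  stopifnot(inherits(x, "cohort_table"))
  starts <- x$cohort_starts

  fits <- lapply(seq_along(starts), function(i)
    suppressWarnings(loglog_slope(x$bands, x$rates[i, ])))
  slopes <- data.frame(
    cohort = starts,
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
    n_points = vapply(fits, `[[`, integer(1), "n_points"))
  rownames(slopes) <- cohort_label(starts)

  pair_list <- if (length(starts) >= 2L)
    lapply(starts[-1], function(rc) pair_ratio(x, rc)) else list()
  pairs <- data.frame(
    recent = vapply(pair_list, `[[`, integer(1), "recent"),
    prior = vapply(pair_list, `[[`, integer(1), "prior"),
    n_common = vapply(pair_list, function(p) nrow(p$common_bands),
                      integer(1)),
    slope_recent = vapply(pair_list, `[[`, numeric(1), "slope_recent"),
    slope_prior = vapply(pair_list, `[[`, numeric(1), "slope_prior"),
    log2_ratio = vapply(pair_list, `[[`, numeric(1), "log2_ratio"))
  if (nrow(pairs)) rownames(pairs) <- cohort_label(pairs$recent)

  smry <- if (sum(!is.na(pairs$log2_ratio)) >= 2L)
    tryCatch(summarize_ratios(pairs), error = function(e) NULL) else NULL

  structure(list(table = x, slopes = slopes, pairs = pairs,
                 summary = smry, fits = fits, call = cl),
            class = "accel_fit")
}

#' @export
print.accel_fit <- function(x, digits = 2, ...) {
  cat("Birth-cohort acceleration fit\n")
  cat(sprintf("  %d cohorts (%s to %s), %d adjacent pairs (%d usable)\n",
              nrow(x$slopes), rownames(x$slopes)[1],
              rownames(x$slopes)[nrow(x$slopes)], nrow(x$pairs),
              sum(!is.na(x$pairs$log2_ratio))))
  if (!is.null(x$summary))
    cat(sprintf("  mean log2 slope ratio %.*f (SE %.*f, mean:SE %.*f)\n",
                digits, x$summary$mean, digits, x$summary$se,
                digits, x$summary$z))
  invisible(x)
}

#' Summarise a birth-cohort acceleration fit
#'
#' @param object an [accel_fit()] object.
#' @param digits decimal places for printing (default 2).
#' @param ... unused.
#' @return an object of class `summary.accel_fit` wrapping the per-cohort
#'   slopes, per-pair log2 ratios and the mean/SE/mean:SE summary.
#' @export
summary.accel_fit <- function(object, digits = 2, ...) {
  structure(list(slopes = object$slopes, pairs = object$pairs,
                 summary = object$summary, digits = digits),
            class = "summary.accel_fit")
}

#' @export
print.summary.accel_fit <- function(x, ...) {
  d <- x$digits
  cat("Per-cohort log-log age-incidence slopes (accelerations):\n")
  print(data.frame(slope = round(x$slopes$slope, d),
                   n = x$slopes$n_points,
                   row.names = rownames(x$slopes)))
  cat("\nAdjacent-cohort log2 slope ratios (common ages only):\n")
  print(round(stats::setNames(x$pairs$log2_ratio, rownames(x$pairs)), d))
  if (!is.null(x$summary))
    cat(sprintf("\nMean %.*f  SE %.*f  Ratio mean:SE %.*f  (n = %d)\n",
                d, x$summary$mean, d, x$summary$se, d, x$summary$z,
                x$summary$n))
  invisible(x)
}

#' Coefficients of an acceleration fit
#'
#' @param object an [accel_fit()] object.
#' @param type `"ratios"` (default) for the adjacent-cohort log2 slope
#'   ratios, named by the recent cohort; `"slopes"` for the per-cohort
#'   accelerations.
#' @param ... unused.
#' @export
coef.accel_fit <- function(object, type = c("ratios", "slopes"), ...) {
  type <- match.arg(type)
  if (type == "ratios")
    stats::setNames(object$pairs$log2_ratio, rownames(object$pairs))
  else
    stats::setNames(object$slopes$slope, rownames(object$slopes))
}

#' Residuals of the per-cohort log-log fits
#'
#' @param object an [accel_fit()] object.
#' @param ... unused.
#' @return long-format data.frame: `cohort`, `age`, `rate`,
#'   `log_residual` (observed minus fitted log rate, natural log).
#' @export
residuals.accel_fit <- function(object, ...) {
  rows <- lapply(seq_along(object$fits), function(i) {
    f <- object$fits[[i]]
    if (is.na(f$slope)) return(NULL)
    data.frame(cohort = object$slopes$cohort[i],
               age = f$ages_used, rate = f$rates_used,
               log_residual = log(f$rates_used) -
                 (f$intercept + f$slope * log(f$ages_used)))
  })
  do.call(rbind, rows)
}

#' Predicted incidence from the per-cohort power-law fits
#'
#' @param object an [accel_fit()] object.
#' @param newdata data.frame with columns `cohort` (start year) and `age`
#'   (years); defaults to the observed design points.
#' @param ... unused.
#' @return `newdata` with a `rate` column of predicted incidence per
#'   100,000 person-years.
#' @export
predict.accel_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    r <- residuals.accel_fit(object)
    newdata <- r[c("cohort", "age")]
  }
  i <- match(newdata$cohort, object$slopes$cohort)
  if (anyNA(i)) stop("cohort not in fit")
  newdata$rate <- exp(object$slopes$intercept[i] +
                        object$slopes$slope[i] * log(newdata$age))
  newdata
}

#' Pointwise acceleration curves for every cohort in a fit
#'
#' @param object an [accel_fit()] object (or a [cohort_table()]).
#' @return a list of `accel_curve` data.frames (cohorts with fewer than 2
#'   usable points are dropped).
#' @export
accel_curves <- function(object) {
  tab <- if (inherits(object, "accel_fit")) object$table else object
  stopifnot(inherits(tab, "cohort_table"))
  out <- list()
  for (i in seq_along(tab$cohort_starts)) {
    usable <- !is.na(tab$rates[i, ]) & tab$rates[i, ] > 0
    if (sum(usable) < 2L) next
    out[[cohort_label(tab$cohort_starts[i])]] <-
      pointwise_acceleration(tab$bands, tab$rates[i, ],
                             cohort_start = tab$cohort_starts[i])
  }
  out
}

#' Plot an acceleration fit
#'
#' `which = 1` draws the per-cohort age-incidence curves on log-log axes
#' (straight lines indicate power-law behaviour; rising level with later
#' cohorts indicates increasing incidence). `which = 2` draws the
#' pointwise acceleration curves (log age axis, linear acceleration axis);
#' later cohorts lying lower indicates declining acceleration.
#'
#' @param x an [accel_fit()] object.
#' @param which 1 (incidence), 2 (acceleration), or 1:2.
#' @param thin if `TRUE`, show only decadal cohorts to reduce overplotting.
#' @param ... passed to the underlying plot functions.
#' @export
plot.accel_fit <- function(x, which = 1:2, thin = FALSE, ...) {
  if (1 %in% which) plot_incidence(x$table, thin = thin, ...)
  if (2 %in% which) plot_acceleration(accel_curves(x), thin = thin, ...)
  invisible(x)
}
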