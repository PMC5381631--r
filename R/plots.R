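#' Log-log age-incidence plot
#'
#' One line per cohort on double-logarithmic axes: power-law age-incidence
#' curves appear straight, their slope being the cohort's acceleration,
#' and a rise in level over successive cohorts reflects rising incidence.
#'
#' @param table a [cohort_table()].
#' @param thin if `TRUE`, draw only decadal cohorts (start years divisible
#'   by 10) to reduce overplotting.
#' @param main title.
#' @param legend draw a cohort legend (default `TRUE`).
#' @param ... further [graphics::matplot()] arguments.
#' @return invisibly, the long-format data.frame of plotted points
#'   (`cohort`, `age`, `rate`).
#' @export
plot_incidence <- function(table, thin = FALSE, main = "Age-specific incidence by birth cohort",
                           legend = TRUE, ...) {
  stopifnot(inherits(table, "cohort_table"))
  keep <- if (thin)
    (table$cohort_starts - table$cohort_starts[1]) %% 10L == 0L
  else rep(TRUE, length(table$cohort_starts))
  m <- table$rates[keep, , drop = FALSE]
  if (!any(!is.na(m) & m > 0)) stop("empty cohort table: nothing to plot")
  cols <- grDevices::hcl.colors(nrow(m), "Zissou 1")
  graphics::matplot(table$bands$rep_age, t(m), type = "b", pch = 16,
                    log = "xy", col = cols, lty = 1,
                    xlab = "Age (years)",
                    ylab = "Incidence per 100,000 person-years",
                    main = main, ...)
  if (legend)
    graphics::legend("topleft", legend = rownames(m), col = cols, lty = 1,
                     cex = 0.6, bty = "n", ncol = 2)
  long <- data.frame(
    cohort = rep(table$cohort_starts[keep], times = ncol(m)),
    age = rep(table$bands$rep_age, each = nrow(m)),
    rate = as.vector(m))
  invisible(long[!is.na(long$rate), ])
}

#' Age-specific acceleration plot
#'
#' Pointwise acceleration curves (finite differences of log incidence over
#' log age) on a log age axis with a linear acceleration axis. Under a
#' pure power law each curve is flat at k - 1; curves of later cohorts
#' lying lower indicate declining acceleration.
#'
#' @param curves a list of `accel_curve` data.frames, as returned by
#'   [accel_curves()].
#' @param thin if `TRUE`, draw only decadal cohorts.
#' @param main title.
#' @param legend draw a cohort legend (default `TRUE`).
#' @param ... further [graphics::plot()] arguments.
#' @return invisibly, the long-format data.frame of plotted points
#'   (`cohort`, `age`, `acceleration`).
#' @export
plot_acceleration <- function(curves, thin = FALSE,
                              main = "Age-specific acceleration by birth cohort",
                              legend = TRUE, ...) {
  if (length(curves) == 0L) stop("no acceleration curves to plot")
  starts <- vapply(curves, function(cv) as.integer(attr(cv, "cohort_start")),
                   integer(1))
  if (thin) curves <- curves[(starts - min(starts)) %% 10L == 0L]
  if (length(curves) == 0L) stop("no acceleration curves to plot")
  xr <- range(unlist(lapply(curves, `[[`, "age")))
  yr <- range(unlist(lapply(curves, `[[`, "acceleration")))
  cols <- grDevices::hcl.colors(length(curves), "Zissou 1")
  graphics::plot(NA, xlim = xr, ylim = yr, log = "x",
                 xlab = "Age (years)", ylab = "Acceleration (d log incidence / d log age)",
                 main = main, ...)
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$age, curves[[i]]$acceleration,
                    col = cols[i], type = "b", pch = 16)
  if (legend)
    graphics::legend("topright", legend = names(curves), col = cols,
                     lty = 1, cex = 0.6, bty = "n", ncol = 2)
  long <- do.call(rbind, lapply(curves, function(cv)
    data.frame(cohort = attr(cv, "cohort_start"), age = cv$age,
               acceleration = cv$acceleration)))
  rownames(long) <- NULL
  invisible(long)
}
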