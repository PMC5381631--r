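# Shared fixture builders and independent oracles.

std_bands <- function() age_bands(seq(25, 85, 5))

# cohort table whose rates follow an exact power law c_scale * age^m,
# fully observed
power_law_cohort_table <- function(cohorts = seq(1895, 1975, 5),
                                   m = 4, c_scale = 1e-4,
                                   bands = std_bands()) {
  rates <- outer(rep(1, length(cohorts)), c_scale * bands$rep_age^m)
  cohort_table(cohorts, bands, rates)
}

# registry table (years x bands) whose diagonals embed a given cohort
# table: cell (y, band a) carries the cohort value of the cohort
# containing y - a, or NA where that cohort cell is missing/out of span
embed_diagonals <- function(ctab, years = 1975:2014) {
  bands <- ctab$bands
  first <- ctab$cohort_starts[1]
  last <- ctab$cohort_starts[length(ctab$cohort_starts)]
  rates <- matrix(NA_real_, length(years), nrow(bands))
  for (yi in seq_along(years)) {
    for (bi in seq_len(nrow(bands))) {
      birth <- years[yi] - bands$lower[bi]
      cstart <- first + 5 * ((birth - first) %/% 5)
      if (cstart < first || cstart > last) next
      rates[yi, bi] <- ctab$rates[match(cstart, ctab$cohort_starts), bi]
    }
  }
  rate_table(years, bands, rates)
}

# brute-force least-squares oracle for the log-log slope: profile out the
# intercept and minimise the residual sum of squares over a slope grid,
# refined geometrically to ~1e-9
grid_slope_oracle <- function(ages, rates, lo = -60, hi = 60) {
  x <- log(ages)
  y <- log(rates)
  sse <- function(b) {
    a <- mean(y) - b * mean(x)
    sum((y - a - b * x)^2)
  }
  for (iter in 1:12) {
    bs <- seq(lo, hi, length.out = 401)
    vals <- vapply(bs, sse, numeric(1))
    best <- bs[which.min(vals)]
    step <- bs[2] - bs[1]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  best
}

# the 16 printed GB-male log2 slope ratios of the published summary row
printed_gb_ratios <- c(
  `1900-04` = 0.03, `1905-09` = 0.01, `1910-14` = -0.07, `1915-19` = -0.03,
  `1920-24` = -0.04, `1925-29` = -0.05, `1930-34` = -0.02, `1935-39` = -0.02,
  `1940-44` = -0.07, `1945-49` = -0.06, `1950-54` = -0.07, `1955-59` = -0.09,
  `1960-64` = -0.12, `1965-69` = -0.02, `1970-74` = -0.20, `1975-79` = -0.28)
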