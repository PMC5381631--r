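#' Parameters of the multistage registry simulator
#'
#' A minimal multistage-carcinogenesis generative model for registry-style
#' incidence tables. Each birth cohort c has a power-law hazard
#' `I(age) = A[c] * age^(k[c] - 1)` (per 100,000 person-years), the
#' straight-line-in-log-log form of a multistage process with `k[c]`
#' rate-limiting steps; a calendar-year multiplier `period_mult[y]` models
#' period effects such as diagnostic intensity. Observed counts are Poisson
#' at the stated person-years, so the noise-free acceleration of cohort c
#' is exactly `k[c] - 1` at every age.
#'
#' `k` and `A` may be given per cohort, or at anchor cohorts as
#' `list(anchors = <birth years>, values = <values>)` and linearly
#' interpolated across the cohort grid (constant beyond the anchors) —
#' four numbers suffice to script a rising-incidence, falling-acceleration
#' scenario.
#'
#' @param cohort_starts cohort grid (default 17 cohorts 1895-1975).
#' @param years registry calendar years (default 1975-2014).
#' @param bands age-band `data.frame` (default 25-29 ... 85+).
#' @param k number of rate-limiting steps per cohort (>= 2); vector over
#'   cohorts, scalar, or anchor list.
#' @param A baseline hazard scale per cohort (incidence per 100,000
#'   person-years at age 1); vector, scalar, or anchor list.
#' @param period_mult calendar-year multiplier: scalar, vector over
#'   `years`, or anchor list over years.
#' @param person_years person-years per (year, band) cell: scalar or
#'   matrix.
#' @return an object of class `multistage_params`.
#' @seealso [simulate.multistage_params()], [ground_truth_summary()]
#' @export
multistage_params <- function(cohort_starts = seq(1895, 1975, by = 5),
                              years = 1975:2014,
                              bands = age_bands(seq(25, 85, 5)),
                              k = 6, A = 1e-6, period_mult = 1,
                              person_years = 3e6) {
  cohort_starts <- as.integer(cohort_starts)
  years <- as.integer(years)
  kv <- resolve_profile(k, cohort_starts, "k")
  Av <- resolve_profile(A, cohort_starts, "A")
  pm <- resolve_profile(period_mult, years, "period_mult")
  if (any(kv < 2)) stop("k must be >= 2 for every cohort")
  if (any(Av < 0)) stop("A must be non-negative")
  if (any(pm < 0)) stop("period_mult must be non-negative")
  py <- person_years
  if (length(py) == 1L)
    py <- matrix(py, length(years), nrow(bands))
  py <- as.matrix(py)
  if (any(py <= 0)) stop("person_years must be positive")
  if (!all(dim(py) == c(length(years), nrow(bands))))
    stop("person_years shape does not match years x bands")
  structure(list(cohort_starts = cohort_starts, years = years,
                 bands = bands, k = stats::setNames(kv, cohort_starts),
                 A = stats::setNames(Av, cohort_starts),
                 period_mult = stats::setNames(pm, years),
                 person_years = py),
            class = "multistage_params")
}

# scalar -> constant; anchor list -> linear interpolation (flat beyond
# anchors); full vector -> checked length
resolve_profile <- function(x, grid, what) {
  if (is.list(x)) {
    if (length(x$anchors) != length(x$values) || length(x$anchors) < 1L)
      stop(sprintf("%s anchors/values mismatch", what))
    if (length(x$anchors) == 1L) return(rep(x$values, length(grid)))
    return(stats::approx(x$anchors, x$values, xout = grid, rule = 2)$y)
  }
  if (length(x) == 1L) return(rep(as.numeric(x), length(grid)))
  if (length(x) != length(grid))
    stop(sprintf("%s must be scalar, anchor list, or length %d", what,
                 length(grid)))
  as.numeric(x)
}

#' @export
print.multistage_params <- function(x, ...) {
  cat(sprintf("Multistage registry simulator: %d cohorts, years %d-%d, %d bands\n",
              length(x$cohort_starts), min(x$years), max(x$years),
              nrow(x$bands)))
  cat(sprintf("  k in [%.2f, %.2f]; A in [%.3g, %.3g]; person-years %.3g-%.3g per cell\n",
              min(x$k), max(x$k), min(x$A), max(x$A),
              min(x$person_years), max(x$person_years)))
  invisible(x)
}

# interpolate a per-cohort profile at arbitrary birth years (flat outside
# the cohort grid), so off-grid diagonals at the registry corners are
# still well defined
profile_at <- function(values, grid, birth_year) {
  if (length(grid) == 1L) return(rep(values, length(birth_year)))
  stats::approx(grid, values, xout = birth_year, rule = 2)$y
}

#' Expected incidence rate under the multistage model
#'
#' `period_mult[year] * A[cohort] * age^(k[cohort] - 1)`, with `k` and `A`
#' interpolated at the given birth year.
#'
#' @param age age in years (> 0).
#' @param cohort_start birth year of the cohort.
#' @param year calendar year (for the period multiplier; years outside the
#'   simulated range take multiplier 1).
#' @param params a [multistage_params()].
#' @return expected incidence per 100,000 person-years.
#' @examples
#' p <- multistage_params(k = 6, A = 1e-6)
#' expected_rate(60, 1940, 2000, p)  # 1e-6 * 60^5 = 777.6
#' @export
expected_rate <- function(age, cohort_start, year, params) {
  if (any(age <= 0)) stop("age must be positive")
  kk <- profile_at(params$k, params$cohort_starts, cohort_start)
  aa <- profile_at(params$A, params$cohort_starts, cohort_start)
  pm <- params$period_mult[as.character(year)]
  pm[is.na(pm)] <- 1
  unname(pm * aa * age^(kk - 1))
}

#' Simulate a registry rate table from the multistage model
#'
#' For every (calendar year, age band) cell, the cell's cohort is the one
#' containing `year - band lower` (the same Lexis-diagonal convention the
#' estimator uses); the expected rate is evaluated at the band's
#' representative age; the observed count is Poisson with mean
#' `expected_rate * person_years / 100000`; and the emitted rate is
#' `100000 * count / person_years`. The result is reproducible under a
#' fixed seed and leaves the global random-number state untouched.
#'
#' @param params a [multistage_params()].
#' @param seed integer seed; `NULL` draws from the current RNG state.
#' @return a [rate_table()] carrying `counts` and `person_years`.
#' @export
simulate_registry <- function(params, seed = NULL) {
  stopifnot(inherits(params, "multistage_params"))
  ny <- length(params$years)
  nb <- nrow(params$bands)
  lam <- matrix(0, ny, nb)
  first <- params$cohort_starts[1]
  last <- params$cohort_starts[length(params$cohort_starts)]
  for (bi in seq_len(nb)) {
    # snap each cell's birth year to the start of its 5-year cohort, so a
    # whole diagonal shares one (k, A) and the noise-free acceleration of
    # cohort c is exactly k[c] - 1; off-grid diagonals clamp to the ends
    birth <- params$years - params$bands$lower[bi]
    cstart <- pmin(pmax(first + 5L * ((birth - first) %/% 5L), first), last)
    mu <- expected_rate(params$bands$rep_age[bi], cstart, params$years,
                        params)
    lam[, bi] <- mu * params$person_years[, bi] / 1e5
  }
  counts <- with_local_seed(seed, {
    matrix(stats::rpois(ny * nb, as.vector(lam)), ny, nb)
  })
  rates <- 1e5 * counts / params$person_years
  rate_table(params$years, params$bands, rates, counts = counts,
             person_years = params$person_years,
             population = "simulated (multistage)", sex = "")
}

#' @rdname simulate_registry
#' @param object a [multistage_params()] (method for [stats::simulate()]).
#' @param nsim number of tables to simulate.
#' @param ... unused.
#' @return for the `simulate` method: a list of `nsim` rate tables
#'   (a single table if `nsim = 1`).
#' @export
simulate.multistage_params <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- if (is.null(seed)) rep(list(NULL), nsim)
           else as.list(seed + seq_len(nsim) - 1L)
  out <- lapply(seeds, function(s) simulate_registry(object, seed = s))
  if (nsim == 1L) out[[1]] else out
}

# evaluate expr under a temporary RNG seed, restoring global state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Ground-truth acceleration summary of a simulator scenario
#'
#' The noise-free truth the estimation pipeline should recover: cohort c's
#' acceleration is `k[c] - 1`, so each adjacent-cohort log2 slope ratio is
#' `log2((k[c] - 1) / (k[c - 5] - 1))`, summarised exactly as the
#' estimator summarises its ratios.
#'
#' Unlike [summarize_ratios()], a constant-k scenario (all true ratios
#' identical, zero spread) is a legitimate ground truth: it is returned
#' with `se = 0` and `z = NA` rather than as an error.
#'
#' @param params a [multistage_params()].
#' @return an `accel_summary` of the true log2 ratios.
#' @export
ground_truth_summary <- function(params) {
  stopifnot(inherits(params, "multistage_params"))
  n <- length(params$cohort_starts)
  if (n < 2L) stop("need at least 2 cohorts for ground-truth ratios")
  acc <- params$k - 1
  r <- unname(log2(acc[-1] / acc[-n]))
  names(r) <- cohort_label(params$cohort_starts[-1])
  if (length(r) >= 2L && stats::sd(r) == 0) {
    return(structure(list(ratios = r, mean = mean(r), se = 0, z = NA_real_,
                          n = length(r)),
                     class = "accel_summary"))
  }
  if (length(r) < 2L)
    stop("fewer than 2 ground-truth ratios; nothing to summarize")
  summarize_ratios(r)
}

#' A rising-incidence, falling-acceleration demonstration scenario
#'
#' Default simulator parameters that qualitatively mimic the British male
#' melanoma pattern: 17 cohorts 1895-1975 observed over registry years
#' 1975-2014 in bands 25-29 ... 85+, with the number of rate-limiting
#' steps declining linearly from `k_first` to `k_last` across cohorts and
#' the baseline scale chosen so expected incidence at age 60 rises
#' geometrically from `rate60_first` to `rate60_last` per 100,000 — i.e.
#' level up, slope down.
#'
#' @param k_first,k_last rate-limiting steps for the first and last
#'   cohort (defaults 7 and 5).
#' @param rate60_first,rate60_last expected incidence at age 60 for the
#'   first and last cohort (defaults 10 and 40 per 100,000).
#' @param person_years person-years per cell (default 3e6, a realistic
#'   national-registry order of magnitude for a 5-year age band).
#' @param ... further arguments to [multistage_params()].
#' @return a [multistage_params()].
#' @export
gb_like_scenario <- function(k_first = 7, k_last = 5,
                             rate60_first = 10, rate60_last = 40,
                             person_years = 3e6, ...) {
  starts <- seq(1895, 1975, by = 5)
  n <- length(starts)
  kv <- seq(k_first, k_last, length.out = n)
  r60 <- exp(seq(log(rate60_first), log(rate60_last), length.out = n))
  Av <- r60 / 60^(kv - 1)
  multistage_params(cohort_starts = starts, k = kv, A = Av,
                    person_years = person_years, ...)
}
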