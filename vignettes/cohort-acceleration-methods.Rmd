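---
title: "Methods: birth-cohort acceleration of cancer incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: birth-cohort acceleration of cancer incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortaccel)
```

## The model and its assumptions

For most adult carcinomas, age-specific incidence $I(t)$ within a birth
cohort rises close to a power of age, $I(t) \approx A\, t^{b}$, so that
$\log I$ is nearly linear in $\log t$. The slope

$$ b \;=\; \frac{d \log I}{d \log t} $$

is the *acceleration* of cancer incidence with age. In the classical
multistage interpretation, a cancer requiring $k$ rate-limiting
transitions has $I(t) \propto t^{k-1}$, so $b$ estimates $k - 1$; but
nothing in the estimator requires that interpretation — $b$ is simply a
summary of how steeply risk climbs with age.

Because overall incidence drifts over calendar time, rates at a fixed age
mix people born in different eras. The analysis therefore works on birth
cohorts. Three quantities are computed:

1. **Per-cohort acceleration**: the ordinary least-squares slope of
   $\log(\text{rate})$ on $\log(\text{age})$ over the cohort's observed
   age bands.
2. **Adjacent-cohort log2 slope ratio**: for each successive cohort pair,
   both slopes are *refit using only the age bands the two cohorts
   share*, and $r = \log_2(b_{\text{recent}} / b_{\text{prior}})$ is
   recorded. The common-age restriction matters: successive cohorts are
   observed over age windows shifted by 5 years, and slopes estimated on
   different age ranges are not comparable if the true log-log curve has
   any curvature.
3. **Summary**: the mean $\bar r$ of the non-missing ratios — the log2 of
   the geometric mean slope ratio, i.e. the average multiplicative change
   in slope per 5-year step of birth year — its standard error
   $\mathrm{SE} = s_r/\sqrt{n}$ (sample standard deviation, $n-1$
   denominator), and the ratio $\bar r/\mathrm{SE}$, the number of
   standard errors the trend sits from zero. The ratios are treated as
   independent draws for this purpose; adjacent ratios in fact share a
   cohort, so the SE is an informal gauge of spread, not a formal test.

## Cohort extraction (Lexis diagonals)

A registry table gives rates by calendar year $y$ and 5-year age band
$[a, a+4]$. The package assigns the cell $(y, [a, a+4])$ to the cohort
containing birth year $y - a$; equivalently, cohort $c$ (births
$c \ldots c+4$) occupies band $[a, a+4]$ during calendar years
$c + a, \ldots, c + a + 4$, and its cohort rate there is the unweighted
arithmetic mean of those 5 annual rates. This is the unique simple
diagonal convention whose predicted support pattern
(`observable_bands()`) matches the staircase of observed cells in the
packaged British-male table at both registry boundaries (the 1895-99
cohort is seen only at 80-84 and 85+ because the registry starts in 1975;
the 1975-79 cohort only at 25-29 through 35-39 because it ends in 2014),
and the end-to-end tests verify that re-extracting cohorts from a
registry surface that embeds the table's diagonals reproduces it
cell-for-cell.

The mean is unweighted because registry rate tables carry no person-year
weights; where counts and person-years are available the package reads
them and validates rate = 100000 · count / person-years, but it does not
reweight the diagonal average. Tables published in 5-year period blocks
are expanded to their constituent years, each carrying the block's rate,
before assignment.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `first_start`, `last_start` | 1895, 1975 | birth year | 17 cohorts: the span observable, at ages 25+, in a registry covering roughly 1975–2014 |
| `min_age` | 25 | years | below 25 case counts are sparse and rates unstable; also avoids the distinct aetiology of childhood/adolescent cancers |
| `min_coverage` | 1.0 | fraction | a cohort cell requires all 5 assigned years; lower it (e.g. 0.6) for registries whose first/last year truncates a diagonal, at the cost of averaging fewer years |
| `digits` (tables) | 1–2 | decimals | registry summary tables print 1 decimal; ratios are reported to 2 |

Representative ages are band midpoints: 27.5, 32.5, …, 82.5. The open
85+ band is placed at 87.5 — the same `lower + 2.5` rule — which keeps
the log-age spacing of design points even. This is a convention, not an
estimate of the mean age within 85+: the true person-time-weighted mean
age there is somewhat higher. Two facts make the choice benign for the
headline statistic: only the oldest few cohorts use the 85+ band at all,
and because both cohorts in a pair are fit on the *same* design points,
the log2 *ratio* is nearly insensitive to any monotone re-placement of
the ages (the same argument covers midpoints vs band lower bounds, which
the package resolves in favour of midpoints).

## Numerical choices and degenerate inputs

* The OLS slope is computed in closed form,
  $b = S_{xy}/S_{xx}$ on $(\log t, \log I)$; it is identical under any
  log base (both axes transform identically) and invariant to rescaling
  the rates. Tests cross-check it against `stats::lm` and against a
  brute-force grid-refinement least-squares search.
* Zero and missing rates are excluded before fitting ($\log 0$ is
  undefined); zero is *observed*, missing is *unobserved*, and the two
  are never conflated by the readers/writers. A cohort with fewer than 2
  usable points has a missing slope.
* A pair with fewer than 2 common usable bands, or a non-positive slope
  on either side, yields a missing ratio, which the summary skips and
  the writers emit as a blank cell.
* Fewer than 2 usable ratios, or ratios with exactly zero spread, leave
  the mean/SE/z summary undefined (an error in `summarize_ratios()`);
  the all-equal case is allowed in `ground_truth_summary()`, where zero
  spread is a legitimate constant-k truth, reported with `se = 0` and
  `z = NA`.
* Pointwise acceleration curves (for plotting) use the finite difference
  $\Delta \log I / \Delta \log t$ between consecutive usable bands,
  attached to the geometric-mean age $\sqrt{t_i t_{i+1}}$ — the natural
  midpoint on a log axis. These curves are a visual diagnostic; no
  numeric conclusion rests on the finite-difference convention.

## The simulator: what it emulates and what it does not

`multistage_params()` defines a generative Lexis surface
$$ \mu(y, a) \;=\; \text{period\_mult}[y] \cdot A[c] \cdot t_a^{\,k[c]-1}, $$
where $c$ is the cohort owning cell $(y, a)$ under the same diagonal
convention the estimator uses, and $t_a$ is the band's representative
age. Counts are Poisson with mean $\mu \cdot \text{person-years}/10^5$.
Evaluating the hazard at the representative age (rather than integrating
over the band) and snapping each diagonal to its cohort's parameters are
deliberate: they make the noise-free acceleration of cohort $c$ exactly
$k[c] - 1$, so any discrepancy in a recovery test isolates estimator
error rather than discretisation error.

`k` and `A` can be given at anchor cohorts and interpolated linearly, so
four numbers script the scenario of interest: rising incidence with
falling acceleration. The shipped default (`gb_like_scenario()`) uses 17
cohorts (1895–1975), registry years 1975–2014, bands 25-29 … 85+, `k`
falling linearly 7 → 5, baseline scale chosen so expected incidence at
age 60 rises geometrically 10 → 40 per 100,000, and 3 × 10⁶ person-years
per cell — the order of magnitude of a national registry's 5-year age
band. These defaults are the package's study conditions for validation;
the tests run the full pipeline on this scenario with person-years
inflated to 10⁹ (recovery of each $k[c]-1$ and each true log2 ratio
within ±0.05) and at the realistic 3 × 10⁶ over 20 seeds (sign stability
of the summary z).

The simulator is deliberately minimal. It does **not** model
overdispersion beyond Poisson, within-band age structure, migration,
changing diagnostic criteria except as a smooth period multiplier,
cohort-size differences across cells, or any melanoma-specific
dose-response (UV exposure). Passing recovery tests therefore shows the
*estimator chain* is faithful under power-law truth with registry-scale
sampling noise; it does not show that real incidence surfaces follow
power laws, nor does it protect against period effects masquerading as
cohort effects — under a rising `period_mult` with constant `k`, the
pipeline's cohort slopes absorb part of the period trend, which is why
the pipeline's simulate mode writes a ground-truth recovery report
(`recovery.csv`) rather than asserting unbiasedness.

## Known limitations

* The mean:SE summary is descriptive; no multiple-testing or dependence
  correction is attempted, and no confidence intervals are attached to
  individual slopes.
* Slope ratios compare only *adjacent* cohorts; a long-run trend is
  summarised through the geometric mean of 5-year steps, not through a
  joint age-period-cohort regression (APC identifiability machinery is
  out of scope).
* Analyses of registry tables rounded to 1 decimal inherit rounding
  noise of roughly ±0.01–0.02 in each log2 ratio, which is the tolerance
  the package's own end-to-end tests use.
* Results at the oldest ages lean on the 85+ placement convention
  described above.
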