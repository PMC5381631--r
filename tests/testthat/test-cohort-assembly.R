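test_that("cohort specs count cohorts and reject bad spans", {
  sp <- cohort_spec(1895, 1975, 5, 25)
  expect_equal(sp$n_cohorts, 17)
  expect_equal(cohort_spec(1900, 1900)$n_cohorts, 1)
  expect_error(cohort_spec(1975, 1895), "empty")
  expect_error(cohort_spec(1895, 1973), "multiple of the step")
})

test_that("assign_years follows the Lexis-diagonal convention at both registry edges", {
  expect_equal(assign_years(1895, 80), 1975:1979)
  expect_equal(assign_years(1975, 35), 2010:2014)
  expect_equal(assign_years(1975, 25), 2000:2004)
  b <- std_bands()
  expect_equal(assign_years(1900, b[b$label == "85+", ]), 1985:1989)
})

test_that("assign_years partitions year x band cells across cohorts", {
  sp <- cohort_spec()
  bands <- std_bands()
  starts <- seq(sp$first_start, sp$last_start, 5)
  for (y in c(1975, 1984, 2001, 2014)) {
    for (bi in seq_len(nrow(bands))) {
      owners <- starts[vapply(starts, function(cs)
        y %in% assign_years(cs, bands$lower[bi]), logical(1))]
      # at most one owning cohort; exactly one when y - lower is in span
      expect_lte(length(owners), 1)
      birth <- y - bands$lower[bi]
      in_span <- birth >= sp$first_start & birth <= sp$last_start + 4
      expect_equal(length(owners), as.integer(in_span))
      if (in_span) expect_equal(owners, sp$first_start +
                                  5 * ((birth - sp$first_start) %/% 5))
    }
  }
})

test_that("observable_bands predicts the staircase support of the fixture", {
  sp <- cohort_spec()
  expect_equal(observable_bands(1975:2014, 1895, sp)$label,
               c("80-84", "85+"))
  expect_equal(observable_bands(1975:2014, 1975, sp)$label,
               c("25-29", "30-34", "35-39"))
  expect_equal(nrow(observable_bands(1975:2014, 1850, sp)), 0)
  # full-pattern agreement with the fixture
  gb <- gb_melanoma_males()
  for (i in seq_along(gb$cohort_starts)) {
    expect_equal(observable_bands(1975:2014, gb$cohort_starts[i], sp)$label,
                 gb$bands$label[!is.na(gb$rates[i, ])],
                 info = paste("cohort", gb$cohort_starts[i]))
  }
})

test_that("build_cohort_table averages assigned years and enforces coverage", {
  sp <- cohort_spec()
  bands <- std_bands()
  years <- 1975:2014
  # constant rate everywhere -> every observable cell is that constant
  const <- rate_table(years, bands, matrix(10, length(years), nrow(bands)))
  ct <- build_cohort_table(const, sp)
  expect_true(all(ct$rates[!is.na(ct$rates)] == 10))
  # support equals the observable_bands prediction at min_coverage = 1
  for (i in seq_along(ct$cohort_starts)) {
    expect_equal(ct$bands$label[!is.na(ct$rates[i, ])],
                 observable_bands(years, ct$cohort_starts[i], sp)$label)
  }

  # rate = year - 1900 -> cell mean is cohort + lower + 2 - 1900
  lin <- rate_table(years, bands,
                    matrix(years - 1900, length(years), nrow(bands)))
  cl <- build_cohort_table(lin, sp)
  for (i in seq_along(cl$cohort_starts)) {
    for (bi in seq_len(nrow(bands))) {
      if (is.na(cl$rates[i, bi])) next
      yrs <- assign_years(cl$cohort_starts[i], bands$lower[bi])
      expect_equal(unname(cl$rates[i, bi]), mean(yrs - 1900))  # brute force
      expect_equal(unname(cl$rates[i, bi]),
                   cl$cohort_starts[i] + bands$lower[bi] + 2 - 1900)
    }
  }

  # coverage rule: 3 of 5 years present
  part <- rate_table(1975:1977, bands, matrix(10, 3, nrow(bands)))
  strict <- build_cohort_table(part, sp, min_coverage = 1)
  expect_true(is.na(strict$rates["1895-99", "80-84"]))
  lax <- build_cohort_table(part, sp, min_coverage = 0.6)
  expect_equal(lax$rates["1895-99", "80-84"], 10)
  expect_error(build_cohort_table(part, sp, min_coverage = 0), "min_coverage")
})

test_that("a registry embedding the fixture's diagonals reproduces it cell-for-cell", {
  gb <- gb_melanoma_males()
  reg <- embed_diagonals(gb, years = 1975:2014)
  rebuilt <- build_cohort_table(reg, cohort_spec())
  expect_equal(rebuilt$rates, gb$rates)
})
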