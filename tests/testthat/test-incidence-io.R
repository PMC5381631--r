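test_that("age-band label dialects parse to identical bands", {
  a <- parse_age_bands(c("25-29", "30-34", "85+"))
  b <- parse_age_bands(c("25–29", "30 - 34", "85 and over"))
  expect_identical(a, b)
  expect_identical(a$label, c("25-29", "30-34", "85+"))
  expect_equal(a$rep_age, c(27.5, 32.5, 87.5))
  expect_true(is.na(a$upper[3]))
  expect_error(parse_age_bands(c("25-29", "banana")), "banana")
  expect_error(parse_age_bands("25-31"), "5-year")
  expect_error(parse_age_bands(c("30-34", "25-29")), "sorted")
})

test_that("rate tables validate years, rates and count consistency", {
  bands <- age_bands(c(25, 30), open_last = FALSE)
  tab <- rate_table(2000:2002, bands, rbind(c(10, 20), c(11, 22), c(12, 24)))
  expect_s3_class(tab, "rate_table")
  expect_equal(sum(!is.na(tab$rates)), 6)
  expect_error(rate_table(c(2000, 2002, 2003), bands,
                          matrix(1, 3, 2)), "non-contiguous")
  expect_error(rate_table(2000:2002, bands, matrix(-1, 3, 2)), "negative")
  # count / person-years cells must imply the stored rate
  cnt <- matrix(5, 1, 2)
  py <- matrix(50000, 1, 2)
  ok <- rate_table(2000, bands, matrix(10, 1, 2), counts = cnt,
                   person_years = py)
  expect_equal(unname(ok$rates[1, 1]), 100000 * 5 / 50000)
  expect_error(rate_table(2000, bands, matrix(99, 1, 2), counts = cnt,
                          person_years = py), "inconsistent")
})

test_that("rate-table files round-trip in both orientations and dialects", {
  bands <- age_bands(c(25, 30), open_last = FALSE)
  tab <- rate_table(2000:2002, bands,
                    rbind(c(10, 20.5), c(11, 22.25), c(12, 24)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rate_table(tab, f)
  back <- read_rate_table(f)
  expect_equal(back$rates, tab$rates)
  expect_equal(back$years, tab$years)

  # transpose orientation
  ft <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(age_band = bands$label, t(tab$rates), check.names = FALSE)
  utils::write.table(df, ft, sep = ",", row.names = FALSE, quote = FALSE)
  back_t <- read_rate_table(ft, schema = list(orientation = "age_rows"))
  expect_equal(back_t$rates, tab$rates)

  # 5-year period rows expand to constituent years carrying the same rate
  fp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("period,25-29,30-34", "1980-84,3,6", "1985-89,4,8"), fp)
  per <- read_rate_table(fp)
  expect_equal(per$years, 1980:1989)
  expect_equal(unname(per$rates[, 1]), rep(c(3, 4), each = 5))

  # counts + person-years schema computes rates
  fc <- withr::local_tempfile(fileext = ".csv")
  fpy <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,25-29", "2000,5"), fc)
  writeLines(c("year,25-29", "2000,50000"), fpy)
  got <- read_rate_table(fc, schema = list(values = "count",
                                           person_years = fpy))
  expect_equal(unname(got$rates[1, 1]), 10)
})

test_that("cohort-table files round-trip at declared precision", {
  gb <- gb_melanoma_males()
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(gb, f, digits = 1)
  back <- read_cohort_table(f)
  expect_identical(back$rates, gb$rates)
  expect_identical(back$cohort_starts, gb$cohort_starts)
  expect_identical(back$bands, gb$bands)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("age_band", f2)
  expect_error(read_cohort_table(f2), "no cohorts")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age_band,1895-99,1902-06", "25-29,1,2"), f3)
  expect_error(read_cohort_table(f3), "5-year steps")
})

test_that("the packaged British-male melanoma fixture has the published structure", {
  gb <- gb_melanoma_males()
  expect_length(gb$cohort_starts, 17)
  expect_equal(nrow(gb$bands), 13)
  expect_equal(sum(!is.na(gb$rates)), 100)
  # spot cells
  expect_equal(gb$rates["1945-49", "60-64"], 41.1)
  expect_equal(gb$rates["1895-99", "85+"], 17.0)
  # each cohort's observed cells form one contiguous run of bands
  runs <- apply(!is.na(gb$rates), 1, function(obs) {
    idx <- unname(which(obs))
    expect_equal(idx, seq(min(idx), max(idx)))
    length(idx)
  })
  expect_equal(max(runs), 8)
  expect_equal(unname(runs[c("1895-99", "1975-79")]), c(2, 3))
  # risk rises consistently through life within every cohort
  for (i in 1:17) {
    r <- gb$rates[i, !is.na(gb$rates[i, ])]
    expect_true(all(diff(r) > 0))
  }
})

test_that("summary files emit the published row layout and round-trip", {
  gb <- gb_melanoma_males()
  fit <- accel_fit(gb)
  f <- withr::local_tempfile(fileext = ".csv")
  write_summary(fit$summary, f, digits = 2)
  hdr <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_length(hdr, 19)  # 16 ratios + Mean + SE + Ratio mean:SE
  back <- read_summary(f)
  expect_equal(back$ratios, round(fit$summary$ratios, 2))

  # a missing leading pair is emitted as a blank cell
  s <- summarize_ratios(c(`1900-04` = NA, `1905-09` = -1.39,
                          `1910-14` = -0.70, `1915-19` = -0.29))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_summary(s, f2)
  row <- strsplit(readLines(f2)[2], ",")[[1]]
  expect_identical(row[1], "")
  back2 <- read_summary(f2)
  expect_true(is.na(back2$ratios[1]))
  expect_equal(back2$n, 3)

  expect_error(summarize_ratios(numeric(0)), "nothing to summarize")
})
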