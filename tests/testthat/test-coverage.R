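test_that("count_registered_on_15th counts persons covering the 15th", {
  expect_identical(count_registered_on_15th(rrec(character(0), character(0),
                                                 idate(character(0)),
                                                 idate(character(0))),
                                            "A", 2010L, 6L), 0L)
  expect_identical(
    count_registered_on_15th(rrec("p1", "A", "2010-01-01", "2010-12-31"),
                             "A", 2010L, 6L), 1L)
  reg <- rbindl(
    rrec(c("p1", "p2", "p3"), "A", "2010-01-01", "2010-12-31"),
    rrec(c("p4", "p5"), "A", "2010-01-01", "2010-06-14")
  )
  # membership via the day-set oracle: whose spell contains 2010-06-15?
  d <- idate("2010-06-15")
  oracle <- sum(vapply(seq_len(nrow(reg)), function(i)
    d %in% seq(reg$start[i], reg$end[i], by = "day"), logical(1)))
  expect_identical(oracle, 3L)
  expect_identical(count_registered_on_15th(reg, "A", 2010L, 6L), 3L)
})

test_that("monthly_raw_rate is the median weekday daily count per person", {
  wd <- month_weekdays(2010L, 6L)
  ev <- evts("p", "A", wd, n = 4L) # 4 events every weekday
  expect_equal(monthly_raw_rate(ev, 10L, "A", 2010L, 6L), 0.4)
  # no events at all
  expect_equal(monthly_raw_rate(ev[0L], 100L, "A", 2010L, 6L), 0)
  # at most five registered -> excluded
  expect_identical(monthly_raw_rate(ev, 5L, "A", 2010L, 6L), NA_real_)
})

test_that("the median absorbs a single-day bulk-upload spike; the mean does not", {
  wd <- month_weekdays(2010L, 6L)
  ev <- rbind(evts("p", "A", wd, n = 2L),          # 2 events per weekday
              evts("p", "A", wd[1L], n = 498L))    # +498 on one day
  med <- monthly_raw_rate(ev, 10L, "A", 2010L, 6L, stat = "median")
  avg <- monthly_raw_rate(ev, 10L, "A", 2010L, 6L, stat = "mean")
  expect_equal(med, 0.2) # median of {500, 2, 2, ...} is 2
  expect_gt(avg, 2 * med)
})

test_that("reference year prefers 2009, falls back to first complete year", {
  # practice with data through 2009: preferred year wins
  reg <- rrec(sprintf("p%d", 1:8), "A", "2000-01-01", "2015-12-31")
  expect_identical(choose_reference_year(reg, "A"), 2009L)
  # no 2009 data; 150 records start before 2012-01-01
  reg2 <- rrec(sprintf("q%d", 1:150), "B", "2011-04-01", "2015-12-31")
  expect_identical(choose_reference_year(reg2, "B"), 2012L)
  # threshold unreachable
  reg3 <- rrec(sprintf("r%d", 1:20), "C", "2011-04-01", "2015-12-31")
  expect_error(choose_reference_year(reg3, "C"), class = "no_reference_year")
})

test_that("normalization divides by the reference-year median and propagates exclusions", {
  m <- rate_series(c(rep(0.5, 12), 0.05, NA), from_year = 2009L)
  m[, normalized_rate := NULL]
  out <- normalize_rates(m, 2009L)
  expect_equal(out$normalized_rate[13L], 0.1)   # 0.05 / 0.5
  expect_equal(out$normalized_rate[1L], 1.0)    # reference month
  expect_true(is.na(out$normalized_rate[14L]))  # EXCLUDED propagates
  mz <- rate_series(rep(0, 12), from_year = 2009L)
  expect_error(normalize_rates(mz, 2009L), class = "zero_reference_rate")
  expect_error(normalize_rates(rate_series(NA_real_, from_year = 2010L), 2009L),
               class = "no_reference_rate")
})

test_that("start-date inference uses the sustained-crossing rule", {
  p <- presence_params(threshold = 0.10, sustain_months = 3L)
  # isolated 0.15 spike must not win; the sustained 0.40 month does
  m <- rate_series(c(0.02, 0.04, 0.15, 0.01, 0.40, 0.55, 0.60, 0.5, 0.45),
                   from_year = 2005L, from_month = 1L)
  expect_identical(infer_start_date(m, p), idate("2005-05-01"))
  # degenerate: everything above threshold
  m2 <- rate_series(rep(0.9, 6), from_year = 2005L)
  expect_identical(infer_start_date(m2, p), idate("2005-01-01"))
  # never crosses
  m3 <- rate_series(rep(0.05, 24), from_year = 2005L)
  expect_true(is.na(infer_start_date(m3, p)))
  # excluded months are skipped, not treated as zero
  m4 <- rate_series(c(0.5, NA, NA, 0.5, 0.5), from_year = 2005L)
  expect_identical(infer_start_date(m4, p), idate("2005-01-01"))
})

test_that("end-date inference checks recording continued to the extract", {
  p <- presence_params(threshold = 0.10)
  ex <- idate("2016-07-20")
  # recording continues into the extract month -> day before extract
  m <- rate_series(rep(1.0, 30), from_year = 2014L)
  expect_identical(infer_end_date(m, ex, p), idate("2016-07-19"))
  # recording stopped 14 months early -> last day of final good month
  m2 <- rate_series(c(rep(1.0, 16), rep(0.01, 14)), from_year = 2014L)
  expect_identical(infer_end_date(m2, ex, p), idate("2015-04-30"))
  # threshold never met
  m3 <- rate_series(rep(0.01, 30), from_year = 2014L)
  expect_true(is.na(infer_end_date(m3, ex, p)))
})

test_that("coverage recovers an abrupt synthetic onset and extract end", {
  sc <- generate_scenario(scenario_config(
    n_practices = 2L, n_persons = 160L, seed = 11,
    backdating_fraction = 0.05, frac_in_sail = 1))
  cov <- practice_coverage(sc$events, sc$registrations, sc$practice_meta)
  j <- merge(cov, sc$truth$practices, by = "practice_id")
  expect_true(all(abs(as.integer(j$data_start) - as.integer(j$true_start)) <= 31))
  expect_identical(j$data_end, j$true_end)
  expect_identical(j$reference_year, rep(2009L, 2L))
})

test_that("practice not contributing data is absent from coverage output", {
  sc <- generate_scenario(scenario_config(n_practices = 4L, n_persons = 120L,
                                          seed = 5, frac_in_sail = 0.5))
  cov <- practice_coverage(sc$events, sc$registrations, sc$practice_meta)
  expect_setequal(cov$practice_id,
                  sc$practice_meta[in_sail == TRUE, practice_id])
})

test_that("coverage is invariant to uniform scaling of event volume", {
  sc <- generate_scenario(scenario_config(n_practices = 2L, n_persons = 120L,
                                          seed = 21, frac_in_sail = 1,
                                          backdating_fraction = 0))
  ev3 <- sc$events[rep(seq_len(.N), 3L)] # every event three times
  m1 <- monthly_rates(sc$events, sc$registrations, sc$practice_meta)
  m3 <- monthly_rates(ev3, sc$registrations, sc$practice_meta)
  expect_equal(m3$raw_rate, 3 * m1$raw_rate, tolerance = 1e-12)
  expect_equal(m3$normalized_rate, m1$normalized_rate, tolerance = 1e-12)
  c1 <- practice_coverage(sc$events, sc$registrations, sc$practice_meta)
  c3 <- practice_coverage(ev3, sc$registrations, sc$practice_meta)
  expect_identical(c1$data_start, c3$data_start)
  expect_identical(c1$data_end, c3$data_end)
})

test_that("sentinel-dated events cannot create pre-1950 rate months", {
  sc <- generate_scenario(scenario_config(n_practices = 2L, n_persons = 120L,
                                          seed = 8, frac_in_sail = 1,
                                          sentinel_fraction = 0.02))
  m <- monthly_rates(sc$events, sc$registrations, sc$practice_meta)
  expect_true(all(m$year >= 1950L))
  # and the 1900 pile does not move the inferred start
  cov <- practice_coverage(sc$events, sc$registrations, sc$practice_meta,
                           monthly = m)
  no_sent <- sc$events[event_date > idate("1950-01-01")]
  cov2 <- practice_coverage(no_sent, sc$registrations, sc$practice_meta)
  expect_identical(cov$data_start, cov2$data_start)
})
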