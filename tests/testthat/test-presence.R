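pmPQR <- pmeta(c("P", "Q", "R"), in_sail = c(TRUE, TRUE, FALSE))

test_that("splitting at coverage boundaries yields up to three flagged records", {
  cov <- cov_row("P", "2008-03-01", "2014-06-30")
  r <- rrec("p", "P", "2005-01-01", "2015-12-31")
  out <- split_by_coverage(r, cov)
  expect_identical(out$start, idate(c("2005-01-01", "2008-03-01", "2014-07-01")))
  expect_identical(out$end, idate(c("2008-02-29", "2014-06-30", "2015-12-31")))
  expect_identical(out$sail_data, c(FALSE, TRUE, FALSE))
  # entirely inside coverage
  r2 <- rrec("p", "P", "2009-01-01", "2010-12-31")
  out2 <- split_by_coverage(r2, cov)
  expect_identical(nrow(out2), 1L)
  expect_true(out2$sail_data)
  # practice without coverage
  r3 <- rrec("p", "R", "2009-01-01", "2010-12-31")
  out3 <- split_by_coverage(r3, cov)
  expect_identical(nrow(out3), 1L)
  expect_false(out3$sail_data)
})

test_that("short gaps are closed towards the second practice", {
  h <- rbindl(rrec("p", "P", "2010-01-01", "2010-03-31"),
              rrec("p", "Q", "2010-04-20", "2010-12-31"))
  out <- close_gaps(h, 30L)
  expect_identical(out[practice_id == "Q", start], idate("2010-04-01"))
  expect_identical(out[practice_id == "P", end], idate("2010-03-31"))
  # 45-day gap stays open under the default
  h2 <- rbindl(rrec("p", "P", "2010-01-01", "2010-03-31"),
               rrec("p", "Q", "2010-05-16", "2010-12-31"))
  expect_identical(close_gaps(h2, 30L)[practice_id == "Q", start],
                   idate("2010-05-16"))
  # disabled
  expect_identical(close_gaps(h, 0L)[practice_id == "Q", start],
                   idate("2010-04-20"))
})

test_that("merging honours the four grouping combinations", {
  recs <- rbindl(rrec("p", "P", "2010-01-01", "2010-06-30"),
                 rrec("p", "Q", "2010-07-01", "2010-12-31"))
  recs[, sail_data := TRUE]
  # (1,0): adjacent available records at different practices merge, id collapses
  m10 <- merge_adjacent(recs, presence_params(group_on_sail_data = 1,
                                              group_on_practice = 0))
  expect_identical(nrow(m10), 1L)
  expect_true(is.na(m10$practice_id))
  expect_true(m10$sail_data)
  # (1,1): same practice, flags differ -> never combined
  recs2 <- rbindl(rrec("p", "P", "2010-01-01", "2010-06-30"),
                  rrec("p", "P", "2010-07-01", "2010-12-31"))
  recs2[, sail_data := c(TRUE, FALSE)]
  m11 <- merge_adjacent(recs2, presence_params(group_on_sail_data = 1,
                                               group_on_practice = 1))
  expect_identical(nrow(m11), 2L)
  # (0,0): everything adjacent merges; mixed flag becomes untracked
  m00 <- merge_adjacent(recs2, presence_params(group_on_sail_data = 0,
                                               group_on_practice = 0))
  expect_identical(nrow(m00), 1L)
  expect_true(is.na(m00$sail_data))
  # (0,1): practice change still blocks
  m01 <- merge_adjacent(recs, presence_params(group_on_sail_data = 0,
                                              group_on_practice = 1))
  expect_identical(nrow(m01), 2L)
  # non-adjacent records never merge
  recs3 <- rbindl(rrec("p", "P", "2010-01-01", "2010-06-30"),
                  rrec("p", "P", "2010-07-03", "2010-12-31"))
  recs3[, sail_data := TRUE]
  expect_identical(nrow(merge_adjacent(recs3, presence_params(
    group_on_sail_data = 0, group_on_practice = 0))), 2L)
})

test_that("exclusion periods are subtracted by interval difference", {
  rec <- copy(rrec("p", "P", "2010-01-01", "2010-12-31"))[, sail_data := TRUE]
  ex <- data.table(person_id = "p", start = idate("2010-06-01"),
                   end = idate("2010-06-30"))
  out <- subtract_exclusions(rec, ex)
  expect_identical(out$start, idate(c("2010-01-01", "2010-07-01")))
  expect_identical(out$end, idate(c("2010-05-31", "2010-12-31")))
  # day-set difference oracle agrees
  want <- setdiff(seq(rec$start, rec$end, by = "day"),
                  seq(ex$start, ex$end, by = "day"))
  got <- unlist(lapply(seq_len(nrow(out)),
                       function(i) seq(out$start[i], out$end[i], by = "day")))
  expect_identical(sort(got), sort(want))
  # no overlap -> identity; full cover -> dropped
  ex2 <- data.table(person_id = "p", start = idate("2011-01-01"),
                    end = idate("2011-12-31"))
  expect_identical(nrow(subtract_exclusions(rec, ex2)), 1L)
  ex3 <- data.table(person_id = "p", start = idate("2009-12-01"),
                    end = idate("2011-01-31"))
  expect_identical(nrow(subtract_exclusions(rec, ex3)), 0L)
})

test_that("build_presence reproduces the hand-derived composite scenario", {
  # one person, three practices (R does not contribute), one exact duplicate,
  # one nested spell, one overlap, one duplicate period, a 10-day gap and a
  # 59-day gap
  h <- rbindl(
    rrec("p", "P", "2000-01-01", "2003-12-31"),
    rrec("p", "P", "2000-01-01", "2003-12-31"),  # duplicate row
    rrec("p", "Q", "2001-06-01", "2001-06-30"),  # nested
    rrec("p", "Q", "2003-10-01", "2004-12-31"),  # overlap: P shortened
    rrec("p", "R", "2003-10-01", "2004-12-31"),  # duplicate period: Q wins
    rrec("p", "P", "2005-01-11", "2008-12-31"),  # 10-day gap: closed
    rrec("p", "R", "2009-01-01", "2012-12-31"),  # not contributing
    rrec("p", "Q", "2013-03-01", NA)             # 59-day gap: NOT closed; open
  )
  cov <- rbindl(cov_row("P", "2001-01-01", "2016-12-31"),
                cov_row("Q", "2002-07-01", "2016-12-30"))
  pmX <- pmeta(c("P", "Q", "R"), in_sail = c(TRUE, TRUE, FALSE),
               extract = "2016-12-31")
  out <- build_presence(h, cov, pmX, params = presence_params(
    group_on_sail_data = 1, group_on_practice = 0))
  expected <- data.table(
    person_id = "p",
    practice_id = c("P", NA, "R", "Q", "Q"),
    start = idate(c("2000-01-01", "2001-01-01", "2009-01-01",
                    "2013-03-01", "2016-12-31")),
    end = idate(c("2000-12-31", "2008-12-31", "2012-12-31",
                  "2016-12-30", "2016-12-31")),
    sail_data = c(FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  expect_identical(out[, .(person_id, practice_id, start, end, sail_data)],
                   expected)
  # and the day-level oracle agrees under every grouping combination
  for (gsd in 0:1) for (gp in 0:1) {
    p <- presence_params(group_on_sail_data = gsd, group_on_practice = gp)
    pres <- build_presence(h, cov, pmX, params = p)
    odays <- presence_days_oracle(materialize_open_ends(h, idate("2016-12-31")),
                                  cov, pmX, NULL, p)
    expect_presence_matches_oracle(pres, odays, p)
  }
})

test_that("presence honours its invariants on a synthetic scenario", {
  sc <- generate_scenario(scenario_config(n_practices = 4L, n_persons = 80L,
                                          seed = 13, exclusion_rate = 0.1))
  cov <- practice_coverage(sc$events, sc$registrations, sc$practice_meta)
  p <- presence_params(group_on_sail_data = 1, group_on_practice = 1)
  pres <- build_presence(sc$registrations, cov, sc$practice_meta,
                         sc$exclusions, p)
  dd <- expand_presence_days(pres)
  # non-overlap per person
  expect_identical(anyDuplicated(dd[, .(person_id, day)]), 0L)
  # every available day lies inside its practice's coverage interval
  j <- dd[sail_data == TRUE][as.data.table(cov), on = "practice_id",
                             `:=`(ds = i.data_start, de = i.data_end)]
  expect_true(all(!is.na(j[sail_data == TRUE]$ds)))
  expect_true(all(j[sail_data == TRUE, day >= ds & day <= de]))
  # raising max_gap_days never loses presence days
  p2 <- presence_params(max_gap_days = 90L, group_on_sail_data = 1,
                        group_on_practice = 1)
  pres2 <- build_presence(sc$registrations, cov, sc$practice_meta,
                          sc$exclusions, p2)
  days1 <- expand_presence_days(pres)[, .N, by = person_id]
  days2 <- expand_presence_days(pres2)[, .N, by = person_id]
  cmp <- merge(days1, days2, by = "person_id", all = TRUE)
  expect_true(all(cmp$N.y >= cmp$N.x, na.rm = TRUE))
})
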