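# Independent day-level oracle. Evaluates the cleaning, gap-closing,
# coverage-flag and exclusion rules one calendar day at a time, without any
# of the package's interval algebra, so that the interval pipeline can be
# checked against brute force:
#   - exact duplicates collapse; identical periods keep the preferred
#     practice (contributing data first, then lower id);
#   - a record properly contained in another kept record is dropped;
#   - a day covered by several surviving records belongs to the record with
#     the latest start (equivalent to shortening the first of an
#     overlapping pair);
#   - an uncovered run of 1..max_gap_days days between covered days belongs
#     to the practice of the next covered day;
#   - a day's availability flag is TRUE iff its practice's coverage
#     interval contains it; exclusion days are removed.

day_count_oracle <- function(a_end, b_start) {
  # days strictly between two dates, by enumeration
  d <- seq(idate(a_end), idate(b_start), by = "day")
  length(d) - 2L
}

clean_days_oracle <- function(history, practice_meta = NULL) {
  h <- unique(as.data.table(history)[, .(person_id, practice_id,
                                         start = idate(start), end = idate(end))])
  sail <- if (is.null(practice_meta)) {
    data.table(practice_id = character(0), in_sail = logical(0))
  } else {
    as.data.table(practice_meta)[, .(practice_id, in_sail = as.logical(in_sail))]
  }
  h[sail, on = "practice_id", in_sail := i.in_sail]
  h[is.na(in_sail), in_sail := FALSE]
  # duplicate periods: keep the preferred practice
  setorder(h, person_id, start, end, -in_sail, practice_id)
  h <- h[, .SD[1L], by = .(person_id, start, end)]
  # drop records properly contained in another surviving record
  keep <- rep(TRUE, nrow(h))
  for (p in unique(h$person_id)) {
    idx <- which(h$person_id == p)
    for (i in idx) for (j in idx) {
      if (i == j) next
      if (h$start[j] <= h$start[i] && h$end[j] >= h$end[i] &&
          !(h$start[j] == h$start[i] && h$end[j] == h$end[i])) {
        keep[i] <- FALSE
      }
    }
  }
  h <- h[keep]
  # day-level ownership: latest-starting covering record wins
  h[, rid := .I]
  dd <- h[, .(day = seq(start, end, by = "day")),
          by = .(rid, person_id, practice_id, start)]
  setorder(dd, person_id, day, start)
  dd[, .(practice_id = practice_id[.N]), by = .(person_id, day)]
}

presence_days_oracle <- function(registrations, coverage, practice_meta,
                                 exclusions = NULL, params = presence_params()) {
  cd <- clean_days_oracle(registrations, practice_meta)
  setorder(cd, person_id, day)
  if (params$max_gap_days > 0L && nrow(cd) > 1L) {
    cd[, prev_day := data.table::shift(day), by = person_id]
    g <- as.integer(cd$day) - as.integer(cd$prev_day) - 1L
    fills <- cd[!is.na(prev_day) & g >= 1L & g <= params$max_gap_days,
                .(person_id, practice_id, from = prev_day + 1L, to = day - 1L)]
    if (nrow(fills)) {
      fills[, fid := .I]
      fd <- fills[, .(day = seq(from, to, by = "day")),
                  by = .(fid, person_id, practice_id)]
      cd <- rbind(cd[, .(person_id, practice_id, day)],
                  fd[, .(person_id, practice_id, day)])
    } else {
      cd <- cd[, .(person_id, practice_id, day)]
    }
  } else {
    cd <- cd[, .(person_id, practice_id, day)]
  }
  cov <- as.data.table(coverage)[!is.na(data_start) & !is.na(data_end)]
  cd[cov, on = "practice_id",
     sail := day >= i.data_start & day <= i.data_end]
  cd[is.na(sail), sail := FALSE]
  if (!is.null(exclusions) && nrow(as.data.table(exclusions))) {
    ex <- as.data.table(exclusions)
    ex[, xid := .I]
    xd <- ex[, .(day = seq(idate(start), idate(end), by = "day")),
             by = .(xid, person_id)]
    cd <- cd[!xd, on = .(person_id, day)]
  }
  setorder(cd, person_id, day)
  cd[]
}

expand_presence_days <- function(presence) {
  p <- as.data.table(presence)
  p[, rid := .I]
  p[, .(day = seq(idate(start), idate(end), by = "day")),
    by = .(rid, person_id, practice_id, sail_data)][
      , .(person_id, practice_id, sail_data, day)]
}

# full equivalence check of pipeline output against the day oracle under
# given grouping semantics
expect_presence_matches_oracle <- function(presence, oracle_days, params) {
  pd <- expand_presence_days(presence)
  setorder(pd, person_id, day)
  od <- copy(oracle_days)
  setorder(od, person_id, day)
  # identical day sets per person
  expect_identical(pd[, .(person_id, day)], od[, .(person_id, day)])
  j <- od[pd, on = .(person_id, day)]
  # where the practice identity is tracked it matches the oracle
  expect_true(all(j[!is.na(i.practice_id), practice_id == i.practice_id]))
  # where the availability flag is tracked it matches the oracle
  expect_true(all(j[!is.na(sail_data), sail == sail_data]))
  # identity may only be collapsed when grouping allows it
  if (params$group_on_practice == 1L) expect_false(anyNA(pd$practice_id))
  if (params$group_on_sail_data == 1L) expect_false(anyNA(pd$sail_data))
  invisible(TRUE)
}
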