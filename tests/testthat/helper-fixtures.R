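library(data.table)

idate <- data.table::as.IDate

# registration rows
rrec <- function(person, practice, start, end) {
  data.table(person_id = person, practice_id = practice,
             start = idate(start), end = idate(end))
}

rbindl <- function(...) rbindlist(list(...))

# practice metadata; extract defaults to just after the usual test horizon
pmeta <- function(ids, in_sail = TRUE, extract = "2017-01-01") {
  n <- length(ids)
  in_sail <- rep_len(in_sail, n)
  ex <- rep_len(idate(extract), n)
  ex[!in_sail] <- NA
  data.table(practice_id = ids, in_sail = in_sail, extract_date = ex)
}

cov_row <- function(practice, start, end, ref = 2009L) {
  data.table(practice_id = practice, data_start = idate(start),
             data_end = idate(end), reference_year = ref)
}

# events: n on each given day at one practice
evts <- function(person, practice, dates, n = 1L) {
  data.table(person_id = person, practice_id = practice,
             event_date = rep(idate(dates), each = n))
}

# monthly-rate series from a vector of normalized rates starting at a month
rate_series <- function(rates, from_year = 2005L, from_month = 1L,
                        registered = 100L) {
  i <- seq_along(rates) - 1L
  ymi <- from_year * 12L + from_month - 1L + i
  data.table(practice_id = "PX", year = ymi %/% 12L, month = ymi %% 12L + 1L,
             registered_count = registered, raw_rate = rates,
             normalized_rate = rates)
}

# random messy one-person history used by the cleaning property tests:
# overlapping, nested and duplicated spells by construction
random_history <- function(person, n_rec = 6L,
                           origin = idate("2005-01-01"), span = 3000L) {
  s <- origin + sample.int(span, n_rec, replace = TRUE)
  len <- sample.int(700L, n_rec, replace = TRUE) - 1L
  h <- data.table(person_id = person,
                  practice_id = sample(c("PA", "PB", "PC"), n_rec, TRUE),
                  start = s, end = s + len)
  if (n_rec >= 2L && runif(1) < 0.5) h[2L, `:=`(start = h$start[1L], end = h$end[1L])]
  if (n_rec >= 3L && runif(1) < 0.5) h <- rbind(h, h[3L])
  h
}

# weekdays of a calendar month
month_weekdays <- function(year, month) {
  from <- idate(sprintf("%04d-%02d-01", year, month))
  to <- seq(from, by = "1 month", length.out = 2L)[2L] - 1L
  d <- seq(from, to, by = "day")
  d[data.table::wday(d) %in% 2:6]
}
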