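# Step 1: infer, per contributing practice, the period of usable electronic
# data from aggregate event-recording rates. Only event VOLUMES are used;
# whether an individual has events recorded never feeds into their own
# follow-up (that would bias the coverage measure against the healthy).

#' Count persons registered at a practice on the 15th of a month
#'
#' The monthly denominator of the event-rate series: distinct persons whose
#' registration spell at the practice contains the 15th day of the month.
#'
#' @param registrations Registration table with finite ends (see
#'   [materialize_open_ends()]).
#' @param practice Practice identifier.
#' @param year,month Calendar month to count.
#' @return Non-negative integer.
#' @export
count_registered_on_15th <- function(registrations, practice, year, month) {
  reg <- as.data.table(registrations)
  d <- data.table::as.IDate(sprintf("%04d-%02d-15", year, month))
  reg <- reg[practice_id == practice]
  if (!nrow(reg)) return(0L)
  reg[, `:=`(start = as_idate(start), end = as_idate(end))]
  length(unique(reg[start <= d & end >= d, person_id]))
}

#' Monthly event rate for one practice-month
#'
#' Robust per-person recording rate: the total event count is tallied for
#' every weekday (Mon-Fri) calendar day of the month, zero-event weekdays
#' included, and the median of those daily counts is divided by the number
#' registered on the 15th. The median across days absorbs single-day spikes
#' (bulk uploads, year-first/month-first backdating piles) that inflate a
#' mean. Months with at most `min_registered` registered persons are
#' excluded (`NA`): too few registrations usually signals missing
#' registration data, not absence of recording.
#'
#' @param events Event table (`person_id`, `practice_id`, `event_date`).
#' @param registered_count Persons registered on the 15th of this month.
#' @param practice Practice identifier.
#' @param year,month Calendar month.
#' @param min_registered Exclusion cutoff; see [presence_params()].
#' @param stat `"median"` (default) or `"mean"` across weekday daily counts;
#'   the mean variant exists to demonstrate its fragility.
#' @return Non-negative numeric, or `NA_real_` when excluded.
#' @export
monthly_raw_rate <- function(events, registered_count, practice, year, month,
                             min_registered = 5L, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (registered_count <= min_registered) return(NA_real_)
  ev <- as.data.table(events)[practice_id == practice]
  i <- as.integer(year) * 12L + as.integer(month) - 1L
  days <- seq(month_index_to_start(i), month_index_to_start(i + 1L) - 1L, by = "day")
  days <- days[is_weekday(days)]
  cnt <- ev[, .N, by = event_date][data.table(event_date = as_idate(days)),
                                   on = "event_date"]
  x <- cnt$N
  x[is.na(x)] <- 0L
  (if (stat == "median") median(x) else mean(x)) / registered_count
}

# reference-year choice given per-month registered counts for one practice
.choose_ref_year <- function(reg_pr, counts, params) {
  ref <- params$reference_year
  ok <- counts[ymi %/% 12L == ref & registered_count > params$min_registered]
  if (nrow(ok)) return(ref)
  if (!nrow(reg_pr)) {
    stop(errorCondition("no registrations at practice",
                        class = c("no_reference_year", "error", "condition")))
  }
  yrs <- sort(unique(data.table::year(reg_pr$start)))
  cand <- seq.int(min(yrs), max(yrs) + 1L)
  for (y in cand) {
    jan1 <- data.table::as.IDate(sprintf("%04d-01-01", y))
    if (sum(reg_pr$start < jan1) >= params$reference_min_registrations) return(y)
  }
  stop(errorCondition(
    sprintf("no year with >= %d registrations starting before its 1 January",
            params$reference_min_registrations),
    class = c("no_reference_year", "error", "condition")))
}

#' Choose the reference year for a practice
#'
#' Normalization needs a period when data is known to be available. The
#' preferred reference year (default 2009, believed to postdate electronic
#' recording onset at all practices) is used whenever the practice has any
#' usable month in it; otherwise the first "complete" year — the earliest
#' year with at least `reference_min_registrations` registration records
#' starting before its 1 January — is used.
#'
#' @inheritParams count_registered_on_15th
#' @param params A [presence_params()] object.
#' @return Integer year. Errors with condition class `no_reference_year`
#'   when no year qualifies; such practices cannot be assigned coverage.
#' @export
choose_reference_year <- function(registrations, practice, params = presence_params()) {
  params <- as_params(params)
  reg <- as.data.table(registrations)[practice_id == practice]
  if (!nrow(reg)) {
    stop(errorCondition("no registrations at practice",
                        class = c("no_reference_year", "error", "condition")))
  }
  reg[, `:=`(start = as_idate(start), end = as_idate(end))]
  ref <- params$reference_year
  counts <- data.table(ymi = (ref * 12L):(ref * 12L + 11L))
  counts[, registered_count := vapply(ymi, function(i) {
    d <- fifteenth(i)
    length(unique(reg[start <= d & (is.na(end) | end >= d), person_id]))
  }, integer(1L))]
  .choose_ref_year(reg, counts, params)
}

#' Normalize a monthly rate series to its reference year
#'
#' Divides each month's raw rate by the practice's reference rate — the
#' median of the non-excluded monthly raw rates inside the reference year —
#' so thresholds are comparable across practices with different recording
#' volumes. Excluded months stay excluded.
#'
#' @param monthly Monthly-rate table for one practice (`year`, `month`,
#'   `registered_count`, `raw_rate`).
#' @param reference_year Year chosen by [choose_reference_year()].
#' @return The table with a `normalized_rate` column.
#' @export
normalize_rates <- function(monthly, reference_year) {
  m <- copy(as.data.table(monthly))
  ref_rates <- m[year == reference_year & !is.na(raw_rate), raw_rate]
  if (!length(ref_rates)) {
    stop(errorCondition("no usable months in reference year",
                        class = c("no_reference_rate", "error", "condition")))
  }
  ref <- median(ref_rates)
  if (ref == 0) {
    stop(errorCondition("reference rate is zero",
                        class = c("zero_reference_rate", "error", "condition")))
  }
  m[, normalized_rate := raw_rate / ref]
  m[]
}

#' Infer the start date of usable data from a normalized rate series
#'
#' Scans the calendar-ordered series for the earliest month whose normalized
#' rate reaches `threshold` and is sustained: the next `sustain_months - 1`
#' usable (non-excluded) months also reach it. Excluded months are skipped
#' as missing, not treated as zero. Returns the first day of that month, or
#' `NA` if the threshold is never sustained.
#'
#' @param monthly Normalized monthly-rate table for one practice.
#' @param params A [presence_params()] object.
#' @return `IDate` or `NA`.
#' @export
infer_start_date <- function(monthly, params = presence_params()) {
  params <- as_params(params)
  m <- copy(as.data.table(monthly))
  setorder(m, year, month)
  nn <- m[!is.na(normalized_rate)]
  if (!nrow(nn)) return(data.table::as.IDate(NA))
  hit <- nn$normalized_rate >= params$threshold
  k <- params$sustain_months - 1L
  for (i in seq_along(hit)) {
    if (!hit[i]) next
    idx <- if (k > 0L && i < length(hit)) seq.int(i + 1L, min(i + k, length(hit))) else integer(0)
    if (all(hit[idx])) {
      return(month_index_to_start(nn$year[i] * 12L + nn$month[i] - 1L))
    }
  }
  data.table::as.IDate(NA)
}

#' Infer the end date of usable data
#'
#' The day before the practice's last data extract is the natural end; it is
#' accepted when the last usable month on record still reaches the
#' threshold. If recording stopped earlier (e.g. a practice closed and its
#' data was extracted later), the end is pulled back to the last day of the
#' latest month that met the threshold. Months after `extract_date - 1` are
#' never considered, so future-dated errors cannot extend coverage.
#'
#' @inheritParams infer_start_date
#' @param extract_date Date of the practice's last data extract.
#' @return `IDate` or `NA` when no month ever met the threshold.
#' @export
infer_end_date <- function(monthly, extract_date, params = presence_params()) {
  params <- as_params(params)
  cand <- as_idate(extract_date) - 1L
  m <- copy(as.data.table(monthly))
  setorder(m, year, month)
  m[, ymi := year * 12L + month - 1L]
  nn <- m[!is.na(normalized_rate) & month_index_to_start(ymi + 1L) - 1L <= cand]
  if (!nrow(nn)) return(data.table::as.IDate(NA))
  if (nn$normalized_rate[nrow(nn)] >= params$threshold) return(cand)
  ok <- nn[normalized_rate >= params$threshold]
  if (!nrow(ok)) return(data.table::as.IDate(NA))
  month_index_to_start(ok$ymi[nrow(ok)] + 1L) - 1L
}

#' Monthly event-recording rates for all contributing practices
#'
#' Builds the persistent intermediate of the coverage step: for every
#' practice contributing data and every month from its first registration
#' (no earlier than 1950) to the last full month before its extract date,
#' the registered count on the 15th, the raw rate (median weekday events per
#' registered person) and the rate normalized to the practice's reference
#' year. A trailing partial extract month is omitted: its post-extract days
#' would read as zeros and fake a recording stop.
#'
#' @param events,registrations,practice_meta Input tables; see
#'   [load_tables()] for schemas.
#' @param params A [presence_params()] object.
#' @param stat Daily-count summary, `"median"` (default) or `"mean"`.
#' @return `data.table` with columns `practice_id`, `year`, `month`,
#'   `registered_count`, `raw_rate`, `normalized_rate`; attribute
#'   `reference_years` maps practices to their reference year (`NA` when
#'   none qualifies) and attribute `issues` lists per-practice problems.
#' @export
monthly_rates <- function(events, registrations, practice_meta,
                          params = presence_params(), stat = c("median", "mean")) {
  stat <- match.arg(stat)
  params <- as_params(params)
  pm <- copy(as.data.table(practice_meta))
  pm[, in_sail := as.logical(in_sail)]
  pm[, extract_date := as_idate(extract_date)]
  censor <- censor_date(pm)
  reg <- materialize_open_ends(registrations, censor)
  ev <- copy(as.data.table(events))
  ev[, event_date := as_idate(event_date)]
  prac <- pm[in_sail == TRUE]
  if (!nrow(prac)) stop("monthly_rates(): no practice contributes data", call. = FALSE)

  issues <- list()
  grid_def <- merge(prac[, .(practice_id, extract_date)],
                    reg[, .(first = min(start)), by = practice_id],
                    by = "practice_id", all.x = TRUE)
  no_reg <- grid_def[is.na(first), practice_id]
  for (p in no_reg) issues[[length(issues) + 1L]] <-
    data.table(practice_id = p, issue = "no_registrations")
  grid_def <- grid_def[!is.na(first)]
  floor1950 <- month_index(data.table::as.IDate("1950-01-01"))
  grid_def[, from := pmax(month_index(first), floor1950)]
  cand <- grid_def$extract_date - 1L
  grid_def[, to := data.table::fifelse(cand == month_end(cand),
                                       month_index(cand), month_index(cand) - 1L)]
  grid_def <- grid_def[from <= to]
  grid <- grid_def[, .(ymi = seq.int(from, to)), by = practice_id]

  # denominators: distinct persons registered on each month's 15th
  grid[, d15 := fifteenth(ymi)]
  grid[, registered_count := reg[.SD, on = .(practice_id, start <= d15, end >= d15),
                                 .(n = uniqueN(person_id[!is.na(person_id)])),
                                 by = .EACHI]$n,
       .SDcols = c("practice_id", "d15")]

  # numerators: zero-filled daily event counts on weekday calendar days
  days <- grid[, .(day = seq(month_index_to_start(ymi),
                             month_index_to_start(ymi + 1L) - 1L, by = "day")),
               by = .(practice_id, ymi)]
  days <- days[is_weekday(day)]
  evc <- ev[, .(n_events = .N), by = .(practice_id, event_date)]
  days[evc, on = .(practice_id, day = event_date), daily_n := i.n_events]
  days[is.na(daily_n), daily_n := 0L]
  stat_fun <- if (stat == "median") function(x) as.numeric(median(x)) else mean
  mstat <- days[, .(daily_stat = stat_fun(daily_n)), by = .(practice_id, ymi)]
  grid[mstat, on = .(practice_id, ymi), raw_rate := i.daily_stat / registered_count]
  grid[registered_count <= params$min_registered, raw_rate := NA_real_]

  # per-practice reference year + normalization
  grid[, normalized_rate := NA_real_]
  refs <- data.table(practice_id = grid_def$practice_id, reference_year = NA_integer_)
  for (p in grid_def$practice_id) {
    counts <- grid[practice_id == p, .(ymi, registered_count)]
    res <- tryCatch({
      ry <- .choose_ref_year(reg[practice_id == p], counts, params)
      rr <- grid[practice_id == p & ymi %/% 12L == ry & !is.na(raw_rate), raw_rate]
      if (!length(rr)) stop(errorCondition(
        "no usable months in reference year",
        class = c("no_reference_rate", "error", "condition")))
      ref <- median(rr)
      if (ref == 0) stop(errorCondition(
        "reference rate is zero",
        class = c("zero_reference_rate", "error", "condition")))
      list(ry = ry, ref = ref)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      issues[[length(issues) + 1L]] <-
        data.table(practice_id = p,
                   issue = class(res)[1L])
    } else {
      refs[practice_id == p, reference_year := res$ry]
      grid[practice_id == p, normalized_rate := raw_rate / res$ref]
    }
  }

  out <- grid[, .(practice_id, year = ymi %/% 12L, month = ymi %% 12L + 1L,
                  registered_count, raw_rate, normalized_rate)]
  setorder(out, practice_id, year, month)
  setattr(out, "reference_years", refs[])
  setattr(out, "issues",
          if (length(issues)) rbindlist(issues)
          else data.table(practice_id = character(0), issue = character(0)))
  out[]
}

#' Infer data coverage for every contributing practice
#'
#' Composes the coverage step: monthly rate series, reference-year choice,
#' normalization, start- and end-date inference. Practices for which no
#' reference year or rate exists get `NA` coverage and are reported in the
#' `issues` attribute (with a warning) rather than aborting the run.
#'
#' @inheritParams monthly_rates
#' @param monthly Optional precomputed [monthly_rates()] table (the
#'   persisted intermediate); computed from the raw tables when `NULL`.
#' @return `data.table` with columns `practice_id`, `data_start`,
#'   `data_end`, `reference_year`; attributes `monthly_rates` and `issues`.
#' @export
practice_coverage <- function(events, registrations, practice_meta,
                              params = presence_params(), monthly = NULL) {
  params <- as_params(params)
  pm <- copy(as.data.table(practice_meta))
  pm[, in_sail := as.logical(in_sail)]
  pm[, extract_date := as_idate(extract_date)]
  if (is.null(monthly)) {
    monthly <- monthly_rates(events, registrations, pm, params)
  }
  refs <- attr(monthly, "reference_years")
  if (is.null(refs)) {
    # monthly table came from disk; re-derive reference years cheaply
    reg <- materialize_open_ends(registrations, censor_date(pm))
    refs <- rbindlist(lapply(pm[in_sail == TRUE, practice_id], function(p) {
      ry <- tryCatch(choose_reference_year(reg, p, params),
                     error = function(e) NA_integer_)
      data.table(practice_id = p, reference_year = as.integer(ry))
    }))
  }
  issues <- attr(monthly, "issues")
  if (is.null(issues)) issues <- data.table(practice_id = character(0),
                                            issue = character(0))
  prac <- pm[in_sail == TRUE]
  out <- vector("list", nrow(prac))
  for (i in seq_len(nrow(prac))) {
    p <- prac$practice_id[i]
    m <- monthly[practice_id == p]
    ry <- if (!is.null(refs)) refs[practice_id == p, reference_year] else NA_integer_
    ds <- de <- data.table::as.IDate(NA)
    if (nrow(m) && length(ry) == 1L && !is.na(ry)) {
      ds <- infer_start_date(m, params)
      de <- infer_end_date(m, prac$extract_date[i], params)
      if (!is.na(ds) && !is.na(de) && ds > de) {
        issues <- rbind(issues, data.table(practice_id = p,
                                           issue = "start_after_end"))
        ds <- de <- data.table::as.IDate(NA)
      }
    }
    out[[i]] <- data.table(practice_id = p, data_start = ds, data_end = de,
                           reference_year = if (length(ry)) ry else NA_integer_)
  }
  cov <- rbindlist(out)
  setorder(cov, practice_id)
  if (nrow(issues)) {
    warning(sprintf("coverage not determined for %d practice(s): %s",
                    uniqueN(issues$practice_id),
                    paste(unique(issues$issue), collapse = ", ")),
            call. = FALSE)
  }
  setattr(cov, "monthly_rates", monthly)
  setattr(cov, "issues", issues)
  cov[]
}
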