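# Date conventions used throughout:
#  - all spells are CLOSED intervals [start, end]; a person registered on
#    both endpoint days; adjacency means next.start == prev.end + 1
#  - open-ended registrations are materialized to a finite censor date
#  - months are indexed as year * 12 + (month - 1) for calendar arithmetic

as_idate <- function(x) {
  if (inherits(x, "IDate")) return(x)
  data.table::as.IDate(x)
}

month_index <- function(d) {
  lt <- as.POSIXlt(as_idate(d))
  (lt$year + 1900L) * 12L + lt$mon
}

month_index_to_start <- function(i) {
  data.table::as.IDate(sprintf("%04d-%02d-01", i %/% 12L, i %% 12L + 1L))
}

month_floor <- function(d) {
  month_index_to_start(month_index(d))
}

month_end <- function(d) {
  month_index_to_start(month_index(d) + 1L) - 1L
}

fifteenth <- function(i) {
  data.table::as.IDate(sprintf("%04d-%02d-15", i %/% 12L, i %% 12L + 1L))
}

is_weekday <- function(d) {
  wd <- data.table::wday(as_idate(d)) # 1 = Sunday ... 7 = Saturday
  wd >= 2L & wd <= 6L
}

add_years <- function(d, k) {
  lt <- as.POSIXlt(as_idate(d))
  lt$year <- lt$year + as.integer(k)
  data.table::as.IDate(as.Date(lt)) # Feb 29 + 1y normalizes to Mar 1
}

#' Whole days strictly between two registration spells
#'
#' The gap between a spell ending on `prev_end` and a later spell starting on
#' `next_start` is the number of days on which the person is covered by
#' neither: `next_start - prev_end - 1`. Adjacent spells (the second starts
#' the day after the first ends) have gap 0 and need no closing; a gap in
#' `[1, max_gap_days]` is closable by [close_gaps()].
#'
#' @param prev_end End date of the earlier spell (vectorised).
#' @param next_start Start date of the later spell (vectorised).
#' @return Integer vector of gap lengths in days.
#' @examples
#' interval_gap(as.Date("2010-03-31"), as.Date("2010-04-01")) # 0, adjacent
#' interval_gap(as.Date("2010-03-31"), as.Date("2010-04-20")) # 19
#' @export
interval_gap <- function(prev_end, next_start) {
  prev_end <- as_idate(prev_end)
  next_start <- as_idate(next_start)
  if (any(next_start <= prev_end)) {
    stop("interval_gap(): records overlap or are out of order ",
         "(next_start must be after prev_end)", call. = FALSE)
  }
  as.integer(next_start) - as.integer(prev_end) - 1L
}

#' Global censor date of a dataset
#'
#' Open-ended registrations are truncated at the latest data-extract date
#' across all contributing practices: beyond it, nothing can be observed.
#'
#' @param practice_meta Practice metadata table with columns `practice_id`,
#'   `in_sail`, `extract_date`.
#' @return An `IDate` scalar.
#' @export
censor_date <- function(practice_meta) {
  pm <- as.data.table(practice_meta)
  ed <- as_idate(pm$extract_date)
  ed <- ed[!is.na(ed)]
  if (!length(ed)) stop("censor_date(): no extract_date available", call. = FALSE)
  max(ed)
}

#' Materialize open-ended registrations
#'
#' Replaces missing end dates (still-registered spells) with the censor date
#' and clips any end beyond it; spells starting after the censor are dropped.
#'
#' @param registrations Registration table (`person_id`, `practice_id`,
#'   `start`, `end`; `end` may be `NA` for open spells).
#' @param censor Censor date; see [censor_date()].
#' @return A `data.table` with finite `IDate` `start`/`end`.
#' @export
materialize_open_ends <- function(registrations, censor) {
  reg <- copy(as.data.table(registrations))
  censor <- as_idate(censor)
  reg[, `:=`(start = as_idate(start), end = as_idate(end))]
  reg[is.na(end), end := censor]
  reg[end > censor, end := censor]
  dropped <- reg[start > censor]
  if (nrow(dropped)) {
    warning(sprintf("%d registration(s) starting after the censor date dropped",
                    nrow(dropped)), call. = FALSE)
    reg <- reg[start <= censor]
  }
  bad <- reg[end < start]
  if (nrow(bad)) {
    stop("materialize_open_ends(): registrations with end < start; ",
         "validate inputs with load_tables()", call. = FALSE)
  }
  reg[]
}
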