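# Step 2b: turn cleaned registration histories into presence records by
# closing short gaps, splitting at practice coverage boundaries, merging
# adjacent records under the grouping semantics, and subtracting known
# per-person exclusion periods. Gap closing runs BEFORE coverage splitting
# so that a closed gap inherits the second practice's coverage status (the
# person would have registered earlier had care been needed); splitting
# always precedes merging.

#' Close short gaps between consecutive registrations
#'
#' A gap of 1 to `max_gap_days` uncovered days between consecutive spells is
#' attributed to the second practice — short registration gaps reflect
#' delayed re-registration after a move, not genuine absence from the
#' covered population — by moving the second spell's start to the day after
#' the first ends. Longer gaps are untouched; `max_gap_days = 0` disables
#' the rule.
#'
#' @param history Cleaned, sorted, non-overlapping registrations (one or
#'   more persons).
#' @param max_gap_days Longest closable gap in days.
#' @return `data.table` with adjusted starts.
#' @export
close_gaps <- function(history, max_gap_days = 30L) {
  h <- copy(as.data.table(history))
  h[, `:=`(start = as_idate(start), end = as_idate(end))]
  setorder(h, person_id, start)
  if (max_gap_days <= 0L || nrow(h) < 2L) return(h[])
  h[, prev_end := data.table::shift(end), by = person_id]
  h[, gap := as.integer(start) - as.integer(prev_end) - 1L]
  h[!is.na(gap) & gap >= 1L & gap <= as.integer(max_gap_days),
    start := prev_end + 1L]
  h[, c("prev_end", "gap") := NULL]
  h[]
}

#' Split registrations at practice coverage boundaries
#'
#' Intersects each spell with its practice's inferred data coverage
#' `[data_start, data_end]`. The covered middle gets `sail_data = TRUE`; any
#' leading or trailing remainder gets `FALSE`, so one spell can yield up to
#' three records. Spells at practices without coverage (not contributing, or
#' coverage undetermined) come back whole with `sail_data = FALSE`.
#' Splitting is done first, before any combining logic.
#'
#' @param records Cleaned registrations (one or more persons).
#' @param coverage Coverage table from [practice_coverage()].
#' @return `data.table` with an added logical `sail_data` column.
#' @export
split_by_coverage <- function(records, coverage) {
  r <- copy(as.data.table(records))
  r[, `:=`(start = as_idate(start), end = as_idate(end))]
  cov <- as.data.table(coverage)[!is.na(data_start) & !is.na(data_end),
                                 .(practice_id, data_start = as_idate(data_start),
                                   data_end = as_idate(data_end))]
  r[cov, on = "practice_id", `:=`(data_start = i.data_start, data_end = i.data_end)]
  keep_cols <- setdiff(names(r), c("data_start", "data_end"))

  seg <- function(s, e, flag) {
    out <- copy(r)[, `:=`(start = s, end = e, sail_data = flag)]
    out[!is.na(start) & !is.na(end) & start <= end,
        c(keep_cols, "sail_data"), with = FALSE]
  }
  no_cov <- is.na(r$data_start)
  pre_s <- data.table::fifelse(no_cov, r$start, r$start)
  pre_e <- data.table::fifelse(no_cov, r$end, pmin(r$end, r$data_start - 1L))
  mid_s <- data.table::fifelse(no_cov, as_idate(NA), pmax(r$start, r$data_start))
  mid_e <- data.table::fifelse(no_cov, as_idate(NA), pmin(r$end, r$data_end))
  post_s <- data.table::fifelse(no_cov, as_idate(NA), pmax(r$start, r$data_end + 1L))
  post_e <- data.table::fifelse(no_cov, as_idate(NA), r$end)
  out <- rbindlist(list(seg(pre_s, pre_e, FALSE),
                        seg(mid_s, mid_e, TRUE),
                        seg(post_s, post_e, FALSE)))
  setorder(out, person_id, start)
  out[]
}

#' Merge adjacent records under the grouping semantics
#'
#' Two adjacent records (the second starts the day after the first ends)
#' merge unless a grouping variable forbids it: with
#' `group_on_sail_data = 1` records with different availability flags never
#' combine, with `group_on_practice = 1` records from different practices
#' never combine. The four combinations yield: (0,0) continuous any-GP
#' registration; (1,0) periods with data available; (0,1) cleaned
#' per-practice history; (1,1) cleaned history with an availability flag.
#' When records from different practices merge the practice id becomes `NA`
#' (identity collapsed); when records with different flags merge the flag
#' becomes `NA` (not tracked).
#'
#' @param records Sorted, non-overlapping records with a `sail_data` column.
#' @param params A [presence_params()] object.
#' @return `data.table` of presence records.
#' @export
merge_adjacent <- function(records, params = presence_params()) {
  params <- as_params(params)
  r <- copy(as.data.table(records))
  r[, `:=`(start = as_idate(start), end = as_idate(end))]
  setorder(r, person_id, start)
  pid <- r$person_id
  new_person <- c(TRUE, pid[-1L] != pid[-length(pid)])
  adj <- c(FALSE, as.integer(r$start[-1L]) == as.integer(r$end[-nrow(r)]) + 1L)
  same_sail <- c(TRUE, {
    a <- r$sail_data[-1L]; b <- r$sail_data[-nrow(r)]
    (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  })
  same_prac <- c(TRUE, {
    a <- r$practice_id[-1L]; b <- r$practice_id[-nrow(r)]
    (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  })
  blocked <- new_person | !adj |
    (params$group_on_sail_data == 1L & !same_sail) |
    (params$group_on_practice == 1L & !same_prac)
  r[, grp := cumsum(blocked)]
  out <- r[, .(
    person_id = person_id[1L],
    practice_id = if (uniqueN(practice_id, na.rm = FALSE) == 1L)
      practice_id[1L] else NA_character_,
    start = start[1L],
    end = end[.N],
    sail_data = if (uniqueN(sail_data, na.rm = FALSE) == 1L)
      sail_data[1L] else NA
  ), by = grp][, grp := NULL]
  setorder(out, person_id, start)
  out[]
}

#' Subtract per-person exclusion periods
#'
#' Removes known periods of missing individual data (for example historical
#' provisioning faults) from presence records: each record is clipped or
#' split around every overlapping exclusion; empty remainders are dropped.
#'
#' @param records Non-overlapping presence records.
#' @param exclusions Table with `person_id`, `start`, `end`; `NULL` or empty
#'   for none.
#' @return `data.table` in the same schema as `records`.
#' @export
subtract_exclusions <- function(records, exclusions) {
  r <- copy(as.data.table(records))
  if (is.null(exclusions) || !nrow(as.data.table(exclusions))) return(r)
  r[, `:=`(start = as_idate(start), end = as_idate(end))]
  ex <- as.data.table(exclusions)
  ex <- ex[, .(person_id, start = as_idate(start), end = as_idate(end))]
  r[, row_id := .I]
  hits <- ex[r, on = .(person_id, start <= end, end >= start),
             .(row_id = i.row_id, ex_start = x.start, ex_end = x.end),
             nomatch = NULL]
  if (!nrow(hits)) return(r[, row_id := NULL][])
  pieces <- lapply(split(hits, by = "row_id"), function(hh) {
    rid <- hh$row_id[1L]
    rec <- r[row_id == rid]
    segs <- data.table(start = rec$start, end = rec$end)
    for (j in seq_len(nrow(hh))) {
      es <- hh$ex_start[j]; ee <- hh$ex_end[j]
      segs <- rbindlist(list(
        segs[end < es | start > ee],                         # untouched
        segs[start < es & end >= es, .(start, end = es - 1L)],
        segs[start <= ee & end > ee, .(start = ee + 1L, end)]
      ))
      segs <- segs[start <= end]
    }
    if (!nrow(segs)) return(NULL)
    out <- rec[rep(1L, nrow(segs))]
    out[, `:=`(start = segs$start, end = segs$end)]
    out
  })
  untouched <- r[!row_id %in% hits$row_id]
  out <- rbindlist(c(list(untouched), pieces), use.names = TRUE)
  out[, row_id := NULL]
  setorder(out, person_id, start)
  out[]
}

#' Build presence records for every individual
#'
#' Runs step 2 end to end: materialize open spells at the censor date, clean
#' each history, close short gaps, split at coverage boundaries, merge under
#' the grouping semantics, and subtract exclusion periods. Registrations at
#' practices absent from the metadata are treated (with a warning) as not
#' contributing data.
#'
#' @param registrations Raw registration table.
#' @param coverage Coverage table from [practice_coverage()].
#' @param practice_meta Practice metadata table.
#' @param exclusions Optional per-person exclusion periods.
#' @param params A [presence_params()] object.
#' @return `data.table` (`person_id`, `practice_id`, `start`, `end`,
#'   `sail_data`), per person sorted and pairwise non-overlapping, with
#'   attributes `conflicts` (the cleaning audit trail), `censor_date` and
#'   `params`.
#' @export
build_presence <- function(registrations, coverage, practice_meta,
                           exclusions = NULL, params = presence_params()) {
  params <- as_params(params)
  pm <- copy(as.data.table(practice_meta))
  pm[, in_sail := as.logical(in_sail)]
  pm[, extract_date := as_idate(extract_date)]
  censor <- censor_date(pm)
  reg <- materialize_open_ends(registrations, censor)
  unknown <- setdiff(unique(reg$practice_id), pm$practice_id)
  if (length(unknown)) {
    warning(sprintf("%d practice id(s) in registrations missing from metadata; treated as not contributing data",
                    length(unknown)), call. = FALSE)
  }
  cleaned <- clean_history(reg, pm)
  conflicts <- attr(cleaned, "conflicts")
  gapped <- close_gaps(cleaned, params$max_gap_days)
  flagged <- split_by_coverage(gapped, coverage)
  merged <- merge_adjacent(flagged, params)
  out <- subtract_exclusions(merged, exclusions)
  out <- out[, .(person_id, practice_id, start, end, sail_data)]
  setorder(out, person_id, start)
  setattr(out, "conflicts", conflicts)
  setattr(out, "censor_date", censor)
  setattr(out, "params", params)
  out[]
}
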