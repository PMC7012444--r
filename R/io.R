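# Delimited-text readers/writers with row-level validation. Dates are
# ISO-8601; an empty registration end field encodes a still-open spell.
# Rows that cannot be typed are rejected WITH a reason and the run
# continues; nothing is ever dropped silently. Implausible but valid dates
# (1900-01-01, future dates) are retained at load — handling them is the
# algorithm's job, not the parser's.

.parse_iso_date <- function(x) {
  d <- data.table::as.IDate(rep(NA_character_, length(x)))
  ok <- !is.na(x) & nzchar(x)
  suppressWarnings(d[ok] <- data.table::as.IDate(x[ok], format = "%Y-%m-%d"))
  d
}

.parse_flag <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("1", "true", "t", "yes")] <- TRUE
  out[lx %in% c("0", "false", "f", "no")] <- FALSE
  out
}

.need_cols <- function(dt, cols, file) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Load and validate the input tables
#'
#' Reads the four delimited input tables, types every column, rejects (and
#' reports) malformed rows, and materializes open registration ends at the
#' censor date.
#'
#' Schemas (comma-separated, header row, ISO dates):
#' * events: `person_id, practice_id, event_date`
#' * registrations: `person_id, practice_id, start, end` (empty `end` =
#'   still registered)
#' * practices: `practice_id, in_sail, extract_date` (`extract_date`
#'   required when `in_sail`)
#' * exclusions (optional): `person_id, start, end`
#'
#' @param events,registrations,practices,exclusions File paths
#'   (`exclusions` may be `NULL`).
#' @param censor Optional censor date; defaults to the latest extract date.
#' @return List with the typed tables (`events`, `registrations` with
#'   finite ends, `practice_meta`, `exclusions`), the `rejects` report
#'   (`table`, `row`, `reason`) and `censor_date`.
#' @export
load_tables <- function(events, registrations, practices, exclusions = NULL,
                        censor = NULL) {
  rejects <- list()
  note <- function(tbl, rows, reason) {
    if (length(rows)) rejects[[length(rejects) + 1L]] <<-
        data.table(table = tbl, row = rows, reason = reason)
  }

  pr <- fread(practices, colClasses = "character")
  .need_cols(pr, c("practice_id", "in_sail", "extract_date"), practices)
  pr[, in_sail := .parse_flag(in_sail)]
  pr[, extract_date := .parse_iso_date(extract_date)]
  bad <- which(is.na(pr$in_sail))
  note("practices", bad, "unparseable_in_sail")
  bad2 <- which(!is.na(pr$in_sail) & pr$in_sail & is.na(pr$extract_date))
  note("practices", bad2, "in_sail_without_extract_date")
  pm <- pr[setdiff(seq_len(.N), c(bad, bad2))]

  cens <- if (is.null(censor)) censor_date(pm) else as_idate(censor)

  ev <- fread(events, colClasses = "character")
  .need_cols(ev, c("person_id", "practice_id", "event_date"), events)
  ev[, event_date := .parse_iso_date(event_date)]
  bad <- which(is.na(ev$event_date) | !nzchar(ev$person_id) | !nzchar(ev$practice_id))
  note("events", bad, "bad_date_or_missing_id")
  ev <- ev[setdiff(seq_len(.N), bad), .(person_id, practice_id, event_date)]

  rg <- fread(registrations, colClasses = "character")
  .need_cols(rg, c("person_id", "practice_id", "start", "end"), registrations)
  open <- !nzchar(trimws(rg$end)) | is.na(rg$end)
  rg[, `:=`(start = .parse_iso_date(start), end = .parse_iso_date(end))]
  bad_start <- which(is.na(rg$start) | !nzchar(rg$person_id) | !nzchar(rg$practice_id))
  note("registrations", bad_start, "bad_start_or_missing_id")
  bad_end <- setdiff(which(!open & is.na(rg$end)), bad_start)
  note("registrations", bad_end, "bad_end_date")
  inverted <- setdiff(which(!is.na(rg$start) & !is.na(rg$end) & rg$end < rg$start),
                      c(bad_start, bad_end))
  note("registrations", inverted, "end_before_start")
  rg <- rg[setdiff(seq_len(.N), c(bad_start, bad_end, inverted)),
           .(person_id, practice_id, start, end)]
  rg <- materialize_open_ends(rg, cens)

  ex <- NULL
  if (!is.null(exclusions)) {
    ex <- fread(exclusions, colClasses = "character")
    .need_cols(ex, c("person_id", "start", "end"), exclusions)
    ex[, `:=`(start = .parse_iso_date(start), end = .parse_iso_date(end))]
    bad <- which(is.na(ex$start) | is.na(ex$end) | !nzchar(ex$person_id))
    note("exclusions", bad, "bad_date_or_missing_id")
    inverted <- setdiff(which(ex$end < ex$start), bad)
    note("exclusions", inverted, "end_before_start")
    ex <- ex[setdiff(seq_len(.N), c(bad, inverted)), .(person_id, start, end)]
  }

  rejects <- if (length(rejects)) rbindlist(rejects) else
    data.table(table = character(0), row = integer(0), reason = character(0))
  if (nrow(rejects)) {
    warning(sprintf("%d input row(s) rejected; see the rejects report",
                    nrow(rejects)), call. = FALSE)
  }
  list(events = ev, registrations = rg, practice_meta = pm, exclusions = ex,
       rejects = rejects, censor_date = cens)
}

#' Write a synthetic scenario to a directory
#'
#' Writes the four pipeline input tables (`events.csv`,
#' `registrations.csv`, `practices.csv`, `exclusions.csv`) and the ground
#' truth (`truth_practices.csv`, `truth_registrations.csv`,
#' `events_with_flags.csv`, `anomalies.csv`). Registration spells running to
#' the censor are written with an empty end field (still registered).
#'
#' @param scenario An `ehr_scenario` from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "ehr_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  fwrite(scenario$events[, .(person_id, practice_id, event_date)], p("events.csv"))
  reg <- copy(scenario$registrations)
  reg[, end := ifelse(as.integer(end) >= as.integer(scenario$config$censor),
                      "", format(end))]
  fwrite(reg, p("registrations.csv"))
  fwrite(scenario$practice_meta, p("practices.csv"))
  fwrite(scenario$exclusions, p("exclusions.csv"))
  fwrite(scenario$truth$practices, p("truth_practices.csv"))
  fwrite(scenario$truth$registrations, p("truth_registrations.csv"))
  fwrite(scenario$events, p("events_with_flags.csv"))
  fwrite(scenario$truth$anomalies, p("anomalies.csv"))
  invisible(dir)
}
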