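# Step 2a: resolve anomalies in raw registration histories so that each
# person is registered with at most one practice on any given day. Four
# deterministic rules, applied in a fixed order:
#   exact duplicates -> duplicate periods -> nested records -> overlaps.
# Duplicate-period preference runs first (and always, whatever output
# options are requested) so the same records survive regardless of later
# interval mutations. Every mutation is logged as one conflict-report row.

.empty_conflicts <- function() {
  data.table(person_id = character(0), kind = character(0),
             detail = character(0), resolution = character(0))
}

.as_history <- function(history) {
  h <- copy(as.data.table(history))
  stopifnot(all(c("person_id", "practice_id", "start", "end") %in% names(h)))
  h[, `:=`(start = as_idate(start), end = as_idate(end))]
  if (anyNA(h$end)) {
    stop("cleaning requires finite end dates; materialize open ends first",
         call. = FALSE)
  }
  h
}

.fmt_rec <- function(h) {
  sprintf("%s[%s..%s]", h$practice_id, format(h$start), format(h$end))
}

#' Remove exactly duplicated registration rows
#'
#' Rows identical on (person, practice, start, end) collapse to one;
#' survivors are sorted by start date then practice id.
#'
#' @param history Registration records (one or more persons).
#' @return `data.table` with attribute `conflicts` (one row per removal).
#' @export
remove_exact_duplicates <- function(history) {
  h <- .as_history(history)
  h[, dup_id := seq_len(.N), by = .(person_id, practice_id, start, end)]
  dropped <- h[dup_id > 1L]
  out <- h[dup_id == 1L][, dup_id := NULL]
  setorder(out, person_id, start, practice_id, end)
  conf <- if (nrow(dropped)) {
    dropped[, .(person_id, kind = "exact_duplicate", detail = .fmt_rec(.SD),
                resolution = "removed_duplicate_row")]
  } else .empty_conflicts()
  setattr(out, "conflicts", conf)
  out[]
}

#' Resolve duplicate periods across practices
#'
#' When one person holds registrations at different practices over an
#' identical period, exactly one survives, chosen by (1) prefer the practice
#' that contributes data, then (2) prefer the lower practice identifier
#' under lexicographic order. The preference is applied unconditionally so
#' the same record is chosen whatever output options are in force.
#'
#' @inheritParams remove_exact_duplicates
#' @param practice_meta Practice metadata (for the `in_sail` flag);
#'   practices absent from it rank as not contributing.
#' @return `data.table` with attribute `conflicts`.
#' @export
resolve_duplicate_periods <- function(history, practice_meta = NULL) {
  h <- .as_history(history)
  sail <- if (is.null(practice_meta)) {
    data.table(practice_id = character(0), in_sail = logical(0))
  } else {
    pm <- as.data.table(practice_meta)
    pm[, .(practice_id, in_sail = as.logical(in_sail))]
  }
  h[sail, on = "practice_id", in_sail := i.in_sail]
  h[is.na(in_sail), in_sail := FALSE]
  setorder(h, person_id, start, end, -in_sail, practice_id)
  h[, dup_id := seq_len(.N), by = .(person_id, start, end)]
  dropped <- h[dup_id > 1L]
  out <- h[dup_id == 1L][, c("dup_id", "in_sail") := NULL]
  setorder(out, person_id, start, practice_id, end)
  conf <- if (nrow(dropped)) {
    dropped[, .(person_id, kind = "duplicate_period", detail = .fmt_rec(.SD),
                resolution = "kept_preferred_practice")]
  } else .empty_conflicts()
  setattr(out, "conflicts", conf)
  out[]
}

#' Resolve nested registration records
#'
#' A record lying entirely within another record's interval is dropped and
#' the outer record kept unchanged, regardless of either record's
#' data-availability status. Records sharing a start date (not covered by
#' the narrower textbook cases) are treated the same way: the shorter lies
#' inside the longer and is dropped.
#'
#' @inheritParams remove_exact_duplicates
#' @return `data.table` with attribute `conflicts`.
#' @export
resolve_nested <- function(history) {
  h <- .as_history(history)
  setorder(h, person_id, start, -end, practice_id)
  # sorted by start (ties: longest first), a record is nested iff some
  # earlier record's end reaches its end
  h[, nested := {
    run_max <- cummax(c(-.Machine$integer.max, head(as.integer(end), -1L)))
    run_max >= as.integer(end)
  }, by = person_id]
  dropped <- h[nested == TRUE]
  out <- h[nested == FALSE][, nested := NULL]
  setorder(out, person_id, start, practice_id, end)
  conf <- if (nrow(dropped)) {
    dropped[, .(person_id, kind = "nested", detail = .fmt_rec(.SD),
                resolution = "kept_outer_record")]
  } else .empty_conflicts()
  setattr(out, "conflicts", conf)
  out[]
}

#' Resolve partially overlapping registration records
#'
#' For two overlapping records the first (earlier-starting) is shortened to
#' end the day before the second starts: analysis of conflicting records
#' shows the second registration is far more likely to carry the events
#' recorded during the overlap. Chains of overlaps are processed
#' left-to-right by start date. A record whose shortening would empty it is
#' dropped (only reachable when nested records were not resolved first).
#'
#' @inheritParams remove_exact_duplicates
#' @return `data.table` with attribute `conflicts`.
#' @export
resolve_overlaps <- function(history) {
  h <- .as_history(history)
  setorder(h, person_id, start, end, practice_id)
  conf <- list()
  repeat {
    h[, next_start := data.table::shift(start, -1L), by = person_id]
    ov <- which(!is.na(h$next_start) & h$end >= h$next_start)
    if (!length(ov)) break
    sh <- h[ov]
    conf[[length(conf) + 1L]] <-
      sh[, .(person_id, kind = "overlap", detail = .fmt_rec(.SD),
             resolution = sprintf("shortened_to_%s", format(next_start - 1L)))]
    h[ov, end := next_start - 1L]
    empty <- which(h$end < h$start)
    if (length(empty)) {
      ed <- h[empty]
      conf[[length(conf) + 1L]] <-
        ed[, .(person_id, kind = "overlap", detail = .fmt_rec(.SD),
               resolution = "dropped_empty_after_shorten")]
      h <- h[-empty]
    }
    setorder(h, person_id, start, end, practice_id)
  }
  h[, next_start := NULL]
  out <- h
  setattr(out, "conflicts",
          if (length(conf)) rbindlist(conf) else .empty_conflicts())
  out[]
}

#' Clean a registration history
#'
#' Fixed-order composition of the four conflict rules; afterwards each
#' person is registered with at most one practice on any calendar day.
#' Accepts one or many persons. The operation is idempotent and its output
#' does not depend on the input row order.
#'
#' @inheritParams resolve_duplicate_periods
#' @return Sorted, pairwise non-overlapping `data.table` of registrations
#'   with attribute `conflicts`, one row per mutation of the input.
#' @examples
#' h <- data.frame(person_id = "p1", practice_id = c("A", "B"),
#'                 start = as.Date(c("2010-01-01", "2010-05-01")),
#'                 end = as.Date(c("2010-06-30", "2010-12-31")))
#' clean_history(h)
#' @export
clean_history <- function(history, practice_meta = NULL) {
  s1 <- remove_exact_duplicates(history)
  s2 <- resolve_duplicate_periods(s1, practice_meta)
  s3 <- resolve_nested(s2)
  s4 <- resolve_overlaps(s3)
  conf <- rbindlist(list(attr(s1, "conflicts"), attr(s2, "conflicts"),
                         attr(s3, "conflicts"), attr(s4, "conflicts")))
  out <- s4
  setorder(out, person_id, start)
  setattr(out, "conflicts", conf)
  out[]
}
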