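#' Parameters for coverage inference and presence building
#'
#' Collects every tunable of the two-step algorithm in one validated object.
#'
#' @param threshold Normalized event-rate threshold a month must reach to
#'   count as having usable data. The rate is relative to the practice's
#'   reference-year recording rate, so `0.10` means 10% of the practice's
#'   normal recording volume.
#' @param max_gap_days Longest gap (in whole uncovered days) between two
#'   consecutive registrations that is closed by attributing the gap to the
#'   second practice. `0` disables gap closing. Default 30 days.
#' @param min_registered A month's rate is only used when strictly more than
#'   this many people are registered at the practice on the 15th. Default 5.
#' @param reference_year Preferred calendar year used to normalize each
#'   practice's event rate, assumed to postdate electronic recording onset
#'   everywhere. Default 2009.
#' @param reference_min_registrations When the preferred reference year has
#'   no usable months for a practice, the first "complete" year is used
#'   instead: the earliest year with at least this many registration records
#'   starting before its 1 January. Default 100.
#' @param sustain_months The inferred data start is the first month at or
#'   above `threshold` such that the following `sustain_months - 1` usable
#'   months also reach it; guards against isolated backdating spikes.
#'   Default 3.
#' @param group_on_sail_data 0 or 1. When 1, adjacent presence records whose
#'   data-availability flags differ are never merged.
#' @param group_on_practice 0 or 1. When 1, adjacent presence records at
#'   different practices are never merged.
#'
#' @return An object of class `presence_params` (a named list).
#' @examples
#' presence_params(threshold = 0.2, group_on_practice = 1)
#' @export
presence_params <- function(threshold = 0.10,
                            max_gap_days = 30L,
                            min_registered = 5L,
                            reference_year = 2009L,
                            reference_min_registrations = 100L,
                            sustain_months = 3L,
                            group_on_sail_data = 1L,
                            group_on_practice = 0L) {
  p <- list(
    threshold = as.numeric(threshold),
    max_gap_days = as.integer(max_gap_days),
    min_registered = as.integer(min_registered),
    reference_year = as.integer(reference_year),
    reference_min_registrations = as.integer(reference_min_registrations),
    sustain_months = as.integer(sustain_months),
    group_on_sail_data = as.integer(group_on_sail_data),
    group_on_practice = as.integer(group_on_practice)
  )
  stopifnot(
    length(p$threshold) == 1L, is.finite(p$threshold), p$threshold > 0,
    p$max_gap_days >= 0L,
    p$min_registered >= 0L,
    p$reference_min_registrations >= 1L,
    p$sustain_months >= 1L,
    p$group_on_sail_data %in% c(0L, 1L),
    p$group_on_practice %in% c(0L, 1L)
  )
  structure(p, class = "presence_params")
}

#' @export
print.presence_params <- function(x, ...) {
  cat("<presence_params>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_params <- function(params) {
  if (inherits(params, "presence_params")) return(params)
  do.call(presence_params, as.list(params))
}
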