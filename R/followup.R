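# Impact of the follow-up requirement on measured annual event rates.
# Follow-up years are anchored at each person's diagnosis date: year k is
# the closed interval [diagnosis + k years, diagnosis + (k+1) years - 1 day],
# matching rate-by-year-since-diagnosis presentations. Deaths are assumed
# excluded upstream.

#' The five follow-up requirements
#'
#' From no restriction at all to continuous data availability over the whole
#' follow-up horizon.
#' @export
followup_requirements <- c("none", "present_at_diagnosis",
                           "present_at_year_start", "present_entire_year",
                           "present_entire_horizon")

.sail_spans <- function(presence) {
  p <- as.data.table(presence)
  stopifnot("sail_data" %in% names(p))
  p <- p[sail_data == TRUE, .(person_id, start = as_idate(start), end = as_idate(end))]
  p
}

#' Eligibility of cohort members under a follow-up requirement
#'
#' Evaluates, for follow-up year `year_index` (0-based, anchored at each
#' person's diagnosis date), whether each cohort member satisfies the
#' requirement given their periods of available data
#' (`sail_data == TRUE` presence records, typically computed with
#' `group_on_sail_data = 1`).
#'
#' @param presence Presence table from [build_presence()].
#' @param cohort Table with `person_id` and `diagnosis_date`.
#' @param requirement One of [followup_requirements].
#' @param year_index Follow-up year k (0 = year from diagnosis).
#' @param horizon_years Horizon for `present_entire_horizon` (default 10).
#' @return Logical vector, one element per cohort row.
#' @export
eligible <- function(presence, cohort, requirement, year_index = 0L,
                     horizon_years = 10L) {
  requirement <- match.arg(requirement, followup_requirements)
  co <- as.data.table(cohort)
  co <- co[, .(person_id, diagnosis_date = as_idate(diagnosis_date))]
  if (requirement == "none") return(rep(TRUE, nrow(co)))
  sp <- .sail_spans(presence)
  covers <- function(at_start, at_end) {
    q <- copy(co)[, `:=`(at_start = at_start, at_end = at_end)]
    # a single span must contain [at_start, at_end]; unmatched rows join to NA
    n <- sp[q, on = .(person_id, start <= at_start, end >= at_end),
            .(n = sum(!is.na(x.start))), by = .EACHI]$n
    n > 0L
  }
  ys <- add_years(co$diagnosis_date, year_index)
  ye <- add_years(co$diagnosis_date, year_index + 1L) - 1L
  switch(requirement,
    present_at_diagnosis = covers(co$diagnosis_date, co$diagnosis_date),
    present_at_year_start = covers(ys, ys),
    present_entire_year = covers(ys, ye),
    present_entire_horizon = covers(co$diagnosis_date,
                                    add_years(co$diagnosis_date, horizon_years) - 1L))
}

#' Annual outcome rate under a follow-up requirement
#'
#' Among cohort members eligible in follow-up year `year_index`, the
#' fraction with at least one outcome event dated within that year.
#' Undefined (NA) when no one is eligible.
#'
#' @inheritParams eligible
#' @param outcome_events Table with `person_id`, `event_date`.
#' @return A single proportion, or `NA_real_`.
#' @export
annual_rate <- function(cohort, outcome_events, presence, requirement,
                        year_index = 0L, horizon_years = 10L) {
  co <- as.data.table(cohort)
  co <- co[, .(person_id, diagnosis_date = as_idate(diagnosis_date))]
  el <- eligible(presence, co, requirement, year_index, horizon_years)
  if (!any(el)) return(NA_real_)
  ev <- as.data.table(outcome_events)
  ev <- ev[, .(person_id, event_date = as_idate(event_date))]
  sub <- co[el]
  sub[, `:=`(ys = add_years(diagnosis_date, year_index),
             ye = add_years(diagnosis_date, year_index + 1L) - 1L)]
  hit <- ev[sub, on = .(person_id, event_date >= ys, event_date <= ye),
            .(n = sum(!is.na(x.event_date))), by = .EACHI]$n
  mean(hit > 0L)
}

#' Annual rates across requirements and follow-up years
#'
#' @inheritParams annual_rate
#' @param requirements Requirements to evaluate (default all five).
#' @param horizon_years Number of follow-up years.
#' @return `data.table` with `requirement`, `year`, `n_eligible`,
#'   `n_event`, `rate`.
#' @export
followup_rates <- function(cohort, outcome_events, presence,
                           requirements = followup_requirements,
                           horizon_years = 10L) {
  co <- as.data.table(cohort)
  co <- co[, .(person_id, diagnosis_date = as_idate(diagnosis_date))]
  ev <- as.data.table(outcome_events)
  ev <- ev[, .(person_id, event_date = as_idate(event_date))]
  out <- list()
  for (req in requirements) {
    for (k in seq_len(horizon_years) - 1L) {
      el <- eligible(presence, co, req, k, horizon_years)
      sub <- co[el]
      n_ev <- if (nrow(sub)) {
        sub[, `:=`(ys = add_years(diagnosis_date, k),
                   ye = add_years(diagnosis_date, k + 1L) - 1L)]
        hits <- ev[sub, on = .(person_id, event_date >= ys, event_date <= ye),
                   .(n = sum(!is.na(x.event_date))), by = .EACHI]$n
        sum(hits > 0L)
      } else 0L
      out[[length(out) + 1L]] <- data.table(
        requirement = req, year = k, n_eligible = sum(el), n_event = n_ev,
        rate = if (sum(el) > 0L) n_ev / sum(el) else NA_real_)
    }
  }
  rbindlist(out)
}

#' Simulate a diagnosis cohort with presence-conditional outcomes
#'
#' Builds, from a synthetic scenario's ground truth, a cohort of persons
#' diagnosed during their available-data presence, and outcome
#' ("prescription-like") events generated with a constant per-presence-year
#' probability `p_outcome` — scaled by the covered fraction of each
#' follow-up year — so the true rate among fully-present person-years is
#' known (`p_outcome`) and the bias of weaker follow-up requirements can be
#' quantified.
#'
#' @param scenario An `ehr_scenario`.
#' @param p_outcome Probability of an outcome event in a fully covered
#'   follow-up year.
#' @param horizon_years Follow-up horizon.
#' @param seed RNG seed.
#' @return List with `cohort` (`person_id`, `diagnosis_date`), `outcomes`
#'   (`person_id`, `event_date`) and the true sail `presence` used.
#' @export
simulate_cohort <- function(scenario, p_outcome = 0.4, horizon_years = 10L,
                            seed = 1L) {
  stopifnot(inherits(scenario, "ehr_scenario"))
  set.seed(as.integer(seed))
  tp <- true_presence(scenario, presence_params(group_on_sail_data = 1L,
                                                group_on_practice = 0L))
  spans <- tp[sail_data == TRUE]
  first <- spans[, .SD[1L], by = person_id][as.integer(end) - as.integer(start) >= 365L]
  if (!nrow(first)) stop("simulate_cohort(): no person with a year of presence", call. = FALSE)
  # diagnosis within the first presence year, leaving room for follow-up
  first[, diagnosis_date := start + floor(runif(.N) * 365)]
  cohort <- first[, .(person_id, diagnosis_date)]

  yrs <- cohort[, .(k = seq_len(horizon_years) - 1L), by = .(person_id, diagnosis_date)]
  yrs[, `:=`(ys = add_years(diagnosis_date, k),
             ye = add_years(diagnosis_date, k + 1L) - 1L)]
  ov <- spans[yrs, on = .(person_id, start <= ye, end >= ys),
              .(covered = as.numeric(sum(pmin(as.integer(x.end), as.integer(i.ye)) -
                              pmax(as.integer(x.start), as.integer(i.ys)) + 1L,
                              na.rm = TRUE)),
                seg_start = as.numeric(suppressWarnings(
                  max(pmax(as.integer(x.start), as.integer(i.ys)), na.rm = TRUE))),
                seg_end = as.numeric(suppressWarnings(
                  max(pmin(as.integer(x.end), as.integer(i.ye)), na.rm = TRUE)))),
              by = .EACHI]
  yrs[, covered := pmax(0, ov$covered)]
  yrs[, `:=`(seg_start = ov$seg_start, seg_end = ov$seg_end)]
  yrs[, frac := covered / (as.integer(ye) - as.integer(ys) + 1L)]
  yrs[, hit := runif(.N) < p_outcome * frac]
  hits <- yrs[hit == TRUE]
  outcomes <- if (nrow(hits)) {
    hits[, .(person_id,
             event_date = data.table::as.IDate(
               seg_start + floor(runif(.N) * (seg_end - seg_start + 1L)),
               origin = "1970-01-01"))]
  } else {
    data.table(person_id = character(0), event_date = as_idate(character(0)))
  }
  list(cohort = cohort, outcomes = outcomes, presence = tp)
}
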