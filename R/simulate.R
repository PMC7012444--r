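# Synthetic practices, registration histories and event streams with ground
# truth. The generator's job is to reproduce the signatures of the data
# pathologies seen in real registration and event tables — backdated events
# piling up on 1 January and month firsts, sentinel dates (1900-01-01),
# future dates, duplicate/nested/overlapping registration spells, short
# registration gaps — not to calibrate to any real population.
#
# Determinism: every person and every practice draws from its own seed
# derived from the scenario seed, so output is independent of enumeration
# order and bit-identical for identical (config, seed).

.derive_seed <- function(seed, salt, i) {
  as.integer((as.numeric(seed) * 1000003 + salt * 97 + i * 7919) %% 2147483629)
}

#' Configuration of a synthetic scenario
#'
#' Defaults describe a plausible mid-2000s primary-care landscape: 76% of
#' practices contribute data, electronic recording starts abruptly on a
#' month first between 2000 and 2008, people move practice about once a
#' decade and emigrate rarely, and a small fraction of events carries
#' erroneous dates. See the methods vignette for the rationale behind each
#' default.
#'
#' @param n_practices,n_persons Scenario size.
#' @param study_start,censor Observation window; open spells are truncated
#'   at `censor`, which is also every contributing practice's extract date.
#' @param true_start Optional onset date(s) of electronic recording,
#'   recycled across contributing practices; drawn uniformly from month
#'   firsts in 2000–2008 when `NULL`.
#' @param onset_shape `"abrupt"` (recording jumps to steady state) or
#'   `"linear_ramp"` (volume ramps up over `onset_ramp_months`).
#' @param onset_ramp_months Ramp length for `"linear_ramp"`.
#' @param frac_in_sail Proportion of practices contributing data.
#' @param backdating_fraction Proportion of events re-dated before the
#'   practice's recording onset, snapped per `backdate_snap`.
#' @param sentinel_fraction Proportion of events dated 1900-01-01.
#' @param future_fraction Proportion of events dated after the censor.
#' @param events_per_person_month Mean recorded events per registered person
#'   per month at steady state (weekday-weighted).
#' @param move_rate,emigration_rate Per-person-year hazards of changing
#'   practice and of leaving the covered area for good.
#' @param exclusion_rate Per-person probability of one known
#'   missing-data exclusion period.
#' @param anomaly_rates Per-history probabilities of injecting each
#'   registration anomaly (`exact_duplicate`, `nested`, `overlap`,
#'   `duplicate_period`, `short_gap` of 1–30 days, `long_gap` of 31–365
#'   days).
#' @param backdate_snap Probabilities that a backdated event snaps to 1
#'   January, to a month first, or stays unsnapped; must sum to 1.
#' @param seed Scenario seed.
#' @return A `scenario_config` object (named list).
#' @export
scenario_config <- function(n_practices = 10L,
                            n_persons = 500L,
                            study_start = "2000-01-01",
                            censor = "2016-12-31",
                            true_start = NULL,
                            onset_shape = c("abrupt", "linear_ramp"),
                            onset_ramp_months = 12L,
                            frac_in_sail = 0.76,
                            backdating_fraction = 0.05,
                            sentinel_fraction = 0.005,
                            future_fraction = 0.001,
                            events_per_person_month = 1.5,
                            move_rate = 0.10,
                            emigration_rate = 0.02,
                            exclusion_rate = 0,
                            anomaly_rates = list(),
                            backdate_snap = c(jan1 = 0.6, month_first = 0.3, none = 0.1),
                            seed = 1L) {
  onset_shape <- match.arg(onset_shape)
  ar <- utils::modifyList(list(exact_duplicate = 0.01, nested = 0.005,
                               overlap = 0.01, duplicate_period = 0.01,
                               short_gap = 0.05, long_gap = 0.10),
                          as.list(anomaly_rates))
  cfg <- list(
    n_practices = as.integer(n_practices),
    n_persons = as.integer(n_persons),
    study_start = as_idate(study_start),
    censor = as_idate(censor),
    true_start = if (is.null(true_start)) NULL else as_idate(true_start),
    onset_shape = onset_shape,
    onset_ramp_months = as.integer(onset_ramp_months),
    frac_in_sail = frac_in_sail,
    backdating_fraction = backdating_fraction,
    sentinel_fraction = sentinel_fraction,
    future_fraction = future_fraction,
    events_per_person_month = events_per_person_month,
    move_rate = move_rate,
    emigration_rate = emigration_rate,
    exclusion_rate = exclusion_rate,
    anomaly_rates = ar,
    backdate_snap = backdate_snap / sum(backdate_snap),
    seed = as.integer(seed)
  )
  props <- c(cfg$frac_in_sail, cfg$backdating_fraction, cfg$sentinel_fraction,
             cfg$future_fraction, cfg$exclusion_rate, unlist(ar))
  stopifnot(
    cfg$n_practices >= 1L,
    cfg$study_start < cfg$censor,
    all(props >= 0 & props <= 1),
    cfg$events_per_person_month > 0,
    cfg$move_rate >= 0, cfg$emigration_rate >= 0,
    cfg$onset_ramp_months >= 1L
  )
  if (cfg$n_persons < 1L && any(unlist(ar) > 0)) {
    stop("scenario_config(): positive anomaly rates need at least one person",
         call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

# one person's registration history; returns list(clean=, observed=, anomalies=, exclusion=)
.simulate_person <- function(cfg, pid, practice_ids) {
  span <- as.integer(cfg$censor) - as.integer(cfg$study_start)
  entry <- if (runif(1) < 0.7) cfg$study_start else
    cfg$study_start + floor(runif(1) * max(1L, span - 365L))
  person_end <- cfg$censor
  if (cfg$emigration_rate > 0) {
    t_emig <- entry + round(rexp(1, cfg$emigration_rate) * 365.25)
    if (t_emig < person_end) person_end <- as_idate(t_emig)
  }
  if (person_end < entry) person_end <- entry

  starts <- ends <- integer(0)
  pracs <- character(0)
  cur <- entry
  prev_prac <- NA_character_
  repeat {
    dur <- if (cfg$move_rate > 0) max(30, round(rexp(1, cfg$move_rate) * 365.25)) else Inf
    e <- as_idate(min(as.integer(cur) + dur, as.integer(person_end)))
    cand <- setdiff(practice_ids, prev_prac)
    p <- if (length(cand)) sample(cand, 1L) else practice_ids[1L]
    starts <- c(starts, as.integer(cur)); ends <- c(ends, as.integer(e))
    pracs <- c(pracs, p); prev_prac <- p
    if (e >= person_end) break
    cur <- e + 1L
  }
  h <- data.table(person_id = pid, practice_id = pracs,
                  start = as_idate(starts), end = as_idate(ends))
  n <- nrow(h)
  ar <- cfg$anomaly_rates
  anomalies <- character(0)

  # long gaps are real absences: applied before the ground-truth snapshot
  if (n >= 2L && runif(1) < ar$long_gap) {
    j <- sample(2:n, 1L)
    g <- sample(31:365, 1L)
    if (h$start[j] + g + 30L <= h$end[j]) {
      h[j, start := start + g]
      anomalies <- c(anomalies, "long_gap")
    }
  }
  clean <- copy(h)

  obs <- copy(h)
  used_pairs <- integer(0) # second index of pairs already perturbed
  if (n >= 2L && runif(1) < ar$overlap) {
    adj <- which(obs$start[-1L] == obs$end[-n] + 1L) + 1L
    adj <- adj[obs$end[adj] - obs$start[adj] >= 4L]
    if (length(adj)) {
      j <- if (length(adj) == 1L) adj else sample(adj, 1L)
      len <- as.integer(obs$end[j] - obs$start[j])
      k <- sample(seq_len(max(1L, (len - 1L) %/% 2L)), 1L)
      obs[j - 1L, end := obs$start[j] + k - 1L]
      used_pairs <- c(used_pairs, j)
      anomalies <- c(anomalies, "overlap")
    }
  }
  if (n >= 2L && runif(1) < ar$short_gap) {
    adj <- setdiff(which(obs$start[-1L] == obs$end[-n] + 1L) + 1L, used_pairs)
    adj <- adj[obs$end[adj] - obs$start[adj] >= 31L]
    if (length(adj)) {
      j <- if (length(adj) == 1L) adj else sample(adj, 1L)
      g <- sample(1:30, 1L)
      obs[j, start := start + g]
      anomalies <- c(anomalies, "short_gap")
    }
  }
  if (runif(1) < ar$nested) {
    big <- which(obs$end - obs$start >= 3L)
    if (length(big)) {
      j <- if (length(big) == 1L) big else sample(big, 1L)
      len <- as.integer(obs$end[j] - obs$start[j])
      s2 <- obs$start[j] + sample(seq_len(len - 1L), 1L)
      e2 <- s2 + sample(0:as.integer(obs$end[j] - s2), 1L)
      other <- setdiff(practice_ids, obs$practice_id[j])
      if (length(other)) {
        obs <- rbind(obs, data.table(person_id = pid,
                                     practice_id = sample(other, 1L),
                                     start = s2, end = e2))
        anomalies <- c(anomalies, "nested")
      }
    }
  }
  if (runif(1) < ar$duplicate_period) {
    j <- sample(nrow(clean), 1L)
    other <- setdiff(practice_ids, clean$practice_id[j])
    if (length(other)) {
      obs <- rbind(obs, data.table(person_id = pid,
                                   practice_id = sample(other, 1L),
                                   start = clean$start[j], end = clean$end[j]))
      anomalies <- c(anomalies, "duplicate_period")
    }
  }
  if (runif(1) < ar$exact_duplicate) {
    obs <- rbind(obs, obs[sample(nrow(obs), 1L)])
    anomalies <- c(anomalies, "exact_duplicate")
  }

  excl <- NULL
  if (cfg$exclusion_rate > 0 && runif(1) < cfg$exclusion_rate) {
    j <- which(clean$end - clean$start >= 60L)
    if (length(j)) {
      j <- if (length(j) == 1L) j else sample(j, 1L)
      len <- as.integer(clean$end[j] - clean$start[j])
      es <- clean$start[j] + sample(seq_len(len - 31L), 1L)
      ee <- as_idate(min(as.integer(es) + sample(30:180, 1L), as.integer(clean$end[j])))
      excl <- data.table(person_id = pid, start = es, end = ee)
    }
  }
  list(clean = clean, observed = obs,
       anomalies = if (length(anomalies))
         data.table(person_id = pid, kind = anomalies) else NULL,
       exclusion = excl)
}

#' Generate registration histories with ground truth
#'
#' Simulates each person's movement through practices from entry to
#' emigration or the censor, then injects the configured registration
#' anomalies. The pre-injection ("clean") history is the ground truth; long
#' gaps, being genuine absences rather than repairable errors, are part of
#' the truth.
#'
#' @param config A [scenario_config()].
#' @param practice_ids Character vector of available practice ids.
#' @return List with `registrations` (observed, anomalous), `clean`
#'   (ground-truth histories), `anomalies` (per-person injection log) and
#'   `exclusions`.
#' @export
generate_population <- function(config,
                                practice_ids = sprintf("PR%03d", seq_len(config$n_practices))) {
  stopifnot(inherits(config, "scenario_config"))
  res <- vector("list", config$n_persons)
  for (i in seq_len(config$n_persons)) {
    set.seed(.derive_seed(config$seed, 1L, i))
    res[[i]] <- .simulate_person(config, sprintf("ID%06d", i), practice_ids)
  }
  list(
    registrations = rbindlist(lapply(res, `[[`, "observed")),
    clean = rbindlist(lapply(res, `[[`, "clean")),
    anomalies = {
      a <- rbindlist(lapply(res, `[[`, "anomalies"))
      if (nrow(a)) a else data.table(person_id = character(0), kind = character(0))
    },
    exclusions = {
      e <- rbindlist(lapply(res, `[[`, "exclusion"))
      if (nrow(e)) e else data.table(person_id = character(0),
                                     start = as_idate(character(0)),
                                     end = as_idate(character(0)))
    }
  )
}

#' Generate the event stream of one practice
#'
#' Weekday-weighted Poisson event counts per registered person-day, starting
#' at the practice's true recording onset (abruptly or along a linear ramp),
#' with the configured fractions of events re-dated before onset
#' (backdating, snapped to 1 January or month firsts), to the 1900-01-01
#' sentinel, or into the future.
#'
#' @param config A [scenario_config()].
#' @param practice List or one-row table with `practice_id`, `true_start`,
#'   `true_end`.
#' @param registrations Ground-truth registration spells (all practices;
#'   filtered internally).
#' @param seed Optional seed for this practice's stream.
#' @return `data.table` (`person_id`, `practice_id`, `event_date`,
#'   `erroneous`).
#' @export
generate_practice_events <- function(config, practice, registrations, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr_id <- practice$practice_id
  ts <- as_idate(practice$true_start)
  te <- as_idate(practice$true_end)
  empty <- data.table(person_id = character(0), practice_id = character(0),
                      event_date = as_idate(character(0)), erroneous = logical(0))
  reg <- as.data.table(registrations)[practice_id == pr_id]
  if (!nrow(reg) || is.na(ts)) return(empty)
  reg[, `:=`(s = pmax(start, ts), e = pmin(end, te))]
  reg <- reg[s <= e]
  if (!nrow(reg)) return(empty)
  reg[, spell_id := .I]
  dd <- reg[, .(day = seq(s, e, by = "day")), by = .(spell_id, person_id)]
  # steady-state mean epm per month; weekdays carry 10x the weekend weight
  base <- config$events_per_person_month * 12 / 365.25
  scale <- 7 / 5.2
  dd[, lambda := base * scale * data.table::fifelse(is_weekday(day), 1, 0.1)]
  if (config$onset_shape == "linear_ramp") {
    ramp_days <- config$onset_ramp_months * 30.44
    dd[, lambda := lambda * pmin(1, as.numeric(day - ts + 1L) / ramp_days)]
  }
  dd[, n := rpois(.N, lambda)]
  dd <- dd[n > 0L]
  if (!nrow(dd)) return(empty)
  ev <- dd[rep(seq_len(.N), n), .(person_id, event_date = day)]
  ev[, `:=`(practice_id = pr_id, erroneous = FALSE)]

  nev <- nrow(ev)
  u <- runif(nev)
  bf <- config$backdating_fraction
  sf <- config$sentinel_fraction
  ff <- config$future_fraction
  backdated <- u < bf
  sentinel <- u >= bf & u < bf + sf
  future <- u >= bf + sf & u < bf + sf + ff
  if (any(backdated)) {
    nb <- sum(backdated)
    y0 <- data.table::year(ts)
    yr <- sample(seq.int(max(1950L, y0 - 10L), y0 - 1L), nb, replace = TRUE)
    v <- runif(nb)
    orig_mon <- data.table::month(ev$event_date[backdated])
    newd <- data.table::as.IDate(sprintf("%04d-01-01", yr)) +
      data.table::fifelse(v < config$backdate_snap[["jan1"]], 0L,
        data.table::fifelse(v < config$backdate_snap[["jan1"]] + config$backdate_snap[["month_first"]],
          as.integer(data.table::as.IDate(sprintf("%04d-%02d-01", yr, orig_mon)) -
                     data.table::as.IDate(sprintf("%04d-01-01", yr))),
          sample(0:364, nb, replace = TRUE)))
    ev[backdated, event_date := newd]
  }
  if (any(sentinel)) ev[sentinel, event_date := data.table::as.IDate("1900-01-01")]
  if (any(future)) {
    ev[future, event_date := config$censor + sample(1:1095, sum(future), replace = TRUE)]
  }
  ev[backdated | sentinel | future, erroneous := TRUE]
  setcolorder(ev, c("person_id", "practice_id", "event_date", "erroneous"))
  ev[]
}

#' Generate a full synthetic scenario
#'
#' Produces the four input tables of the pipeline (events, registrations,
#' practice metadata, exclusions) plus the ground truth needed to test it:
#' true per-practice recording periods, clean registration histories, the
#' anomaly-injection log, and an `erroneous` flag on every event.
#'
#' @param config A [scenario_config()].
#' @return An object of class `ehr_scenario`: a list with elements
#'   `events`, `registrations`, `practice_meta`, `exclusions`, `truth`
#'   (list: `practices`, `registrations`, `anomalies`) and `config`.
#' @examples
#' sc <- generate_scenario(scenario_config(n_practices = 3, n_persons = 20, seed = 7))
#' sc
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(.derive_seed(config$seed, 0L, 0L))
  n <- config$n_practices
  ids <- sprintf("PR%03d", seq_len(n))
  in_sail <- runif(n) < config$frac_in_sail
  if (!any(in_sail)) in_sail[1L] <- TRUE
  ts <- if (!is.null(config$true_start)) {
    rep(as_idate(config$true_start), length.out = n)
  } else {
    # recording onsets on month firsts, 2000-01 .. 2008-12
    month_index_to_start(sample((2000L * 12L):(2008L * 12L + 11L), n, replace = TRUE))
  }
  extract <- rep(config$censor, n)
  truth_prac <- data.table(
    practice_id = ids, in_sail = in_sail,
    true_start = data.table::fifelse(in_sail, ts, as_idate(NA)),
    true_end = data.table::fifelse(in_sail, extract - 1L, as_idate(NA)),
    extract_date = data.table::fifelse(in_sail, extract, as_idate(NA))
  )
  practice_meta <- truth_prac[, .(practice_id, in_sail, extract_date)]

  pop <- generate_population(config, ids)

  ev_list <- vector("list", n)
  for (j in seq_len(n)) {
    if (!in_sail[j]) next
    ev_list[[j]] <- generate_practice_events(
      config, truth_prac[j], pop$clean,
      seed = .derive_seed(config$seed, 2L, j))
  }
  events <- rbindlist(ev_list[!vapply(ev_list, is.null, logical(1L))])
  if (is.null(events) || !nrow(events)) {
    events <- data.table(person_id = character(0), practice_id = character(0),
                         event_date = as_idate(character(0)), erroneous = logical(0))
  }
  setorder(events, practice_id, person_id, event_date)

  structure(list(
    events = events,
    registrations = pop$registrations,
    practice_meta = practice_meta,
    exclusions = pop$exclusions,
    truth = list(practices = truth_prac, registrations = pop$clean,
                 anomalies = pop$anomalies),
    config = config
  ), class = "ehr_scenario")
}

#' @export
print.ehr_scenario <- function(x, ...) {
  cat(sprintf(
    "<ehr_scenario> %d practices (%d contributing), %d persons, %d registrations, %d events (%.1f%% erroneous)\n",
    nrow(x$practice_meta), sum(x$practice_meta$in_sail),
    uniqueN(x$registrations$person_id), nrow(x$registrations),
    nrow(x$events), 100 * mean(x$events$erroneous)))
  invisible(x)
}

#' Ground-truth presence intervals of a synthetic scenario
#'
#' Day-level construction of each person's true presence under given
#' grouping semantics, from the clean histories and true practice recording
#' periods (not from the pipeline's interval algebra): days are expanded,
#' short registration gaps filled towards the second practice, availability
#' flagged against the true coverage, exclusion days removed, and runs
#' collapsed back to intervals.
#'
#' @param scenario An `ehr_scenario`.
#' @param params A [presence_params()] object (grouping flags and
#'   `max_gap_days` are honoured).
#' @return `data.table` (`person_id`, `practice_id`, `start`, `end`,
#'   `sail_data`) like [build_presence()].
#' @export
true_presence <- function(scenario, params = presence_params()) {
  stopifnot(inherits(scenario, "ehr_scenario"))
  params <- as_params(params)
  reg <- copy(scenario$truth$registrations)
  reg[, spell_id := .I]
  dd <- reg[, .(day = seq(start, end, by = "day")),
            by = .(spell_id, person_id, practice_id)]
  setorder(dd, person_id, day)
  if (params$max_gap_days > 0L) {
    dd[, prev_day := data.table::shift(day), by = person_id]
    g <- as.integer(dd$day) - as.integer(dd$prev_day) - 1L
    fills <- dd[!is.na(prev_day) & g >= 1L & g <= params$max_gap_days,
                .(person_id, practice_id, from = prev_day + 1L, to = day - 1L)]
    if (nrow(fills)) {
      fills[, spell_id := .I]
      fill_days <- fills[, .(day = seq(from, to, by = "day")),
                         by = .(spell_id, person_id, practice_id)]
      dd <- rbind(dd[, .(person_id, practice_id, day)],
                  fill_days[, .(person_id, practice_id, day)])
    } else {
      dd <- dd[, .(person_id, practice_id, day)]
    }
  } else {
    dd <- dd[, .(person_id, practice_id, day)]
  }
  tp <- scenario$truth$practices
  dd[tp, on = "practice_id",
     sail_data := i.in_sail & !is.na(i.true_start) &
       day >= i.true_start & day <= i.true_end]
  dd[is.na(sail_data), sail_data := FALSE]
  ex <- scenario$exclusions
  if (!is.null(ex) && nrow(ex)) {
    exd <- as.data.table(ex)[, .(day = seq(as_idate(start), as_idate(end), by = "day")),
                             by = person_id]
    dd <- dd[!exd, on = .(person_id, day)]
  }
  setorder(dd, person_id, day)
  np <- c(TRUE, dd$person_id[-1L] != dd$person_id[-nrow(dd)])
  brk <- np | c(TRUE, as.integer(dd$day[-1L]) != as.integer(dd$day[-nrow(dd)]) + 1L)
  if (params$group_on_sail_data == 1L) {
    brk <- brk | c(TRUE, dd$sail_data[-1L] != dd$sail_data[-nrow(dd)])
  }
  if (params$group_on_practice == 1L) {
    brk <- brk | c(TRUE, dd$practice_id[-1L] != dd$practice_id[-nrow(dd)])
  }
  dd[, grp := cumsum(brk)]
  out <- dd[, .(
    person_id = person_id[1L],
    practice_id = if (uniqueN(practice_id) == 1L) practice_id[1L] else NA_character_,
    start = day[1L], end = day[.N],
    sail_data = if (uniqueN(sail_data) == 1L) sail_data[1L] else NA
  ), by = grp][, grp := NULL]
  setorder(out, person_id, start)
  out[]
}
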