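---
title: "Measuring follow-up time: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring follow-up time: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrpresence)
library(data.table)
```

## The model

An individual's follow-up time in a primary-care databank is the
intersection of two processes: the *dataset's* coverage (which practices
contribute, and over what period each has usable electronic data) and the
*individual's* trajectory through that coverage (registration spells,
moves, absences). Neither is directly observed. The recording onset of a
practice is unknown — event dates cannot be trusted near the boundary
because systems accept arbitrary dates, producing sentinel values
(1900-01-01 is the classic), future dates, and legitimate backdating piled
on 1 January and month firsts. Registration histories carry duplicate rows,
spells nested inside others, partial overlaps between practices (which
administrative rules forbid, so they are errors) and identical spells at
two practices.

`ehrpresence` therefore estimates coverage from *aggregate* event volumes,
and cleans histories with *deterministic* rules. A deliberate principle is
inherited from the problem setting: whether an individual has events
recorded is never used as evidence of that individual's presence —
doing so would bias the covered population toward service users.

### Step 1: practice coverage from event rates

For practice $p$ and calendar month $m$, let $n_{pm}$ be the number of
distinct persons registered on the 15th and $x_{pmd}$ the event count on
weekday $d$ (Mon–Fri, zero-filled). The raw rate is

$$ r_{pm} = \mathrm{median}_d(x_{pmd}) \, / \, n_{pm}, $$

excluded ($\mathrm{NA}$) when $n_{pm} \le 5$ — months with almost no
registrations signal missing registration data, not absent recording. The
median is taken **across weekday calendar days**, not across persons: the
rationale for a median at all is robustness to single-day spikes
(backdating piles, bulk uploads), which only a median over days provides.
Weekends are excluded because recording is a weekday activity; public
holidays are *not* excluded (they are jurisdiction-specific and unknowable
in general) — they appear as occasional low-count weekdays that the median
absorbs.

Rates are normalized per practice by the median of the non-excluded monthly
rates of a reference year: 2009 where the practice has usable months then
(2009 is taken to postdate recording onset everywhere), otherwise the first
*complete* year — the earliest with at least 100 registration records
starting before its 1 January. The user-facing `threshold` (default 0.10)
is applied to this normalized series, so "10%" means a tenth of the
practice's own normal recording volume.

**Start rule.** Onset ramps are gradual at many practices and isolated
pre-onset months can cross any threshold by backdating alone. The inferred
`data_start` is therefore the first day of the earliest month at or above
the threshold that is *sustained*: the next `sustain_months - 1` usable
months (default 2 more, i.e. three in a row) also reach it. Excluded months
are skipped as missing rather than counted as zeros, for the same reason
they are excluded from the rate series. A bare first-crossing rule is
recovered with `sustain_months = 1`.

**End rule.** The natural end is the day before the practice's last data
extract. It is accepted if the last usable month on record still meets the
threshold; otherwise (a practice that closed and was extracted much later)
the end is pulled back to the last day of the latest month that met it. Two
numerical choices guard this check: months after `extract_date - 1` never
enter the series, so future-dated errors cannot extend coverage; and a
trailing *partial* extract month is dropped from the series, because its
post-extract days would be zero-filled and could fake a premature stop. The
same user threshold is used at both ends.

### Step 2: individual presence

Cleaning applies four rules per person, in a fixed order chosen so that the
always-applied duplicate-period preference acts on unmutated records:

1. *Exact duplicates* collapse to one row.
2. *Duplicate periods* (identical span, different practices) keep one
   record: prefer the practice contributing data, then the lower practice
   id under lexicographic order. Applied regardless of requested output,
   so the surviving record never depends on options.
3. *Nested records* keep the outer record, whatever either record's
   data-availability status. Spells sharing a start date (a case the three
   textbook rules do not cover) are treated as nested — the longer
   survives — which minimizes fragmentation.
4. *Overlaps* shorten the first record to end the day before the second
   starts; in observed conflicting pairs the second registration is far
   more likely to hold the overlap-period events. Chains of three or more
   overlapping records are processed left-to-right by start date to a
   fixed point.

After cleaning: gaps of 1–`max_gap_days` uncovered days (default 30)
between consecutive spells are closed by extending the *second* spell
backwards — a short gap is a re-registration delay, and someone needing
care during it would have registered sooner; spells are split at coverage
boundaries into `sail_data` TRUE/FALSE segments; adjacent segments merge
unless a grouping switch (`group_on_sail_data`, `group_on_practice`)
forbids it; per-person exclusion periods (known missing data) are
subtracted last.

Interval conventions: all spells are closed on both ends, adjacency means
`next.start == prev.end + 1`, and the gap between spells counts the days
covered by neither, so "closable" means `interval_gap` in
`[1, max_gap_days]`. Open-ended spells are materialized at a global censor
date (the latest extract date) when loaded. Where merging collapses
practice identity the id becomes `NA`; where it spans mixed availability
the flag becomes `NA` (not tracked) rather than a misleading boolean.

Ordering was genuinely open in one place: whether gap closing runs before
or after coverage splitting. It runs **before**, so a closed gap inherits
the second practice's coverage status, consistent with the delayed
re-registration rationale. (Splitting before merging is fixed by the
semantics themselves.)

## Parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.10 | normalized monthly rate a month must reach |
| `sustain_months` | 3 | consecutive usable months required at threshold |
| `min_registered` | 5 | strict lower bound of the monthly denominator |
| `reference_year` | 2009 | preferred normalization year |
| `reference_min_registrations` | 100 | records defining a "complete" fallback year |
| `max_gap_days` | 30 | longest closable registration gap (days) |
| `group_on_sail_data` | 1 | never merge across availability change |
| `group_on_practice` | 0 | never merge across practice change |

## The synthetic world

No deposited dataset exists for this problem, so the generator *is* the
test bed. Its defaults state one plausible world and are not tuned per
test:

* 76% of practices contribute data (the participation level of the real
  setting); recording starts abruptly on a month first drawn from
  2000–2008 (practices adopt systems at month boundaries; a
  `linear_ramp` onset is available); every contributing practice is
  extracted at the censor date, 2016-12-31.
* 1.5 events per registered person-month at steady state, weekday-weighted
  10:1 — roughly the order of real consultation-plus-coding volumes.
* 5% of events are backdated before onset (snapped to 1 January with
  probability 0.6, a month first with 0.3, unsnapped otherwise), 0.5% get
  the 1900-01-01 sentinel, 0.1% future dates.
* people change practice with hazard 0.10/year and emigrate for good with
  0.02/year; registration anomalies are injected per history with small
  probabilities (duplicates 1%, nested 0.5%, overlaps 1%, identical
  periods 1%, short gaps 5%, long gaps 10%), matching the rarity of real
  conflicts.

Long gaps are injected *before* the ground-truth snapshot — they are real
absences, not repairable errors; the four conflict anomalies and short
gaps are injected after, so the clean history is the truth the pipeline
should recover. Determinism is per-entity: every person and practice draws
from a seed derived from the scenario seed, so output is independent of
enumeration order.

What the generator does **not** emulate: real Welsh demography, seasonal
consultation patterns, practice closures/mergers, deaths (the follow-up
module assumes the dead are excluded upstream), and un-deregistered
emigrants who silently stop being followed — the one bias the algorithm
cannot repair even on real data. A green test therefore establishes that
the algorithm recovers the stated world's truth, not that any particular
real-data percentage would be reproduced.

## Follow-up impact

`simulate_cohort()` diagnoses each person during their first presence year
and generates outcome events with a constant per-presence-year probability
(scaled by the covered fraction of each diagnosis-anchored year), so the
true rate among fully-present person-years is known exactly — a gold
standard the real analysis lacks. `followup_rates()` then measures annual
rates under five requirements (`none`, `present_at_diagnosis`,
`present_at_year_start`, `present_entire_year`, `present_entire_horizon`).
Follow-up years are anchored at the diagnosis date, matching
rate-by-year-since-diagnosis figures; calendar-year anchoring was the
alternative and is not provided. With no requirement, emigrants stay in
the denominator after their data ends, so the measured rate decays with
follow-up year while the per-year-requirement rate stays near truth — the
attrition-bias signature, which the acceptance suite checks grows over a
ten-year horizon.

```{r impact, eval = FALSE}
sc  <- generate_scenario(scenario_config(n_persons = 800, seed = 41,
                                         emigration_rate = 0.06))
sim <- simulate_cohort(sc, p_outcome = 0.4)
followup_rates(sim$cohort, sim$outcomes, sim$presence,
               c("none", "present_at_year_start"))
```

## Numerical and degenerate-input choices

* Excluded months are `NA` throughout; they propagate through
  normalization and are skipped by both scan rules.
* A zero reference rate or an unfindable reference year is a per-practice
  error: the practice gets `NA` coverage and a logged issue; other
  practices are unaffected.
* Rate months are floored at 1950-01: the sentinel pile can only ever
  occupy its own (excluded, zero-denominator) months.
* Overlap shortening that would empty a record drops it with a logged
  conflict — unreachable when nested records are resolved first, but kept
  for direct calls.
* Registrations starting after the censor are dropped with a warning;
  ends beyond it are clipped.
* Ties everywhere resolve by lexicographic practice id, making every
  output a pure function of the input tables.

## Verification strategy

Every interval operation is checked against an independent day-level
oracle that re-evaluates the rules by brute force (duplicate preference,
containment drop, latest-start-wins ownership, gap filling, per-day
flagging), on fixtures and on thousands of generated persons under all
four grouping combinations. Cleaning is property-tested for idempotence,
permutation invariance, one-registration-per-day and conservation.
Coverage inference is tested for exact recovery in the pathology-free
world, 31-day recovery under 20% backdating, threshold monotonicity,
scale invariance, and the median-vs-mean robustness contrast. The
acceptance suite (`tests/testthat/test-acceptance.R`) states each of these
as a separate criterion; none of its thresholds were adjusted after
measurement.

## Known limitations

* The sustained-crossing start rule and the choice of median for the
  reference rate are this package's documented choices; the underlying
  method is described only as "a threshold" and "with reference to the
  rate".
* Gap semantics: a "gap of 2–30 days" between recorded dates maps here to
  1–30 days actually uncovered (`interval_gap`), a documented
  reinterpretation exposed via `max_gap_days`.
* Practices with very few patients can have legitimately zero median
  weekday counts; their coverage is undetermined rather than guessed.
* No attempt is made to detect un-deregistered emigrants; downstream
  studies must consider this residual loss to follow-up.
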