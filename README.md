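# ehrpresence

Measuring individual follow-up time in routinely-collected primary care
data.

## The problem

Longitudinal studies on routinely-collected health data must know *who is
in the covered population, and when*: a person only counts as "at risk" if
an event, had it occurred, would actually appear in the dataset. In a
primary-care databank this is genuinely hard. Only some GP practices
contribute data; each started electronic recording at an unknown date and
was last extracted at a known one; and each individual has a tangle of
registration spells — moves between practices, moves in and out of the
covered area, plus outright data errors (duplicate rows, overlapping or
nested spells, identical spells at two practices). Using recorded events as
evidence of presence biases the cohort towards the sick; a single
at-baseline check causes silent attrition over follow-up.

`ehrpresence` implements a two-step algorithm that turns event, registration
and practice tables into clean per-person *presence records*:

1. **Practice coverage.** For every contributing practice and calendar
   month, compute the number of persons registered on the 15th (the
   denominator) and the **median** number of events recorded per weekday
   (zero-filled; the median defeats the 1-January / month-first backdating
   piles and bulk-upload spikes that wreck a mean). Rates are normalized to
   a reference year (2009 by default, or the practice's first complete
   year). The data start is the first month whose normalized rate reaches a
   user threshold (default 10%) and sustains it; the data end is the day
   before the last extract, pulled back if recording demonstrably stopped
   earlier.

2. **Individual presence.** Each person's registration history is cleaned
   by deterministic conflict rules — exact duplicates removed; identical
   periods keep the practice contributing data, then the lower id; nested
   spells keep the outer record; overlapping spells shorten the first to
   end just before the second starts — then short gaps (≤ 30 days by
   default) are attributed to the second practice, spells are split at
   coverage boundaries into flagged segments, merged under two grouping
   switches, and known per-person exclusion periods subtracted.

The two switches reproduce four useful outputs:

| `group_on_sail_data` | `group_on_practice` | result |
|---|---|---|
| 0 | 0 | continuous registration with any GP |
| 1 | 0 | periods with data available |
| 0 | 1 | cleaned per-practice registration history |
| 1 | 1 | cleaned history + availability flag |

Because the real databank is access-restricted, the package ships a
synthetic-data generator (`generate_scenario()`) that emulates every
pathology above *with ground truth*, so the whole pipeline is testable at
day-level resolution — and a follow-up impact module (`followup_rates()`)
that quantifies how the choice of follow-up requirement (none / present at
diagnosis / at year start / entire year / entire horizon) distorts measured
annual event rates.

## Worked example

```r
library(ehrpresence)

sc  <- generate_scenario(scenario_config(n_practices = 5, n_persons = 200, seed = 42))
sc
#> <ehr_scenario> 5 practices (4 contributing), 200 persons, 481 registrations,
#>   28498 events (5.7% erroneous)

cov <- practice_coverage(sc$events, sc$registrations, sc$practice_meta)
cov
#>    practice_id data_start   data_end reference_year
#> 1:       PR001 2008-10-01 2016-12-30           2009
#> 2:       PR002 2000-05-01 2016-12-30           2009
#> 3:       PR003 2006-09-01 2016-12-30           2009
#> 4:       PR004 2000-02-01 2016-12-30           2009
```

Each row is a practice's inferred period of usable data: `data_start` is
the first month that sustainably crossed the 10% normalized-rate threshold
(here it recovers every practice's true onset exactly — compare
`sc$truth$practices`), and `data_end` is the day before the extract. The
fifth practice does not contribute data and has no coverage row.

```r
pres <- build_presence(sc$registrations, cov, sc$practice_meta, sc$exclusions)
head(pres, 3)
#>    person_id practice_id      start        end sail_data
#> 1:  ID000001       PR004 2000-01-01 2000-01-31     FALSE
#> 2:  ID000001       PR004 2000-02-01 2016-12-30      TRUE
#> 3:  ID000001       PR004 2016-12-31 2016-12-31     FALSE
```

Person `ID000001` was registered at `PR004` throughout, but the practice's
data only starts 2000-02-01: their registration is split into an
uncovered month, a long covered span (`sail_data = TRUE` — this is their
follow-up time), and the final uncovered day after the data end. The
cleaning audit trail is attached:

```r
attr(pres, "conflicts")[, .N, by = kind]
#>                kind     N
#> 1:  exact_duplicate     3
#> 2: duplicate_period     2
#> 3:           nested     1
#> 4:          overlap     2
```

File-based runs (`run_pipeline()`, or the CLI
`Rscript inst/cli/ehrpresence.R run-all --out DIR`) also persist the
monthly-rate intermediate, reusing it when the inputs' content hashes are
unchanged, and write a `run_metadata.json` recording every parameter and
the censor date.

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end from scratch —
synthetic scenario, table round trip, coverage inference, presence
building and the follow-up impact analysis — and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
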