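Package: ehrpresence
Title: Measuring Individual Follow-Up Time in Routinely-Collected Primary
    Care Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes, for each individual in a routinely-collected primary
    care dataset, the periods over which they are genuinely covered by the
    data ("follow-up time"). A two-step algorithm first infers, per GP
    practice, the period of usable electronic recording from monthly
    event-recording rates (median weekday events per registered person,
    normalized to a reference year, with a user threshold), then converts
    each individual's raw registration history into cleaned, non-overlapping
    presence intervals: exact duplicates, duplicate periods, nested and
    overlapping registrations are resolved by deterministic rules, short
    gaps between consecutive registrations are closed, registrations are
    split at practice data-coverage boundaries and merged under configurable
    grouping semantics. Includes a synthetic-data generator emulating the
    data pathologies of real registration and event tables (backdated and
    sentinel event dates, duplicate and overlapping spells) and tools to
    quantify the impact of different follow-up requirements on measured
    annual event rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
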