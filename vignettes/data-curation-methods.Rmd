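---
title: "Methods: foundational data curation for CDM DataMarts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foundational data curation for CDM DataMarts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmcurate)
```

## The problem

Distributed research networks harmonize each partner's electronic health
record (EHR) data into a common data model (CDM) so that identical queries
can run everywhere. Before a partner's DataMart — its local instantiation
of the CDM, re-extracted ("refreshed") quarterly — can be used for
research, it must clear a *foundational data curation* bar: a standardized
query characterizes the trailing ten years of patient-level data, computes
descriptive statistics, and evaluates a catalog of data checks. Required
check exceptions block approval of the refresh; investigative exceptions
must be investigated and, where remediable, mitigated over subsequent
cycles.

`cdmcurate` implements that engine end to end: a config-driven CDM schema,
a versioned check catalog, threshold-based exception detection with
approval gating, refresh-history persistence analysis, descriptive
statistics, EDC-style reporting — plus a synthetic DataMart generator so
the whole system is exercised without any real patient data.

## The check taxonomy

Checks fall into four categories, following the Kahn data-quality
framework as adapted for lay audiences:

* **conformance** — do values adhere to the CDM's format? (required
  tables/fields present, values parse as their declared kind, coded values
  in their value sets, unique primary keys, resolving foreign keys);
* **completeness** — do values appear where we expect them? (missingness
  of designated fields, terminology mapping coverage, record latency);
* **plausibility** — do the values that appear make sense? (future dates,
  illogical date orderings, out-of-range vitals, volume outliers);
* **persistence** — do large numbers of records appear or disappear
  between refreshes?

A *check* is a broad rule; a *measure* is its instantiation on one table,
field or stratum, so one check may expand to dozens of measures. A check
raises an exception iff any of its applicable measures does; measures with
an empty denominator are `not_applicable` and never count. The packaged
`cycle16` catalog holds 46 checks (the `cycle7` catalog the 36 of them
active in that earlier cycle); each check records whether it is `named`
in the network's public reporting or `reconstructed` here to fill out the
catalog.

## Thresholds

Most checks compare an error proportion against a threshold. The network
default — and the package default — is **< 5% of records in error**; the
comparator expresses the *pass* condition, so a proportion exactly at 0.05
is an exception, with no tolerance fudge (proportions are exact rationals
of integer counts). A handful of checks use other metrics:

* `months` for the latency checks (pass while latency ≤ 3 months);
* `relative_change` for persistence (pass while the drop vs the prior
  refresh is ≤ 5%);
* `absolute_count` for table-population checks (≥ 1 record);
* `ratio` with a **closed band** for the records-per-entity checks
  (encounters per visit in [1.0, 1.5]; diagnoses per encounter in
  [0.5, 30]). The band metric is a small extension of the threshold
  vocabulary: a single comparator cannot express a two-sided plausibility
  band.

Where the network would derive a heuristic threshold from observed
performance (e.g. the 80th percentile), `calibrate_thresholds()` provides
that as an *offline* utility over simulated-network results; evaluation
never adjusts thresholds silently.

## Reconstructed detectors

Three named checks are motivated but not operationally defined in public
descriptions; their detectors are this package's own reconstructions, with
every constant exposed as a catalog parameter:

* **Monthly volume outliers (DC2.08).** For each month *m* of the volume
  series (at least 13 months required), the baseline is the median of the
  surrounding ±6 in-series months excluding *m*; *m* is flagged when its
  count falls below α·baseline or above β·baseline (defaults α = 0.25,
  β = 4.0). The most recent 3 months are not evaluated, since data may
  still be accruing at extraction. The detector is scale invariant by
  construction. The series starts at the first month with data (bounded by
  the lookback window) — a long all-zero prefix would otherwise flag the
  onset of data itself.
* **Latency (DC3.07/3.11/3.14).** The most recent *complete* month is the
  latest month whose count reaches at least 50% of the median of the 12
  preceding months (≥, a closed comparison); latency is the whole-month
  gap from that month to the refresh date, with a 3-month default
  threshold.
* **Persistence (DC4.01–DC4.03).** DC4.01 compares per-table record
  counts, DC4.02 distinct-patient counts, against the immediately prior
  refresh (each windowed to its own refresh date); DC4.03 compares record
  counts per *closed* calendar year — years fully elapsed at the prior
  refresh, so both sides saw the complete year. The 5% decrease threshold
  reuses the network's only stated numeric threshold; an upper bound on
  increases is configurable.

## Boundary conventions

Dates are ISO-8601 calendar dates; all windowing is date-based. "Future"
means strictly after the refresh date — a record dated on the refresh date
is not future. Plausible ranges are closed intervals (a systolic value
exactly at the 260 mmHg bound is inside). The encounter window for linked
diagnoses/procedures is the closed interval
[min(admit, discharge) − W, max(admit, discharge) + W] with W = 7 days by
default; using min/max keeps the window well-defined when
discharge-before-admit is itself the defect under test. Missing values are
`NA`, the empty string, or the `"NI"` (no information) sentinel.

## The lookback window

The curation query characterizes the trailing 10 years. `apply_lookback()`
drops fact-table records *older* than the window start (the boundary day
itself is retained), keeps records with missing dates (and accounts for
them), and keeps records dated after the refresh date — those must remain
visible to the future-date check, so the window is one-sided by design.
DEMOGRAPHIC and DEATH are never windowed directly: DEMOGRAPHIC is
restricted to patients with at least one retained fact record, and DEATH
follows its patients. Calendar years (crosstabs, DC4.03) are plain
calendar years of each table's date field; there is no fiscal-year option.

## The synthetic DataMart generator

`generate_datamart()` builds a clean, fully conformant DataMart —
patients, encounters with a configurable type mix and facility shares,
diagnoses/procedures/labs/prescriptions/vitals per encounter as Poisson
counts, deaths following each patient's last event — and then *injects*
defects per an `error_profile()`, post-generation, logging every injected
defect (table, key, field, kind) in an audit log the check engine never
reads. Injection rather than generation-time weaving gives an exact
per-record oracle: for every proportion-based check, the measured
numerator must equal the audit count exactly, not just statistically.

Design choices that make the oracle exact:

* each record receives at most one defect; later injection modes sample
  only among untouched records;
* a future-date defect shifts the *whole encounter bundle* (admit,
  discharge, and all linked record dates) past the refresh date, logging
  each changed field — so the illogical-date check is not polluted and
  every per-field future-date measure has an exact count;
* encounters of deceased patients are exempt from future-date shifts
  (they would otherwise trip the after-death rule);
* orphan injection avoids principal-flagged diagnoses and
  already-defective encounters, which would silently change the
  principal-diagnosis denominator or numerator;
* deterministic counts where tests need guarantees (deaths are
  `round(rate × n)` patients), while per-record injection stays Bernoulli
  so realized defect fractions follow the exact binomial law.

Monthly encounter volumes carry a mild linear growth trend (30% over the
date range) and a 5% seasonal modulation, giving the volume-outlier
detector a realistic background. Codes are drawn from small packaged toy
LOINC/RxNorm/ICD/CPT lists (no terminology downloads); codes are sampled
without replacement within an encounter, so clean data contain no
duplicate clinical rows. Each record carries a hidden facility tag — not a
CDM field — so feed-level scenario events are realizable.

`generate_refresh_sequence()` generates the full final-period DataMart
once and snapshots it at each refresh date, so refreshes accumulate
consistently; still-open discharges are clamped to the snapshot date.
Scenario events: `feed_loss` permanently drops the facility subset whose
combined share best matches the stated magnitude; `feed_gain` onboards a
new facility (forward-only by default, `backfill = TRUE` to include its
history — public descriptions do not say whether onboarding backfills);
`quarter_gap` drops one calendar quarter from a single refresh;
`etl_change` drops a random fraction of rows of the affected tables from
that refresh onward; `no_submission` omits the refresh entirely (the gray
cells of the refresh grid).

### What the generator does and does not emulate

It emulates the record volumes, coding-system mix, missingness structure
and refresh dynamics that the checks measure. It does **not** emulate
clinical realism — no comorbidity structure, no realistic medication
patterns, no claims data. Passing tests therefore demonstrate that the
*engine* measures what was injected, under volumes and defect rates the
operator controls; they say nothing about how messy real EHR extracts are.

### Fixture sizes

Default populations in tests and experiments are 150–300 patients over a
three-year range (roughly 900–1,800 encounters), and the simulated network
uses 20 DataMarts × 6 cycles at 70 patients each. Below roughly 100
patients the volume-outlier check starts flagging honest Poisson noise
(monthly counts of ~10 against a 0.25 × median floor), which is a real
property of the detector at tiny volumes, not an artifact — clean-pass
fixtures therefore stay at or above 150 patients.

## Approval semantics

`run_curation()` windows the refresh, evaluates every catalog check,
aggregates measure exceptions to check level (logical OR — the aggregation
rule is this package's choice), counts required and investigative
exceptions, and approves iff required exceptions are zero. Persistence
checks without a prior refresh are `not_applicable`, mirroring how a
first refresh cannot be compared; at the single-measure evaluation surface
(`evaluate_measure()`), asking a history-dependent check without a history
is an error instead, so callers cannot silently skip it.

## Known limitations

* The catalog beyond the publicly named checks is a reconstruction;
  measure counts are schema-dependent by design and are not comparable to
  any real network's measure inventory.
* Unparseable raw values are recorded at CSV load time; a refresh built
  in memory is already typed, so the datatype-conformance check can only
  fire on data read from disk.
* `etl_change` events must not target parent tables of other retained
  tables (the default targets DIAGNOSIS); dropping parents would create
  orphans the audit log does not know about.
* Network-level experiments are qualitative: they reproduce trajectory
  *shapes* (declining / constant / churning prevalence), not any real
  network's percentages.
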