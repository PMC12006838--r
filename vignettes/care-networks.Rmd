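---
title: "Temporal patient-sharing networks: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal patient-sharing networks: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carenet)
library(data.table)
```

# The model

`carenet` studies collaboration among clinicians through the patients they
share. The raw material is the thinnest possible encounter record — patient
id, provider id, appointment date — which any EHR can export at scale.

Two edge-creation semantics are implemented side by side.

**Atemporal (the traditional baseline).** For each patient with $k$
distinct providers, all $\binom{k}{2}$ unordered pairs become edges. Timing
is ignored entirely: a provider seen once a decade before another provider's
first visit is still "connected" to them.

**Temporal (timeline projection).** Each provider's *care interval* for a
patient runs from their first to their last appointment with that patient.
Two providers are related for that patient only when their intervals
overlap; the relationship span is the overlap
$[\max(\mathrm{enter}_u, \mathrm{enter}_v),\ \min(\mathrm{exit}_u,
\mathrm{exit}_v)]$. This encodes the assumption that plausible
coordination — messages, shared notes, conversations — happens among
providers active on the patient *in the same period*.

Edges are aggregated across patients within an *analysis window*: the edge
weight is the number of distinct patients whose relationship qualifies for
the window. For every patient, temporal relationships are a subset of
atemporal pairs, so aggregated temporal edge sets, per-pair weights and
per-node degrees are all bounded by their atemporal counterparts — the
mechanism behind the headline observation that static methods overestimate
provider connectivity. When every appointment of a patient falls on one
day the two methods coincide exactly; the test suite asserts both
properties.

## Assumptions and their limits

* A care interval is a contiguous proxy for involvement. A provider seen in
  2005 and again in 2010 is treated as "present" throughout; the method has
  no gap-splitting rule. This overstates long-gap providers' presence and
  is the conservative direction (it can only make the temporal network
  *more* similar to the atemporal one).
* Closed intervals at day granularity: a pair overlapping on exactly one
  day has a valid relationship with start = end. Same-day co-visits are the
  strongest co-care signal, so excluding single-day overlap would silently
  drop them. Degenerate single-appointment intervals (enter = exit) follow
  from the same rule.
* Appointment *rows* are kept as given, duplicates included: same-day
  repeat encounters are legitimate and indistinguishable from accidental
  duplication, and duplicates cannot change intervals (min/max-invariant);
  they only affect appointment-count statistics.

# Windows and containment

An `analysis_window` is a closed date interval plus a containment policy:

* `contained` — a relationship counts only if its whole span lies inside
  the window. This is the strict reading of "the start date and end date
  are included in the timeframe".
* `intersects` — one shared day suffices.

For whole-study analyses the policies agree (the full window contains every
span). For yearly windows they genuinely differ: a relationship spanning
New Year's Eve belongs to *no* year under `contained` and to *both* years
under `intersects`. There is no canonical answer — attribution of an
interval to a sub-window is inherently a modelling choice — so both
policies are first-class and every windowed report records which one was
used. `contained` is the default because it is the stricter, more literal
rule. Windowing the *atemporal* network is even less well defined (its
edges carry no dates); we adopt the minimal timing assumption that both
providers must have at least one appointment with the shared patient inside
the window. Note that under these conventions yearly temporal and
atemporal columns are not directly comparable across policies, and no
attempt is made to reproduce any particular institution's yearly table.

# Measure conventions

| quantity | formula | degenerate convention |
|---|---|---|
| network density | $2E / (N(N-1))$ | 0 when $N < 2$ |
| care density | $\sum_e w_e / E$ | 0 when $E = 0$ |
| degree centrality | distinct neighbours | 0 for isolates |

Degenerate cases return 0 rather than erroring so that sparse yearly
windows produce complete tables. Density is always reported as a fraction
in $[0, 1]$ per the formula above; any published density exceeding 1 must
come from a different normalisation, which we do not attempt to guess.

Fixed-length time units are used for relative-time analyses: months of
30.44 days and years of 365.25 days. Calendar months are irregular (28-31
days), which makes month-bucketed curves depend on diagnosis dates in
distracting ways; the fixed lengths are reproducible and configurable.
Calendar arithmetic is used where the rule is genuinely calendar-based: the
cohort inclusion window "six months after diagnosis" advances the diagnosis
date by six calendar months with day clamping (2010-08-31 + 6 months =
2011-02-28), inclusive on both ends, matching clinical convention.

**Patient retention.** A patient's span runs from their first appointment
on or after diagnosis to their last appointment overall; they are retained
at horizon $h$ when the span reaches $h \times 365.25$ days. The default
denominator is the *at-risk* rule: only patients diagnosed at least $h$
years before the study end can possibly be observed retained at $h$, so
later diagnoses are excluded from that horizon's denominator. The
alternative `all_patients` denominator is provided for sensitivity
analysis; with a fixed denominator the retention curve is monotonically
non-increasing, which the tests assert.

**Provider tenure.** Span from a provider's first to last appointment
across all patients, in 30.44-day months, with the single-appointment
fraction reported separately (those providers have tenure 0 by
construction, so the single-appointment and ≥ 1-year groups are disjoint).

**Relative care density.** For one provider, year $k$ in network is
$[\mathrm{enter} + (k-1) \cdot 365.25\,\mathrm{d},\ \mathrm{enter} + k
\cdot 365.25\,\mathrm{d})$ with enter = first appointment overall; the
reported value is the care density of the ego network restricted to each
window, with empty years reported as 0 rather than omitted so start-up
periods are visible.

# The synthetic cohort generator

Real appointment extracts of this kind are institutional data and cannot
ship with the package, so every downstream module is exercised against a
seeded generator whose **defaults are the stated world**: a 2002–2016
early-stage breast-cancer cohort with stage mix 2116/1452/514 (I/II/III out
of 4082), 15.3 distinct providers per patient (median 12), 72.7 appointment
rows per patient (median 54), network retention 71.4%/43%/14% at 2/5/10
years, and 39.8% of providers appearing for exactly one appointment.

Published cohort tables give summary statistics, not distributional forms,
so the families below are the package's own choices, made once and
documented here:

* **Counts.** Providers-per-patient and appointments-per-patient are
  shifted negative binomials ($1 + \mathrm{NB}$), the standard
  overdispersed count family; right skew is required because both printed
  means exceed their medians. The dispersion parameters (size 1.5 and 1.2)
  are fixed by the calibration requirement that the medians land at 12 and
  54 for the given means — they are derived constants, not tuning knobs.
  The two counts are coupled *comonotonically* (one shared uniform driving
  both quantile functions): patients who see many providers also have many
  appointments, which is clinically sensible and guarantees
  appointments ≥ providers without truncation bias on either mean.
* **Follow-up.** Piecewise-exponential survival through the three
  retention knots — the simplest curve that hits all printed fractions
  exactly in expectation — with the last segment's hazard extended beyond
  ten years, truncated at the study end. The first appointment is planted
  on the diagnosis day (so every simulated patient passes the cohort
  filter) and the last at the end of follow-up, making the measured span
  equal the drawn follow-up.
* **Provider pool.** A single pooled panel of 2500 providers with rank-decay
  popularity weights ($\mathrm{rank}^{-1.1}$), giving a heavy-tailed
  volume distribution (a few very-high-volume providers, a long tail of
  low-volume ones). Per-stage panels are deliberately not used: providers
  overlap across stages in real cohorts. A configured 39.8% of the pool is
  *transient*: once sampled, a transient provider contributes exactly one
  appointment and is never drawn again, which realises the
  single-appointment provider share and guarantees non-overlapping
  intervals (hence a strictly smaller temporal edge set) in every default
  cohort.
* **Oncology front-loading.** Oncology-related providers' assignment
  weight is multiplied by $1 + 4 e^{-t/365\,\mathrm{d}}$ with $t$ days
  since diagnosis, so the oncology share of visits peaks in the first year
  and decays — the qualitative shape needed to make the visit-share curve
  non-trivially testable. The amplitude and decay are configurable; no
  published value constrains them.
* **Pre-diagnosis appointments** default to zero. The appointments-per-
  patient target is calibrated against post-diagnosis rows; adding a
  default pre-diagnosis block would silently inflate that statistic. The
  block is available (`prediagnosis_mean`) for exercising the lookback
  filter.

What the generator does **not** emulate: weekday/clinic scheduling
structure, regimen-driven visit spacing, stage-dependent provider and
appointment counts (printed per-stage differences are small), referral
topology among providers, and secular trends in diagnosis volume (diagnosis
dates are uniform; real cohorts grow over time). A green calibration test
therefore establishes that the pipeline *recovers configured cohort-level
statistics from generated data* — it does not establish fidelity of any
within-network microstructure to a real institution.

# Numerical and degenerate-input choices

* Canonical pair ordering is lexicographic on provider id; all edge tables
  are deduplicated and sorted under it, so edge sets compare as sets and
  exports are deterministic.
* All randomness flows through one explicit integer seed; same seed means
  byte-identical CSVs, edge lists and reports, asserted end-to-end through
  the CLI.
* Empty inputs (no appointments, empty registry, edgeless snapshots,
  years with no activity) produce empty or zero-valued outputs, never
  errors; genuine inconsistencies (edge endpoints absent from a node set,
  unknown provider ids, malformed dates, mixed pair kinds) fail fast with
  precise messages.
* Appointments whose provider lacks a provider record are kept, treated as
  specialty "unknown" and not oncology-related: dropping them would bias
  network size, and real extracts always contain such providers.
* Full-time/part-time status of oncologists is accepted as an input label
  (`fte_status`) and never inferred; no computational criterion for it
  exists.

# Known limitations

* Care intervals ignore within-episode gaps (see above).
* The atemporal windowing rule is our minimal assumption; other rules
  (e.g., attributing an atemporal edge to the year of first co-occurrence)
  would change yearly atemporal columns.
* Retention conflates institutional retention with data availability: a
  patient who transfers care elsewhere is indistinguishable from one who
  exits the network.
* The generator is calibrated at cohort level only; per-stage and per-year
  statistics emerge from the shared machinery and are not separately
  matched.
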