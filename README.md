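# carenet

Temporal patient-sharing provider networks from outpatient appointment data.

## The problem

Health-services researchers use social network analysis to study how
clinicians collaborate: providers are nodes, and an edge means two providers
treated at least one common patient, weighted by the number of shared
patients. The traditional ("atemporal") construction connects *every* pair
of providers who ever saw the same patient, regardless of when — a provider
seen once in 2003 becomes connected to one first seen in 2015. Because
clinical collaboration is only plausible among providers caring for a
patient *over the same period*, atemporal networks systematically
overestimate the number of provider–provider relationships and distort
measures built on them.

`carenet` implements a temporal alternative by timeline projection. For each
patient, every provider's care interval runs from their first to their last
appointment with that patient:

```
enter(p, v) = min{ date(a) : a is an appointment of patient p with provider v }
exit(p, v)  = max{ date(a) : ... }
```

Two providers *u*, *v* of patient *p* are related iff their closed intervals
overlap,

```
max(enter_u, enter_v) <= min(exit_u, exit_v)
```

and the relationship span is that overlap. Edges are aggregated across
patients per analysis window: the weight of edge (u, v) is the number of
distinct patients whose (u, v) relationship qualifies under the window's
containment policy (`contained`: the whole span inside the window;
`intersects`: at least one shared day). The atemporal baseline — all
C(k, 2) pairs over a patient's k providers — is built alongside so the two
methods can be compared on identical inputs; the temporal edge set is
provably a subset of the atemporal one.

The measure suite covers:

* **network density** `2E / (N (N − 1))`,
* **care density** `(sum of edge weights) / (number of edges)` — average
  patients shared per connection,
* **degree centrality** (distinct neighbours), **ego networks** (star
  subgraph of one provider),
* yearly institutional statistics (absolute time), care density by year
  since a provider entered the network (relative time), provider tenure,
  patient retention at fixed horizons, and the oncology share of visits by
  month since diagnosis.

Because real EHR extracts of this kind cannot be redistributed, the package
includes a seeded synthetic cohort generator whose defaults are calibrated
to a published early-stage breast-cancer cohort (4082 patients diagnosed
2002–2016; 15.3 providers and 72.7 appointments per patient; retention
71.4% / 43% / 14% at 2 / 5 / 10 years; 39.8% single-appointment providers).

## Worked example

```r
library(carenet)
library(data.table)

co <- generate_cohort(generator_config(n_patients = 300), seed = 42)
f  <- filter_cohort(co$registry, co$appointments,
                    study_end = co$config$study_end)

w  <- full_window(f$appointments)
tp <- temporal_pairs(provider_intervals(f$appointments))
te <- aggregate_edges(tp, "temporal", w)
ae <- aggregate_edges(atemporal_pairs(f$appointments), "atemporal", w,
                      appointments = f$appointments)
nrow(te); nrow(ae)
#> [1] 30688
#> [1] 36314
```

Even on a 300-patient cohort the atemporal construction reports ~18% more
provider relationships than actually co-occur in time; at full cohort scale
the gap widens further. Care density, the average number of patients shared
per connection, is correspondingly *underestimated* by the atemporal method
(1.49 vs the temporal 1.54 here), because it divides by an inflated edge
count.

```r
snap <- build_snapshot(f$appointments, te, w)
network_density(snap)
#> [1] 0.0317

top <- f$appointments[, .(npt = uniqueN(patient_id)), by = provider_id][order(-npt)][1]
degree_centrality(snap, top$provider_id)
#> [1] 1034
relative_care_density(tp, f$appointments, top$provider_id, max_years = 3)
#>    year_in_network n_edges care_density
#> 1:               1      44     1.181818
#> 2:               2      62     1.129032
#> 3:               3      90     1.222222

patient_retention(f$appointments, f$registry, study_end = co$config$study_end)
#>    horizon_years n_at_risk n_retained  fraction
#> 1:             2       261        184 0.7049808
#> 2:             5       202         97 0.4801980
#> 3:            10       114         23 0.2017544
```

The retention row reads: of the 261 patients diagnosed at least two years
before the study end (the "at-risk" denominator), 70.5% still had
appointments spanning two or more years after their first post-diagnosis
visit. `validate_cohort()` reports all calibration statistics next to their
configured targets.

## Command line

```sh
Rscript inst/cli/carenet.R simulate --out data/ --seed 1 --n-patients 500
Rscript inst/cli/carenet.R build   --appointments data/appointments.csv \
    --registry data/registry.csv --providers data/providers.csv \
    --method both --policy contained --out edges/
Rscript inst/cli/carenet.R report  --appointments data/appointments.csv \
    --registry data/registry.csv --providers data/providers.csv --out report/
```

(After installation the wrapper is also available at
`system.file("cli", "carenet.R", package = "carenet")`.) All CLI output is
byte-identical to the corresponding library calls; rerunning with the same
seed reproduces every file exactly.

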