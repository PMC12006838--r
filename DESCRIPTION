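Package: carenet
Title: Temporal Patient-Sharing Provider Networks from Appointment Data
Version: 0.1.0
Authors@R:
    person("carenet", "maintainers", email = "carenet@example.org",
           role = c("aut", "cre"))
Description: Builds patient-sharing provider networks from outpatient
    appointment records. Temporal edges are created by a timeline-projection
    method: each provider's per-patient care interval runs from their first
    to their last appointment with that patient, and two providers are
    connected only when their intervals overlap. An atemporal pairwise
    baseline connects every pair of providers who ever treated the same
    patient. The package supplies the associated measure suite (network
    density, care density, degree centrality, ego networks, windowed
    institutional statistics in absolute and relative time, provider tenure,
    patient retention), a seeded synthetic longitudinal cohort generator
    calibrated to a published early-stage breast-cancer cohort, and a
    command-line pipeline (simulate, build, report).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    jsonlite,
    lubridate,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
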