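#' Network density
#'
#' Fraction of potential connections that are actual connections,
#' `2E / (N (N - 1))`. Snapshots with fewer than two nodes have no potential
#' connections and return 0 by convention, so sparse yearly windows never
#' error.
#'
#' @param snapshot A `network_snapshot`, or any list with `nodes` and
#'   `edges` tables.
#' @return A number in `[0, 1]`.
#' @export
network_density <- function(snapshot) {
  n <- nrow(snapshot$nodes)
  e <- nrow(snapshot$edges)
  if (n < 2) return(0)
  2 * e / (n * (n - 1))
}

#' Care density
#'
#' Average number of patients shared per provider connection: the sum of
#' edge weights divided by the number of edges. Edgeless inputs return 0 by
#' convention.
#'
#' @param x A `network_snapshot` or an aggregated edge table.
#' @return A nonnegative number.
#' @export
care_density <- function(x) {
  edges <- if (inherits(x, "network_snapshot")) x$edges else as.data.table(x)
  if (nrow(edges) == 0) return(0)
  sum(edges$weight) / nrow(edges)
}

#' Degree centrality of a provider
#'
#' Number of distinct providers adjacent to `provider_id` in the snapshot.
#'
#' @param snapshot A `network_snapshot`.
#' @param provider_id Provider to query; must be a node of the snapshot.
#' @return A nonnegative integer.
#' @export
degree_centrality <- function(snapshot, provider_id) {
  if (!provider_id %in% snapshot$nodes$provider_id) {
    stop(sprintf("provider %s is not a node of this snapshot", provider_id),
         call. = FALSE)
  }
  e <- snapshot$edges
  neighbours <- c(e$provider_b[e$provider_a == provider_id],
                  e$provider_a[e$provider_b == provider_id])
  length(unique(neighbours))
}

#' Ego network of a provider
#'
#' The star subgraph of one central provider: the centre, its neighbours,
#' and only the edges incident to the centre. Edges among neighbours are
#' excluded.
#'
#' @param edges Aggregated edge table.
#' @param provider_id Central provider.
#' @param window Optional [analysis_window()] recorded on the snapshot
#'   (defaults to the span of the supplied edges' windows).
#' @param appointments Optional appointment table used to attach
#'   patient-count node weights; when absent, node weights are `NA`.
#' @return A `network_snapshot` restricted to the star.
#' @export
ego_network <- function(edges, provider_id, window = NULL,
                        appointments = NULL) {
  edges <- as.data.table(edges)
  incident <- edges[provider_a == provider_id | provider_b == provider_id]
  known <- provider_id %in% c(edges$provider_a, edges$provider_b)
  if (!is.null(appointments)) {
    known <- known || provider_id %in% as.data.table(appointments)$provider_id
  }
  if (!known) {
    stop(sprintf("unknown provider: %s", provider_id), call. = FALSE)
  }
  node_ids <- sort(unique(c(provider_id,
                            incident$provider_a, incident$provider_b)))
  if (is.null(window)) {
    window <- if (nrow(edges)) {
      analysis_window(min(edges$window_start), max(edges$window_end))
    } else {
      analysis_window("1900-01-01", "1900-01-01")
    }
  }
  nodes <- data.table(provider_id = node_ids, patient_count = NA_integer_)
  if (!is.null(appointments)) {
    appointments <- as.data.table(appointments)
    counts <- appointments[date >= window$start & date <= window$end &
                             provider_id %in% node_ids,
                           .(patient_count = uniqueN(patient_id)),
                           by = provider_id]
    nodes[counts, patient_count := i.patient_count, on = "provider_id"]
  }
  structure(list(nodes = nodes, edges = incident, window = as_window(window)),
            class = "network_snapshot")
}

#' Yearly institutional network statistics
#'
#' For each calendar year: new diagnoses (registry dates in the year),
#' active patients and providers (at least one appointment in the year),
#' temporal and atemporal edge counts and edge-weight sums under the chosen
#' containment policy, and both network densities. Temporal relationships
#' are computed once from each patient's full appointment history and then
#' windowed by year, so a relationship spanning several years is attributed
#' per the policy.
#'
#' @param registry,appointments Cohort tables (after [filter_cohort()]).
#' @param years Integer years to report; default spans the appointment data.
#' @param containment_policy `"contained"` or `"intersects"`.
#' @return A `measure_report` whose `tables$yearly` has one row per year.
#' @export
yearly_institutional_stats <- function(registry, appointments, years = NULL,
                                       containment_policy = "contained") {
  registry <- as.data.table(registry)
  appointments <- as.data.table(appointments)
  if (is.null(years)) {
    yrs <- sort(unique(c(
      if (nrow(appointments)) as.integer(format(appointments$date, "%Y")),
      if (nrow(registry)) as.integer(format(registry$diagnosis_date, "%Y"))
    )))
  } else {
    yrs <- sort(as.integer(years))
  }
  tp <- temporal_pairs(provider_intervals(appointments))
  ap <- atemporal_pairs(appointments)
  rows <- lapply(yrs, function(y) {
    w <- year_window(y, containment_policy)
    in_year <- appointments[date >= w$start & date <= w$end]
    te <- aggregate_edges(tp, "temporal", w)
    ae <- aggregate_edges(ap, "atemporal", w, appointments = appointments)
    snap_nodes <- uniqueN(in_year$provider_id)
    dens <- function(e) {
      if (snap_nodes < 2) 0 else 2 * nrow(e) / (snap_nodes * (snap_nodes - 1))
    }
    data.table(
      year = y,
      n_diagnoses = sum(format(registry$diagnosis_date, "%Y") == as.character(y)),
      n_patients = uniqueN(in_year$patient_id),
      n_providers = snap_nodes,
      temporal_edges = nrow(te),
      atemporal_edges = nrow(ae),
      temporal_weight_sum = sum(te$weight),
      atemporal_weight_sum = sum(ae$weight),
      temporal_density = dens(te),
      atemporal_density = dens(ae)
    )
  })
  tab <- if (length(rows)) rbindlist(rows) else data.table(
    year = integer(), n_diagnoses = integer(), n_patients = integer(),
    n_providers = integer(), temporal_edges = integer(),
    atemporal_edges = integer(), temporal_weight_sum = integer(),
    atemporal_weight_sum = integer(), temporal_density = numeric(),
    atemporal_density = numeric())
  measure_report(list(yearly = tab),
                 meta = list(analysis = "yearly_institutional_stats",
                             containment_policy = containment_policy))
}

#' Care density by year in network, relative to a provider's enter date
#'
#' Relative-time ego analysis: year `k` in network is the window
#' `[enter + (k - 1) * 365.25 d, enter + k * 365.25 d)`, where `enter` is the
#' provider's first appointment date across all patients. For each relative
#' year the provider's ego network is built from the pair relationships that
#' qualify under the containment policy and its care density reported. Years
#' with no qualifying relationships are reported as 0 with zero edges.
#'
#' @param pairs Temporal pair relationships ([temporal_pairs()]) for the
#'   whole cohort.
#' @param appointments Appointment table (defines the enter date).
#' @param provider_id Central provider; must have at least one appointment.
#' @param max_years Last relative year to report; default runs through the
#'   provider's last incident relationship (or last appointment).
#' @param containment_policy `"contained"` or `"intersects"`.
#' @return A `data.table` with `year_in_network`, `n_edges`, `care_density`.
#' @export
relative_care_density <- function(pairs, appointments, provider_id,
                                  max_years = NULL,
                                  containment_policy = "contained") {
  pairs <- as.data.table(pairs)
  appointments <- as.data.table(appointments)
  pid <- provider_id
  own <- appointments[appointments[["provider_id"]] == pid]
  if (nrow(own) == 0) {
    stop(sprintf("unknown provider: %s", provider_id), call. = FALSE)
  }
  enter <- min(own$date)
  incident <- pairs[provider_a == provider_id | provider_b == provider_id]
  if (is.null(max_years)) {
    last <- max(c(incident$end_date, own$date))
    max_years <- max(1L, ceiling((as.numeric(last - enter) + 1) / YEAR_DAYS))
  }
  rows <- lapply(seq_len(max_years), function(k) {
    w0 <- enter + round((k - 1) * YEAR_DAYS)
    w1 <- enter + round(k * YEAR_DAYS) - 1  # closed upper bound, day grid
    w <- analysis_window(w0, w1, anchor = "relative_to_provider_enter",
                         containment_policy = containment_policy)
    e <- aggregate_edges(incident, "temporal", w)
    data.table(year_in_network = k, n_edges = nrow(e),
               care_density = care_density(e))
  })
  rbindlist(rows)[]
}

#' Provider tenure statistics
#'
#' Tenure is the span from a provider's first to last appointment across the
#' whole cohort, in fixed-length months of `month_days` days. Reports mean
#' and median tenure, the fraction of providers with exactly one appointment
#' row overall, and the fractions remaining at least 1, 5 and 10 years; the
#' same statistics are repeated restricted to oncology-related providers
#' when a provider table is supplied.
#'
#' @param appointments Appointment table.
#' @param providers Optional provider table with `oncology_related` flags.
#' @param month_days Month length in days (default 30.44).
#' @return A `measure_report` with a `tenure` table (rows `all` and,
#'   when available, `oncology_related`).
#' @export
provider_tenure_stats <- function(appointments, providers = NULL,
                                  month_days = MONTH_DAYS) {
  appointments <- as.data.table(appointments)
  per <- if (nrow(appointments)) {
    appointments[, .(first = min(date), last = max(date), n_rows = .N),
                 by = provider_id]
  } else {
    data.table(provider_id = character(), first = as.Date(character()),
               last = as.Date(character()), n_rows = integer())
  }
  per[, tenure_months := as.numeric(last - first) / month_days]
  summarise <- function(d, label) {
    if (nrow(d) == 0) {
      return(data.table(group = label, n_providers = 0L,
                        mean_tenure_months = NA_real_,
                        median_tenure_months = NA_real_,
                        frac_single_appointment = NA_real_,
                        frac_ge_1y = NA_real_, frac_ge_5y = NA_real_,
                        frac_ge_10y = NA_real_))
    }
    data.table(
      group = label, n_providers = nrow(d),
      mean_tenure_months = mean(d$tenure_months),
      median_tenure_months = median(d$tenure_months),
      frac_single_appointment = mean(d$n_rows == 1L),
      frac_ge_1y = mean(d$tenure_months >= 12),
      frac_ge_5y = mean(d$tenure_months >= 60),
      frac_ge_10y = mean(d$tenure_months >= 120)
    )
  }
  tabs <- list(summarise(per, "all"))
  if (!is.null(providers)) {
    providers <- as.data.table(providers)
    onc_ids <- providers[oncology_related == TRUE, provider_id]
    tabs <- c(tabs, list(summarise(per[provider_id %in% onc_ids],
                                   "oncology_related")))
  }
  measure_report(list(tenure = rbindlist(tabs)),
                 meta = list(analysis = "provider_tenure_stats",
                             month_days = month_days))
}

#' Patient retention at fixed horizons
#'
#' A patient's network span runs from their first appointment on or after
#' diagnosis to their last appointment overall; the patient is retained at
#' horizon `h` when that span is at least `h * 365.25` days. With the
#' default `"at_risk"` denominator, the horizon-`h` denominator includes
#' only patients diagnosed early enough to be observable at `h` (diagnosis
#' at least `h * 365.25` days before `study_end`); `"all_patients"` uses the
#' full cohort regardless of observability.
#'
#' @param appointments,registry Cohort tables (after [filter_cohort()]).
#' @param horizons_years Horizons, in years (default `c(2, 5, 10)`).
#' @param study_end End of the observation period (`Date` or string);
#'   default is the last appointment date.
#' @param denominator `"at_risk"` or `"all_patients"`.
#' @return A `data.table` with `horizon_years`, `n_at_risk`, `n_retained`,
#'   `fraction`.
#' @export
patient_retention <- function(appointments, registry,
                              horizons_years = c(2, 5, 10),
                              study_end = NULL,
                              denominator = c("at_risk", "all_patients")) {
  denominator <- match.arg(denominator)
  appointments <- as.data.table(appointments)
  registry <- as.data.table(registry)
  if (is.null(study_end)) {
    study_end <- if (nrow(appointments)) max(appointments$date) else
      max(registry$diagnosis_date)
  }
  study_end <- as.Date(study_end)
  ap <- merge(appointments, registry[, .(patient_id, diagnosis_date)],
              by = "patient_id")
  spans <- ap[, .(
    first_post = if (any(date >= diagnosis_date))
      min(date[date >= diagnosis_date]) else as.Date(NA),
    last_any = max(date)
  ), by = .(patient_id, diagnosis_date)]
  spans <- spans[!is.na(first_post)]
  spans[, span_days := as.numeric(last_any - first_post)]
  rows <- lapply(horizons_years, function(h) {
    need <- h * YEAR_DAYS
    at_risk <- if (denominator == "at_risk") {
      spans[as.numeric(study_end - diagnosis_date) >= need]
    } else {
      spans
    }
    n <- nrow(at_risk)
    r <- sum(at_risk$span_days >= need)
    data.table(horizon_years = h, n_at_risk = n, n_retained = r,
               fraction = if (n > 0) r / n else NA_real_)
  })
  rbindlist(rows)[]
}

#' Share of oncology-related appointments by month since diagnosis
#'
#' Buckets each post-cohort appointment into fixed-length months relative to
#' the patient's diagnosis (`month m` covers
#' `[diagnosis + m * month_days, diagnosis + (m + 1) * month_days)`; months
#' may be negative when pre-diagnosis appointments are present) and reports
#' the percentage of appointments in each bucket whose provider is
#' oncology-related. Months with no appointments are absent from the output.
#' Providers missing from the provider table count as not oncology-related.
#'
#' @param appointments,registry Cohort tables (after [filter_cohort()]).
#' @param providers Provider table with `oncology_related`.
#' @param stage_filter Optional subset of stages (`"I"`, `"II"`, `"III"`).
#' @param month_days Month length in days (default 30.44).
#' @return A `data.table` with `month_since_diagnosis`, `n_appointments`,
#'   `n_oncology`, `percent_oncology`.
#' @export
oncology_fraction_by_month <- function(appointments, registry, providers,
                                       stage_filter = NULL,
                                       month_days = MONTH_DAYS) {
  appointments <- as.data.table(appointments)
  registry <- as.data.table(registry)
  providers <- as.data.table(providers)
  if (!is.null(stage_filter)) {
    registry <- registry[stage %in% stage_filter]
  }
  ap <- merge(appointments,
              registry[, .(patient_id, diagnosis_date)], by = "patient_id")
  if (nrow(ap) == 0) {
    return(data.table(month_since_diagnosis = integer(),
                      n_appointments = integer(), n_oncology = integer(),
                      percent_oncology = numeric()))
  }
  ap[, month_idx := as.integer(floor(
    as.numeric(date - diagnosis_date) / month_days))]
  ap <- merge(ap, providers[, .(provider_id, onc = oncology_related)],
              by = "provider_id", all.x = TRUE)
  ap[is.na(onc), onc := FALSE]
  out <- ap[, .(n_appointments = .N, n_oncology = sum(onc)),
            by = .(month_since_diagnosis = month_idx)]
  out[, percent_oncology := 100 * n_oncology / n_appointments]
  setorder(out, month_since_diagnosis)
  out[]
}

#' Cohort-level network summary
#'
#' Pooled (and optionally per-stage) summary over the whole study period:
#' counts of patients, providers and unique temporal / atemporal edges, and
#' mean / median / range of providers per patient, appointment rows per
#' patient, node size (distinct patients per provider) and temporal /
#' atemporal edge weights. Per-stage rows recompute every quantity on the
#' stage's patients only, so providers shared across stages are counted in
#' each stage they serve.
#'
#' @param registry,appointments Cohort tables (after [filter_cohort()]).
#' @param by_stage Also compute per-stage blocks.
#' @param containment_policy Containment policy recorded on the whole-study
#'   window (the full window contains every relationship, so the policy does
#'   not change pooled numbers).
#' @return A `measure_report` with tables `counts` and `distributions`.
#' @export
cohort_summary <- function(registry, appointments, by_stage = TRUE,
                           containment_policy = "contained") {
  registry <- as.data.table(registry)
  appointments <- as.data.table(appointments)

  one_block <- function(reg, ap, label) {
    if (nrow(ap) == 0) {
      counts <- data.table(group = label, n_patients = nrow(reg),
                           n_providers = 0L, temporal_edges = 0L,
                           atemporal_edges = 0L, temporal_weight_sum = 0L,
                           atemporal_weight_sum = 0L)
      return(list(counts = counts, distributions = data.table(
        group = character(), metric = character(), mean = numeric(),
        median = numeric(), min = numeric(), max = numeric())))
    }
    w <- full_window(ap, containment_policy)
    tp <- temporal_pairs(provider_intervals(ap))
    te <- aggregate_edges(tp, "temporal", w)
    ae <- aggregate_edges(atemporal_pairs(ap), "atemporal", w,
                          appointments = ap)
    per_patient <- ap[, .(n_providers = uniqueN(provider_id),
                          n_appointments = .N), by = patient_id]
    node_size <- ap[, .(patient_count = uniqueN(patient_id)),
                    by = provider_id]
    dist_row <- function(metric, x) {
      if (length(x) == 0) {
        data.table(group = label, metric = metric, mean = NA_real_,
                   median = NA_real_, min = NA_real_, max = NA_real_)
      } else {
        data.table(group = label, metric = metric, mean = mean(x),
                   median = as.numeric(median(x)), min = min(x), max = max(x))
      }
    }
    list(
      counts = data.table(
        group = label,
        n_patients = uniqueN(ap$patient_id),
        n_providers = uniqueN(ap$provider_id),
        temporal_edges = nrow(te),
        atemporal_edges = nrow(ae),
        temporal_weight_sum = sum(te$weight),
        atemporal_weight_sum = sum(ae$weight)),
      distributions = rbindlist(list(
        dist_row("providers_per_patient", per_patient$n_providers),
        dist_row("appointments_per_patient", per_patient$n_appointments),
        dist_row("node_size", node_size$patient_count),
        dist_row("temporal_edge_size", te$weight),
        dist_row("atemporal_edge_size", ae$weight)))
    )
  }

  blocks <- list(one_block(registry, appointments, "pooled"))
  if (by_stage && nrow(registry)) {
    for (st in intersect(c("I", "II", "III"), unique(registry$stage))) {
      reg_s <- registry[stage == st]
      ap_s <- appointments[patient_id %in% reg_s$patient_id]
      blocks <- c(blocks, list(one_block(reg_s, ap_s, paste0("stage_", st))))
    }
  }
  measure_report(
    list(counts = rbindlist(lapply(blocks, `[[`, "counts")),
         distributions = rbindlist(lapply(blocks, `[[`, "distributions"))),
    meta = list(analysis = "cohort_summary",
                containment_policy = containment_policy))
}
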