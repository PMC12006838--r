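library(data.table)

# Compact appointment-table constructor. Dates may be integer day offsets
# from a fixed origin, which keeps hand-built cases readable.
DAY0 <- as.Date("2010-01-01")

appts <- function(patient, provider, day) {
  data.table(
    patient_id = as.character(patient),
    provider_id = as.character(provider),
    date = if (inherits(day, "Date")) day else DAY0 + as.integer(day)
  )
}

# Random single-patient appointment history: <= max_providers providers,
# <= max_appts appointment rows over a ~2-year span.
random_patient <- function(id, max_providers = 15, max_appts = 60) {
  k <- sample.int(max_providers, 1)
  n <- sample(seq(k, max_appts), 1)
  providers <- sprintf("p%02d", sample.int(99, k))
  appts(id,
        c(providers, sample(providers, n - k, replace = TRUE)),
        sample.int(730, n, replace = TRUE) - 1)
}

# Independent oracle for temporal pair relationships: enumerate every
# provider pair of the patient and test min/max appointment-date overlap
# directly, without intervals or joins.
brute_force_temporal_pairs <- function(ap) {
  ap <- as.data.table(ap)
  stopifnot(length(unique(ap$patient_id)) <= 1)
  provs <- sort(unique(ap$provider_id))
  rows <- list()
  if (length(provs) >= 2) {
    for (i in seq_len(length(provs) - 1)) {
      for (j in seq(i + 1, length(provs))) {
        da <- ap$date[ap$provider_id == provs[i]]
        db <- ap$date[ap$provider_id == provs[j]]
        s <- max(min(da), min(db))
        e <- min(max(da), max(db))
        if (s <= e) {
          rows[[length(rows) + 1]] <- data.table(
            patient_id = ap$patient_id[1], provider_a = provs[i],
            provider_b = provs[j], start_date = s, end_date = e)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.table(patient_id = character(), provider_a = character(),
                      provider_b = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character())))
  }
  out <- rbindlist(rows)
  setorder(out, patient_id, provider_a, provider_b)
  out[]
}

# Small generator configuration for fast multi-cohort property tests.
small_config <- function(n_patients = 60, ...) {
  generator_config(n_patients = n_patients, provider_pool_size = 300,
                   ...)
}

# Cheap content fingerprint for identity/difference assertions.
digest_table <- function(dt) {
  paste(unlist(lapply(dt, as.character)), collapse = "|")
}

# Write a cohort to CSVs the way the CLI expects them.
write_cohort_csvs <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ap <- data.table::copy(cohort$appointments)
  setnames(ap, "date", "appointment_date")
  data.table::fwrite(ap, file.path(dir, "appointments.csv"))
  data.table::fwrite(cohort$registry, file.path(dir, "registry.csv"))
  prov <- data.table::copy(cohort$providers)
  prov[, oncology_related := as.integer(oncology_related)]
  data.table::fwrite(prov, file.path(dir, "providers.csv"))
  dir
}
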