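#' Read an appointment table
#'
#' Reads a CSV of outpatient encounters, one row per patient-provider
#' appointment on a calendar day. Duplicate rows (same patient, provider and
#' date) are preserved: they contribute to appointment counts but cannot
#' change per-provider care intervals.
#'
#' @param path Path to a CSV with columns
#'   `patient_id,provider_id,appointment_date` (dates ISO-8601).
#' @return A `data.table` with columns `patient_id`, `provider_id` (character)
#'   and `date` (`Date`), one row per appointment.
#' @export
read_appointments <- function(path) {
  dt <- read_input_csv(path, c("patient_id", "provider_id", "appointment_date"))
  dt[, `:=`(patient_id = as.character(patient_id),
            provider_id = as.character(provider_id))]
  check_nonempty_ids(dt, c("patient_id", "provider_id"), path)
  dt[, date := parse_date_column(appointment_date, path)]
  dt[, appointment_date := NULL]
  setcolorder(dt, c("patient_id", "provider_id", "date"))
  dt[]
}

#' Read a tumor-registry table
#'
#' @param path Path to a CSV with columns `patient_id,diagnosis_date,stage`;
#'   stage must be one of `I`, `II`, `III` and patient ids must be unique.
#' @return A `data.table` with `patient_id`, `diagnosis_date` (`Date`),
#'   `stage` (character).
#' @export
read_registry <- function(path) {
  dt <- read_input_csv(path, c("patient_id", "diagnosis_date", "stage"))
  dt[, patient_id := as.character(patient_id)]
  check_nonempty_ids(dt, "patient_id", path)
  dt[, diagnosis_date := parse_date_column(diagnosis_date, path)]
  dt[, stage := as.character(stage)]
  bad <- which(!dt$stage %in% c("I", "II", "III"))
  if (length(bad)) {
    stop(sprintf("%s: invalid stage %s on data line %d (allowed: I, II, III)",
                 path, dQuote(dt$stage[bad[1]]), bad[1]), call. = FALSE)
  }
  if (anyDuplicated(dt$patient_id)) {
    dup <- dt$patient_id[duplicated(dt$patient_id)][1]
    stop(sprintf("%s: duplicate registry record for patient %s", path, dup),
         call. = FALSE)
  }
  dt[]
}

#' Read a provider table
#'
#' @param path Path to a CSV with columns
#'   `provider_id,specialty,oncology_related` and optionally `fte_status`
#'   (`full_time`, `part_time` or `unknown`). `oncology_related` is 0/1.
#' @return A `data.table` with `provider_id`, `specialty` (character),
#'   `oncology_related` (logical), `fte_status` (character).
#' @export
read_providers <- function(path) {
  dt <- read_input_csv(path, c("provider_id", "specialty", "oncology_related"),
                       optional = "fte_status")
  dt[, provider_id := as.character(provider_id)]
  check_nonempty_ids(dt, "provider_id", path)
  if (anyDuplicated(dt$provider_id)) {
    dup <- dt$provider_id[duplicated(dt$provider_id)][1]
    stop(sprintf("%s: duplicate provider record for %s", path, dup),
         call. = FALSE)
  }
  onc <- dt$oncology_related
  if (!all(onc %in% c(0, 1, "0", "1", TRUE, FALSE, "TRUE", "FALSE"))) {
    stop(sprintf("%s: oncology_related must be 0/1", path), call. = FALSE)
  }
  dt[, oncology_related := as.logical(as.integer(as.character(oncology_related)))]
  if (!"fte_status" %in% names(dt)) {
    dt[, fte_status := "unknown"]
  } else {
    dt[, fte_status := as.character(fte_status)]
    dt[is.na(fte_status) | fte_status == "", fte_status := "unknown"]
    bad <- setdiff(unique(dt$fte_status), c("full_time", "part_time", "unknown"))
    if (length(bad)) {
      stop(sprintf("%s: invalid fte_status %s", path, dQuote(bad[1])),
           call. = FALSE)
    }
  }
  dt[, specialty := as.character(specialty)]
  dt[]
}

read_input_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  dt <- data.table::fread(path, colClasses = "character",
                          na.strings = NULL, header = TRUE)
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  dt[, intersect(names(dt), c(required, optional)), with = FALSE]
}

# Strict ISO-8601 parse; reports the first offending data line (1-based,
# excluding the header) rather than silently producing NA.
parse_date_column <- function(x, path) {
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(rep(NA_character_, length(x)))
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  bad <- which(!ok | is.na(d))
  if (length(bad)) {
    stop(sprintf("%s: malformed date %s on data line %d",
                 path, dQuote(x[bad[1]]), bad[1]), call. = FALSE)
  }
  d
}

check_nonempty_ids <- function(dt, cols, path) {
  for (col in cols) {
    bad <- which(is.na(dt[[col]]) | dt[[col]] == "")
    if (length(bad)) {
      stop(sprintf("%s: empty %s on data line %d", path, col, bad[1]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Apply the cohort inclusion rule and appointment extraction bounds
#'
#' A patient is eligible when they have at least one appointment between
#' their diagnosis date and `window_months` calendar months after it
#' (day-clamped, both ends inclusive). For eligible patients, appointments
#' are restricted to the extraction bounds: from `lookback_years` calendar
#' years before diagnosis through `study_end`. Appointments whose patient is
#' not in the registry are dropped with a warning, since they signal a
#' registry/appointment mismatch.
#'
#' The operation is idempotent and never increases patient or appointment
#' counts.
#'
#' @param registry Registry table ([read_registry()]).
#' @param appointments Appointment table ([read_appointments()]).
#' @param window_months Inclusion window after diagnosis, in calendar months.
#' @param lookback_years Extraction lookback before diagnosis, in calendar
#'   years.
#' @param study_end Last date of the extraction period (`Date` or string).
#' @param quiet Suppress the summary message about dropped rows.
#' @return A list with elements `registry` (eligible patients) and
#'   `appointments` (their appointments within bounds).
#' @export
filter_cohort <- function(registry, appointments, window_months = 6L,
                          lookback_years = 2L, study_end, quiet = FALSE) {
  registry <- as.data.table(registry)
  appointments <- as.data.table(appointments)
  study_end <- as.Date(study_end)
  if (is.na(study_end)) stop("study_end must be a valid date", call. = FALSE)

  unknown <- setdiff(unique(appointments$patient_id), registry$patient_id)
  if (length(unknown)) {
    warning(sprintf(
      "dropping %d appointment row(s) for %d patient id(s) absent from the registry",
      sum(appointments$patient_id %in% unknown), length(unknown)
    ), call. = FALSE)
    appointments <- appointments[!patient_id %in% unknown]
  }
  if (nrow(registry) == 0) {
    return(list(registry = registry[0], appointments = appointments[0]))
  }

  ap <- merge(appointments,
              registry[, .(patient_id, diagnosis_date)],
              by = "patient_id")
  incl_end <- add_months_clamped(registry$diagnosis_date, window_months)
  incl <- registry[, .(patient_id, diagnosis_date,
                       incl_end = incl_end)]
  ap_incl <- merge(ap, incl[, .(patient_id, incl_end)], by = "patient_id")
  eligible <- unique(ap_incl[date >= diagnosis_date & date <= incl_end,
                             patient_id])

  out_registry <- registry[patient_id %in% eligible]
  ap <- ap[patient_id %in% eligible]
  lookback_start <- add_months_clamped(ap$diagnosis_date, -12L * lookback_years)
  keep <- ap$date >= lookback_start & ap$date <= study_end
  n_dropped <- sum(!keep)
  if (!quiet && n_dropped > 0) {
    message(sprintf(
      "filter_cohort: dropped %d appointment row(s) outside extraction bounds",
      n_dropped))
  }
  out_appointments <- ap[keep, .(patient_id, provider_id, date)]
  list(registry = out_registry[], appointments = out_appointments[])
}

# Calendar-month shift with day-of-month clamping (e.g. 2010-08-31 plus six
# months is 2011-02-28), matching clinical convention for "n months after".
add_months_clamped <- function(dates, months) {
  lubridate::add_with_rollback(dates, lubridate::period(months, "months"),
                               roll_to_first = FALSE)
}

#' Write an aggregated edge list as TSV
#'
#' One row per edge, canonical order (`provider_a < provider_b`, rows sorted
#' by pair). Round-trips losslessly through [read_edge_list()].
#'
#' @param edges Aggregated edge table ([aggregate_edges()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  edges <- as.data.table(edges)
  cols <- c("provider_a", "provider_b", "weight", "kind",
            "window_start", "window_end")
  missing <- setdiff(cols, names(edges))
  if (length(missing)) {
    stop(sprintf("edge table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- edges[, ..cols]
  setorder(out, provider_a, provider_b, kind)
  out[, `:=`(window_start = format(window_start),
             window_end = format(window_end))]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path Input path.
#' @return A `data.table` of aggregated edges.
#' @export
read_edge_list <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("provider_a", "provider_b", "kind",
                  "window_start", "window_end"),
    integer = "weight"))
  dt[, `:=`(window_start = as.Date(window_start),
            window_end = as.Date(window_end))]
  dt[]
}

#' Export a network snapshot as GraphML
#'
#' Nodes carry a `patient_count` attribute (distinct patients seen in the
#' snapshot window) and edges a `weight` attribute (distinct shared
#' patients), mirroring the node-size / edge-thickness encoding of the
#' visualised networks.
#'
#' @param snapshot A `network_snapshot` ([build_snapshot()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "network_snapshot"))
  nodes <- snapshot$nodes
  edges <- snapshot$edges
  stray <- setdiff(unique(c(edges$provider_a, edges$provider_b)),
                   nodes$provider_id)
  if (length(stray)) {
    stop(sprintf("edge endpoint(s) missing from node set: %s",
                 paste(head(stray, 3), collapse = ", ")), call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (nrow(nodes)) {
    g <- igraph::add_vertices(g, nrow(nodes), name = nodes$provider_id,
                              patient_count = as.numeric(nodes$patient_count))
  }
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$provider_a, edges$provider_b),
                           weight = as.numeric(edges$weight))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML snapshot back into node and edge tables
#'
#' Inverse of [write_graphml()] up to row order; used for round-trip
#' validation and downstream tooling.
#'
#' @param path GraphML path.
#' @return A list with `nodes` (provider_id, patient_count) and `edges`
#'   (provider_a, provider_b, weight) tables in canonical order.
#' @export
read_graphml_snapshot <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0) {
    nodes <- data.table(provider_id = character(), patient_count = integer())
    edges <- data.table(provider_a = character(), provider_b = character(),
                        weight = integer())
    return(list(nodes = nodes, edges = edges))
  }
  nodes <- data.table(
    provider_id = igraph::V(g)$name,
    patient_count = as.integer(round(igraph::V(g)$patient_count))
  )
  setorder(nodes, provider_id)
  if (igraph::ecount(g) > 0) {
    ends <- igraph::as_edgelist(g, names = TRUE)
    a <- pmin(ends[, 1], ends[, 2])
    b <- pmax(ends[, 1], ends[, 2])
    edges <- data.table(provider_a = a, provider_b = b,
                        weight = as.integer(round(igraph::E(g)$weight)))
    setorder(edges, provider_a, provider_b)
  } else {
    edges <- data.table(provider_a = character(), provider_b = character(),
                        weight = integer())
  }
  list(nodes = nodes, edges = edges)
}
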