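#' Per-patient provider care intervals
#'
#' For every (patient, provider) pair, the care interval runs from the
#' provider's first appointment with that patient (`enter_date`) to their
#' last (`exit_date`). Both endpoints are dates of actual appointments, so a
#' provider seen once has a degenerate interval with `enter == exit`.
#'
#' @param appointments Appointment table; may span many patients.
#' @return A `data.table` with columns `patient_id`, `provider_id`,
#'   `enter_date`, `exit_date`, one row per patient-provider pair.
#' @export
provider_intervals <- function(appointments) {
  appointments <- as.data.table(appointments)
  if (nrow(appointments) == 0) {
    return(data.table(patient_id = character(), provider_id = character(),
                      enter_date = as.Date(character()),
                      exit_date = as.Date(character())))
  }
  out <- appointments[, .(enter_date = min(date), exit_date = max(date)),
                      by = .(patient_id, provider_id)]
  setorder(out, patient_id, provider_id)
  out[]
}

#' Care intervals for a single patient
#'
#' Convenience wrapper around [provider_intervals()] that asserts the input
#' belongs to one patient.
#'
#' @param appointments Appointments of one patient.
#' @return Interval table as in [provider_intervals()].
#' @export
build_intervals <- function(appointments) {
  appointments <- as.data.table(appointments)
  if (nrow(appointments) > 0 && uniqueN(appointments$patient_id) != 1L) {
    stop("build_intervals expects appointments of a single patient",
         call. = FALSE)
  }
  provider_intervals(appointments)
}

#' Temporal pair relationships by interval overlap
#'
#' The timeline-projection edge rule: two providers of the same patient are
#' related exactly when their care intervals overlap, using closed-interval
#' semantics at day granularity (sharing a single day counts). The
#' relationship span is the overlap,
#' `[max(enter_a, enter_b), min(exit_a, exit_b)]`. Pairs are emitted in
#' canonical order `provider_a < provider_b`.
#'
#' @param intervals Interval table ([provider_intervals()]); may span many
#'   patients (pairs are formed within patient only).
#' @return A `data.table` with `patient_id`, `provider_a`, `provider_b`,
#'   `start_date`, `end_date`.
#' @export
temporal_pairs <- function(intervals) {
  intervals <- as.data.table(intervals)
  empty <- data.table(patient_id = character(), provider_a = character(),
                      provider_b = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()))
  if (nrow(intervals) == 0) return(empty)
  if (anyDuplicated(intervals[, .(patient_id, provider_id)])) {
    stop("temporal_pairs expects one interval per (patient, provider)",
         call. = FALSE)
  }
  x <- copy(intervals)
  pairs <- x[x, on = "patient_id", allow.cartesian = TRUE][
    provider_id < i.provider_id]
  if (nrow(pairs) == 0) return(empty)
  pairs[, `:=`(start_date = pmax(enter_date, i.enter_date),
               end_date = pmin(exit_date, i.exit_date))]
  out <- pairs[start_date <= end_date,
               .(patient_id, provider_a = provider_id,
                 provider_b = i.provider_id, start_date, end_date)]
  setorder(out, patient_id, provider_a, provider_b)
  out[]
}

#' Atemporal provider pairs
#'
#' The traditional pairwise baseline: for each patient, every unordered pair
#' of distinct providers who treated that patient, regardless of when.
#'
#' @param appointments Appointment table; pairs are formed within patient.
#' @return A `data.table` with `patient_id`, `provider_a`, `provider_b` in
#'   canonical order.
#' @export
atemporal_pairs <- function(appointments) {
  appointments <- as.data.table(appointments)
  empty <- data.table(patient_id = character(), provider_a = character(),
                      provider_b = character())
  if (nrow(appointments) == 0) return(empty)
  seen <- unique(appointments[, .(patient_id, provider_id)])
  pairs <- seen[seen, on = "patient_id", allow.cartesian = TRUE][
    provider_id < i.provider_id,
    .(patient_id, provider_a = provider_id, provider_b = i.provider_id)]
  setorder(pairs, patient_id, provider_a, provider_b)
  pairs[]
}

#' Aggregate per-patient pairs into weighted edges for a window
#'
#' Temporal aggregation counts a patient toward a provider pair when the
#' pair's relationship span qualifies under the window's containment policy:
#' with `"contained"` the whole span must lie inside the window, with
#' `"intersects"` sharing one day suffices. Atemporal aggregation counts a
#' patient when **both** providers have at least one appointment with that
#' patient inside the window (the minimal timing assumption that lets the
#' atemporal network be windowed at all); it therefore needs the appointment
#' table. Edge weight is the number of distinct qualifying patients; pairs
#' with weight zero are omitted.
#'
#' @param pairs Output of [temporal_pairs()] (for `kind = "temporal"`) or
#'   [atemporal_pairs()] (for `kind = "atemporal"`).
#' @param kind `"temporal"` or `"atemporal"`; mixing pair tables and kinds is
#'   an error.
#' @param window An [analysis_window()].
#' @param appointments Required when `kind = "atemporal"`.
#' @return A `data.table` with `provider_a`, `provider_b`, `weight`, `kind`,
#'   `window_start`, `window_end`, canonically ordered.
#' @export
aggregate_edges <- function(pairs, kind = c("temporal", "atemporal"),
                            window, appointments = NULL) {
  kind <- match.arg(kind)
  window <- as_window(window)
  pairs <- as.data.table(pairs)
  has_span <- all(c("start_date", "end_date") %in% names(pairs))
  if (kind == "temporal" && !has_span && nrow(pairs) > 0) {
    stop("temporal aggregation needs pair relationships with start/end dates",
         call. = FALSE)
  }
  if (kind == "atemporal" && has_span) {
    stop("atemporal aggregation got temporal pair relationships; pass ",
         "atemporal_pairs() output", call. = FALSE)
  }

  if (kind == "temporal") {
    qual <- if (nrow(pairs) == 0) pairs else if
    (window$containment_policy == "contained") {
      pairs[start_date >= window$start & end_date <= window$end]
    } else {
      pairs[start_date <= window$end & end_date >= window$start]
    }
  } else {
    if (is.null(appointments)) {
      stop("atemporal aggregation requires the appointment table",
           call. = FALSE)
    }
    appointments <- as.data.table(appointments)
    present <- unique(appointments[date >= window$start & date <= window$end,
                                   .(patient_id, provider_id)])
    qual <- pairs[present, on = c("patient_id", provider_a = "provider_id"),
                  nomatch = NULL]
    qual <- qual[present, on = c("patient_id", provider_b = "provider_id"),
                 nomatch = NULL]
  }

  if (nrow(qual) == 0) {
    return(data.table(provider_a = character(), provider_b = character(),
                      weight = integer(), kind = character(),
                      window_start = as.Date(character()),
                      window_end = as.Date(character())))
  }
  out <- qual[, .(weight = uniqueN(patient_id)),
              by = .(provider_a, provider_b)]
  kind_label <- kind
  out[, `:=`(kind = kind_label, window_start = window$start,
             window_end = window$end)]
  setorder(out, provider_a, provider_b)
  out[]
}

#' Build a network snapshot for a window
#'
#' Nodes are all providers with at least one appointment inside the window,
#' including isolates; node weight is the number of distinct patients the
#' provider saw in the window. Edges are the supplied aggregated edges,
#' whose endpoints must all be active in the window.
#'
#' @param appointments Appointment table.
#' @param edges Aggregated edges computed over the same window
#'   ([aggregate_edges()]); may mix kinds only if deduplicated upstream.
#' @param window An [analysis_window()].
#' @return A `network_snapshot`: list with `nodes` (provider_id,
#'   patient_count), `edges`, `window`.
#' @export
build_snapshot <- function(appointments, edges, window) {
  window <- as_window(window)
  appointments <- as.data.table(appointments)
  edges <- as.data.table(edges)
  active <- appointments[date >= window$start & date <= window$end]
  nodes <- if (nrow(active)) {
    active[, .(patient_count = uniqueN(patient_id)), by = provider_id]
  } else {
    data.table(provider_id = character(), patient_count = integer())
  }
  setorder(nodes, provider_id)
  stray <- setdiff(unique(c(edges$provider_a, edges$provider_b)),
                   nodes$provider_id)
  if (length(stray)) {
    stop(sprintf(
      "edge endpoint(s) without appointments in window: %s",
      paste(head(stray, 3), collapse = ", ")), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, window = window),
            class = "network_snapshot")
}

#' @export
print.network_snapshot <- function(x, ...) {
  cat(sprintf("<network_snapshot: %d node(s), %d edge(s), %s .. %s>\n",
              nrow(x$nodes), nrow(x$edges),
              format(x$window$start), format(x$window$end)))
  invisible(x)
}
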