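#' Construct an analysis window
#'
#' A window is a closed date interval `[start, end]` over which edges are
#' aggregated and snapshots are taken, together with the rule used to decide
#' whether a temporal pair relationship belongs to the window.
#'
#' @param start,end Inclusive window bounds (`Date` or `"YYYY-MM-DD"`).
#' @param anchor How the window is anchored in time: `"absolute"` (calendar
#'   dates), `"relative_to_diagnosis"` or `"relative_to_provider_enter"`.
#'   The anchor is descriptive metadata carried into reports; relative
#'   windows are materialised as absolute dates before use.
#' @param containment_policy `"contained"` counts a relationship only when
#'   its whole `[start_date, end_date]` span lies inside the window;
#'   `"intersects"` counts it when the spans share at least one day.
#' @return An object of class `analysis_window`.
#' @examples
#' analysis_window("2010-01-01", "2010-12-31")
#' @export
analysis_window <- function(start, end,
                            anchor = c("absolute", "relative_to_diagnosis",
                                       "relative_to_provider_enter"),
                            containment_policy = c("contained", "intersects")) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) {
    stop("window bounds must be valid dates", call. = FALSE)
  }
  if (start > end) {
    stop("window start must not be after window end", call. = FALSE)
  }
  structure(
    list(start = start, end = end,
         anchor = match.arg(anchor),
         containment_policy = match.arg(containment_policy)),
    class = "analysis_window"
  )
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window %s .. %s, anchor=%s, policy=%s>\n",
              format(x$start), format(x$end), x$anchor,
              x$containment_policy))
  invisible(x)
}

#' Window spanning a calendar year
#'
#' @param year Calendar year (integer).
#' @param containment_policy Passed to [analysis_window()].
#' @return An `analysis_window` covering `year`-01-01 to `year`-12-31.
#' @export
year_window <- function(year, containment_policy = "contained") {
  analysis_window(sprintf("%d-01-01", year), sprintf("%d-12-31", year),
                  containment_policy = containment_policy)
}

#' Window covering a set of appointments
#'
#' Convenience constructor for whole-study analyses: the tightest absolute
#' window containing every appointment date.
#'
#' @param appointments Appointment table (see [read_appointments()]).
#' @param containment_policy Passed to [analysis_window()].
#' @return An `analysis_window`.
#' @export
full_window <- function(appointments, containment_policy = "contained") {
  if (nrow(appointments) == 0) {
    return(analysis_window("1900-01-01", "1900-01-01",
                           containment_policy = containment_policy))
  }
  analysis_window(min(appointments$date), max(appointments$date),
                  containment_policy = containment_policy)
}

# Average month / year lengths used for tenure and relative-time bucketing.
# Fixed fractional lengths keep buckets equal-width and reproducible across
# calendar irregularities.
MONTH_DAYS <- 30.44
YEAR_DAYS <- 365.25

as_window <- function(x) {
  if (inherits(x, "analysis_window")) return(x)
  stop("expected an analysis_window object", call. = FALSE)
}
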