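#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the published cohort the generator emulates: 4082
#' early-stage breast-cancer patients diagnosed 2002-2016 with stage mix
#' 2116/1452/514 (I/II/III); 15.3 distinct providers per patient (median 12)
#' and 72.7 appointment rows per patient (median 54); network retention of
#' 71.4% at two years, 43% at five and 14% at ten; and 39.8% of providers
#' appearing for a single appointment. Counts use shifted negative-binomial
#' draws (mean/size); the size parameters 1.5 and 1.2 place the medians at
#' the printed values for the given means. Retention follows a
#' piecewise-exponential survival curve through the knots, so each knot is
#' met exactly in expectation.
#'
#' @param n_patients Number of patients to simulate.
#' @param diagnosis_start,diagnosis_end Bounds of the uniform diagnosis-date
#'   window.
#' @param study_end End of the observation period; follow-up is truncated
#'   here.
#' @param stage_probs Named probabilities for stages I/II/III (sum to 1).
#' @param providers_per_patient,appointments_per_patient Lists with `mean`
#'   and `size` (negative-binomial dispersion) for the per-patient counts.
#'   The two counts are coupled comonotonically: patients who see many
#'   providers also have many appointments.
#' @param retention_knots Named survival fractions; names are horizons in
#'   years. Must be strictly decreasing.
#' @param provider_pool_size Size of the institutional provider pool.
#' @param oncology_fraction Fraction of the pool drawn from oncology-related
#'   specialties.
#' @param oncology_specialties,other_specialties Specialty label sets.
#' @param single_visit_provider_weight Fraction of the pool constrained to a
#'   single appointment overall (transient providers).
#' @param popularity_exponent Exponent `a` of the rank-based popularity
#'   weights `rank^-a` over the pool; larger values concentrate care in
#'   fewer providers.
#' @param oncology_frontload List with `amplitude` and `decay_days`: the
#'   sampling weight of oncology-related providers is multiplied by
#'   `1 + amplitude * exp(-days_since_diagnosis / decay_days)`, so the
#'   oncology share of visits is highest in the first year after diagnosis.
#' @param prediagnosis_mean Mean number of pre-diagnosis appointments per
#'   patient (Poisson; default 0, i.e. no pre-diagnosis block).
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(
    n_patients = 4082L,
    diagnosis_start = "2002-01-01",
    diagnosis_end = "2016-12-31",
    study_end = "2016-12-31",
    stage_probs = c(I = 2116, II = 1452, III = 514) / 4082,
    providers_per_patient = list(mean = 15.3, size = 1.5),
    appointments_per_patient = list(mean = 72.7, size = 1.2),
    retention_knots = c(`2` = 0.714, `5` = 0.43, `10` = 0.14),
    provider_pool_size = 2500L,
    oncology_fraction = 0.12,
    oncology_specialties = c("medical oncology", "radiation oncology",
                             "surgical oncology", "hematology/oncology",
                             "gynecologic oncology"),
    other_specialties = c("internal medicine", "family medicine",
                          "obstetrics/gynecology", "radiology", "pathology",
                          "cardiology", "dermatology", "endocrinology",
                          "gastroenterology", "physical therapy",
                          "plastic surgery", "general surgery", "psychiatry",
                          "anesthesiology", "ophthalmology", "orthopedics",
                          "urology", "neurology", "pulmonology", "nursing"),
    single_visit_provider_weight = 0.398,
    popularity_exponent = 1.1,
    oncology_frontload = list(amplitude = 4, decay_days = 365),
    prediagnosis_mean = 0) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    diagnosis_start = as.Date(diagnosis_start),
    diagnosis_end = as.Date(diagnosis_end),
    study_end = as.Date(study_end),
    stage_probs = stage_probs,
    providers_per_patient = providers_per_patient,
    appointments_per_patient = appointments_per_patient,
    retention_knots = retention_knots,
    provider_pool_size = as.integer(provider_pool_size),
    oncology_fraction = oncology_fraction,
    oncology_specialties = oncology_specialties,
    other_specialties = other_specialties,
    single_visit_provider_weight = single_visit_provider_weight,
    popularity_exponent = popularity_exponent,
    oncology_frontload = oncology_frontload,
    prediagnosis_mean = prediagnosis_mean
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_patients <= 0 || cfg$provider_pool_size <= 0) {
    stop("n_patients and provider_pool_size must be positive", call. = FALSE)
  }
  if (abs(sum(cfg$stage_probs) - 1) > 1e-9) {
    stop("stage_probs must sum to 1", call. = FALSE)
  }
  if (length(cfg$stage_probs) != 3 ||
      !setequal(names(cfg$stage_probs), c("I", "II", "III"))) {
    stop("stage_probs must be named I, II, III", call. = FALSE)
  }
  kn <- cfg$retention_knots
  if (is.null(names(kn)) || any(is.na(as.numeric(names(kn))))) {
    stop("retention_knots must be named by horizon in years", call. = FALSE)
  }
  if (any(diff(as.numeric(names(kn))) <= 0) || any(diff(kn) >= 0) ||
      any(kn <= 0) || any(kn >= 1)) {
    stop("retention_knots must be strictly decreasing fractions in (0, 1) ",
         "at increasing horizons", call. = FALSE)
  }
  for (fld in c("providers_per_patient", "appointments_per_patient")) {
    d <- cfg[[fld]]
    if (!is.list(d) || is.null(d$mean) || is.null(d$size) ||
        d$mean <= 1 || d$size <= 0) {
      stop(sprintf("%s needs mean > 1 and size > 0", fld), call. = FALSE)
    }
  }
  if (cfg$diagnosis_start > cfg$diagnosis_end ||
      cfg$diagnosis_end > cfg$study_end) {
    stop("need diagnosis_start <= diagnosis_end <= study_end", call. = FALSE)
  }
  if (cfg$single_visit_provider_weight < 0 ||
      cfg$single_visit_provider_weight >= 1) {
    stop("single_visit_provider_weight must be in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

# Inverse-CDF sampler for the piecewise-exponential follow-up curve defined
# by the retention knots; the hazard of the last segment extends beyond the
# last knot. Returns follow-up in years.
sample_followup_years <- function(n, knots) {
  t_k <- as.numeric(names(knots))
  h_k <- -log(as.numeric(knots))            # cumulative hazard at knots
  t0 <- c(0, t_k[-length(t_k)])
  h0 <- c(0, h_k[-length(h_k)])
  lam <- (h_k - h0) / (t_k - t0)            # per-segment hazard rates
  hstar <- -log(runif(n))
  seg <- findInterval(hstar, h_k) + 1L      # segment index; > last => tail
  seg_t0 <- c(t0, t_k[length(t_k)])
  seg_h0 <- c(h0, h_k[length(h_k)])
  seg_lam <- c(lam, lam[length(lam)])
  seg_t0[seg] + (hstar - seg_h0[seg]) / seg_lam[seg]
}

#' Generate a synthetic breast-cancer cohort
#'
#' Draws registry, provider and appointment tables with the statistical
#' structure described in [generator_config()]. The procedure per patient:
#' diagnosis date uniform in the diagnosis window and stage from the stage
#' mix; follow-up from the piecewise-exponential retention curve, truncated
#' at `study_end`; provider and appointment counts from comonotonically
#' coupled shifted negative binomials; providers sampled from a rank-decay
#' popularity distribution over the pool (transient providers are exhausted
#' after their single appointment); appointment dates placed in
#' `[diagnosis, diagnosis + follow-up]` with the first at diagnosis and the
#' last at the end of follow-up, and providers assigned to dates with
#' oncology-related providers up-weighted early after diagnosis.
#'
#' Every patient has an appointment on the diagnosis day, so the whole
#' cohort passes [filter_cohort()]. Output is deterministic for a fixed
#' seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; all randomness flows through it.
#' @return A list with `registry`, `providers`, `appointments` tables and
#'   the `config` and `seed` used.
#' @export
generate_cohort <- function(config = generator_config(), seed) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  if (missing(seed) || is.na(as.integer(seed))) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  set.seed(as.integer(seed))
  cfg <- config
  pool <- cfg$provider_pool_size

  # --- provider pool ---------------------------------------------------
  prov_ids <- sprintf("dr%05d", seq_len(pool))
  is_onc <- runif(pool) < cfg$oncology_fraction
  specialty <- character(pool)
  specialty[is_onc] <- sample(cfg$oncology_specialties, sum(is_onc),
                              replace = TRUE)
  specialty[!is_onc] <- sample(cfg$other_specialties, sum(!is_onc),
                               replace = TRUE)
  fte <- rep("unknown", pool)
  med_onc <- which(specialty == "medical oncology")
  fte[med_onc] <- sample(c("full_time", "part_time"), length(med_onc),
                         replace = TRUE, prob = c(2 / 3, 1 / 3))
  popularity <- sample(seq_len(pool)^(-cfg$popularity_exponent))
  n_transient <- round(cfg$single_visit_provider_weight * pool)
  transient <- rep(FALSE, pool)
  transient[sample.int(pool, n_transient)] <- TRUE

  # --- patient-level draws ---------------------------------------------
  n <- cfg$n_patients
  pat_ids <- sprintf("pt%05d", seq_len(n))
  diag_span <- as.integer(cfg$diagnosis_end - cfg$diagnosis_start)
  diagnosis <- cfg$diagnosis_start +
    floor(runif(n) * (diag_span + 1))
  stage <- sample(c("I", "II", "III"), n, replace = TRUE,
                  prob = cfg$stage_probs[c("I", "II", "III")])
  fu_days <- round(sample_followup_years(n, cfg$retention_knots) * YEAR_DAYS)
  fu_days <- pmin(fu_days, as.integer(cfg$study_end - diagnosis))
  u_counts <- runif(n)
  k_prov <- 1L + qnbinom(u_counts, size = cfg$providers_per_patient$size,
                         mu = cfg$providers_per_patient$mean - 1)
  n_appt <- 1L + qnbinom(u_counts, size = cfg$appointments_per_patient$size,
                         mu = cfg$appointments_per_patient$mean - 1)
  n_appt <- pmax(n_appt, k_prov)
  n_pre <- if (cfg$prediagnosis_mean > 0) {
    stats::rpois(n, cfg$prediagnosis_mean)
  } else {
    integer(n)
  }

  # --- per-patient appointment assembly --------------------------------
  amp <- cfg$oncology_frontload$amplitude
  decay <- cfg$oncology_frontload$decay_days
  transient_used <- rep(FALSE, pool)
  out_prov <- vector("list", n)
  out_date <- vector("list", n)
  for (i in seq_len(n)) {
    wt <- popularity
    wt[transient & transient_used] <- 0
    k_i <- min(k_prov[i], sum(wt > 0))
    picked <- sample.int(pool, k_i, prob = wt)
    trans_i <- picked[transient[picked]]
    regs_i <- picked[!transient[picked]]
    transient_used[trans_i] <- TRUE
    n_i <- if (length(regs_i) == 0) k_i else n_appt[i]
    t_i <- fu_days[i]
    d <- if (n_i == 1L) 0L else
      c(0L, t_i, if (n_i > 2L) as.integer(floor(runif(n_i - 2L) * (t_i + 1))))
    d <- sort(d)

    # anchors: one slot per provider, oncology-related providers biased to
    # early slots via the front-loading weight
    slot_w_onc <- 1 + amp * exp(-d / decay)
    slots <- seq_len(n_i)
    onc_first <- c(picked[is_onc[picked]], picked[!is_onc[picked]])
    anchor_slot <- integer(k_i)
    remaining <- slots
    for (j in seq_len(k_i)) {
      pj <- onc_first[j]
      wj <- if (is_onc[pj]) slot_w_onc[remaining] else rep(1, length(remaining))
      pick <- if (length(remaining) == 1L) remaining else
        remaining[sample.int(length(remaining), 1L, prob = wj)]
      anchor_slot[j] <- pick
      remaining <- setdiff(remaining, pick)
    }
    assignee <- integer(n_i)
    assignee[anchor_slot] <- onc_first

    # remaining slots go to non-transient providers only, split between the
    # oncology and other groups by the time-decaying mixture weight
    if (length(remaining) > 0) {
      regs_onc <- regs_i[is_onc[regs_i]]
      regs_oth <- regs_i[!is_onc[regs_i]]
      w_onc_grp <- length(regs_onc) * slot_w_onc[remaining]
      p_onc <- w_onc_grp / (w_onc_grp + length(regs_oth))
      go_onc <- runif(length(remaining)) < p_onc
      fill <- integer(length(remaining))
      if (any(go_onc)) {
        fill[go_onc] <- regs_onc[
          ceiling(runif(sum(go_onc)) * length(regs_onc))]
      }
      if (any(!go_onc)) {
        fill[!go_onc] <- regs_oth[
          ceiling(runif(sum(!go_onc)) * length(regs_oth))]
      }
      assignee[remaining] <- fill
    }

    if (n_pre[i] > 0 && length(regs_i) > 0) {
      lb <- as.integer(diagnosis[i] -
                         add_months_clamped(diagnosis[i], -24L))
      d_pre <- -as.integer(ceiling(runif(n_pre[i]) * lb))
      p_pre <- regs_i[ceiling(runif(n_pre[i]) * length(regs_i))]
      d <- c(d, d_pre)
      assignee <- c(assignee, p_pre)
    }
    out_prov[[i]] <- assignee
    out_date[[i]] <- as.integer(diagnosis[i]) + d
  }

  appointments <- data.table(
    patient_id = rep(pat_ids, lengths(out_prov)),
    provider_id = prov_ids[unlist(out_prov)],
    date = as.Date(unlist(out_date), origin = "1970-01-01")
  )
  setorder(appointments, patient_id, date, provider_id)

  used <- sort(unique(appointments$provider_id))
  providers <- data.table(provider_id = prov_ids, specialty = specialty,
                          oncology_related = is_onc, fte_status = fte)
  providers <- providers[provider_id %in% used]
  setorder(providers, provider_id)

  registry <- data.table(patient_id = pat_ids, diagnosis_date = diagnosis,
                         stage = stage)
  list(registry = registry[], providers = providers[],
       appointments = appointments[], config = cfg,
       seed = as.integer(seed))
}

#' Recompute the generator's calibration statistics from a cohort
#'
#' Measures, from the three tables alone, the statistics the generator is
#' calibrated to: mean and median providers and appointment rows per
#' patient, retention at the configured horizons (at-risk denominators) and
#' the single-appointment provider fraction. When a config is supplied the
#' configured targets are reported alongside.
#'
#' @param registry,providers,appointments Cohort tables.
#' @param config Optional [generator_config()] providing targets and
#'   `study_end`.
#' @return A `measure_report` with a `calibration` table (columns `metric`,
#'   `observed`, `target`).
#' @export
validate_cohort <- function(registry, providers, appointments,
                            config = NULL) {
  registry <- as.data.table(registry)
  appointments <- as.data.table(appointments)
  horizons <- if (!is.null(config)) {
    as.numeric(names(config$retention_knots))
  } else {
    c(2, 5, 10)
  }
  study_end <- if (!is.null(config)) config$study_end else
    if (nrow(appointments)) max(appointments$date) else as.Date(NA)

  if (nrow(appointments) == 0) {
    per <- data.table(n_providers = numeric(), n_appointments = numeric())
    single_frac <- 0
    ret <- data.table(horizon_years = horizons, fraction = 0)
  } else {
    per <- appointments[, .(n_providers = uniqueN(provider_id),
                            n_appointments = .N), by = patient_id]
    by_prov <- appointments[, .N, by = provider_id]
    single_frac <- mean(by_prov$N == 1L)
    ret <- patient_retention(appointments, registry,
                             horizons_years = horizons,
                             study_end = study_end)
  }
  stat <- function(x, f) if (nrow(per) == 0) 0 else f(x)
  metrics <- data.table(
    metric = c("providers_per_patient_mean", "providers_per_patient_median",
               "appointments_per_patient_mean",
               "appointments_per_patient_median",
               paste0("retention_", horizons, "y"),
               "single_visit_provider_fraction"),
    observed = c(stat(per$n_providers, mean),
                 stat(per$n_providers, function(x) as.numeric(median(x))),
                 stat(per$n_appointments, mean),
                 stat(per$n_appointments, function(x) as.numeric(median(x))),
                 if (nrow(appointments)) ret$fraction else rep(0, length(horizons)),
                 single_frac)
  )
  if (!is.null(config)) {
    metrics[, target := c(config$providers_per_patient$mean, NA,
                          config$appointments_per_patient$mean, NA,
                          as.numeric(config$retention_knots),
                          config$single_visit_provider_weight)]
  }
  measure_report(list(calibration = metrics),
                 meta = list(analysis = "validate_cohort",
                             study_end = format(study_end)))
}
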