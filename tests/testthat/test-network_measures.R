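make_snapshot <- function(node_ids, edge_pairs, weights = NULL) {
  w <- analysis_window(DAY0, DAY0 + 365)
  nodes <- data.table(provider_id = node_ids,
                      patient_count = rep(1L, length(node_ids)))
  edges <- if (length(edge_pairs)) {
    data.table(
      provider_a = vapply(edge_pairs, `[`, "", 1),
      provider_b = vapply(edge_pairs, `[`, "", 2),
      weight = if (is.null(weights)) rep(1L, length(edge_pairs)) else
        as.integer(weights),
      kind = "temporal", window_start = w$start, window_end = w$end)
  } else {
    data.table(provider_a = character(), provider_b = character(),
               weight = integer(), kind = character(),
               window_start = as.Date(character()),
               window_end = as.Date(character()))
  }
  structure(list(nodes = nodes, edges = edges, window = w),
            class = "network_snapshot")
}

test_that("network_density matches 2E/(N(N-1)) with the N<2 convention", {
  complete3 <- make_snapshot(c("A", "B", "C"),
                             list(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_equal(network_density(complete3), 1)
  four3 <- make_snapshot(c("A", "B", "C", "D"),
                         list(c("A", "B"), c("A", "C"), c("A", "D")))
  expect_equal(network_density(four3), 0.5)
  expect_equal(network_density(make_snapshot("A", list())), 0)
  expect_equal(network_density(make_snapshot(character(), list())), 0)
})

test_that("care_density is the mean edge weight, 0 when edgeless", {
  expect_equal(care_density(make_snapshot(c("A", "B"), list(c("A", "B")), 5)), 5)
  expect_equal(care_density(make_snapshot(c("A", "B", "C"),
                                          list(c("A", "B"), c("A", "C")),
                                          c(2, 4))), 3)
  all1 <- make_snapshot(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
  expect_equal(care_density(all1), 1)
  expect_equal(care_density(make_snapshot(c("A", "B"), list())), 0)
  # invariant under edge reordering
  s <- make_snapshot(c("A", "B", "C"), list(c("A", "B"), c("B", "C")), c(7, 1))
  s2 <- s
  s2$edges <- s$edges[2:1]
  expect_equal(care_density(s), care_density(s2))
})

test_that("degree_centrality counts distinct neighbours", {
  star <- make_snapshot(c("A", "B", "C", "D"),
                        list(c("A", "B"), c("A", "C"), c("A", "D")))
  expect_equal(degree_centrality(star, "A"), 3)
  expect_equal(degree_centrality(star, "B"), 1)
  iso <- make_snapshot(c("A", "B"), list())
  expect_equal(degree_centrality(iso, "A"), 0)
  expect_error(degree_centrality(star, "ZZ"), "not a node")

  # oracle equivalence on random graphs
  set.seed(11)
  for (rep in 1:5) {
    ids <- sprintf("n%02d", 1:8)
    pool <- t(combn(ids, 2))
    pick <- sample(nrow(pool), 12)
    snap <- make_snapshot(ids, lapply(pick, function(i) pool[i, ]))
    for (v in ids) {
      nb <- unique(c(pool[pick, 2][pool[pick, 1] == v],
                     pool[pick, 1][pool[pick, 2] == v]))
      expect_equal(degree_centrality(snap, v), length(nb))
    }
  }
})

test_that("ego_network extracts the star subgraph", {
  tri <- make_snapshot(c("A", "B", "C"),
                       list(c("A", "B"), c("A", "C"), c("B", "C")))
  ego <- ego_network(tri$edges, "A")
  expect_equal(ego$nodes$provider_id, c("A", "B", "C"))
  expect_equal(nrow(ego$edges), 2)
  expect_false(any(ego$edges$provider_a == "B" & ego$edges$provider_b == "C"))

  # ego care density composes with care_density
  star <- make_snapshot(c("A", "B", "C"), list(c("A", "B"), c("A", "C")),
                        c(2, 4))
  expect_equal(care_density(ego_network(star$edges, "A")), 3)

  # isolated provider known only through appointments
  ap <- appts("p1", "lonely", 3)
  solo <- ego_network(tri$edges[0], "lonely", appointments = ap)
  expect_equal(solo$nodes$provider_id, "lonely")
  expect_equal(nrow(solo$edges), 0)
  expect_error(ego_network(tri$edges, "ZZ"), "unknown provider")
})

test_that("single-patient atemporal snapshots are complete graphs", {
  set.seed(12)
  for (rep in 1:5) {
    ap <- random_patient("solo")
    w <- full_window(ap)
    edges <- aggregate_edges(atemporal_pairs(ap), "atemporal", w,
                             appointments = ap)
    snap <- build_snapshot(ap, edges, w)
    if (nrow(snap$nodes) >= 2) expect_equal(network_density(snap), 1)
  }
})

test_that("yearly_institutional_stats matches independent recomputation", {
  reg <- data.table(patient_id = "p1",
                    diagnosis_date = as.Date("2005-03-01"), stage = "I")
  ap <- appts("p1", "A", as.Date("2005-03-01"))
  ys <- yearly_institutional_stats(reg, ap)$tables$yearly
  expect_equal(nrow(ys), 1)
  expect_equal(ys$n_patients, 1L)
  expect_equal(ys$n_providers, 1L)
  expect_equal(ys$temporal_edges, 0L)

  # a year with no activity reports zeros
  ys2 <- yearly_institutional_stats(reg, ap, years = 2005:2006)$tables$yearly
  expect_equal(unlist(ys2[year == 2006, -"year"]), c(
    n_diagnoses = 0, n_patients = 0, n_providers = 0, temporal_edges = 0,
    atemporal_edges = 0, temporal_weight_sum = 0, atemporal_weight_sum = 0,
    temporal_density = 0, atemporal_density = 0))

  # synthetic cohort rows equal per-year recomputation from scratch
  co <- generate_cohort(small_config(30), seed = 21)
  f <- filter_cohort(co$registry, co$appointments,
                     study_end = co$config$study_end, quiet = TRUE)
  tab <- yearly_institutional_stats(f$registry, f$appointments,
                                    years = c(2008, 2012))$tables$yearly
  tp <- temporal_pairs(provider_intervals(f$appointments))
  at <- atemporal_pairs(f$appointments)
  for (y in c(2008, 2012)) {
    w <- year_window(y)
    in_y <- f$appointments[date >= w$start & date <= w$end]
    te <- aggregate_edges(tp, "temporal", w)
    ae <- aggregate_edges(at, "atemporal", w, appointments = f$appointments)
    row <- tab[year == y]
    expect_equal(row$n_patients, uniqueN(in_y$patient_id))
    expect_equal(row$n_providers, uniqueN(in_y$provider_id))
    expect_equal(row$temporal_edges, nrow(te))
    expect_equal(row$atemporal_edges, nrow(ae))
    expect_equal(row$temporal_weight_sum, sum(te$weight))
    expect_equal(row$atemporal_weight_sum, sum(ae$weight))
    expect_equal(row$n_diagnoses,
                 sum(format(f$registry$diagnosis_date, "%Y") == y))
  }
})

test_that("temporal degree centrality never exceeds atemporal", {
  co <- generate_cohort(small_config(40), seed = 31)
  f <- filter_cohort(co$registry, co$appointments,
                     study_end = co$config$study_end, quiet = TRUE)
  w <- full_window(f$appointments)
  te <- aggregate_edges(temporal_pairs(provider_intervals(f$appointments)),
                        "temporal", w)
  ae <- aggregate_edges(atemporal_pairs(f$appointments), "atemporal", w,
                        appointments = f$appointments)
  snap_t <- build_snapshot(f$appointments, te, w)
  snap_a <- build_snapshot(f$appointments, ae, w)
  for (v in snap_t$nodes$provider_id) {
    expect_lte(degree_centrality(snap_t, v), degree_centrality(snap_a, v))
  }
})

test_that("relative_care_density windows by year since provider entry", {
  # hand-built ego: year 1 holds weights {2, 2}, year 2 holds {6}
  mk <- function(pids, partner, day) {
    rbind(appts(pids, "EGO", day), appts(pids, partner, day))
  }
  ap <- rbind(
    mk(c("p1", "p2"), "B", 10), mk(c("p3", "p4"), "C", 40),
    mk(c("q1", "q2", "q3", "q4", "q5", "q6"), "D", 400))
  tp <- temporal_pairs(provider_intervals(ap))
  rcd <- relative_care_density(tp, ap, "EGO")
  expect_equal(rcd$year_in_network, 1:2)
  expect_equal(rcd$care_density, c(2, 6))

  # provider active a single year
  one <- relative_care_density(tp, appts("p1", "B", c(0, 10)), "B")
  expect_equal(nrow(one), 1)

  # empty middle year reported as zero
  gap <- rbind(mk("p1", "B", 5), mk("p2", "B", 800))
  rcd_gap <- relative_care_density(temporal_pairs(provider_intervals(gap)),
                                   gap, "EGO")
  expect_equal(rcd_gap[year_in_network == 2, n_edges], 0L)
  expect_equal(rcd_gap[year_in_network == 2, care_density], 0)

  expect_error(relative_care_density(tp, ap, "ZZ"), "unknown provider")
})

test_that("provider_tenure_stats reports tenure in 30.44-day months", {
  ap <- rbind(appts("p1", "A", c(0, 411)),   # tenure 411 / 30.44 months
              appts("p2", "B", 100))         # single appointment
  rep <- provider_tenure_stats(ap)$tables$tenure
  expect_equal(rep$n_providers, 2L)
  expect_equal(rep$mean_tenure_months, mean(c(411 / 30.44, 0)))
  expect_equal(rep$frac_single_appointment, 0.5)
  expect_equal(rep$frac_ge_1y, 0.5)  # 13.5 months >= 12

  # single-appointment and >=1-year sets are disjoint
  expect_lte(rep$frac_single_appointment + rep$frac_ge_1y, 1)

  prov <- data.table(provider_id = c("A", "B"),
                     specialty = c("medical oncology", "radiology"),
                     oncology_related = c(TRUE, FALSE),
                     fte_status = "unknown")
  both <- provider_tenure_stats(ap, prov)$tables$tenure
  onc <- both[group == "oncology_related"]
  expect_equal(onc$n_providers, 1L)
  expect_equal(onc$mean_tenure_months, 411 / 30.44)
})

test_that("patient_retention applies span and at-risk rules", {
  reg <- data.table(patient_id = c("a", "b", "c"),
                    diagnosis_date = as.Date(c("2008-01-01", "2008-01-01",
                                               "2016-01-01")),
                    stage = "I")
  ap <- rbind(appts("a", "A", as.Date("2008-01-01")),
              appts("a", "A", as.Date("2008-01-01") + 800),  # span 800 d
              appts("b", "A", as.Date("2008-06-01")),        # span 0
              appts("c", "A", as.Date("2016-02-01")))
  ret <- patient_retention(ap, reg, horizons_years = c(2, 5),
                           study_end = "2016-12-31")
  r2 <- ret[horizon_years == 2]
  # c diagnosed < 2y before study_end: excluded from the denominator
  expect_equal(r2$n_at_risk, 2L)
  expect_equal(r2$n_retained, 1L)   # 800 >= 730.5, b's span 0 is not
  expect_equal(r2$fraction, 0.5)
  r5 <- ret[horizon_years == 5]
  expect_equal(r5$n_retained, 0L)   # 800 < 1826.25

  # all-patients denominator keeps everyone
  ret_all <- patient_retention(ap, reg, horizons_years = 2,
                               study_end = "2016-12-31",
                               denominator = "all_patients")
  expect_equal(ret_all$n_at_risk, 3L)

  # single-visit cohort retains nobody at any horizon
  solo <- appts(c("a", "b", "c"), "A",
                as.Date(c("2008-01-01", "2008-01-01", "2016-01-01")))
  ret0 <- patient_retention(solo, reg, horizons_years = c(2, 5),
                            study_end = "2030-01-01")
  expect_true(all(ret0$n_retained == 0))

  # monotone non-increasing over horizons on a fixed at-risk set
  ret_fix <- patient_retention(ap, reg, horizons_years = c(1, 2, 5),
                               study_end = "2016-12-31",
                               denominator = "all_patients")
  expect_true(all(diff(ret_fix$fraction) <= 0))
})

test_that("oncology_fraction_by_month buckets and computes percentages", {
  reg <- data.table(patient_id = "p",
                    diagnosis_date = DAY0, stage = "II")
  prov <- data.table(provider_id = c("onc", "gp"),
                     specialty = c("medical oncology", "family medicine"),
                     oncology_related = c(TRUE, FALSE),
                     fte_status = "unknown")
  # month 0: 3 oncology + 1 other -> 75%; month 2: oncology only -> 100%
  ap <- rbind(appts("p", "onc", c(1, 5, 20)), appts("p", "gp", 10),
              appts("p", "onc", 65))
  out <- oncology_fraction_by_month(ap, reg, prov)
  expect_equal(out$month_since_diagnosis, c(0L, 2L))  # month 1 absent
  expect_equal(out$percent_oncology, c(75, 100))
  expect_equal(out$n_appointments, c(4L, 1L))

  # unknown providers count as non-oncology; stage filter applies
  ap2 <- rbind(ap, appts("p", "mystery", 2))
  out2 <- oncology_fraction_by_month(ap2, reg, prov)
  expect_equal(out2[month_since_diagnosis == 0, percent_oncology], 60)
  expect_equal(nrow(oncology_fraction_by_month(ap, reg, prov,
                                               stage_filter = "I")), 0)
})

test_that("cohort_summary reports recomputable distributions", {
  reg <- data.table(patient_id = c("p1", "p2"),
                    diagnosis_date = DAY0, stage = c("I", "II"))
  ap <- rbind(appts("p1", c("A", "B", "C"), 0),
              appts("p2", c("A", "D", "E", "F", "G"), 0))
  rep <- cohort_summary(reg, ap)
  d <- rep$tables$distributions
  ppp <- d[group == "pooled" & metric == "providers_per_patient"]
  expect_equal(ppp$mean, 4)
  expect_equal(ppp$median, 4)
  expect_equal(c(ppp$min, ppp$max), c(3, 5))

  # single-patient block: mean = median = both range endpoints
  s1 <- d[group == "stage_I" & metric == "providers_per_patient"]
  expect_equal(unlist(s1[, .(mean, median, min, max)]),
               c(mean = 3, median = 3, min = 3, max = 3))

  # pooled provider count equals the union across stages
  counts <- rep$tables$counts
  expect_equal(counts[group == "pooled", n_providers], 7L)
  expect_lte(counts[group == "pooled", n_providers],
             sum(counts[group != "pooled", n_providers]))
})
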