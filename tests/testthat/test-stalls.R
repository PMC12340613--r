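cal <- default_calib()

# hand-built capillary time series for the event logic
make_ts <- function(flux, po2 = NULL, qc = NULL, cap = "c1", revisit = 8) {
  n <- length(flux)
  tibble::tibble(
    capillary_id = cap, visit_index = seq_len(n),
    visit_time_s = (seq_len(n) - 1) * revisit,
    po2 = po2 %||% rep(30, n), flux = flux,
    qc_pass = qc %||% rep(TRUE, n)
  )
}

test_that("event detection follows the zero-flux run definition", {
  expect_equal(nrow(detect_stalls(make_ts(c(8, 9, 7, 8)), 8)), 0L)

  ev <- detect_stalls(make_ts(c(8, 0, 0, 9), po2 = c(30, 8, 10, 31)), 8)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_visit, 2L)
  expect_equal(ev$end_visit, 3L)
  expect_equal(ev$n_visits, 2L)
  expect_equal(ev$duration_s, 16)
  expect_equal(ev$stall_po2, 9)

  # separated runs are distinct events
  ev2 <- detect_stalls(make_ts(c(0, 5, 0, 0, 5, 0)), 8)
  expect_equal(nrow(ev2), 3L)

  # a qc-failed visit breaks a run and flags the adjacent events
  ev3 <- detect_stalls(make_ts(c(8, 0, 0, 0, 8),
                               qc = c(TRUE, TRUE, FALSE, TRUE, TRUE)), 8)
  expect_equal(nrow(ev3), 2L)
  expect_true(all(ev3$qc_break_adjacent))
})

test_that("every zero-flux qc-passing visit belongs to exactly one event", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    flux <- sample(c(0, 0, 5, 8, 12), n, replace = TRUE)
    qc <- runif(n) > 0.1
    ts <- make_ts(flux, qc = qc)
    ev <- detect_stalls(ts, 8)
    covered <- as.integer(unlist(lapply(
      seq_len(nrow(ev)), function(r) seq(ev$start_visit[r], ev$end_visit[r]))))
    expect_equal(sort(covered), sort(ts$visit_index[flux == 0 & qc]))
    expect_equal(anyDuplicated(covered), 0L)
  }
})

test_that("hypoxia classes use strict thresholds and partition the events", {
  cls <- classify_hypoxia(c(4.9, 5, 9.99, 10, 15.4))
  expect_equal(as.character(cls),
               c("severe", "hypoxic", "hypoxic", "normoxic", "normoxic"))
  set.seed(56)
  po2 <- runif(200, 0, 30)
  tab <- table(classify_hypoxia(po2))
  expect_equal(sum(tab), 200)
  expect_equal(unname(tab["severe"]), sum(po2 < 5))
  expect_equal(unname(tab["hypoxic"]), sum(po2 >= 5 & po2 < 10))
})

test_that("scheduled stalls in a simulated session are recovered exactly", {
  acq <- acq_config(n_visits = 9)
  truths <- dplyr::bind_rows(
    quick_truth(capillary_id = "a", rbc_arrivals = "regular",
                stall_schedule = tibble::tibble(start_visit = 3L, end_visit = 3L),
                po2_stalled = 6),
    quick_truth(capillary_id = "b", rbc_arrivals = "regular",
                stall_schedule = tibble::tibble(start_visit = c(2L, 7L),
                                                end_visit = c(2L, 8L)),
                po2_stalled = 20)
  )
  ses <- simulate_session(truths, acq, cal, seed = 58)
  ts <- analyze_session(ses)
  ev <- detect_stalls(ts)
  expect_equal(nrow(ev), 3L)
  sched <- dplyr::bind_rows(lapply(seq_len(nrow(truths)), function(i) {
    s <- truths$stall_schedule[[i]]
    s$capillary_id <- truths$capillary_id[i]
    s
  }))
  got <- ev[order(ev$capillary_id, ev$start_visit),
            c("capillary_id", "start_visit", "end_visit")]
  want <- sched[order(sched$capillary_id, sched$start_visit),
                c("capillary_id", "start_visit", "end_visit")]
  expect_equal(as.data.frame(got), as.data.frame(want))
  expect_equal(as.character(ev$hypoxia_class[ev$capillary_id == "a"]), "hypoxic")
})

test_that("peri-stall alignment collapses events to t = 0", {
  ts <- make_ts(c(8, 9, 0, 0, 10, 8), po2 = c(30, 31, 9, 11, 29, 30))
  ev <- detect_stalls(ts, 8)
  al <- align_peri_stall(ev, ts, max_offset = 2)
  t0 <- al[al$offset == 0, ]
  expect_equal(t0$flux, 0)
  expect_equal(t0$po2, 10) # event mean
  expect_equal(al$po2[al$offset == -1], 31)
  expect_equal(al$po2[al$offset == 1], 29)
  s <- summarize_peri_stall(al)
  expect_equal(s$flux_mean[s$offset == 0], 0)
})

test_that("aligned dynamics show the stall drop and recovery on simulated data", {
  ses <- simulate_stall_cohort(seed = 7, n_stalls = 8L, n_hypoxic = 3L)
  ts <- analyze_session(ses)
  ev <- detect_stalls(ts)
  s <- summarize_peri_stall(align_peri_stall(ev, ts, max_offset = 2))
  expect_equal(s$flux_mean[s$offset == 0], 0)
  expect_gt(s$po2_mean[s$offset == -1] - s$po2_mean[s$offset == 0], 5)
  expect_gt(s$po2_mean[s$offset == 1] - s$po2_mean[s$offset == 0], 5)
  expect_gt(s$flux_mean[s$offset == 1], 5)
})

test_that("pre/post pO2 differences center on zero for stationary capillaries", {
  set.seed(59)
  diffs <- replicate(100, {
    po2 <- rnorm(9, 30, 2)
    flux <- c(8, 8, 8, 8, 0, 8, 8, 8, 8)
    ts <- make_ts(flux, po2 = po2)
    ev <- detect_stalls(ts, 8)
    al <- align_peri_stall(ev, ts, max_offset = 3)
    mean(al$po2[al$offset < 0]) - mean(al$po2[al$offset > 0])
  })
  expect_lt(abs(mean(diffs)), 3 * 2 * sqrt(2 / 3) / sqrt(100))
})

test_that("stall-vs-tissue regression matches closed forms and the oracle", {
  x <- c(10, 20, 30, 40, 55)
  cmp <- tibble::tibble(tissue_po2 = x, stall_po2 = 0.8 * x - 4)
  fit <- fit_stall_vs_tissue(cmp)
  expect_equal(fit$slope, 0.8, tolerance = 1e-12)
  expect_equal(fit$intercept, -4, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  fit_id <- fit_stall_vs_tissue(tibble::tibble(tissue_po2 = x, stall_po2 = x))
  expect_equal(fit_id$slope, 1, tolerance = 1e-12)

  set.seed(60)
  for (i in 1:10) {
    xx <- runif(20, 5, 60)
    yy <- 0.7 * xx - 2 + rnorm(20, 0, 8)
    f <- fit_stall_vs_tissue(tibble::tibble(tissue_po2 = xx, stall_po2 = yy))
    o <- oracle_ols(xx, yy)
    expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-10)
  }

  expect_error(fit_stall_vs_tissue(cmp[1:2, ]), "fewer than 3")
  expect_error(fit_stall_vs_tissue(
    tibble::tibble(tissue_po2 = rep(20, 5), stall_po2 = 1:5)), "variance")

  # per-group fits stay separate
  cmp2 <- dplyr::bind_rows(
    tibble::tibble(tissue_po2 = x, stall_po2 = 0.79 * x - 4, group = "awake"),
    tibble::tibble(tissue_po2 = x, stall_po2 = 0.61 * x + 16, group = "anesthesia")
  )
  f2 <- fit_stall_vs_tissue(cmp2)
  expect_equal(f2$slope[f2$group == "awake"], 0.79, tolerance = 1e-10)
  expect_equal(f2$slope[f2$group == "anesthesia"], 0.61, tolerance = 1e-10)
  expect_equal(nrow(tidy(f2)), 4L)
})

test_that("neighbor tables compare stall-concurrent and reference windows", {
  # neighbor identical in both conditions: delta 0, ratio 1
  staller <- make_ts(c(8, 8, 0, 8, 8), cap = "s")
  neighbor <- make_ts(rep(6, 5), po2 = rep(25, 5), cap = "n")
  ts <- dplyr::bind_rows(staller, neighbor)
  ev <- detect_stalls(ts, 8)
  ne <- neighbor_effects(ts, ev)
  expect_equal(nrow(ne), 1L)
  expect_equal(ne$delta_po2, 0)
  expect_equal(ne$flux_ratio, 1)

  # no events: empty table
  ts0 <- dplyr::bind_rows(make_ts(rep(8, 5), cap = "a"), make_ts(rep(6, 5), cap = "b"))
  expect_equal(nrow(neighbor_effects(ts0, detect_stalls(ts0, 8))), 0L)
})

test_that("an injected neighbor effect is recovered and attenuates with distance", {
  acq <- acq_config(n_visits = 8)
  deltas <- t(sapply(1:6, function(s) {
    truths <- dplyr::bind_rows(
      quick_truth(capillary_id = "staller", rbc_arrivals = "regular",
                  count_rate_plasma = 10, po2_stalled = 5,
                  stall_schedule = tibble::tibble(start_visit = 3L, end_visit = 6L)),
      quick_truth(capillary_id = "near", rbc_arrivals = "regular",
                  count_rate_plasma = 10, x_um = 10),
      quick_truth(capillary_id = "far", rbc_arrivals = "regular",
                  count_rate_plasma = 10, x_um = 400)
    )
    ses <- simulate_session(truths, acq, cal, seed = 600 + s,
                            neighbor_coupling = list(delta_po2 = -3,
                                                     flux_ratio = 0.96,
                                                     range_um = 50))
    ts <- analyze_session(ses)
    ne <- neighbor_effects(ts, detect_stalls(ts))
    c(near = ne$delta_po2[ne$capillary_id == "near"],
      far = ne$delta_po2[ne$capillary_id == "far"])
  }))
  expect_lt(mean(deltas[, "near"]), 0)
  expect_lt(mean(deltas[, "near"]), mean(deltas[, "far"]))
})

test_that("duration histograms count events, not capillaries", {
  ev <- tibble::tibble(n_visits = c(1L, 1L, 1L, 2L, 4L),
                       duration_s = c(8, 8, 8, 16, 32))
  h <- stall_duration_histogram(ev)
  expect_equal(h$n_events[h$n_visits == 1], 3L)
  expect_equal(h$n_events[h$n_visits == 2], 1L)
  expect_equal(h$n_events[h$n_visits == 4], 1L)
  expect_equal(h$duration_s, h$n_visits * 8)
  expect_equal(sum(h$n_events), 5L)

  h5 <- stall_duration_histogram(
    tibble::tibble(n_visits = rep(1L, 5), duration_s = rep(8, 5)))
  expect_equal(nrow(h5), 1L)
  expect_equal(h5$n_events, 5L)
})
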