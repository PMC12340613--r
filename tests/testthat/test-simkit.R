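cal <- default_calib()

test_that("default acquisition gives 300 ms per point", {
  acq <- acq_config()
  expect_equal(cycle_duration_us(acq), 300)
  expect_equal(visit_duration_s(acq), 0.3)
})

test_that("a 10-minute session at 8 s revisit yields 75 visits per capillary", {
  n_visits <- floor(600 / 8)
  expect_equal(n_visits, 75)
  acq <- acq_config(n_visits = n_visits, n_cycles = 10L)
  truths <- dplyr::bind_rows(lapply(1:15, function(i)
    capillary_truth(capillary_id = paste0("c", i), count_rate_plasma = 2,
                    count_rate_rbc = 0.2)))
  ses <- simulate_session(truths, acq, cal, seed = 1)
  expect_equal(nrow(ses$ledger), 15 * 75)
  per_cap <- table(ses$ledger$capillary_id)
  expect_true(all(per_cap == 75))
  # visits interleave: capillary offsets are spread within one revisit interval
  t1 <- ses$ledger$visit_time_s[ses$ledger$visit_index == 1]
  expect_equal(sort(unique(t1)), (0:14) * 8 / 15)
})

test_that("an always-stalled capillary emits one clean lifetime and no dips", {
  p <- 12
  truth <- capillary_truth(po2_stalled = p, count_rate_plasma = 30,
                           stall_schedule = tibble::tibble(start_visit = 1L,
                                                           end_visit = 3L))
  acq <- acq_config(n_visits = 3)
  pm <- simulate_point_measurement(truth, acq, 2, cal, seed = 5)
  tr <- build_intensity_trace(pm)
  bt <- binarize_otsu(tr)
  expect_equal(nrow(bt$rbc_intervals), 0L)
  f <- fit_decay(build_decay(pm))
  expect_equal(as.numeric(lifetime_to_po2(f$tau_us, cal)), p, tolerance = 0.05 * p)
  expect_equal(f$tau_us, po2_to_lifetime(p, cal), tolerance = 0.02)
})

test_that("mean counts per cycle follow the RBC occupancy", {
  # occupancy = flux * transit = 10/s * 10 ms = 0.10; RBC phase emits nothing
  truth <- capillary_truth(flux_rate = 10, rbc_transit_ms = 10,
                           count_rate_plasma = 20, count_rate_rbc = 0,
                           rbc_arrivals = "regular")
  acq <- acq_config(n_visits = 1)
  pm <- simulate_point_measurement(truth, acq, 1, cal, seed = 21)
  expected <- 20 * (1 - 10 * 0.010)
  sigma <- sqrt(expected / acq$n_cycles) # Poisson total over 1000 cycles
  counts <- build_intensity_trace(pm)$counts
  expect_lt(abs(mean(counts) - expected), 3 * sigma + 20 * 0.01)
})

test_that("photon totals are Poisson-consistent on constant-rate segments", {
  truth <- capillary_truth(flux_rate = 0, count_rate_plasma = 15)
  acq <- acq_config(n_visits = 1, n_cycles = 100L)
  set.seed(31)
  counts <- unlist(lapply(1:200, function(i) {
    v <- simulate_point_measurement(truth, acq, 1, cal)
    build_intensity_trace(v)$counts
  }))
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.05)
})

test_that("pooled arrivals from the generator refit their true lifetime within 1%", {
  p <- 50
  truth <- capillary_truth(flux_rate = 0, po2_flowing = p, tissue_po2 = p,
                           count_rate_plasma = 100)
  acq <- acq_config(n_visits = 1)
  pm <- simulate_point_measurement(truth, acq, 1, cal, seed = 13)
  f <- fit_decay(build_decay(pm))
  expect_lt(abs(f$tau_us - po2_to_lifetime(p, cal)) / po2_to_lifetime(p, cal), 0.01)
})

test_that("the ledger round-trips the stall schedule", {
  acq <- acq_config(n_visits = 12)
  truths <- dplyr::bind_rows(
    quick_truth(capillary_id = "a"),
    quick_truth(capillary_id = "b",
                stall_schedule = tibble::tibble(start_visit = 10L, end_visit = 10L)),
    quick_truth(capillary_id = "c",
                stall_schedule = tibble::tibble(start_visit = c(2L, 7L),
                                                end_visit = c(3L, 7L)))
  )
  ses <- simulate_session(truths, acq, cal, seed = 3)
  led <- ses$ledger
  expect_true(all(led$true_flux[led$stalled] == 0))
  expect_true(all(led$true_n_rbc[led$stalled] == 0))
  b <- led[led$capillary_id == "b", ]
  expect_equal(b$visit_index[b$stalled], 10L)
  expect_equal(sum(led$stalled[led$capillary_id == "c"]), 3L)
  expect_true(all(led$true_n_rbc[!led$stalled] >= 0))
})

test_that("empty sessions and invalid schedules are handled", {
  acq0 <- acq_config(n_visits = 0)
  ses <- simulate_session(capillary_truth(), acq0, cal, seed = 1)
  expect_equal(nrow(ses$photons), 0L)
  expect_equal(nrow(ses$ledger), 0L)

  sched <- tibble::tibble(start_visit = 5L, end_visit = 9L)
  truth <- capillary_truth(stall_schedule = sched)
  expect_error(simulate_session(truth, acq_config(n_visits = 7), cal),
               "past the session")
  expect_error(capillary_truth(count_rate_plasma = -1), "nonnegative")
  expect_error(capillary_truth(count_rate_rbc = 25, count_rate_plasma = 20),
               "excluded")
  expect_error(capillary_truth(flux_rate = -2), "nonnegative")
})

test_that("sessions are reproducible under a fixed seed", {
  truth <- quick_truth()
  acq <- acq_config(n_visits = 2)
  s1 <- simulate_session(truth, acq, cal, seed = 77)
  s2 <- simulate_session(truth, acq, cal, seed = 77)
  expect_identical(s1$photons, s2$photons)
  expect_identical(s1$ledger, s2$ledger)
})

test_that("synthetic angiograms honor their tube specifications", {
  # empty specs: background only
  ang0 <- simulate_angiogram(c(20, 20, 10), c(1, 1, 1), NULL, seed = 1)
  expect_equal(sum(ang0$truth_mask), 0L)
  expect_equal(nrow(ang0$centerline), 0L)

  # cylinder volume: pi r^2 L within 5%
  ang <- simulate_angiogram(c(50, 41, 41), c(1, 1, 1),
                            tube_spec(0, 20, 20, 49, 20, 20, radius_um = 3),
                            seed = 2)
  expect_lt(abs(sum(ang$truth_mask) - pi * 9 * 50) / (pi * 9 * 50), 0.05)
  expect_true(all(ang$truth_mask[ang$centerline]))
  expect_true(all(ang$labels[!ang$truth_mask] == 0L))

  # labeled tube at a constructed offset
  ang2 <- simulate_angiogram(c(30, 30, 30), c(1, 1, 1),
                             tube_spec(0, 25, 15, 29, 25, 15, radius_um = 2,
                                       label = "arteriole"),
                             seed = 3)
  # point voxel (15,5,15) sits at position (14,4,14) um; the tube edge is the
  # labeled voxel row at y = 23 um, so the gap is 19 um
  d <- nearest_large_vessel(c(15, 5, 15), ang2$labels, c(1, 1, 1))
  expect_lt(abs(d$arteriole_um - 19), 1 + 1e-9)

  expect_warning(
    simulate_angiogram(c(10, 10, 10), c(1, 1, 1),
                       tube_spec(-20, 5, 5, 30, 5, 5, radius_um = 2), seed = 4),
    "clipped"
  )
})
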