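cal <- default_calib()

test_that("intensity traces count photons per cycle", {
  acq <- acq_config()
  tr0 <- build_intensity_trace(tibble::tibble(cycle = integer(), t_us = numeric()),
                               acq = acq)
  expect_true(all(tr0$counts == 0))
  expect_equal(nrow(tr0), 1000L)

  truth <- capillary_truth(flux_rate = 0, count_rate_plasma = 20)
  pm <- simulate_point_measurement(truth, acq_config(n_visits = 1), 1, cal, seed = 2)
  tr <- build_intensity_trace(pm)
  expect_equal(mean(tr$counts), 20, tolerance = 0.05)
})

test_that("a single 10-ms dip spans about 33 cycles", {
  # flux 2/s with regular spacing puts at most one passage in 300 ms
  truth <- capillary_truth(flux_rate = 2, rbc_transit_ms = 10, speed_um_ms = 0.6,
                           count_rate_plasma = 25, count_rate_rbc = 0,
                           rbc_arrivals = "regular")
  pm <- simulate_point_measurement(truth, acq_config(n_visits = 1), 1, cal, seed = 8)
  tr <- build_intensity_trace(pm)
  runs <- rle(tr$counts <= 5)
  dip <- max(runs$lengths[runs$values])
  expect_gte(dip, 28)
  expect_lte(dip, 38)
})

test_that("noiseless two-level traces binarize exactly", {
  acq <- acq_config(n_cycles = 100L)
  counts <- rep(20L, 100)
  counts[40:59] <- 5L
  pm <- point_measurement(
    tibble::tibble(cycle = rep(1:100, counts), t_us = 50), acq)
  tr <- build_intensity_trace(pm)
  bt <- binarize_otsu(tr, smooth_window = 0L)
  # ties break toward the lower threshold, so clean two-level data puts the
  # threshold exactly at the low level (values <= threshold are RBC)
  expect_gte(bt$threshold, 5)
  expect_lt(bt$threshold, 20)
  expect_equal(nrow(bt$rbc_intervals), 1L)
  expect_identical(which(bt$cycles$label == "rbc"), 40:59)
})

test_that("constant and contrast-free traces claim no RBC evidence", {
  acq <- acq_config(n_cycles = 200L)
  pm <- point_measurement(tibble::tibble(cycle = rep(1:200, each = 3), t_us = 50), acq)
  bt <- binarize_otsu(build_intensity_trace(pm))
  expect_equal(bt$flag, "constant_trace")
  expect_equal(count_flux(bt, 0.3), 0)

  # pure shot noise (a stalled visit): Otsu would split it, the contrast
  # criterion must refuse
  truth <- capillary_truth(flux_rate = 0, count_rate_plasma = 15)
  pm2 <- simulate_point_measurement(truth, acq_config(n_visits = 1), 1, cal, seed = 4)
  bt2 <- binarize_otsu(build_intensity_trace(pm2))
  expect_equal(bt2$flag, "no_dip_contrast")
  expect_equal(nrow(bt2$rbc_intervals), 0L)
})

test_that("flux and speed are simple functions of the intervals", {
  acq <- acq_config(n_cycles = 1000L)
  counts <- rep(20L, 1000)
  counts[101:110] <- 0L # 3 ms dip
  pm <- point_measurement(
    tibble::tibble(cycle = rep(1:1000, counts), t_us = 50), acq)
  bt <- binarize_otsu(build_intensity_trace(pm), smooth_window = 0L,
                      min_dip_cycles = 3L)
  expect_equal(count_flux(bt, 0.3), 1 / 0.3)
  expect_equal(as.numeric(estimate_speed(bt, rbc_path_length_um = 6)), 2)

  # no intervals: zero flux, absent speed
  pm0 <- point_measurement(
    tibble::tibble(cycle = rep(1:1000, 20), t_us = 50), acq)
  bt0 <- binarize_otsu(build_intensity_trace(pm0))
  expect_equal(count_flux(bt0, 0.3), 0)
  expect_true(is.na(estimate_speed(bt0)))
})

test_that("flux is invariant to uniform count rescaling", {
  set.seed(9)
  counts <- rpois(1000, 12)
  counts[c(200:240, 600:650)] <- rpois(92, 1)
  acq <- acq_config()
  mk <- function(k) {
    pm <- point_measurement(tibble::tibble(cycle = rep(1:1000, counts * k), t_us = 50), acq)
    binarize_otsu(build_intensity_trace(pm))
  }
  b1 <- mk(1L); b5 <- mk(5L)
  expect_equal(nrow(b1$rbc_intervals), nrow(b5$rbc_intervals))
  expect_equal(b1$rbc_intervals$start_s, b5$rbc_intervals$start_s)
})

test_that("quality control rejects count drops and weak separations", {
  acq <- acq_config()
  truth <- quick_truth()
  pm <- simulate_point_measurement(truth, acq_config(n_visits = 1), 1, cal, seed = 6)
  tr <- build_intensity_trace(pm)
  bt <- binarize_otsu(tr)
  expect_true(qc_measurement(tr, baseline_counts = mean(tr$counts), bt = bt)$qc_pass)
  qc <- qc_measurement(tr, baseline_counts = mean(tr$counts) * 10, bt = bt)
  expect_false(qc$qc_pass)
  expect_match(qc$qc_reasons, "count_drop")

  # claimed RBC intervals with weak class separation must be rejected
  weak <- structure(
    list(rbc_intervals = tibble::tibble(start_s = 0.1, end_s = 0.11,
                                        n_cycles = 33L),
         separation = 0.1, threshold = 10, flag = NA_character_),
    class = "binarized_trace")
  qc0 <- qc_measurement(tr, baseline_counts = mean(tr$counts), bt = weak)
  expect_false(qc0$qc_pass)
  expect_match(qc0$qc_reasons, "low_separation")
})

test_that("scheduled dips are recovered exactly at high SNR", {
  acq <- acq_config(n_visits = 8)
  truths <- dplyr::bind_rows(lapply(1:3, function(i)
    quick_truth(capillary_id = paste0("c", i), rbc_arrivals = "regular",
                flux_rate = c(5, 10, 13)[i])))
  ses <- simulate_session(truths, acq, cal, seed = 14)
  ts <- analyze_session(ses)
  mm <- dplyr::inner_join(ts, ses$ledger, by = c("capillary_id", "visit_index"))
  expect_gte(mean(mm$n_rbc == mm$true_n_rbc_resolved), 0.99)
  expect_equal(mm$flux, mm$n_rbc / 0.3)
})

test_that("recovered speed tracks the generative transit time", {
  # transit 15 ms with a 6-um path length corresponds to 0.4 um/ms
  acq <- acq_config(n_visits = 6)
  ses <- simulate_session(quick_truth(rbc_arrivals = "regular"), acq, cal, seed = 19)
  ts <- analyze_session(ses)
  sp <- median(ts$speed_um_ms, na.rm = TRUE)
  expect_lt(abs(sp - 0.4) / 0.4, 0.1)
})
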