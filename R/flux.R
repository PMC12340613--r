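#' Per-cycle intensity trace of a point measurement
#'
#' Counts photons per excitation/collection cycle over the full cycle,
#' giving the intensity-versus-time trace in which red blood cell passages
#' appear as dips (the phosphorescent probe is confined to plasma).
#'
#' @param pm a [point_measurement], or a photons tibble (columns `cycle`,
#'   `t_us`) with `acq` supplied.
#' @param acq required when `pm` is a bare tibble.
#' @return an `intensity_trace`: tibble with `cycle`, `time_s` (cycle
#'   midpoint from visit start) and `counts`, with the visit duration and
#'   cycle length in attributes.
#' @export
build_intensity_trace <- function(pm, acq = NULL) {
  if (inherits(pm, "point_measurement")) {
    acq <- pm$acq
    photons <- pm$photons
  } else {
    stopifnot(is.data.frame(pm), inherits(acq, "acq_config"))
    photons <- pm
  }
  n <- acq$n_cycles
  cyc_s <- cycle_duration_us(acq) * 1e-6
  counts <- tabulate(photons$cycle, nbins = n)
  tr <- tb(cycle = seq_len(n), time_s = (seq_len(n) - 0.5) * cyc_s,
           counts = counts)
  structure(tr, class = c("intensity_trace", class(tr)),
            cycle_s = cyc_s, duration_s = visit_duration_s(acq))
}

# symmetric cleanup at the acquisition's cycle resolution: close plasma gaps
# shorter than min_dip_cycles between two dips, then drop dips shorter than
# min_dip_cycles. The simulator's ledger applies the same rule to the true
# occupancy labels, so "resolvable" means the same thing on both sides.
clean_rbc_labels <- function(rbc, min_dip_cycles) {
  runs <- rle(rbc)
  n <- length(runs$values)
  if (n > 2L) {
    interior <- 2:(n - 1L)
    close_gap <- !runs$values[interior] & runs$lengths[interior] < min_dip_cycles
    runs$values[interior][close_gap] <- TRUE
    rbc <- inverse.rle(runs)
    runs <- rle(rbc)
  }
  runs$values[runs$values & runs$lengths < min_dip_cycles] <- FALSE
  inverse.rle(runs)
}

#' Binarize an intensity trace into plasma and RBC phases
#'
#' Applies Otsu's threshold to the (optionally moving-average smoothed)
#' counts-per-cycle trace; cycles at or below the threshold are labeled RBC.
#' Maximal RBC runs shorter than `min_dip_cycles` are relabeled plasma
#' (single-cycle shot-noise dips carry no flux evidence). Partial dips at the
#' trace edges are kept as RBC intervals. A constant trace carries no RBC
#' evidence and is returned all-plasma with a flag.
#'
#' Otsu's method always splits a trace, even a dip-free one where it would
#' only partition shot noise. Dye-exclusion dips are therefore only accepted
#' when the low class sits well below the plasma class relative to the
#' shot-noise scale of the thresholded values: the trace is binarized only
#' if `mean(high) - mean(low) > min_contrast_sd * sqrt(mean(high) / w)`
#' with `w` the smoothing window (counts are Poisson, so a `w`-cycle
#' average has standard deviation `sqrt(mean / w)`). Otherwise the trace is
#' returned all-plasma with flag `"no_dip_contrast"`. This criterion stands
#' in for the manual pre-selection of traces with clear dips that precedes
#' automated binarization in practice.
#'
#' @param tr an [build_intensity_trace()] trace.
#' @param smooth_window moving-average window in cycles (default 3; 0 or 1
#'   disables). Smoothing matters: with the dips occupying only a few
#'   percent of the cycles, Otsu on raw counts prefers splitting the plasma
#'   shot noise over isolating the dips, and a short moving average
#'   restores the valley between the classes.
#' @param min_dip_cycles resolution of the cleanup: plasma gaps shorter
#'   than this between two dips are closed, then dips shorter than this are
#'   dropped.
#' @param min_contrast_sd dip-contrast criterion in plasma-noise standard
#'   deviations.
#' @param threshold optional externally supplied threshold (e.g. estimated
#'   once per capillary from all visits of a session, as
#'   [analyze_session()] does). When given, Otsu and the contrast criterion
#'   are skipped: a single visit holding only a sliver of one dip carries
#'   too little low-class mass to threshold on its own, while the pooled
#'   session trace does not.
#' @return a `binarized_trace`: list with `cycles` (the trace plus a
#'   `label` column), `rbc_intervals` (tibble of `start_s`, `end_s`,
#'   `n_cycles`), the `threshold` used, the Otsu `separation` (between-class
#'   over total variance) and a `flag`.
#' @export
binarize_otsu <- function(tr, smooth_window = 3L, min_dip_cycles = 5L,
                          min_contrast_sd = 3, threshold = NULL) {
  stopifnot(inherits(tr, "intensity_trace"))
  counts <- tr$counts
  cyc_s <- attr(tr, "cycle_s")
  if (length(unique(counts)) == 1L) {
    cycles <- tibble::as_tibble(tr)
    cycles$label <- "plasma"
    return(structure(
      list(cycles = cycles,
           rbc_intervals = tb(start_s = numeric(), end_s = numeric(),
                              n_cycles = integer()),
           threshold = NA_real_, separation = 0, flag = "constant_trace"),
      class = "binarized_trace"
    ))
  }
  x <- counts
  if (smooth_window > 1L) {
    k <- rep(1 / smooth_window, smooth_window)
    x <- as.numeric(stats::filter(counts, k, sides = 2))
    # half-window edges keep their raw values
    x[is.na(x)] <- counts[is.na(x)]
  }
  if (!is.null(threshold)) {
    if (is.na(threshold)) {
      # session-level contrast check found no dip evidence for this capillary
      cycles <- tibble::as_tibble(tr)
      cycles$label <- "plasma"
      return(structure(
        list(cycles = cycles,
             rbc_intervals = tb(start_s = numeric(), end_s = numeric(),
                                n_cycles = integer()),
             threshold = NA_real_, separation = 0, flag = "no_dip_contrast"),
        class = "binarized_trace"
      ))
    }
    dip_level <- attr(threshold, "dip_level")
    thr_num <- as.numeric(threshold)
    rbc <- x <= thr_num
    n <- length(x)
    w0 <- mean(rbc)
    sep <- if (any(rbc) && any(!rbc)) {
      w0 * (1 - w0) * (mean(x[rbc]) - mean(x[!rbc]))^2 / (sum((x - mean(x))^2) / n)
    } else 0
    rbc <- clean_rbc_labels(rbc, min_dip_cycles)
    runs <- rle(rbc)
    ends_i <- cumsum(runs$lengths)
    starts_i <- ends_i - runs$lengths + 1L
    w <- which(runs$values)
    if (!is.null(dip_level) && length(w) > 0) {
      # a dye-exclusion dip reaches down toward the RBC intensity level;
      # noise runs hover just under the threshold and are rejected
      deep_enough <- vapply(w, function(k) {
        min(x[starts_i[k]:ends_i[k]]) <= (dip_level + thr_num) / 2
      }, logical(1))
      for (k in w[!deep_enough]) rbc[starts_i[k]:ends_i[k]] <- FALSE
      runs <- rle(rbc)
      ends_i <- cumsum(runs$lengths)
      starts_i <- ends_i - runs$lengths + 1L
      w <- which(runs$values)
    }
    cycles <- tibble::as_tibble(tr)
    cycles$label <- ifelse(rbc, "rbc", "plasma")
    return(structure(
      list(cycles = cycles,
           rbc_intervals = tb(start_s = (starts_i[w] - 1L) * cyc_s,
                              end_s = ends_i[w] * cyc_s,
                              n_cycles = runs$lengths[w]),
           threshold = thr_num, separation = sep, flag = NA_character_),
      class = "binarized_trace"
    ))
  }
  thr <- otsu_threshold(x)
  rbc <- x <= as.numeric(thr)
  mu_hi <- mean(x[!rbc])
  mu_lo <- mean(x[rbc])
  # shot-noise scale of the thresholded (smoothed) values: Poisson counts
  # averaged over w cycles have variance mu / w
  w_eff <- max(1L, smooth_window)
  noise_band <- min_contrast_sd * sqrt(max(mu_hi, 0) / w_eff)
  if (!any(rbc) || !any(!rbc) || (mu_hi - mu_lo) <= noise_band) {
    cycles <- tibble::as_tibble(tr)
    cycles$label <- "plasma"
    return(structure(
      list(cycles = cycles,
           rbc_intervals = tb(start_s = numeric(), end_s = numeric(),
                              n_cycles = integer()),
           threshold = as.numeric(thr), separation = attr(thr, "separation"),
           flag = "no_dip_contrast"),
      class = "binarized_trace"
    ))
  }
  # keep the operating threshold clear of the plasma noise band (Otsu can
  # land inside it when smoothed dip edges fill the inter-class gap)
  thr_op <- min(as.numeric(thr), mu_hi - noise_band)
  rbc <- x <= thr_op
  thr <- structure(thr_op, separation = attr(thr, "separation"))
  rbc <- clean_rbc_labels(rbc, min_dip_cycles)
  runs <- rle(rbc)
  ends_i <- cumsum(runs$lengths)
  starts_i <- ends_i - runs$lengths + 1L
  w <- which(runs$values)
  intervals <- tb(
    start_s = (starts_i[w] - 1L) * cyc_s,
    end_s = ends_i[w] * cyc_s,
    n_cycles = runs$lengths[w]
  )
  cycles <- tibble::as_tibble(tr)
  cycles$label <- ifelse(rbc, "rbc", "plasma")
  structure(
    list(cycles = cycles, rbc_intervals = intervals,
         threshold = as.numeric(thr),
         separation = attr(thr, "separation"), flag = NA_character_),
    class = "binarized_trace"
  )
}

#' Session-pooled binarization threshold for one capillary
#'
#' Pools the (smoothed) counts-per-cycle of every visit of one capillary
#' and computes a single Otsu threshold plus the dip-contrast criterion on
#' the pooled sample. Even when an individual visit contains only a sliver
#' of a single RBC passage, the pooled trace carries enough low-class mass
#' for a stable threshold.
#'
#' @param traces list of [build_intensity_trace()] traces (one per visit).
#' @inheritParams binarize_otsu
#' @return the pooled threshold, or `NA` when the pooled trace shows no dip
#'   contrast (no detectable RBC passages anywhere in the session).
#' @export
session_flux_threshold <- function(traces, smooth_window = 3L,
                                   min_contrast_sd = 3) {
  smooth1 <- function(counts) {
    if (smooth_window > 1L) {
      x <- as.numeric(stats::filter(counts, rep(1 / smooth_window, smooth_window),
                                    sides = 2))
      x[is.na(x)] <- counts[is.na(x)]
      x
    } else as.numeric(counts)
  }
  x <- unlist(lapply(traces, function(tr) smooth1(tr$counts)), use.names = FALSE)
  if (length(unique(x)) <= 1L) return(NA_real_)
  thr <- otsu_threshold(x)
  rbc <- x <= as.numeric(thr)
  mu_hi <- mean(x[!rbc]); mu_lo <- mean(x[rbc])
  w_eff <- max(1L, smooth_window)
  noise_band <- min_contrast_sd * sqrt(max(mu_hi, 0) / w_eff)
  if (!any(rbc) || !any(!rbc) || (mu_hi - mu_lo) <= noise_band) {
    return(NA_real_)
  }
  # the operating threshold must sit clear of the plasma noise band, else
  # plasma cycles leak into the RBC class; Otsu can land inside the band
  # when smoothed dip-edge values fill the gap between the classes.
  # mu_lo (the pooled dip level) travels along as the dip-depth reference.
  structure(min(as.numeric(thr), mu_hi - noise_band), dip_level = mu_lo)
}

#' @export
print.binarized_trace <- function(x, ...) {
  cat(sprintf(
    "<binarized_trace> %d RBC interval(s), threshold %.3g (separation %.2f)%s\n",
    nrow(x$rbc_intervals), x$threshold, x$separation,
    if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""
  ))
  invisible(x)
}

#' RBC flux from a binarized trace
#'
#' Flux is the number of RBC intervals present in the trace divided by its
#' duration.
#'
#' @param bt a [binarize_otsu()] result.
#' @param duration_s trace duration in seconds (0.3 s for the default
#'   acquisition).
#' @return flux in RBCs per second.
#' @export
count_flux <- function(bt, duration_s) {
  stopifnot(inherits(bt, "binarized_trace"), duration_s > 0)
  nrow(bt$rbc_intervals) / duration_s
}

#' RBC speed from dip durations
#'
#' Estimates speed as an assumed RBC path length through the focal volume
#' divided by the median dip duration. The path length is an explicit
#' assumption parameter (default 6 um, a typical RBC long axis) and is
#' reported alongside the estimate.
#'
#' @param bt a [binarize_otsu()] result.
#' @param rbc_path_length_um assumed path length, micrometers.
#' @return speed in um/ms (with the path length as an attribute), or `NA`
#'   when the trace holds no RBC intervals.
#' @export
estimate_speed <- function(bt, rbc_path_length_um = 6) {
  stopifnot(inherits(bt, "binarized_trace"))
  if (nrow(bt$rbc_intervals) == 0L) {
    return(structure(NA_real_, rbc_path_length_um = rbc_path_length_um))
  }
  dwell_ms <- median(bt$rbc_intervals$end_s - bt$rbc_intervals$start_s) * 1000
  structure(rbc_path_length_um / dwell_ms,
            rbc_path_length_um = rbc_path_length_um)
}

#' Quality control for one visit
#'
#' Rejects visits with a substantial drop in photon counts per cycle
#' (mean below `frac_of_baseline` of the capillary's session-median mean
#' counts) and visits that claim RBC intervals while the Otsu class
#' separation (between-class variance over total variance) is too weak to
#' trust the binarization.
#'
#' @param tr an [build_intensity_trace()] trace.
#' @param baseline_counts session-median of mean counts/cycle for this
#'   capillary.
#' @param bt optional [binarize_otsu()] result for the separation rule.
#' @param frac_of_baseline minimum fraction of baseline counts.
#' @param min_separation minimum Otsu separation when RBC intervals are
#'   claimed.
#' @return one-row tibble with `qc_pass` and `qc_reasons`.
#' @export
qc_measurement <- function(tr, baseline_counts, bt = NULL,
                           frac_of_baseline = 0.5, min_separation = 0.2) {
  stopifnot(inherits(tr, "intensity_trace"))
  reasons <- character()
  if (is.finite(baseline_counts) &&
      mean(tr$counts) < frac_of_baseline * baseline_counts) {
    reasons <- c(reasons, "count_drop")
  }
  if (!is.null(bt) && nrow(bt$rbc_intervals) > 0L &&
      bt$separation < min_separation) {
    reasons <- c(reasons, "low_separation")
  }
  tb(qc_pass = length(reasons) == 0L,
     qc_reasons = if (length(reasons) == 0L) NA_character_ else
       paste(reasons, collapse = ","))
}
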