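#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the pipeline with its default. The
#' configuration (and its hash) is stamped onto every table the pipeline
#' emits, so any output can be reproduced from its stored configuration.
#'
#' @param discard_head_us decay head discarded for the EOM response (us).
#' @param min_photons minimum pooled photons for a lifetime fit.
#' @param objective decay-fit objective, `"poisson"` or `"ls"`.
#' @param background fit a constant background term.
#' @param hypoxic_mmhg,severe_mmhg hypoxia class thresholds (strict `<`).
#' @param min_dip_cycles shortest RBC dip kept, cycles.
#' @param smooth_window moving-average window for binarization (0 = raw).
#' @param frac_of_baseline,min_separation QC thresholds ([qc_measurement()]).
#' @param rbc_path_length_um assumed RBC path length for speed.
#' @param eat_bin_width_um EAT profile bin width (um).
#' @param plateau_min_um floor of the EAT plateau cutoff (um).
#' @param half_extent subvolume crop half-width around a point (voxels).
#' @param density_bin_um vessel-density histogram bin width (um).
#' @param seed seed recorded for provenance.
#' @return a `run_config` list.
#' @export
run_config <- function(discard_head_us = 5, min_photons = 500,
                       objective = "poisson", background = TRUE,
                       hypoxic_mmhg = 10, severe_mmhg = 5,
                       min_dip_cycles = 5L, smooth_window = 3L,
                       frac_of_baseline = 0.5, min_separation = 0.2,
                       rbc_path_length_um = 6, eat_bin_width_um = 1,
                       plateau_min_um = 10, half_extent = 75L,
                       density_bin_um = 1, seed = NULL) {
  stopifnot(discard_head_us >= 0, min_photons >= 0,
            severe_mmhg <= hypoxic_mmhg, min_dip_cycles >= 1,
            frac_of_baseline >= 0, frac_of_baseline <= 1,
            min_separation >= 0, min_separation <= 1,
            rbc_path_length_um > 0, eat_bin_width_um > 0,
            plateau_min_um >= 0, half_extent >= 1, density_bin_um > 0)
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rlang::hash(unclass(config))
}

stamp_config <- function(x, config) {
  attr(x, "run_config") <- config
  attr(x, "run_config_hash") <- config_hash(config)
  x
}

#' Analyze a session of point measurements into a capillary time series
#'
#' Runs the per-visit pipeline over every capillary and visit of a session:
#' decay pooling and single-exponential lifetime fit, Stern-Volmer
#' conversion to pO2, intensity-trace binarization, flux and speed, and
#' quality control against the capillary's session-median counts.
#'
#' @param session a `stallox_session` (from [simulate_session()] or
#'   [read_session()]).
#' @param config a [run_config()].
#' @param calib calibration override; defaults to the session's.
#' @return a tibble with one row per visit: `capillary_id`, `visit_index`,
#'   `visit_time_s`, `tau_us`, `po2`, `n_photons`, `flux`, `speed_um_ms`,
#'   `n_rbc`, `separation`, `qc_pass`, `qc_reasons`, `group` (plus `depth_um`
#'   and point coordinates when the session carries them). The acquisition
#'   config and run-config hash ride along as attributes.
#' @export
analyze_session <- function(session, config = run_config(), calib = NULL) {
  stopifnot(inherits(session, "stallox_session"), inherits(config, "run_config"))
  calib <- calib %||% session$calib
  if (is.null(calib)) abort("no calibration available: supply `calib`")
  acq <- session$acq
  dur <- visit_duration_s(acq)
  led <- session$ledger
  if (nrow(led) == 0L) {
    out <- tb(capillary_id = character(), visit_index = integer(),
              visit_time_s = numeric(), tau_us = numeric(), po2 = numeric(),
              n_photons = numeric(), flux = numeric(), speed_um_ms = numeric(),
              n_rbc = integer(), separation = numeric(), qc_pass = logical(),
              qc_reasons = character(), group = character())
    return(stamp_config(structure(out, acq = acq), config))
  }
  # photons arrive grouped by (capillary, visit); recover the contiguous
  # chunks from change points instead of building per-photon keys
  np <- nrow(session$photons)
  pc <- session$photons$capillary_id
  pv <- session$photons$visit_index
  if (np > 0) {
    chg <- c(TRUE, pc[-1L] != pc[-np] | pv[-1L] != pv[-np])
    chunk_start <- which(chg)
    chunk_end <- c(chunk_start[-1L] - 1L, np)
    chunk_key <- paste(pc[chunk_start], pv[chunk_start])
    idx_by_visit <- split(seq_along(chunk_start), chunk_key)
  } else {
    chunk_start <- chunk_end <- integer()
    idx_by_visit <- list()
  }

  n_out <- nrow(led)
  traces <- vector("list", n_out)
  bts <- vector("list", n_out)
  phs <- vector("list", n_out)
  # pass 1: per-visit traces, then one pooled binarization threshold per
  # capillary (a single visit can hold too little of a dip to threshold)
  for (r in seq_len(n_out)) {
    k <- paste(led$capillary_id[r], led$visit_index[r])
    chunks <- idx_by_visit[[k]]
    rows_ph <- if (is.null(chunks)) integer() else
      unlist(lapply(chunks, function(ci) chunk_start[ci]:chunk_end[ci]),
             use.names = FALSE)
    phs[[r]] <- tibble::new_tibble(
      list(cycle = session$photons$cycle[rows_ph],
           t_us = session$photons$t_us[rows_ph]),
      nrow = length(rows_ph))
    traces[[r]] <- build_intensity_trace(phs[[r]], acq = acq)
  }
  thr_by_cap <- lapply(
    split(seq_len(n_out), led$capillary_id),
    function(rr) session_flux_threshold(traces[rr],
                                        smooth_window = config$smooth_window)
  )
  col <- list(tau_us = numeric(n_out), po2 = numeric(n_out),
              n_photons = numeric(n_out), flux = numeric(n_out),
              speed_um_ms = numeric(n_out), n_rbc = integer(n_out),
              separation = numeric(n_out), mean_counts = numeric(n_out),
              lifetime_ok = logical(n_out))
  for (r in seq_len(n_out)) {
    ph <- phs[[r]]
    tr <- traces[[r]]
    bt <- binarize_otsu(tr, smooth_window = config$smooth_window,
                        min_dip_cycles = config$min_dip_cycles,
                        threshold = thr_by_cap[[led$capillary_id[r]]])
    h <- build_decay(ph$t_us - acq$excitation_us,
                     discard_head_us = config$discard_head_us, acq = acq)
    f <- fit_decay(h, objective = config$objective,
                   background = config$background,
                   min_photons = config$min_photons)
    bts[[r]] <- bt
    col$tau_us[r] <- f$tau_us
    col$po2[r] <- if (f$converged) as.numeric(lifetime_to_po2(f$tau_us, calib)) else NA_real_
    col$n_photons[r] <- f$n_photons
    col$flux[r] <- count_flux(bt, dur)
    col$speed_um_ms[r] <- as.numeric(
      estimate_speed(bt, rbc_path_length_um = config$rbc_path_length_um))
    col$n_rbc[r] <- nrow(bt$rbc_intervals)
    col$separation[r] <- bt$separation
    col$mean_counts[r] <- mean(tr$counts)
    col$lifetime_ok[r] <- f$converged
  }
  out <- tibble::as_tibble(c(
    list(capillary_id = led$capillary_id, visit_index = led$visit_index,
         visit_time_s = led$visit_time_s),
    col,
    list(group = if ("group" %in% names(led)) led$group else
      rep(NA_character_, n_out))
  ))
  # QC needs the session-median counts per capillary
  out <- dplyr::group_by(out, .data$capillary_id)
  out <- dplyr::mutate(out, baseline_counts = median(.data$mean_counts))
  out <- dplyr::ungroup(out)
  qc <- dplyr::bind_rows(lapply(seq_len(nrow(out)), function(r) {
    qc_measurement(traces[[r]], out$baseline_counts[r], bt = bts[[r]],
                   frac_of_baseline = config$frac_of_baseline,
                   min_separation = config$min_separation)
  }))
  out$qc_pass <- qc$qc_pass & out$lifetime_ok
  out$qc_reasons <- ifelse(
    out$lifetime_ok, qc$qc_reasons,
    ifelse(is.na(qc$qc_reasons), "low_photons",
           paste(qc$qc_reasons, "low_photons", sep = ","))
  )
  out$lifetime_ok <- NULL
  if (!is.null(session$truths) &&
      all(c("capillary_id", "depth_um") %in% names(session$truths))) {
    out <- dplyr::left_join(
      out,
      session$truths[, c("capillary_id", "depth_um", "x_um", "y_um", "z_um")],
      by = "capillary_id"
    )
  }
  out <- structure(out, acq = acq,
                   positions = if (!is.null(session$truths))
                     session$truths[, intersect(c("capillary_id", "x_um", "y_um", "z_um"),
                                                names(session$truths))] else NULL,
                   binarized = setNames(bts, paste(led$capillary_id, led$visit_index)))
  stamp_config(out, config)
}
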