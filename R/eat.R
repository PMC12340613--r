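#' Erythrocyte-associated transient (EAT) profile
#'
#' Re-bins plasma-phase photon arrival times by distance to the nearest RBC
#' passage. Each photon's distance is the time from its cycle to the nearest
#' RBC interval midpoint in the same visit multiplied by the RBC speed; the
#' photons pooled in each distance bin form a decay histogram that is fitted
#' ([fit_decay()]) and converted to pO2. Because pO2 is elevated next to
#' RBCs and relaxes toward the tissue value between them, the far-from-RBC
#' plateau of this profile serves as a tissue-pO2 proxy.
#'
#' Only qc-passing, flowing (non-stall) visits should be supplied; visits
#' without any detected RBC interval contribute no photons (their distances
#' are undefined) and are dropped with a message.
#'
#' @param photons tibble of one capillary's photons over the selected
#'   visits: columns `visit_index`, `cycle`, `t_us`.
#' @param intervals tibble of detected RBC intervals for the same visits:
#'   columns `visit_index`, `start_s`, `end_s` (from [binarize_otsu()]).
#' @param acq the [acq_config].
#' @param speed_um_ms RBC speed used to convert time to distance.
#' @param calib an [sv_calibration] for per-bin pO2.
#' @param bin_width_um distance bin width, micrometers.
#' @param discard_head_us decay head discarded before fitting.
#' @param min_photons per-bin photon threshold below which the bin's pO2 is
#'   flagged insufficient (and excluded from plateau pooling).
#' @return an `eat_profile`: tibble with one row per distance bin
#'   (`bin_lo_um`, `bin_hi_um`, `n_photons`, `tau_us`, `po2`, `sufficient`);
#'   the photon-level table (distance + decay time) and the median
#'   inter-RBC distance are kept in attributes for [estimate_tissue_po2()].
#' @export
build_eat_profile <- function(photons, intervals, acq, speed_um_ms, calib,
                              bin_width_um = 1, discard_head_us = 5,
                              min_photons = 500) {
  stopifnot(inherits(acq, "acq_config"), inherits(calib, "sv_calibration"),
            speed_um_ms > 0, bin_width_um > 0)
  if (nrow(intervals) == 0L) {
    abort("no RBC intervals in any visit: the EAT profile is undefined without RBCs")
  }
  have_rbc <- unique(intervals$visit_index)
  dropped <- setdiff(unique(photons$visit_index), have_rbc)
  if (length(dropped) > 0) {
    message(sprintf("dropping %d visit(s) without RBC intervals from the EAT pool",
                    length(dropped)))
  }
  photons <- photons[photons$visit_index %in% have_rbc, , drop = FALSE]

  cyc_s <- cycle_duration_us(acq) * 1e-6
  # photon absolute time in the visit and decay time within the cycle
  t_abs <- (photons$cycle - 1L) * cyc_s + photons$t_us * 1e-6
  decay_us <- photons$t_us - acq$excitation_us

  mids_by_visit <- split((intervals$start_s + intervals$end_s) / 2,
                         intervals$visit_index)
  starts_by_visit <- split(intervals$start_s, intervals$visit_index)
  ends_by_visit <- split(intervals$end_s, intervals$visit_index)

  dist_um <- rep(NA_real_, nrow(photons))
  in_rbc <- rep(FALSE, nrow(photons))
  for (v in as.character(have_rbc)) {
    sel <- photons$visit_index == as.integer(v)
    if (!any(sel)) next
    mids <- sort(mids_by_visit[[v]])
    ta <- t_abs[sel]
    j <- findInterval(ta, mids)
    d_lo <- ifelse(j >= 1L, ta - mids[pmax(j, 1L)], Inf)
    d_hi <- ifelse(j < length(mids), mids[pmin(j + 1L, length(mids))] - ta, Inf)
    dist_um[sel] <- pmin(d_lo, d_hi) * 1000 * speed_um_ms
    st <- starts_by_visit[[v]]; en <- ends_by_visit[[v]]
    k <- findInterval(ta, st)
    in_rbc[sel] <- k >= 1L & ta <= en[pmax(k, 1L)]
  }

  keep <- !in_rbc & decay_us >= discard_head_us & decay_us < acq$collection_us
  pool <- tb(distance_um = dist_um[keep], decay_us = decay_us[keep])

  # median inter-RBC distance (gaps between successive interval midpoints)
  gaps <- unlist(lapply(mids_by_visit, function(m) diff(sort(m))), use.names = FALSE)
  median_gap_um <- if (length(gaps) > 0) median(gaps) * 1000 * speed_um_ms else NA_real_

  nb <- max(1L, ceiling(max(pool$distance_um, 0) / bin_width_um))
  bin <- pmin(floor(pool$distance_um / bin_width_um) + 1L, nb)
  rows <- lapply(seq_len(nb), function(b) {
    d <- pool$decay_us[bin == b]
    n <- length(d)
    if (n >= min_photons) {
      h <- build_decay(d, discard_head_us = discard_head_us, acq = acq)
      f <- fit_decay(h, min_photons = min_photons)
      po2 <- if (f$converged) {
        as.numeric(lifetime_to_po2(f$tau_us, calib))
      } else NA_real_
      tb(bin_lo_um = (b - 1) * bin_width_um, bin_hi_um = b * bin_width_um,
         n_photons = n, tau_us = f$tau_us, po2 = po2,
         sufficient = f$converged)
    } else {
      tb(bin_lo_um = (b - 1) * bin_width_um, bin_hi_um = b * bin_width_um,
         n_photons = n, tau_us = NA_real_, po2 = NA_real_, sufficient = FALSE)
    }
  })
  prof <- dplyr::bind_rows(rows)
  structure(
    prof, class = c("eat_profile", class(prof)),
    photons = pool, speed_um_ms = speed_um_ms,
    median_inter_rbc_um = median_gap_um,
    calib = calib, acq = acq, discard_head_us = discard_head_us,
    min_photons = min_photons
  )
}

#' Tissue pO2 from the far-from-RBC plateau of an EAT profile
#'
#' Pools every retained photon at distance at least `plateau_cutoff_um` from
#' the nearest RBC, fits one decay, and converts the lifetime to pO2. The
#' default cutoff is the larger of 10 um and half the median inter-RBC
#' distance, so the pooled photons sit on the inter-RBC plateau where the
#' intravascular pO2 has relaxed to the level of the surrounding tissue.
#'
#' @param prof an [build_eat_profile()] result.
#' @param plateau_cutoff_um override for the plateau cutoff.
#' @param min_photons minimum pooled far-field photons for a sufficient
#'   estimate.
#' @return one-row tibble: `tissue_po2`, `tau_us`, `plateau_cutoff_um`,
#'   `n_photons`, `sufficient`.
#' @export
estimate_tissue_po2 <- function(prof, plateau_cutoff_um = NULL,
                                min_photons = NULL) {
  stopifnot(inherits(prof, "eat_profile"))
  min_photons <- min_photons %||% attr(prof, "min_photons")
  cutoff <- plateau_cutoff_um %||%
    max(10, attr(prof, "median_inter_rbc_um") / 2, na.rm = TRUE)
  pool <- attr(prof, "photons")
  far <- pool$decay_us[pool$distance_um >= cutoff]
  if (length(far) < min_photons) {
    return(tb(tissue_po2 = NA_real_, tau_us = NA_real_,
              plateau_cutoff_um = cutoff, n_photons = length(far),
              sufficient = FALSE))
  }
  h <- build_decay(far, discard_head_us = attr(prof, "discard_head_us"),
                   acq = attr(prof, "acq"))
  f <- fit_decay(h, min_photons = min_photons)
  tb(
    tissue_po2 = if (f$converged)
      as.numeric(lifetime_to_po2(f$tau_us, attr(prof, "calib"))) else NA_real_,
    tau_us = f$tau_us, plateau_cutoff_um = cutoff,
    n_photons = length(far), sufficient = f$converged
  )
}
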