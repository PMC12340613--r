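#' Ground-truth description of one simulated capillary
#'
#' Collects every generative parameter for a simulated capillary point: the
#' oxygen levels it carries while flowing and while stalled, the far-field
#' (inter-RBC) tissue pO2 and the length constant of the erythrocyte-
#' associated transient (EAT) gradient between them, the RBC traffic (flux,
#' transit time, speed), the photon count rates during plasma and RBC
#' phases (the probe is excluded from RBCs, so `count_rate_rbc <
#' count_rate_plasma`), and the stall schedule.
#'
#' @param capillary_id identifier.
#' @param po2_flowing intravascular (near-RBC) pO2 during normal flow, mmHg.
#' @param po2_stalled equilibrium pO2 during a stall, mmHg.
#' @param tissue_po2 far-field inter-RBC pO2, mmHg.
#' @param eat_length_um length constant of the exponential EAT gradient from
#'   `po2_flowing` (at an RBC) toward `tissue_po2`, micrometers.
#' @param flux_rate RBCs per second during normal flow.
#' @param rbc_transit_ms duration of one dye-exclusion dip, milliseconds.
#' @param speed_um_ms RBC speed, micrometers per millisecond.
#' @param count_rate_plasma,count_rate_rbc expected photons per cycle during
#'   plasma and RBC passage.
#' @param dark_rate expected background photons per cycle, uniform over the
#'   collection window.
#' @param rbc_arrivals `"poisson"` (default; memoryless arrivals at
#'   `flux_rate`) or `"regular"` (even spacing with random phase).
#' @param stall_schedule tibble with columns `start_visit`, `end_visit`
#'   (inclusive visit indices) of scheduled stalls.
#' @param x_um,y_um,z_um position of the measurement point (for neighbor
#'   distances), micrometers.
#' @param depth_um cortical depth of the point, micrometers.
#' @param group session group label carried through the pipeline
#'   (`"awake"` or `"anesthesia"`).
#' @return a one-row tibble; bind rows to build a cohort.
#' @export
capillary_truth <- function(capillary_id = "cap1",
                            po2_flowing = 40, po2_stalled = 10,
                            tissue_po2 = 30, eat_length_um = 5,
                            flux_rate = 8, rbc_transit_ms = 6,
                            speed_um_ms = 1,
                            count_rate_plasma = 20, count_rate_rbc = 2,
                            dark_rate = 0,
                            rbc_arrivals = c("poisson", "regular"),
                            stall_schedule = NULL,
                            x_um = 0, y_um = 0, z_um = 0,
                            depth_um = 150, group = "awake") {
  rbc_arrivals <- match.arg(rbc_arrivals)
  if (min(po2_flowing, po2_stalled, tissue_po2) < 0) {
    abort("pO2 values must be nonnegative")
  }
  if (min(count_rate_plasma, count_rate_rbc, dark_rate) < 0) {
    abort("count rates must be nonnegative")
  }
  if (count_rate_rbc >= count_rate_plasma) {
    abort("count_rate_rbc must be below count_rate_plasma (dye is excluded from RBCs)")
  }
  if (flux_rate < 0) abort("flux_rate must be nonnegative")
  if (speed_um_ms <= 0 || rbc_transit_ms <= 0 || eat_length_um <= 0) {
    abort("speed, transit time and EAT length constant must be positive")
  }
  if (is.null(stall_schedule)) {
    stall_schedule <- tb(start_visit = integer(), end_visit = integer())
  }
  stopifnot(all(c("start_visit", "end_visit") %in% names(stall_schedule)))
  if (any(stall_schedule$end_visit < stall_schedule$start_visit) ||
      any(stall_schedule$start_visit < 1L)) {
    abort("stall_schedule windows must satisfy 1 <= start_visit <= end_visit")
  }
  tb(
    capillary_id = capillary_id, po2_flowing = po2_flowing,
    po2_stalled = po2_stalled, tissue_po2 = tissue_po2,
    eat_length_um = eat_length_um, flux_rate = flux_rate,
    rbc_transit_ms = rbc_transit_ms, speed_um_ms = speed_um_ms,
    count_rate_plasma = count_rate_plasma, count_rate_rbc = count_rate_rbc,
    dark_rate = dark_rate, rbc_arrivals = rbc_arrivals,
    stall_schedule = list(tibble::as_tibble(stall_schedule)),
    x_um = x_um, y_um = y_um, z_um = z_um,
    depth_um = depth_um, group = group
  )
}

is_stalled_visit <- function(truth, visit_index) {
  sched <- truth$stall_schedule[[1]]
  any(visit_index >= sched$start_visit & visit_index <= sched$end_visit)
}

# lay down RBC passage intervals over one visit; returns merged intervals
rbc_intervals_for_visit <- function(truth, T_s) {
  transit_s <- truth$rbc_transit_ms / 1000
  if (truth$flux_rate <= 0) {
    return(matrix(numeric(), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  if (truth$rbc_arrivals == "poisson") {
    n_arr <- rpois(1L, truth$flux_rate * (T_s + transit_s))
    starts <- sort(runif(n_arr, -transit_s, T_s))
  } else {
    spacing <- 1 / truth$flux_rate
    phase <- runif(1L, 0, spacing)
    ks <- seq(ceiling((-transit_s - phase) / spacing),
              floor((T_s - phase) / spacing))
    starts <- phase + spacing * ks
  }
  if (length(starts) == 0L) {
    return(matrix(numeric(), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  ends <- starts + transit_s
  # merge overlapping passages into maximal occupied intervals
  keep_start <- c(TRUE, starts[-1L] > cummax(ends[-length(ends)]))
  grp <- cumsum(keep_start)
  m <- cbind(start = tapply(starts, grp, min), end = tapply(ends, grp, max))
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

# core per-visit generator; truth is a one-row tibble (or list)
sim_visit <- function(truth, acq, calib, stalled,
                      po2_shift = 0, flux_factor = 1, min_dip_cycles = 3L) {
  n <- acq$n_cycles
  cyc_s <- cycle_duration_us(acq) * 1e-6
  T_s <- visit_duration_s(acq)
  tc <- (seq_len(n) - 0.5) * cyc_s

  tr <- if (is.data.frame(truth)) as.list(truth) else truth
  eff <- tr
  eff$flux_rate <- if (stalled) 0 else tr$flux_rate * flux_factor

  ivl <- rbc_intervals_for_visit(eff, T_s)
  n_rbc <- sum(ivl[, "end"] > 0 & ivl[, "start"] < T_s)

  if (nrow(ivl) > 0) {
    i <- findInterval(tc, ivl[, "start"])
    in_rbc <- i > 0L & tc <= ivl[pmax(i, 1L), "end"]
    mids <- (ivl[, "start"] + ivl[, "end"]) / 2
    j <- findInterval(tc, mids)
    d_lo <- ifelse(j >= 1L, tc - mids[pmax(j, 1L)], Inf)
    d_hi <- ifelse(j < length(mids), mids[pmin(j + 1L, length(mids))] - tc, Inf)
    d_s <- pmin(d_lo, d_hi)
    d_um <- d_s * 1000 * tr$speed_um_ms
  } else {
    in_rbc <- rep(FALSE, n)
    d_um <- rep(Inf, n)
  }
  resolved <- clean_rbc_labels(in_rbc, min_dip_cycles)
  runs <- rle(resolved)
  n_rbc_resolved <- sum(runs$values)

  if (stalled) {
    po2_c <- rep(tr$po2_stalled, n)
  } else {
    po2_c <- tr$tissue_po2 + (tr$po2_flowing - tr$tissue_po2) *
      exp(-d_um / tr$eat_length_um)
    po2_c <- pmax(po2_c + po2_shift, 0)
  }
  tau_c <- po2_to_lifetime(po2_c, calib)
  rate_c <- ifelse(in_rbc, tr$count_rate_rbc, tr$count_rate_plasma)

  n_sig <- rpois(n, rate_c)
  tau_p <- rep(tau_c, n_sig)
  C <- acq$collection_us
  u <- runif(length(tau_p))
  tdec <- -tau_p * log1p(-u * (1 - exp(-C / tau_p)))
  n_dark <- if (tr$dark_rate > 0) rpois(n, tr$dark_rate) else integer(n)
  tdark <- runif(sum(n_dark)) * C
  bw <- acq$decay_bin_width_us
  quantize <- function(t) pmin((floor(t / bw) + 0.5) * bw, C - bw / 2)
  cyc <- c(rep(seq_len(n), n_sig), rep(seq_len(n), n_dark))
  t_us <- acq$excitation_us + quantize(c(tdec, tdark))
  o <- order(cyc, t_us)

  list(
    cycle = cyc[o], t_us = t_us[o],
    intervals = ivl,
    n_rbc = n_rbc,
    n_rbc_resolved = n_rbc_resolved,
    true_po2 = mean(po2_c),
    true_po2_photon_weighted = sum(rate_c * po2_c) / sum(rate_c)
  )
}

validate_schedule <- function(truth, acq) {
  sched <- truth$stall_schedule[[1]]
  if (nrow(sched) > 0 && any(sched$end_visit > acq$n_visits)) {
    abort(sprintf("stall window extends past the session (%d visits)", acq$n_visits))
  }
}

#' Simulate one photon-counting point measurement
#'
#' Generates a single visit's photon arrival times from a ground-truth
#' capillary description. RBC passage intervals are laid down from the flux
#' rate and transit time; each cycle's local pO2 is the stalled equilibrium
#' during a scheduled stall, and otherwise follows the EAT gradient (an
#' exponential relaxation from the near-RBC value to the tissue value with
#' the ground-truth length constant, evaluated at the distance to the nearest
#' RBC midpoint). The pO2 sets the phosphorescence lifetime through the
#' inverse Stern-Volmer relation; photon counts per cycle are Poisson with
#' rate depending on RBC presence, arrival times are drawn from the
#' exponential decay truncated to the collection window (plus uniform dark
#' counts) and quantized to the decay bin width.
#'
#' @param truth a one-row tibble from [capillary_truth()].
#' @param acq an [acq_config].
#' @param visit_index which visit of the session this is.
#' @param calib an [sv_calibration]; the simulator uses its inverse.
#' @param seed optional RNG seed for this visit.
#' @return a [point_measurement] whose `truth` field carries the RBC
#'   intervals and per-visit true pO2/flux for recovery tests.
#' @export
simulate_point_measurement <- function(truth, acq, visit_index, calib,
                                       seed = NULL) {
  stopifnot(inherits(acq, "acq_config"), inherits(calib, "sv_calibration"))
  if (!is.null(seed)) set.seed(seed)
  validate_schedule(truth, acq)
  if (visit_index < 1L || visit_index > acq$n_visits) {
    abort("visit_index outside the session")
  }
  stalled <- is_stalled_visit(truth, visit_index)
  v <- sim_visit(truth, acq, calib, stalled)
  point_measurement(
    tb(cycle = v$cycle, t_us = v$t_us), acq,
    capillary_id = truth$capillary_id, visit_index = visit_index,
    visit_time_s = (visit_index - 1L) * acq$revisit_interval_s,
    truth = v[c("intervals", "n_rbc", "n_rbc_resolved", "true_po2",
                "true_po2_photon_weighted")]
  )
}

#' Simulate a full multi-capillary measurement session
#'
#' Interleaves visits across capillaries at the acquisition's revisit
#' interval (capillary `i`'s visit `v` occurs at
#' `(v-1) * revisit + (i-1) * revisit / n_capillaries`), simulating every
#' visit with [simulate_point_measurement()]'s generative model, and records
#' a ground-truth ledger with each visit's true pO2, RBC count and stall
#' state for downstream recovery tests. `true_n_rbc_resolved` is the number
#' of RBC passages an ideal detector could count at the acquisition's cycle
#' resolution (runs of RBC-occupied cycles at least `min_dip_cycles` long);
#' passages separated by less than one cycle are unresolvable in principle.
#'
#' Optional `neighbor_coupling` injects a local effect of a stall on
#' co-measured flowing capillaries: while any other capillary is stalled,
#' a flowing capillary's pO2 is shifted by `delta_po2 * exp(-d / range_um)`
#' and its flux scaled toward `flux_ratio`, with `d` the 3D distance between
#' measurement points.
#'
#' @param truths tibble of ground-truth capillaries ([capillary_truth()] rows).
#' @param acq an [acq_config].
#' @param calib an [sv_calibration].
#' @param seed RNG seed for the whole session.
#' @param neighbor_coupling `NULL`, or
#'   `list(delta_po2 = , flux_ratio = , range_um = )`.
#' @param min_dip_cycles resolution used for the ledger's
#'   `true_n_rbc_resolved` bookkeeping.
#' @return a `stallox_session`: list with `photons` (capillary_id,
#'   visit_index, cycle, t_us), `ledger`, `acq`, `calib`, `truths`.
#' @export
simulate_session <- function(truths, acq, calib, seed = NULL,
                             neighbor_coupling = NULL, min_dip_cycles = 5L) {
  stopifnot(nrow(truths) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(nrow(truths))) validate_schedule(truths[i, ], acq)
  n_cap <- nrow(truths)
  offs <- (seq_len(n_cap) - 1L) * acq$revisit_interval_s / n_cap

  stall_mat <- matrix(FALSE, nrow = max(acq$n_visits, 0L), ncol = n_cap)
  for (i in seq_len(n_cap)) {
    sched <- truths$stall_schedule[[i]]
    for (k in seq_len(nrow(sched))) {
      stall_mat[sched$start_visit[k]:sched$end_visit[k], i] <- TRUE
    }
  }

  truth_rows <- lapply(seq_len(n_cap), function(i) as.list(truths[i, ]))

  n_rows <- acq$n_visits * n_cap
  cyc_chunks <- vector("list", n_rows)
  t_chunks <- vector("list", n_rows)
  n_per <- integer(n_rows)
  led <- list(
    capillary_id = character(n_rows), visit_index = integer(n_rows),
    visit_time_s = numeric(n_rows), stalled = logical(n_rows),
    true_po2 = numeric(n_rows), true_po2_photon_weighted = numeric(n_rows),
    true_flux = numeric(n_rows), true_n_rbc = integer(n_rows),
    true_n_rbc_resolved = integer(n_rows), true_speed_um_ms = numeric(n_rows),
    po2_shift = numeric(n_rows), flux_factor = numeric(n_rows),
    group = character(n_rows)
  )
  idx <- 1L
  for (v in seq_len(acq$n_visits)) {
    for (i in seq_len(n_cap)) {
      truth <- truth_rows[[i]]
      stalled <- stall_mat[v, i]
      shift <- 0; ffac <- 1
      if (!is.null(neighbor_coupling) && !stalled) {
        others <- which(stall_mat[v, ] & seq_len(n_cap) != i)
        if (length(others) > 0) {
          d <- sqrt((truths$x_um[others] - truth$x_um)^2 +
                    (truths$y_um[others] - truth$y_um)^2 +
                    (truths$z_um[others] - truth$z_um)^2)
          g <- exp(-min(d) / neighbor_coupling$range_um)
          shift <- neighbor_coupling$delta_po2 * g
          ffac <- 1 - (1 - neighbor_coupling$flux_ratio) * g
        }
      }
      vis <- sim_visit(truth, acq, calib, stalled, po2_shift = shift,
                       flux_factor = ffac, min_dip_cycles = min_dip_cycles)
      cyc_chunks[[idx]] <- vis$cycle
      t_chunks[[idx]] <- vis$t_us
      n_per[idx] <- length(vis$cycle)
      led$capillary_id[idx] <- truth$capillary_id
      led$visit_index[idx] <- v
      led$visit_time_s[idx] <- (v - 1L) * acq$revisit_interval_s + offs[i]
      led$stalled[idx] <- stalled
      led$true_po2[idx] <- if (stalled) truth$po2_stalled else vis$true_po2
      led$true_po2_photon_weighted[idx] <- vis$true_po2_photon_weighted
      led$true_flux[idx] <- vis$n_rbc / visit_duration_s(acq)
      led$true_n_rbc[idx] <- vis$n_rbc
      led$true_n_rbc_resolved[idx] <- vis$n_rbc_resolved
      led$true_speed_um_ms[idx] <- truth$speed_um_ms
      led$po2_shift[idx] <- shift
      led$flux_factor[idx] <- ffac
      led$group[idx] <- truth$group
      idx <- idx + 1L
    }
  }
  photons <- tb(
    capillary_id = rep(led$capillary_id, n_per),
    visit_index = rep(led$visit_index, n_per),
    cycle = as.integer(unlist(cyc_chunks, use.names = FALSE) %||% integer()),
    t_us = as.numeric(unlist(t_chunks, use.names = FALSE) %||% numeric())
  )
  ledger <- tibble::as_tibble(led)
  structure(
    list(photons = photons, ledger = ledger, acq = acq, calib = calib,
         truths = truths, schema = "stallox-session/1"),
    class = "stallox_session"
  )
}

#' @export
print.stallox_session <- function(x, ...) {
  cat(sprintf(
    "<stallox_session> %d capillaries x %d visits, %d photons (%d stall visits)\n",
    nrow(x$truths), x$acq$n_visits, nrow(x$photons), sum(x$ledger$stalled)
  ))
  invisible(x)
}

#' Simulate a stall cohort with known hypoxic fraction
#'
#' Generates the package's reference stall cohort: `n_stalls` capillaries,
#' each scheduled to stall exactly once, with `n_hypoxic` of the stalls
#' assigned a hypoxic equilibrium pO2 drawn uniformly from
#' `hypoxic_range` and the remainder from `normoxic_range`. Stall durations
#' are mostly a single visit (70% one, 20% two, 10% three visits), placed
#' with at least two flowing visits before and one after. RBC arrivals are
#' regular so that every flowing visit contains resolvable RBC passages and
#' the scheduled stall set is exactly the set of zero-flux visits.
#'
#' @param seed RNG seed.
#' @param n_stalls number of stalling capillaries.
#' @param n_hypoxic number of stalls assigned a sub-10-mmHg equilibrium.
#' @param hypoxic_range,normoxic_range uniform ranges (mmHg) for the stalled
#'   equilibrium pO2 of the two classes.
#' @param n_visits visits per capillary.
#' @param count_rate_plasma expected photons per cycle in plasma.
#' @param calib simulator calibration.
#' @return a `stallox_session`; the scheduled events (with their true stall
#'   pO2 and class) are in attribute `"scheduled_events"`.
#' @export
simulate_stall_cohort <- function(seed = NULL, n_stalls = 32L,
                                  n_hypoxic = 13L,
                                  hypoxic_range = c(2, 8),
                                  normoxic_range = c(14, 32),
                                  n_visits = 7L,
                                  count_rate_plasma = 10,
                                  calib = sv_calibration(40, 5e-4)) {
  if (!is.null(seed)) set.seed(seed)
  acq <- acq_config(n_visits = n_visits)
  hyp <- sample(rep(c(TRUE, FALSE), c(n_hypoxic, n_stalls - n_hypoxic)))
  stall_po2 <- ifelse(hyp,
                      runif(n_stalls, hypoxic_range[1], hypoxic_range[2]),
                      runif(n_stalls, normoxic_range[1], normoxic_range[2]))
  dur <- sample(1:3, n_stalls, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  start <- vapply(dur, function(d) {
    hi <- max(3L, n_visits - d) # at least 2 flowing visits precede the stall
    sample(seq(3L, hi), 1L)
  }, integer(1))
  flowing <- runif(n_stalls, 25, 50)
  tissue <- pmax(flowing - runif(n_stalls, 5, 15), 1)
  truths <- dplyr::bind_rows(lapply(seq_len(n_stalls), function(i) {
    capillary_truth(
      capillary_id = sprintf("cap%02d", i),
      po2_flowing = flowing[i], po2_stalled = stall_po2[i],
      tissue_po2 = tissue[i], flux_rate = 8, rbc_transit_ms = 15,
      speed_um_ms = 0.4, count_rate_plasma = count_rate_plasma,
      count_rate_rbc = 1, dark_rate = 0.5, rbc_arrivals = "regular",
      stall_schedule = tb(start_visit = start[i],
                          end_visit = start[i] + dur[i] - 1L),
      x_um = runif(1, 0, 400), y_um = runif(1, 0, 400),
      z_um = runif(1, 50, 300), depth_um = runif(1, 50, 300)
    )
  }))
  ses <- simulate_session(truths, acq, calib)
  attr(ses, "scheduled_events") <- tb(
    capillary_id = truths$capillary_id,
    start_visit = start, end_visit = start + dur - 1L,
    true_stall_po2 = stall_po2, hypoxic = hyp
  )
  ses
}
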