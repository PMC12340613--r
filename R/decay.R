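#' Point measurement container
#'
#' One visit's worth of photon-counting cycles at a single capillary point.
#' Arrival times are stored per cycle in microseconds from cycle start, so
#' they span `[0, excitation_us + collection_us)`.
#'
#' @param photons tibble with columns `cycle` (1-based cycle index) and
#'   `t_us` (arrival time within the cycle, microseconds).
#' @param acq the [acq_config] the measurement was taken with.
#' @param capillary_id,visit_index,visit_time_s identifying metadata.
#' @param truth optional ground-truth list attached by the simulator.
#' @return an object of class `point_measurement`.
#' @export
point_measurement <- function(photons, acq, capillary_id = NA_character_,
                              visit_index = NA_integer_,
                              visit_time_s = NA_real_, truth = NULL) {
  stopifnot(inherits(acq, "acq_config"),
            is.data.frame(photons), all(c("cycle", "t_us") %in% names(photons)))
  if (nrow(photons) > 0) {
    if (any(photons$t_us < 0 | photons$t_us >= cycle_duration_us(acq))) {
      abort("arrival times must lie within [0, cycle duration)")
    }
    if (any(photons$cycle < 1L | photons$cycle > acq$n_cycles)) {
      abort("cycle indices must lie in [1, n_cycles]")
    }
  }
  structure(
    list(photons = tibble::as_tibble(photons), acq = acq,
         capillary_id = capillary_id, visit_index = as.integer(visit_index),
         visit_time_s = visit_time_s, truth = truth),
    class = "point_measurement"
  )
}

#' @export
print.point_measurement <- function(x, ...) {
  cat(sprintf(
    "<point_measurement> capillary %s, visit %s: %d photons over %d cycles\n",
    x$capillary_id, x$visit_index, nrow(x$photons), x$acq$n_cycles
  ))
  invisible(x)
}

new_decay_histogram <- function(t_us, counts, bin_width_us, discard_head_us,
                                collection_us, n_cycles_pooled, empty = FALSE) {
  h <- tb(t_us = t_us, counts = counts)
  structure(
    h,
    class = c("decay_histogram", class(h)),
    bin_width_us = bin_width_us, discard_head_us = discard_head_us,
    collection_us = collection_us, n_cycles_pooled = n_cycles_pooled,
    empty = empty
  )
}

#' Pool photon arrival times into a phosphorescence decay histogram
#'
#' Arrival times are re-referenced to the end of the excitation window and
#' pooled across all cycles of a visit into uniform bins spanning
#' `[discard_head_us, collection_us)`. The head of the decay is discarded to
#' exclude the electro-optic modulator response (default 5 us); photons that
#' arrive during the excitation window are excluded.
#'
#' @param pm a [point_measurement], or a numeric vector of decay times
#'   (microseconds from end of excitation) when `acq` is supplied.
#' @param discard_head_us initial decay time discarded, microseconds.
#' @param bin_width_us histogram bin width; defaults to the acquisition's
#'   decay bin width.
#' @param acq required when `pm` is a bare numeric vector of decay times.
#' @return a `decay_histogram`: a tibble with bin centers `t_us` and photon
#'   `counts`, plus binning metadata in attributes. An empty measurement
#'   yields all-zero counts with attribute `empty = TRUE`.
#' @export
build_decay <- function(pm, discard_head_us = 5, bin_width_us = NULL, acq = NULL) {
  if (inherits(pm, "point_measurement")) {
    acq <- pm$acq
    decay_t <- pm$photons$t_us - acq$excitation_us
    n_pooled <- acq$n_cycles
  } else {
    stopifnot(is.numeric(pm), inherits(acq, "acq_config"))
    decay_t <- pm
    n_pooled <- NA_integer_
  }
  stopifnot(discard_head_us >= 0)
  bin_width_us <- bin_width_us %||% acq$decay_bin_width_us
  # a trailing sliver narrower than one bin is dropped
  nb <- floor((acq$collection_us - discard_head_us) / bin_width_us + 1e-9)
  if (nb < 2L) abort("fewer than 2 decay bins; widen the window or narrow the bins")
  edges <- discard_head_us + bin_width_us * (0:nb)
  keep <- decay_t >= discard_head_us & decay_t < edges[nb + 1L]
  idx <- floor((decay_t[keep] - discard_head_us) / bin_width_us) + 1L
  idx[idx > nb] <- nb
  counts <- tabulate(idx, nbins = nb)
  empty <- length(decay_t) == 0L
  if (empty) warn("empty measurement: decay histogram has no photons")
  new_decay_histogram(
    t_us = (edges[-1L] + edges[-(nb + 1L)]) / 2, counts = counts,
    bin_width_us = bin_width_us, discard_head_us = discard_head_us,
    collection_us = acq$collection_us, n_cycles_pooled = n_pooled,
    empty = empty
  )
}

#' Expected (noise-free) decay histogram for a known lifetime
#'
#' Returns the expected-value decay histogram of a single-exponential decay
#' with lifetime `tau_us` plus an optional uniform background, scaled to
#' `total_photons`. Bin contents are exact integrals of the model over each
#' bin, so fitting this histogram recovers `tau_us` to optimizer precision.
#' This is the simulator's noiseless mode, used for exact-fit checks.
#'
#' @param tau_us true lifetime, microseconds.
#' @param acq an [acq_config].
#' @param total_photons expected total photon count in the histogram.
#' @param background_frac fraction of `total_photons` contributed by a
#'   uniform background.
#' @inheritParams build_decay
#' @return a `decay_histogram` with non-integer (expected) counts.
#' @export
expected_decay <- function(tau_us, acq, total_photons = 1e4,
                           background_frac = 0, discard_head_us = 5,
                           bin_width_us = NULL) {
  stopifnot(tau_us > 0, total_photons > 0,
            background_frac >= 0, background_frac < 1)
  bin_width_us <- bin_width_us %||% acq$decay_bin_width_us
  nb <- floor((acq$collection_us - discard_head_us) / bin_width_us + 1e-9)
  edges <- discard_head_us + bin_width_us * (0:nb)
  sig <- exp(-edges[-(nb + 1L)] / tau_us) - exp(-edges[-1L] / tau_us)
  sig <- sig / sum(sig) * total_photons * (1 - background_frac)
  bg <- total_photons * background_frac / nb
  new_decay_histogram(
    t_us = (edges[-1L] + edges[-(nb + 1L)]) / 2, counts = sig + bg,
    bin_width_us = bin_width_us, discard_head_us = discard_head_us,
    collection_us = acq$collection_us, n_cycles_pooled = NA_integer_
  )
}

# shared fit core operating on bin centers + counts
fit_decay_core <- function(t, counts, objective = c("poisson", "ls"),
                           background = TRUE) {
  objective <- match.arg(objective)
  n <- length(t)
  # initialization: background from the tail 10% of bins, lifetime from the
  # log-linear slope of background-subtracted counts, amplitude from the
  # first retained bin
  b0 <- if (background) mean(tail(counts, max(3L, floor(n * 0.1)))) else 0
  r <- counts - b0
  use <- which(r > 0 & seq_len(n) <= ceiling(n * 0.6))
  if (length(use) >= 3L) {
    w <- r[use]
    xt <- t[use]; yl <- log(r[use])
    xm <- sum(w * xt) / sum(w); ym <- sum(w * yl) / sum(w)
    slope <- sum(w * (xt - xm) * (yl - ym)) / sum(w * (xt - xm)^2)
    tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else diff(range(t)) / 3
  } else {
    tau0 <- diff(range(t)) / 3
  }
  tau0 <- min(max(tau0, t[2] - t[1]), 50 * max(t))
  a0 <- max((counts[1] - b0) / exp(-t[1] / tau0), max(counts[1], 1) * 0.1, 1e-6)

  mu_fun <- function(p) pmax(p[1] * exp(-t / p[2]) + (if (background) p[3] else 0), 1e-12)
  if (objective == "poisson") {
    fn <- function(p) {
      mu <- mu_fun(p)
      sum(mu - counts * log(mu))
    }
    gr <- function(p) {
      mu <- mu_fun(p)
      e <- exp(-t / p[2])
      common <- 1 - counts / mu
      g <- c(sum(common * e), sum(common * p[1] * e * t) / p[2]^2, sum(common))
      if (background) g else g[1:2]
    }
  } else {
    fn <- function(p) sum((counts - mu_fun(p))^2)
    gr <- function(p) {
      mu <- mu_fun(p)
      e <- exp(-t / p[2])
      common <- -2 * (counts - mu)
      g <- c(sum(common * e), sum(common * p[1] * e * t) / p[2]^2, sum(common))
      if (background) g else g[1:2]
    }
  }
  par0 <- if (background) c(a0, tau0, max(b0, 0)) else c(a0, tau0)
  lower <- if (background) c(1e-10, (t[2] - t[1]) / 10, 0) else c(1e-10, (t[2] - t[1]) / 10)
  upper <- if (background) c(Inf, 100 * max(t), Inf) else c(Inf, 100 * max(t))
  # factr is relative to the objective magnitude, which grows with the photon
  # count; keep it tight so large histograms converge in parameter space too
  opt <- optim(par0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = 1000L, factr = 10, pgtol = 1e-10))
  if (!all(is.finite(opt$par)) || !is.finite(opt$value)) {
    abort("decay fit did not reach a finite optimum")
  }
  list(
    amplitude = opt$par[1], tau_us = opt$par[2],
    background = if (background) opt$par[3] else 0,
    objective = objective, value = opt$value,
    converged = opt$convergence == 0L, mu = mu_fun(opt$par)
  )
}

#' Fit a single-exponential decay to a pooled histogram
#'
#' Fits the model \eqn{A e^{-t/\tau} + B} to a [build_decay] histogram.
#' The default objective is the Poisson negative log-likelihood, the correct
#' noise model for photon counting; ordinary least squares is available as an
#' option. Histograms holding fewer than `min_photons` photons are returned
#' un-fitted with `converged = FALSE` (the quality-control rule for
#' low-signal visits).
#'
#' @param h a `decay_histogram`.
#' @param objective `"poisson"` (default) or `"ls"`.
#' @param background fit a constant background term `B` (default `TRUE`).
#' @param min_photons minimum pooled photon count to attempt a fit.
#' @return a `decay_fit` object; see [tidy.decay_fit()] and
#'   [glance.decay_fit()] for tabular access. `fit_residual` is the Poisson
#'   deviance (or residual sum of squares) per degree of freedom.
#' @export
fit_decay <- function(h, objective = c("poisson", "ls"), background = TRUE,
                      min_photons = 500) {
  stopifnot(inherits(h, "decay_histogram"))
  objective <- match.arg(objective)
  n_photons <- sum(h$counts)
  if (n_photons < min_photons) {
    return(structure(
      list(tau_us = NA_real_, amplitude = NA_real_, background = NA_real_,
           fit_residual = NA_real_, n_photons = n_photons, converged = FALSE,
           flag = "low_photons", objective = objective),
      class = "decay_fit"
    ))
  }
  core <- fit_decay_core(h$t_us, h$counts, objective, background)
  dof <- max(nrow(h) - (2L + background), 1L)
  resid <- if (objective == "poisson") {
    pos <- h$counts > 0
    dev <- 2 * sum(core$mu - h$counts) +
      2 * sum(h$counts[pos] * log(h$counts[pos] / core$mu[pos]))
    dev / dof
  } else {
    sum((h$counts - core$mu)^2) / dof
  }
  structure(
    list(tau_us = core$tau_us, amplitude = core$amplitude,
         background = core$background, fit_residual = resid,
         n_photons = n_photons, converged = core$converged, flag = NA_character_,
         objective = objective),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<decay_fit> tau = %.3f us (A = %.3g, B = %.3g), %d photons, residual %.3g\n",
      x$tau_us, x$amplitude, x$background, round(x$n_photons), x$fit_residual
    ))
  } else {
    cat(sprintf("<decay_fit> not converged (%s), %d photons\n",
                x$flag %||% "optimizer", round(x$n_photons)))
  }
  invisible(x)
}

#' Tidiers for decay fits
#'
#' @param x a `decay_fit`.
#' @param ... unused.
#' @return `tidy()` gives one row per model term; `glance()` one row of fit
#'   summaries.
#' @export
tidy.decay_fit <- function(x, ...) {
  tb(
    term = c("amplitude", "tau_us", "background"),
    estimate = c(x$amplitude, x$tau_us, x$background)
  )
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tb(
    tau_us = x$tau_us, n_photons = x$n_photons,
    fit_residual = x$fit_residual, converged = x$converged,
    flag = x$flag
  )
}
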