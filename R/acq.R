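#' Acquisition configuration for phosphorescence point measurements
#'
#' Describes the excitation/collection cycle structure of a point
#' measurement and the session timing. The defaults mirror a typical
#' two-photon phosphorescence lifetime protocol: 1000 cycles of 10 us
#' excitation followed by 290 us of photon collection, i.e. 300 ms per
#' point visit, with each point revisited roughly every 8 s for ~10 min.
#'
#' @param excitation_us excitation window per cycle, microseconds.
#' @param collection_us collection (photon counting) window per cycle,
#'   microseconds.
#' @param n_cycles number of cycles per visit.
#' @param revisit_interval_s time between successive visits to the same
#'   point, seconds.
#' @param n_visits number of visits per point in a session.
#' @param decay_bin_width_us width of the decay-histogram bins used when
#'   arrival times are quantized, microseconds.
#' @return an object of class `acq_config`.
#' @examples
#' acq <- acq_config()
#' visit_duration_s(acq) # 0.3 s per point
#' @export
acq_config <- function(excitation_us = 10, collection_us = 290,
                       n_cycles = 1000L, revisit_interval_s = 8,
                       n_visits = 75L, decay_bin_width_us = 0.5) {
  stopifnot(
    excitation_us > 0, collection_us > 0, n_cycles >= 1,
    revisit_interval_s > 0, n_visits >= 0, decay_bin_width_us > 0
  )
  structure(
    list(
      excitation_us = as.numeric(excitation_us),
      collection_us = as.numeric(collection_us),
      n_cycles = as.integer(n_cycles),
      revisit_interval_s = as.numeric(revisit_interval_s),
      n_visits = as.integer(n_visits),
      decay_bin_width_us = as.numeric(decay_bin_width_us)
    ),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat(sprintf(
    "<acq_config> %d cycles x (%g us excitation + %g us collection) = %g ms/visit; %d visits every %g s\n",
    x$n_cycles, x$excitation_us, x$collection_us,
    x$n_cycles * cycle_duration_us(x) / 1000, x$n_visits, x$revisit_interval_s
  ))
  invisible(x)
}

#' @rdname acq_config
#' @param acq an `acq_config`.
#' @export
cycle_duration_us <- function(acq) acq$excitation_us + acq$collection_us

#' @rdname acq_config
#' @export
visit_duration_s <- function(acq) acq$n_cycles * cycle_duration_us(acq) * 1e-6
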