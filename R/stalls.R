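#' Detect capillary stall events
#'
#' A stall event is a maximal run of consecutive qc-passing visits with
#' flux exactly 0. Runs separated by at least one flowing visit are distinct
#' events; a qc-failed visit breaks a run (conservatively), and events
#' adjacent to qc-failed visits are flagged. Consecutive zero-flux visits
#' are treated as one continuous event even though flow could in principle
#' resume and re-stall between visits — the per-event visit list is retained
#' so alternative groupings can be formed.
#'
#' @param ts a capillary time series from [analyze_session()] (or any tibble
#'   with `capillary_id`, `visit_index`, `flux`, `po2`, `qc_pass`).
#' @param revisit_interval_s time between visits; taken from the series'
#'   acquisition attribute when present.
#' @param hypoxic_mmhg,severe_mmhg class thresholds for
#'   [classify_hypoxia()].
#' @return a tibble of events: `event_id`, `capillary_id`, `start_visit`,
#'   `end_visit`, `n_visits`, `duration_s`, `stall_po2` (mean over event
#'   visits), `hypoxia_class`, `qc_break_adjacent`, and a `visits` list
#'   column.
#' @export
detect_stalls <- function(ts, revisit_interval_s = NULL,
                          hypoxic_mmhg = 10, severe_mmhg = 5) {
  revisit_interval_s <- revisit_interval_s %||% attr(ts, "acq")$revisit_interval_s
  if (is.null(revisit_interval_s)) {
    abort("supply `revisit_interval_s` (series carries no acquisition config)")
  }
  empty <- tb(event_id = integer(), capillary_id = character(),
              start_visit = integer(), end_visit = integer(),
              n_visits = integer(), duration_s = numeric(),
              stall_po2 = numeric(), hypoxia_class = factor(
                character(), levels = c("normoxic", "hypoxic", "severe")),
              qc_break_adjacent = logical(), visits = list())
  if (nrow(ts) == 0L) return(empty)
  out <- list()
  for (cid in unique(ts$capillary_id)) {
    d <- dplyr::arrange(ts[ts$capillary_id == cid, ], .data$visit_index)
    state <- ifelse(!d$qc_pass, "bad", ifelse(d$flux == 0, "zero", "flow"))
    runs <- rle(state)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values == "zero")) {
      i0 <- starts[k]; i1 <- ends[k]
      adj_bad <- (i0 > 1L && state[i0 - 1L] == "bad") ||
        (i1 < length(state) && state[i1 + 1L] == "bad")
      out[[length(out) + 1L]] <- tb(
        capillary_id = cid,
        start_visit = d$visit_index[i0], end_visit = d$visit_index[i1],
        n_visits = i1 - i0 + 1L,
        duration_s = (i1 - i0 + 1L) * revisit_interval_s,
        stall_po2 = mean(d$po2[i0:i1]),
        qc_break_adjacent = adj_bad,
        visits = list(d[i0:i1, c("visit_index", "visit_time_s", "po2", "flux")])
      )
    }
  }
  if (length(out) == 0L) return(empty)
  ev <- dplyr::bind_rows(out)
  ev$event_id <- seq_len(nrow(ev))
  ev$hypoxia_class <- classify_hypoxia(ev$stall_po2, hypoxic_mmhg, severe_mmhg)
  ev[, names(empty)]
}

#' Classify stall oxygen levels
#'
#' Below 10 mmHg cellular respiration becomes oxygen-limited, so stalls
#' whose mean pO2 drops under that level are classed hypoxic, and under
#' 5 mmHg severe. Both comparisons are strict (`<`): a stall at exactly
#' 10 mmHg is normoxic.
#'
#' @param po2 stall pO2 value(s), mmHg.
#' @param hypoxic_mmhg,severe_mmhg thresholds, mmHg.
#' @return factor with levels `normoxic`, `hypoxic`, `severe`.
#' @examples
#' classify_hypoxia(c(4.9, 7, 10, 15.4))
#' @export
classify_hypoxia <- function(po2, hypoxic_mmhg = 10, severe_mmhg = 5) {
  stopifnot(severe_mmhg <= hypoxic_mmhg)
  cls <- ifelse(po2 < severe_mmhg, "severe",
                ifelse(po2 < hypoxic_mmhg, "hypoxic", "normoxic"))
  factor(cls, levels = c("normoxic", "hypoxic", "severe"))
}

#' Align flux and pO2 around stall events
#'
#' Arranges each event's surrounding visits on a relative-visit axis with
#' the stall collapsed to offset 0: negative offsets count visits before
#' stall onset, positive offsets after stall end, and offset 0 carries the
#' event-mean pO2 and flux 0 regardless of event duration. Events near the
#' session edges contribute partial rows; qc-failed context visits are
#' omitted.
#'
#' @param events a [detect_stalls()] table.
#' @param ts the capillary time series the events came from.
#' @param max_offset largest relative offset included, in visits.
#' @return tibble with `event_id`, `capillary_id`, `offset`, `po2`, `flux`.
#' @seealso [summarize_peri_stall()]
#' @export
align_peri_stall <- function(events, ts, max_offset = 5L) {
  stopifnot(nrow(events) >= 1L)
  rows <- list()
  for (r in seq_len(nrow(events))) {
    cid <- events$capillary_id[r]
    d <- ts[ts$capillary_id == cid & ts$qc_pass, ]
    for (off in seq(-max_offset, max_offset)) {
      if (off == 0L) {
        rows[[length(rows) + 1L]] <- tb(
          event_id = events$event_id[r], capillary_id = cid, offset = 0L,
          po2 = events$stall_po2[r], flux = 0)
      } else {
        v <- if (off < 0L) events$start_visit[r] + off else events$end_visit[r] + off
        hit <- d[d$visit_index == v, ]
        if (nrow(hit) == 1L) {
          rows[[length(rows) + 1L]] <- tb(
            event_id = events$event_id[r], capillary_id = cid, offset = off,
            po2 = hit$po2, flux = hit$flux)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' @rdname align_peri_stall
#' @param aligned an `align_peri_stall()` table.
#' @export
summarize_peri_stall <- function(aligned) {
  dplyr::summarise(
    dplyr::group_by(aligned, .data$offset),
    po2_mean = mean(.data$po2), po2_sd = sd(.data$po2),
    flux_mean = mean(.data$flux), flux_sd = sd(.data$flux),
    n_events = dplyr::n(), .groups = "drop"
  )
}

#' Regress stall pO2 on estimated tissue pO2
#'
#' Ordinary least squares of the pO2 reached during a stall on the tissue
#' pO2 estimated (via the EAT plateau) while the same capillary was flowing,
#' fitted separately per group label when one is present. A slope below 1
#' with a negative intercept indicates stalls falling below the surrounding
#' tissue oxygen.
#'
#' @param cmp tibble with columns `stall_po2`, `tissue_po2` and optionally
#'   `group` (one row per event).
#' @return a `stall_tissue_fit` tibble: `group`, `slope`, `intercept`,
#'   `r_squared`, `n`; the underlying `lm` objects ride in an attribute.
#'   Access coefficients per group with `tidy()` / `glance()`.
#' @export
fit_stall_vs_tissue <- function(cmp) {
  stopifnot(all(c("stall_po2", "tissue_po2") %in% names(cmp)))
  if (!"group" %in% names(cmp)) cmp$group <- "all"
  cmp <- cmp[stats::complete.cases(cmp[, c("stall_po2", "tissue_po2")]), ]
  groups <- unique(cmp$group)
  models <- list()
  rows <- lapply(groups, function(g) {
    d <- cmp[cmp$group == g, ]
    if (nrow(d) < 3L) abort(sprintf("group '%s' has fewer than 3 events", g))
    if (stats::var(d$tissue_po2) == 0) {
      abort(sprintf("group '%s' has no tissue-pO2 variance", g))
    }
    m <- lm(stall_po2 ~ tissue_po2, data = d)
    models[[g]] <<- m
    tb(group = g, slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
       r_squared = summary(m)$r.squared, n = nrow(d))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("stall_tissue_fit", class(out)), models = models)
}

#' @export
tidy.stall_tissue_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(x$group, function(g) {
    m <- attr(x, "models")[[g]]
    s <- summary(m)$coefficients
    tb(group = g, term = c("intercept", "tissue_po2"),
       estimate = unname(s[, 1]), std.error = unname(s[, 2]))
  }))
}

#' @export
glance.stall_tissue_fit <- function(x, ...) {
  tibble::as_tibble(x[, c("group", "r_squared", "n")])
}

#' Effect of a stall on co-measured neighbor capillaries
#'
#' For every capillary that never stalled in the session, compares its mean
#' pO2 and flux over visits concurrent with any detected stall event against
#' visits during which no stall was detected anywhere in the session
#' (reference windows exclude all stall-concurrent visits, since undetected
#' concurrent stalls would otherwise contaminate the baseline). Concurrency
#' is by visit index: visits are interleaved, so visit `v` of a neighbor is
#' acquired within one revisit interval of visit `v` of the stalling
#' capillary. Distance to the (nearest) stalling capillary is 3D Euclidean
#' between measurement points.
#'
#' @param ts capillary time series ([analyze_session()]).
#' @param events a [detect_stalls()] table.
#' @param positions tibble `capillary_id`, `x_um`, `y_um`, `z_um`; defaults
#'   to the series' attribute when the session carried coordinates.
#' @return a `neighbor_effects` tibble: one row per neighbor with
#'   `po2_stall`, `po2_ref`, `delta_po2`, `flux_stall`, `flux_ref`,
#'   `flux_ratio`, `distance_um` and visit counts. Neighbors with no
#'   concurrent (or no reference) visits are excluded. With no events the
#'   table is empty.
#' @seealso [fit_neighbor_distance()]
#' @export
neighbor_effects <- function(ts, events, positions = NULL) {
  positions <- positions %||% attr(ts, "positions")
  empty <- tb(capillary_id = character(), n_stall_visits = integer(),
              n_ref_visits = integer(), po2_stall = numeric(),
              po2_ref = numeric(), delta_po2 = numeric(),
              flux_stall = numeric(), flux_ref = numeric(),
              flux_ratio = numeric(), distance_um = numeric())
  if (nrow(events) == 0L) {
    return(structure(empty, class = c("neighbor_effects", class(empty))))
  }
  stall_caps <- unique(events$capillary_id)
  stall_visits <- sort(unique(unlist(
    lapply(seq_len(nrow(events)),
           function(r) seq(events$start_visit[r], events$end_visit[r]))
  )))
  rows <- list()
  for (cid in setdiff(unique(ts$capillary_id), stall_caps)) {
    d <- ts[ts$capillary_id == cid & ts$qc_pass, ]
    conc <- d[d$visit_index %in% stall_visits, ]
    ref <- d[!d$visit_index %in% stall_visits, ]
    if (nrow(conc) == 0L || nrow(ref) == 0L) next
    dist <- NA_real_
    if (!is.null(positions) && all(c("x_um", "y_um", "z_um") %in% names(positions))) {
      p0 <- positions[positions$capillary_id == cid, ]
      ps <- positions[positions$capillary_id %in% stall_caps, ]
      if (nrow(p0) == 1L && nrow(ps) > 0L) {
        dist <- min(sqrt((ps$x_um - p0$x_um)^2 + (ps$y_um - p0$y_um)^2 +
                           (ps$z_um - p0$z_um)^2))
      }
    }
    rows[[length(rows) + 1L]] <- tb(
      capillary_id = cid,
      n_stall_visits = nrow(conc), n_ref_visits = nrow(ref),
      po2_stall = mean(conc$po2, na.rm = TRUE),
      po2_ref = mean(ref$po2, na.rm = TRUE),
      delta_po2 = mean(conc$po2, na.rm = TRUE) - mean(ref$po2, na.rm = TRUE),
      flux_stall = mean(conc$flux), flux_ref = mean(ref$flux),
      flux_ratio = mean(conc$flux) / mean(ref$flux),
      distance_um = dist
    )
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty
  structure(out, class = c("neighbor_effects", class(out)))
}

#' Linear trend of neighbor effects with distance from the stall
#'
#' @param ne a [neighbor_effects()] table with distances.
#' @return tibble with one row per response (`delta_po2`, `flux_ratio`):
#'   slope, intercept, r-squared against `distance_um`.
#' @export
fit_neighbor_distance <- function(ne) {
  d <- ne[is.finite(ne$distance_um), ]
  if (nrow(d) < 3L) abort("need at least 3 neighbors with distances")
  fit1 <- lm(delta_po2 ~ distance_um, data = d)
  fit2 <- lm(flux_ratio ~ distance_um, data = d)
  tb(
    response = c("delta_po2", "flux_ratio"),
    slope = c(coef(fit1)[2], coef(fit2)[2]),
    intercept = c(coef(fit1)[1], coef(fit2)[1]),
    r_squared = c(summary(fit1)$r.squared, summary(fit2)$r.squared),
    n = nrow(d)
  )
}

#' Histogram of stall durations
#'
#' Events are counted by their duration in visits (and seconds). A
#' capillary that stalls several times contributes each event separately.
#'
#' @param events a [detect_stalls()] table.
#' @param revisit_interval_s seconds per visit step; defaults to
#'   `duration_s / n_visits` of the events themselves.
#' @return tibble `n_visits`, `duration_s`, `n_events`.
#' @export
stall_duration_histogram <- function(events, revisit_interval_s = NULL) {
  if (nrow(events) == 0L) {
    return(tb(n_visits = integer(), duration_s = numeric(), n_events = integer()))
  }
  revisit_interval_s <- revisit_interval_s %||%
    (events$duration_s[1] / events$n_visits[1])
  out <- dplyr::count(events, .data$n_visits, name = "n_events")
  out$duration_s <- out$n_visits * revisit_interval_s
  out[, c("n_visits", "duration_s", "n_events")]
}
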