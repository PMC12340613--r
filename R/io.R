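SESSION_SCHEMA <- "stallox-session/1"
ANGIO_SCHEMA <- "stallox-angiogram/1"

acq_to_list <- function(acq) unclass(acq)
acq_from_list <- function(l) do.call(acq_config, l)
calib_to_list <- function(cal) {
  if (is.null(cal)) return(NULL)
  list(tau0_us = cal$tau0_us, kq = cal$kq, valid_range = cal$valid_range)
}
calib_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  sv_calibration(l$tau0_us, l$kq, unlist(l$valid_range))
}

truths_to_list <- function(truths) {
  lapply(seq_len(nrow(truths)), function(i) {
    row <- as.list(truths[i, ])
    row$stall_schedule <- as.data.frame(truths$stall_schedule[[i]])
    row
  })
}
truths_from_list <- function(l) {
  dplyr::bind_rows(lapply(l, function(row) {
    sched <- row$stall_schedule
    row$stall_schedule <- NULL
    sched <- if (is.null(sched) || length(sched) == 0) {
      tb(start_visit = integer(), end_visit = integer())
    } else {
      tb(start_visit = vapply(sched, function(s) as.integer(s$start_visit), integer(1)),
         end_visit = vapply(sched, function(s) as.integer(s$end_visit), integer(1)))
    }
    row <- lapply(row, function(x) if (is.list(x)) unlist(x) else x)
    do.call(capillary_truth, c(row, list(stall_schedule = sched)))
  }))
}

#' Write and read measurement sessions
#'
#' The on-disk container is a directory holding `photons.csv` (one row per
#' photon: session, capillary, visit, cycle, arrival time), `ledger.csv`
#' (the per-visit ground truth, when present) and `meta.json` (schema
#' version, acquisition configuration, calibration and capillary ground
#' truth). The round trip is lossless: `readr` serializes doubles with
#' shortest-round-trip precision, so arrival-time lists come back
#' bit-identical.
#'
#' Several sessions may share one container only if their acquisition
#' configurations are identical; mixed configurations are rejected.
#'
#' @param session a `stallox_session`, or an unnamed list of them.
#' @param dir container directory (created if needed).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a `stallox_session` (or a list of them when the container
#'   holds several).
#' @export
write_session <- function(session, dir) {
  sessions <- if (inherits(session, "stallox_session")) list(session) else session
  stopifnot(length(sessions) >= 1L,
            all(vapply(sessions, inherits, logical(1), "stallox_session")))
  acqs <- lapply(sessions, function(s) unclass(s$acq))
  if (length(unique(acqs)) != 1L) {
    abort("sessions with mixed acquisition configs cannot share a container")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  photons <- dplyr::bind_rows(lapply(seq_along(sessions), function(i) {
    ph <- sessions[[i]]$photons
    ph$session_id <- i
    ph[, c("session_id", "capillary_id", "visit_index", "cycle", "t_us")]
  }))
  ledgers <- dplyr::bind_rows(lapply(seq_along(sessions), function(i) {
    led <- sessions[[i]]$ledger
    if (nrow(led) == 0) return(NULL)
    led$session_id <- i
    dplyr::relocate(led, "session_id")
  }))
  readr::write_csv(photons, file.path(dir, "photons.csv"))
  if (nrow(ledgers) > 0) {
    readr::write_csv(ledgers, file.path(dir, "ledger.csv"))
  }
  meta <- list(
    schema = SESSION_SCHEMA,
    n_sessions = length(sessions),
    acq = acq_to_list(sessions[[1]]$acq),
    calib = calib_to_list(sessions[[1]]$calib),
    truths = lapply(sessions, function(s)
      if (is.null(s$truths)) NULL else truths_to_list(s$truths))
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) abort("not a session container: meta.json missing")
  meta <- jsonlite::read_json(meta_path)
  if (!identical(meta$schema, SESSION_SCHEMA)) {
    abort(sprintf("unsupported container schema '%s' (expected '%s')",
                  meta$schema %||% "<missing>", SESSION_SCHEMA))
  }
  acq <- acq_from_list(lapply(meta$acq, unlist))
  calib <- calib_from_list(meta$calib)
  photons <- readr::read_csv(file.path(dir, "photons.csv"),
                             col_types = readr::cols(
                               session_id = readr::col_integer(),
                               capillary_id = readr::col_character(),
                               visit_index = readr::col_integer(),
                               cycle = readr::col_integer(),
                               t_us = readr::col_double()))
  if (nrow(photons) > 0 &&
      any(photons$t_us < 0 | photons$t_us >= cycle_duration_us(acq))) {
    abort("container is inconsistent: arrival times outside the cycle")
  }
  ledger_path <- file.path(dir, "ledger.csv")
  ledgers <- if (file.exists(ledger_path)) {
    readr::read_csv(ledger_path, col_types = readr::cols(), progress = FALSE)
  } else NULL
  n <- meta$n_sessions %||% 1L
  sessions <- lapply(seq_len(n), function(i) {
    ph <- photons[photons$session_id == i,
                  c("capillary_id", "visit_index", "cycle", "t_us")]
    led <- if (!is.null(ledgers) && nrow(ledgers) > 0) {
      l <- ledgers[ledgers$session_id == i, ]
      l$session_id <- NULL
      tibble::as_tibble(l)
    } else NULL
    tr <- meta$truths[[i]]
    structure(
      list(photons = tibble::as_tibble(ph),
           ledger = led %||% tb(),
           acq = acq, calib = calib,
           truths = if (is.null(tr)) NULL else truths_from_list(tr),
           schema = SESSION_SCHEMA),
      class = "stallox_session"
    )
  })
  if (n == 1L) sessions[[1]] else sessions
}

#' Write and read angiogram volumes
#'
#' The intensity volume is stored as a multi-page 32-bit float TIFF (one
#' page per z-slice, values min-max scaled to `[0, 1]`), the label and
#' ground-truth masks as companion TIFFs, and everything else — voxel size,
#' intensity range, label codes, measurement points — in a JSON sidecar.
#'
#' @param ang an [angiogram_volume()].
#' @param path base path; `<path>.tif`, `<path>_labels.tif`,
#'   `<path>_mask.tif` and `<path>.json` are written next to each other.
#' @return `write_angiogram()` returns `path` invisibly;
#'   `read_angiogram()` the reconstructed `angiogram`.
#' @export
write_angiogram <- function(ang, path) {
  stopifnot(inherits(ang, "angiogram"))
  rng <- range(ang$intensity)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  norm <- (ang$intensity - rng[1]) / scale
  pages <- lapply(seq_len(dim(norm)[3]), function(z) norm[, , z])
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32L)
  if (!is.null(ang$labels)) {
    lp <- lapply(seq_len(dim(ang$labels)[3]), function(z) ang$labels[, , z] / 255)
    tiff::writeTIFF(lp, paste0(path, "_labels.tif"), bits.per.sample = 32L)
  }
  if (!is.null(ang$truth_mask)) {
    mp <- lapply(seq_len(dim(ang$truth_mask)[3]),
                 function(z) ang$truth_mask[, , z] * 1)
    tiff::writeTIFF(mp, paste0(path, "_mask.tif"), bits.per.sample = 32L)
  }
  sidecar <- list(
    schema = ANGIO_SCHEMA,
    dim = dim(ang$intensity),
    voxel_size_um = ang$voxel_size_um,
    intensity_range = rng,
    label_codes = list(arteriole = 1, venule = 2),
    has_labels = !is.null(ang$labels),
    has_truth_mask = !is.null(ang$truth_mask),
    points = ang$points
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_angiogram
#' @export
read_angiogram <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(sidecar$schema, ANGIO_SCHEMA)) {
    abort("unsupported angiogram sidecar schema")
  }
  d <- as.integer(sidecar$dim)
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  stopifnot(length(pages) == d[3])
  a <- array(0, dim = d)
  for (z in seq_len(d[3])) a[, , z] <- pages[[z]]
  rng <- sidecar$intensity_range
  a <- a * (rng[2] - rng[1]) + rng[1]
  labels <- NULL
  if (isTRUE(sidecar$has_labels)) {
    lp <- tiff::readTIFF(paste0(path, "_labels.tif"), all = TRUE)
    labels <- array(0L, dim = d)
    for (z in seq_len(d[3])) labels[, , z] <- as.integer(round(lp[[z]] * 255))
  }
  mask <- NULL
  if (isTRUE(sidecar$has_truth_mask)) {
    mp <- tiff::readTIFF(paste0(path, "_mask.tif"), all = TRUE)
    mask <- array(FALSE, dim = d)
    for (z in seq_len(d[3])) mask[, , z] <- mp[[z]] > 0.5
  }
  pts <- sidecar$points
  angiogram_volume(a, sidecar$voxel_size_um, labels = labels,
                   truth_mask = mask,
                   points = if (is.null(pts)) NULL else tibble::as_tibble(pts))
}
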