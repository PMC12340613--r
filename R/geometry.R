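#' Angiogram volume container
#'
#' A 3D fluorescence angiogram with its voxel size (possibly anisotropic)
#' and optional large-vessel labels. Voxel indices are 1-based (R's array
#' convention); the physical position of voxel `(i, j, k)` is
#' `((i,j,k) - 1) * voxel_size_um`, and all distances are computed between
#' voxel centers in micrometers with the anisotropy honored.
#'
#' @param intensity 3D numeric array.
#' @param voxel_size_um length-3 positive numeric, um per voxel along each
#'   axis.
#' @param labels optional 3D integer array of large-vessel labels aligned
#'   with `intensity`: 0 none, 1 arteriole, 2 venule.
#' @param truth_mask,centerline optional simulator ground truth (logical
#'   array; matrix of voxel coordinates).
#' @param points optional tibble of measurement points (`x`, `y`, `z` voxel
#'   coordinates, `depth_um`).
#' @return an object of class `angiogram`.
#' @export
angiogram_volume <- function(intensity, voxel_size_um = c(1, 1, 1),
                             labels = NULL, truth_mask = NULL,
                             centerline = NULL, points = NULL) {
  stopifnot(length(dim(intensity)) == 3L, length(voxel_size_um) == 3L,
            all(voxel_size_um > 0))
  if (!is.null(labels)) stopifnot(identical(dim(labels), dim(intensity)))
  if (!is.null(truth_mask)) stopifnot(identical(dim(truth_mask), dim(intensity)))
  structure(
    list(intensity = intensity, voxel_size_um = as.numeric(voxel_size_um),
         labels = labels, truth_mask = truth_mask, centerline = centerline,
         points = points, bounds = NULL, clipped = FALSE),
    class = "angiogram"
  )
}

#' @export
print.angiogram <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<angiogram> %d x %d x %d voxels @ (%g, %g, %g) um%s\n",
              d[1], d[2], d[3], x$voxel_size_um[1], x$voxel_size_um[2],
              x$voxel_size_um[3],
              if (isTRUE(x$clipped)) " [clipped subvolume]" else ""))
  invisible(x)
}

#' Crop a subvolume around a measurement point
#'
#' Extracts the cube extending `half_extent` voxels in all directions from
#' the point (151 voxels per axis for the default 75), clipping at the
#' volume boundary with the actually realized bounds recorded.
#'
#' @param ang an [angiogram_volume()].
#' @param point length-3 voxel coordinates (1-based) of the measurement
#'   point.
#' @param half_extent half-width of the crop, voxels.
#' @return an `angiogram` whose `bounds` field records the crop
#'   `(lo, hi)` per axis, `clipped` whether the boundary was hit, and
#'   `point` the point's coordinates inside the crop.
#' @export
crop_subvolume <- function(ang, point, half_extent = 75L) {
  stopifnot(inherits(ang, "angiogram"), length(point) == 3L)
  d <- dim(ang$intensity)
  point <- as.integer(round(point))
  if (any(point < 1L) || any(point > d)) abort("point lies outside the volume")
  lo <- pmax(point - as.integer(half_extent), 1L)
  hi <- pmin(point + as.integer(half_extent), d)
  sub <- ang$intensity[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- angiogram_volume(
    sub, ang$voxel_size_um,
    labels = if (!is.null(ang$labels))
      ang$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
    truth_mask = if (!is.null(ang$truth_mask))
      ang$truth_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  )
  out$bounds <- cbind(lo = lo, hi = hi)
  out$clipped <- any(lo > point - half_extent) || any(hi < point + half_extent)
  out$point <- point - lo + 1L
  out
}

#' Smooth and binarize an angiogram volume
#'
#' Applies a 3x3x3 median filter (replicate boundary handling) followed by a
#' global Otsu threshold on the voxel intensities; voxels above the
#' threshold are vessel. A constant volume yields an empty mask with a flag.
#'
#' @param vol a 3D array or an [angiogram_volume()].
#' @param median_filter apply the 3x3x3 median filter first.
#' @return logical 3D array (vessel mask) with attributes `threshold` and
#'   `flag`.
#' @export
binarize_angiogram <- function(vol, median_filter = TRUE) {
  a <- if (inherits(vol, "angiogram")) vol$intensity else vol
  stopifnot(length(dim(a)) == 3L)
  if (median_filter) {
    a <- array(.median_filter3_cpp(as.numeric(a), dim(a)), dim = dim(a))
  }
  if (length(unique(as.numeric(a))) == 1L) {
    mask <- array(FALSE, dim = dim(a))
    attr(mask, "threshold") <- NA_real_
    attr(mask, "flag") <- "constant_volume"
    return(mask)
  }
  thr <- otsu_threshold(as.numeric(a))
  mask <- a > as.numeric(thr)
  attr(mask, "threshold") <- as.numeric(thr)
  attr(mask, "flag") <- NA_character_
  mask
}

#' Skeletonize a binary vessel mask to centerlines
#'
#' 3D homotopic thinning: simple voxels (whose removal preserves local
#' topology) are peeled from alternating directions until only one-voxel-
#' wide centerlines remain; curve endpoints are preserved. The skeleton is a
#' subset of the mask and has the same number of connected components.
#' Out-of-volume neighbors are treated as continuing the boundary value, so
#' vessels truncated by the crop are not eroded from their cut ends.
#'
#' @param mask logical 3D array.
#' @return logical 3D array of centerline voxels.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) return(mask)
  .skeletonize3_cpp(mask, dim(mask))
}

#' Vessel-density histogram around a measurement point
#'
#' Computes the Euclidean distance (um, anisotropy-corrected, between voxel
#' centers) from the point to every vessel-classified voxel and bins the
#' voxel counts into 1-um bins (the local vessel density in arbitrary
#' units as a function of distance).
#'
#' @param point length-3 voxel coordinates (1-based) of the measurement
#'   point.
#' @param mask logical 3D vessel mask.
#' @param voxel_size_um length-3 um per voxel.
#' @param bin_width_um histogram bin width.
#' @return tibble `bin_lo_um`, `bin_hi_um`, `n_voxels`; the total vessel
#'   voxel count rides in attribute `total_voxels` (the bin counts sum to
#'   it exactly).
#' @export
density_histogram <- function(point, mask, voxel_size_um = c(1, 1, 1),
                              bin_width_um = 1) {
  stopifnot(length(point) == 3L, length(dim(mask)) == 3L, bin_width_um > 0)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    out <- tb(bin_lo_um = numeric(), bin_hi_um = numeric(), n_voxels = integer())
    attr(out, "total_voxels") <- 0L
    attr(out, "point") <- point
    return(out)
  }
  d <- sqrt(((idx[, 1] - point[1]) * voxel_size_um[1])^2 +
              ((idx[, 2] - point[2]) * voxel_size_um[2])^2 +
              ((idx[, 3] - point[3]) * voxel_size_um[3])^2)
  nb <- floor(max(d) / bin_width_um) + 1L
  counts <- tabulate(floor(d / bin_width_um) + 1L, nbins = nb)
  out <- tb(bin_lo_um = (seq_len(nb) - 1) * bin_width_um,
            bin_hi_um = seq_len(nb) * bin_width_um,
            n_voxels = counts)
  attr(out, "total_voxels") <- nrow(idx)
  attr(out, "point") <- point
  out
}

#' Distance from a point to the nearest labeled arteriole and venule
#'
#' Minimum anisotropy-corrected Euclidean distance from the measurement
#' point to any voxel carrying each label — i.e. to the vessel's edge, not
#' its centerline. A point inside a labeled vessel has distance 0.
#'
#' @param point length-3 voxel coordinates (1-based).
#' @param labels 3D integer array: 0 none, 1 arteriole, 2 venule.
#' @param voxel_size_um length-3 um per voxel.
#' @return one-row tibble `arteriole_um`, `venule_um`; a label absent from
#'   the volume gives `NA` and is named in attribute `missing_labels`.
#' @export
nearest_large_vessel <- function(point, labels, voxel_size_um = c(1, 1, 1)) {
  stopifnot(length(point) == 3L, length(dim(labels)) == 3L)
  one <- function(code) {
    idx <- which(labels == code, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NA_real_)
    min(sqrt(((idx[, 1] - point[1]) * voxel_size_um[1])^2 +
               ((idx[, 2] - point[2]) * voxel_size_um[2])^2 +
               ((idx[, 3] - point[3]) * voxel_size_um[3])^2))
  }
  out <- tb(arteriole_um = one(1L), venule_um = one(2L))
  missing <- c("arteriole", "venule")[c(is.na(out$arteriole_um), is.na(out$venule_um))]
  attr(out, "missing_labels") <- missing
  out
}

#' Compare mean vessel-density curves between hypoxia classes
#'
#' Averages per-event density histograms within each class (hypoxic:
#' stall pO2 below the threshold; normoxic otherwise) bin by bin. Events
#' whose histograms end before the longest one contribute zero counts in
#' the missing bins.
#'
#' @param histograms named list of [density_histogram()] tables, one per
#'   event.
#' @param classes character/factor vector parallel to `histograms`
#'   (values `"hypoxic"` / `"normoxic"`, e.g. from collapsing
#'   [classify_hypoxia()]).
#' @return tibble `class`, `bin_lo_um`, `bin_hi_um`, `mean_count`,
#'   `sd_count`, `n_events`; if one class is absent the single remaining
#'   curve is returned with attribute `missing_class`.
#' @export
compare_density_by_class <- function(histograms, classes) {
  stopifnot(length(histograms) == length(classes), length(histograms) >= 1L)
  classes <- as.character(classes)
  bw <- if (nrow(histograms[[1]]) > 0)
    histograms[[1]]$bin_hi_um[1] - histograms[[1]]$bin_lo_um[1] else 1
  nb <- max(vapply(histograms, nrow, integer(1)))
  mat <- vapply(histograms, function(h) {
    c(h$n_voxels, rep(0L, nb - nrow(h)))
  }, numeric(nb))
  rows <- lapply(unique(classes), function(cl) {
    m <- mat[, classes == cl, drop = FALSE]
    tb(class = cl, bin_lo_um = (seq_len(nb) - 1) * bw,
       bin_hi_um = seq_len(nb) * bw,
       mean_count = rowMeans(m),
       sd_count = apply(m, 1, sd),
       n_events = ncol(m))
  })
  out <- dplyr::bind_rows(rows)
  present <- unique(classes)
  missing <- setdiff(c("normoxic", "hypoxic"), present)
  if (length(missing) > 0) {
    warn(sprintf("class '%s' has no events; returning single-class curve",
                 paste(missing, collapse = ",")))
    attr(out, "missing_class") <- missing
  }
  out
}
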