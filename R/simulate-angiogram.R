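#' Tube specifications for synthetic angiograms
#'
#' @param x0,y0,z0,x1,y1,z1 segment endpoints in micrometers (voxel `(1,1,1)`
#'   sits at the origin).
#' @param radius_um tube radius.
#' @param label `"none"`, `"arteriole"` or `"venule"`.
#' @param intensity fluorescence amplitude of the tube.
#' @return one-row tibble; bind rows for multiple tubes.
#' @export
tube_spec <- function(x0, y0, z0, x1, y1, z1, radius_um = 3,
                      label = c("none", "arteriole", "venule"),
                      intensity = 1) {
  label <- match.arg(label)
  stopifnot(radius_um > 0, intensity > 0)
  tb(x0 = x0, y0 = y0, z0 = z0, x1 = x1, y1 = y1, z1 = z1,
     radius_um = radius_um, label = label, intensity = intensity)
}

# separable Gaussian blur along each axis (kernel renormalized at edges)
gaussian_blur3 <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    n <- dim(a)[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(pmin(i + seq(-r, r), n), 1L)
      for (m in seq_along(j)) K[i, j[m]] <- K[i, j[m]] + k[m]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- K %*% matrix(ap, nrow = dp[1])
    dim(ap) <- dp
    a <- aperm(ap, order(perm))
  }
  a
}

#' Simulate a 3D angiogram volume with known vessel ground truth
#'
#' Builds a binary tube mask from centerline segments and radii, records
#' the ground-truth centerline voxels and large-vessel labels, and renders
#' an intensity volume as background plus tube fluorescence, Gaussian-
#' blurred and corrupted with Gaussian noise. Tubes extending past the
#' volume are clipped with a warning.
#'
#' @param dim length-3 integer volume dimensions (voxels).
#' @param voxel_size_um length-3 um per voxel (anisotropy allowed).
#' @param tubes tibble of [tube_spec()] rows (empty/NULL for an
#'   all-background volume).
#' @param seed RNG seed for the noise.
#' @param background background intensity.
#' @param noise_sd Gaussian noise standard deviation.
#' @param blur_sigma_um optical blur, um (0 disables).
#' @param points optional measurement-point tibble passed through.
#' @return an [angiogram_volume()] with `truth_mask`, `centerline`
#'   (voxel-coordinate matrix, a subset of the mask) and `labels` filled in.
#' @export
simulate_angiogram <- function(dim, voxel_size_um = c(1, 1, 1), tubes = NULL,
                               seed = NULL, background = 0.1,
                               noise_sd = 0.05, blur_sigma_um = 0.5,
                               points = NULL) {
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  if (!is.null(seed)) set.seed(seed)
  dim <- as.integer(dim)
  # voxel-center coordinates in um
  cx <- (seq_len(dim[1]) - 1) * voxel_size_um[1]
  cy <- (seq_len(dim[2]) - 1) * voxel_size_um[2]
  cz <- (seq_len(dim[3]) - 1) * voxel_size_um[3]
  X <- array(rep(cx, times = dim[2] * dim[3]), dim = dim)
  Y <- array(rep(rep(cy, each = dim[1]), times = dim[3]), dim = dim)
  Z <- array(rep(cz, each = dim[1] * dim[2]), dim = dim)

  mask <- array(FALSE, dim = dim)
  labels <- array(0L, dim = dim)
  signal <- array(0, dim = dim)
  center_vox <- NULL
  extent <- (dim - 1) * voxel_size_um
  if (!is.null(tubes) && nrow(tubes) > 0) {
    for (r in seq_len(nrow(tubes))) {
      p0 <- c(tubes$x0[r], tubes$y0[r], tubes$z0[r])
      p1 <- c(tubes$x1[r], tubes$y1[r], tubes$z1[r])
      if (any(c(p0, p1) < -tubes$radius_um[r]) ||
          any(c(p0, p1) > extent + tubes$radius_um[r])) {
        warn(sprintf("tube %d extends outside the volume and is clipped", r))
      }
      v <- p1 - p0
      len2 <- sum(v^2)
      if (len2 == 0) {
        d2 <- (X - p0[1])^2 + (Y - p0[2])^2 + (Z - p0[3])^2
      } else {
        t_par <- ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] + (Z - p0[3]) * v[3]) / len2
        t_par <- pmin(pmax(t_par, 0), 1)
        d2 <- (X - (p0[1] + t_par * v[1]))^2 +
          (Y - (p0[2] + t_par * v[2]))^2 +
          (Z - (p0[3] + t_par * v[3]))^2
      }
      inside <- d2 <= tubes$radius_um[r]^2
      mask <- mask | inside
      signal[inside] <- pmax(signal[inside], tubes$intensity[r])
      if (tubes$label[r] != "none") {
        labels[inside] <- if (tubes$label[r] == "arteriole") 1L else 2L
      }
      # centerline voxels: nearest voxels along the segment, kept within mask
      step <- min(voxel_size_um) / 2
      tt <- seq(0, 1, length.out = max(2L, ceiling(sqrt(len2) / step) + 1L))
      pts <- cbind(p0[1] + tt * v[1], p0[2] + tt * v[2], p0[3] + tt * v[3])
      vox <- unique(cbind(round(pts[, 1] / voxel_size_um[1]) + 1L,
                          round(pts[, 2] / voxel_size_um[2]) + 1L,
                          round(pts[, 3] / voxel_size_um[3]) + 1L))
      ok <- vox[, 1] >= 1 & vox[, 1] <= dim[1] &
        vox[, 2] >= 1 & vox[, 2] <= dim[2] &
        vox[, 3] >= 1 & vox[, 3] <= dim[3]
      vox <- vox[ok, , drop = FALSE]
      ok <- mask[vox] # labels only on vessel voxels; centerline subset of mask
      center_vox <- rbind(center_vox, vox[ok, , drop = FALSE])
    }
  }
  labels[!mask] <- 0L
  intensity <- background + signal
  if (blur_sigma_um > 0) {
    intensity <- gaussian_blur3(intensity, blur_sigma_um / voxel_size_um)
  }
  if (noise_sd > 0) {
    intensity <- intensity + array(rnorm(prod(dim), 0, noise_sd), dim = dim)
  }
  angiogram_volume(intensity, voxel_size_um, labels = labels,
                   truth_mask = mask,
                   centerline = if (is.null(center_vox))
                     matrix(integer(), ncol = 3) else unique(center_vox),
                   points = points)
}
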