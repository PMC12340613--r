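test_that("subvolume crops span 151 voxels and clip with a flag", {
  ang <- simulate_angiogram(c(160, 160, 160), c(1, 1, 1), NULL, seed = 71,
                            noise_sd = 0.01, blur_sigma_um = 0)
  sub <- crop_subvolume(ang, c(80, 80, 80), 75)
  expect_equal(dim(sub$intensity), c(151L, 151L, 151L))
  expect_false(sub$clipped)
  expect_equal(sub$point, c(76L, 76L, 76L))

  corner <- crop_subvolume(ang, c(3, 80, 158), 75)
  expect_true(corner$clipped)
  expect_equal(dim(corner$intensity), c(78L, 151L, 78L))

  expect_error(crop_subvolume(ang, c(0, 5, 5), 75), "outside")

  # crop of a crop at the same center equals the single crop when unclipped
  sub30 <- crop_subvolume(ang, c(80, 80, 80), 30)
  sub30b <- crop_subvolume(sub30, sub30$point, 30)
  expect_identical(sub30b$intensity, sub30$intensity)
})

test_that("binarization is exact on clean volumes and removes impulse noise", {
  # a two-level slab: the median filter preserves a flat interface exactly
  vol <- array(0.1, dim = c(20, 20, 20))
  vol[6:20, , ] <- 1
  truth <- vol > 0.5
  mask <- binarize_angiogram(vol)
  expect_equal(sum(mask != truth), 0L)

  # single-voxel impulse removed by the median filter
  vol2 <- vol
  vol2[2, 2, 2] <- 5
  mask2 <- binarize_angiogram(vol2)
  expect_false(mask2[2, 2, 2])
  expect_equal(sum(mask2 != truth), 0L)

  flat <- binarize_angiogram(array(0.3, dim = c(5, 5, 5)))
  expect_equal(sum(flat), 0L)
  expect_equal(attr(flat, "flag"), "constant_volume")
})

test_that("a synthetic tube is segmented with high overlap at realistic noise", {
  ang <- simulate_angiogram(c(50, 41, 41), c(1, 1, 1),
                            tube_spec(0, 20, 20, 49, 20, 20, radius_um = 5),
                            seed = 72)
  mask <- binarize_angiogram(ang)
  dice <- 2 * sum(mask & ang$truth_mask) / (sum(mask) + sum(ang$truth_mask))
  expect_gte(dice, 0.9)
})

test_that("skeletons are thin, inside the mask, and topology-preserving", {
  ang <- simulate_angiogram(c(50, 41, 41), c(1, 1, 1),
                            tube_spec(0, 20, 20, 49, 20, 20, radius_um = 3),
                            seed = 73)
  sk <- skeletonize_mask(ang$truth_mask)
  expect_true(all(ang$truth_mask[sk]))
  idx <- which(sk, arr.ind = TRUE)
  # a single one-voxel-wide path along the tube axis, full length
  expect_equal(length(unique(idx[, 1])), nrow(idx))
  expect_gte(nrow(idx), 50 - 2)
  expect_equal(oracle_components26(sk), 1L)

  empty <- skeletonize_mask(array(FALSE, dim = c(5, 5, 5)))
  expect_equal(sum(empty), 0L)

  two <- simulate_angiogram(c(40, 41, 41), c(1, 1, 1),
                            dplyr::bind_rows(
                              tube_spec(0, 10, 10, 39, 10, 10, radius_um = 2),
                              tube_spec(0, 30, 30, 39, 30, 30, radius_um = 2)),
                            seed = 74)
  sk2 <- skeletonize_mask(two$truth_mask)
  expect_equal(oracle_components26(sk2), 2L)
  expect_equal(oracle_components26(two$truth_mask), 2L)
})

test_that("density histograms conserve voxel counts and honor anisotropy", {
  mask <- array(FALSE, dim = c(30, 30, 30))
  mask[25, 15, 15] <- TRUE
  h <- density_histogram(c(15, 15, 15), mask, c(1, 1, 1))
  expect_equal(sum(h$n_voxels), 1L)
  expect_equal(h$n_voxels[h$bin_lo_um == 10], 1L)

  set.seed(75)
  mask2 <- array(runif(27e3) < 0.1, dim = c(30, 30, 30))
  h2 <- density_histogram(c(10, 20, 5), mask2, c(0.8, 0.8, 2))
  expect_equal(sum(h2$n_voxels), sum(mask2))
  expect_equal(sum(h2$n_voxels), attr(h2, "total_voxels"))

  h0 <- density_histogram(c(5, 5, 5), array(FALSE, dim = c(10, 10, 10)), c(1, 1, 1))
  expect_equal(sum(h0$n_voxels), 0)
})

test_that("cumulative density around a point grows like distance cubed", {
  d <- 41L
  ctr <- c(21, 21, 21)
  idx <- as.matrix(expand.grid(1:d, 1:d, 1:d))
  r <- sqrt(rowSums((t(t(idx) - ctr))^2))
  mask <- array(r <= 15, dim = c(d, d, d))
  h <- density_histogram(ctr, mask, c(1, 1, 1))
  cum <- cumsum(h$n_voxels)
  sel <- h$bin_hi_um %in% c(6, 9, 12, 15)
  ratio <- cum[sel] / ((4 / 3) * pi * h$bin_hi_um[sel]^3)
  expect_lt(diff(range(ratio)) / mean(ratio), 0.15)
})

test_that("module distances match a brute-force voxel scan", {
  set.seed(76)
  mask <- array(runif(8 * 9 * 10) < 0.15, dim = c(8, 9, 10))
  vox <- c(0.7, 1.1, 3)
  pt <- c(3, 4, 5)
  h <- density_histogram(pt, mask, vox, bin_width_um = 0.5)
  # brute force: loop over every voxel
  dists <- c()
  for (x in 1:8) for (y in 1:9) for (z in 1:10) {
    if (mask[x, y, z]) {
      dists <- c(dists, sqrt(((x - pt[1]) * vox[1])^2 +
                               ((y - pt[2]) * vox[2])^2 +
                               ((z - pt[3]) * vox[3])^2))
    }
  }
  brute <- tabulate(floor(dists / 0.5) + 1L, nbins = nrow(h))
  expect_equal(h$n_voxels, brute)

  labels <- array(0L, dim = c(8, 9, 10))
  labels[mask] <- 1L
  nv <- nearest_large_vessel(pt, labels, vox)
  expect_equal(nv$arteriole_um, min(dists), tolerance = 1e-9)
})

test_that("nearest large-vessel distances handle all label cases", {
  labels <- array(0L, dim = c(12, 12, 12))
  labels[4, 5, 1] <- 1L
  nv <- nearest_large_vessel(c(1, 1, 1), labels, c(1, 1, 1))
  expect_equal(nv$arteriole_um, 5) # 3-4-0 triangle
  expect_true(is.na(nv$venule_um))
  expect_equal(attr(nv, "missing_labels"), "venule")

  labels[4, 5, 1] <- 2L
  labels[1, 1, 1] <- 1L
  nv2 <- nearest_large_vessel(c(1, 1, 1), labels, c(1, 1, 1))
  expect_equal(nv2$arteriole_um, 0)
  expect_equal(nv2$venule_um, 5)
})

test_that("density comparisons by class average per-bin counts", {
  h1 <- tibble::tibble(bin_lo_um = 0:2, bin_hi_um = 1:3, n_voxels = c(5L, 10L, 20L))
  h2 <- tibble::tibble(bin_lo_um = 0:2, bin_hi_um = 1:3, n_voxels = c(5L, 10L, 20L))
  cmp <- compare_density_by_class(list(h1, h2), c("hypoxic", "normoxic"))
  hyp <- cmp[cmp$class == "hypoxic", ]
  nor <- cmp[cmp$class == "normoxic", ]
  expect_equal(hyp$mean_count, nor$mean_count)
  expect_equal(hyp$mean_count, c(5, 10, 20))

  expect_warning(
    one <- compare_density_by_class(list(h1), "hypoxic"),
    "no events"
  )
  expect_equal(attr(one, "missing_class"), "normoxic")

  # constructed class-dependent far-field density diverges far, agrees near
  mknear <- function(far) tibble::tibble(bin_lo_um = 0:9, bin_hi_um = 1:10,
                                         n_voxels = c(rep(8L, 5), rep(far, 5)))
  cmp2 <- compare_density_by_class(
    list(mknear(20L), mknear(20L), mknear(5L), mknear(5L)),
    c("normoxic", "normoxic", "hypoxic", "hypoxic"))
  near_diff <- abs(cmp2$mean_count[cmp2$class == "normoxic" & cmp2$bin_lo_um < 5] -
                     cmp2$mean_count[cmp2$class == "hypoxic" & cmp2$bin_lo_um < 5])
  far_diff <- abs(cmp2$mean_count[cmp2$class == "normoxic" & cmp2$bin_lo_um >= 5] -
                    cmp2$mean_count[cmp2$class == "hypoxic" & cmp2$bin_lo_um >= 5])
  expect_true(all(near_diff == 0))
  expect_true(all(far_diff > 0))
})
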