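test_that("resampling: identity, constants and a closed-form gradient", {
  v <- array(rnorm(8 * 8 * 8), dim = c(8L, 8L, 8L))
  voxel_spacing(v) <- c(1, 1, 3)
  out <- resample_volume(v, c(1, 1, 3))
  expect_equal(out, v, ignore_attr = TRUE)

  cv <- array(7.5, dim = c(6L, 6L, 6L))
  voxel_spacing(cv) <- c(2, 2, 2)
  out2 <- resample_volume(cv, c(1, 1, 1))
  expect_true(all(abs(out2 - 7.5) < 1e-12))
  expect_equal(voxel_spacing(out2), c(1, 1, 1))

  # linear gradient in physical mm: trilinear interpolation is exact away
  # from the clamped border
  d <- c(10L, 10L, 10L)
  sp <- c(2, 2, 2)
  xs <- (seq_len(d[1]) - 0.5) * sp[1]
  g <- array(0, dim = d)
  for (i in seq_len(d[1])) g[i, , ] <- 3 * xs[i]
  voxel_spacing(g) <- sp
  out3 <- resample_volume(g, c(1, 1, 1))
  xs_new <- (seq_len(dim(out3)[1]) - 0.5) * 1
  interior <- 2:(dim(out3)[1] - 1)
  expect_lt(max(abs(out3[interior, 5, 5] - 3 * xs_new[interior])), 1e-10)

  # label path: nearest keeps labels integral
  m <- empty_mask(c(8L, 8L, 8L), spacing = c(2, 2, 2))
  m <- paint_box(m, c(3, 3, 3), c(6, 6, 6), 2L)
  mr <- resample_volume(m, c(1, 1, 1), method = "nearest")
  expect_true(all(mr %in% c(0L, 2L)))
  expect_equal(sum(mr == 2L), 8 * sum(m == 2L))
})

test_that("CT normalization clips at the 0.5/99.5 percentiles then z-scores", {
  set.seed(1)
  ct <- array(rnorm(4000, 50, 20), dim = c(20L, 20L, 10L))
  out <- normalize_ct(ct)
  expect_lt(abs(mean(out)), 1e-6)
  expect_lt(abs(sd(out) - 1), 1e-6)

  # an extreme outlier maps to the same value as the 99.5th percentile
  ct2 <- ct
  ct2[1] <- 1e6
  out2 <- normalize_ct(ct2)
  hi <- quantile(ct2, 0.995, names = FALSE, type = 7)
  idx_hi <- which.min(abs(ct2 - hi))
  expect_equal(out2[1], max(out2))
  expect_lt(abs(out2[1] - out2[idx_hi]), 0.01)

  # clip bounds equal independently computed order statistics (1000 points)
  set.seed(2)
  x <- array(runif(1000), dim = c(10L, 10L, 10L))
  b <- attr(normalize_ct(x), "clip_bounds")
  sorted <- sort(as.vector(x))
  oracle_q <- function(p) {
    h <- (1000 - 1) * p + 1
    lo <- floor(h)
    sorted[lo] + (h - lo) * (sorted[lo + 1] - sorted[lo])
  }
  expect_equal(b[1], oracle_q(0.005))
  expect_equal(b[2], oracle_q(0.995))

  expect_error(normalize_ct(array(3, dim = c(4L, 4L, 4L))), "degenerate")
})

test_that("PET normalization is the exact min-max map", {
  v <- array(c(2, 4, 6, 2, 4, 6, 2, 6), dim = c(2L, 2L, 2L))
  out <- normalize_pet(v)
  expect_equal(as.vector(out), c(0, 0.5, 1, 0, 0.5, 1, 0, 1))
  set.seed(3)
  r <- array(runif(512, 5, 9), dim = c(8L, 8L, 8L))
  outr <- normalize_pet(r)
  expect_equal(min(outr), 0)
  expect_equal(max(outr), 1)
  u <- array(seq(0, 1, length.out = 64), dim = c(4L, 4L, 4L))
  expect_equal(as.vector(normalize_pet(u)), as.vector(u))
  expect_error(normalize_pet(array(1, dim = c(3L, 3L, 3L))), "degenerate")
})

test_that("brain crop locator finds the top bright region centroid", {
  d <- c(40L, 40L, 40L)
  pet <- array(abs(rnorm(prod(d), 0.2, 0.05)), dim = d)
  # bright sphere near the top, centred at (14, 26)
  centre <- c(14, 26, 38)
  for (i in 10:18) for (j in 22:30) for (k in 35:40) {
    if (sum((c(i, j, k) - centre)^2) <= 16) pet[i, j, k] <- 8
  }
  reg <- locate_brain_crop(pet, extent = c(20L, 20L, 10L))
  expect_lt(max(abs(reg$centre - centre[1:2])), 1)
  expect_equal(reg$top_slice, max(which(apply(pet > reg$threshold, 3, any))))

  # two disjoint blobs: joint centroid of above-threshold voxels
  pet2 <- array(abs(rnorm(prod(d), 0.2, 0.05)), dim = d)
  pet2[10:12, 10:12, 38:40] <- 8
  pet2[30:32, 30:32, 38:40] <- 8
  reg2 <- locate_brain_crop(pet2, extent = c(20L, 20L, 10L))
  expect_lt(max(abs(reg2$centre - c(21, 21))), 1)

  expect_error(locate_brain_crop(array(0, dim = d)), "Otsu|detect")
})

test_that("cropping pads out-of-bounds voxels and round-trips coordinates", {
  d <- c(30L, 30L, 30L)
  v <- array(seq_len(prod(d)), dim = d)
  reg <- structure(list(centre = c(15, 15), top_slice = 25L,
                        extent = c(10L, 10L, 8L),
                        start = c(11L, 11L, 18L), threshold = 0),
                   class = "crop_region")
  out <- apply_crop(v, reg, pad = -1)
  expect_equal(dim(out), c(10L, 10L, 8L))
  expect_equal(out[1, 1, 1], v[11, 11, 18])
  expect_true(all(out != -1))

  # corner region: overhang filled with the pad value
  reg2 <- structure(list(centre = c(1, 1), top_slice = 4L,
                         extent = c(10L, 10L, 8L),
                         start = c(-4L, -4L, -3L), threshold = 0),
                    class = "crop_region")
  out2 <- apply_crop(v, reg2, pad = -1)
  expect_equal(out2[1, 1, 1], -1)
  expect_equal(out2[6, 6, 5], v[1, 1, 1])

  # round trip: cropped voxel coordinates map back to the original grid
  orig <- crop_to_original(c(6, 6, 5), reg2)
  expect_equal(as.vector(orig), c(1, 1, 1))
  orig2 <- crop_to_original(c(3, 4, 2), reg)
  expect_equal(as.vector(orig2), c(13, 14, 19))
})

test_that("standard crop loses no labelled voxels on in-range phantoms", {
  ph <- generate_phantom(phantom_config(seed = 17L))
  pp <- preprocess_pair(ph$ct, ph$pet, ph$mask)  # full 260x260x104 extent
  expect_equal(sum(pp$mask > 0), sum(resample_volume(
    ph$mask, c(1, 1, 3), "nearest") > 0))
})

test_that("nearest-neighbour label resampling preserves component counts", {
  ph <- generate_phantom(phantom_config(seed = 23L, n_tumours = 2L,
                                        n_nodes = 2L,
                                        lesion_volume_range = c(600, 3000)))
  n0 <- length(extract_lesions(ph$mask)$lesions)
  mr <- resample_volume(ph$mask, c(1, 1, 3), "nearest")
  storage.mode(mr) <- "integer"
  expect_equal(length(extract_lesions(mr)$lesions), n0)
})
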