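# Patch augmentation: mirroring, rotation about the axial axis, isotropic
# scaling, elastic deformation (spatial transforms shared between image and
# label, label resampled nearest-neighbour), plus image-only Gaussian noise
# and gamma correction.

#' Augmentation configuration
#'
#' @param mirror flip each axis independently with probability 1/2.
#' @param rotate random rotation about the z (axial) axis.
#' @param max_angle maximum rotation in degrees (default 15).
#' @param scale random isotropic scaling.
#' @param scale_range multiplicative range (default c(0.9, 1.1)).
#' @param elastic random smooth displacement field.
#' @param elastic_alpha displacement magnitude in voxels (default 2).
#' @param elastic_grid coarse control-grid size per axis (default 4).
#' @param noise additive Gaussian intensity noise (image only).
#' @param noise_sd noise standard deviation (default 0.02).
#' @param gamma per-channel gamma correction (image only).
#' @param gamma_range exponent range (default c(0.8, 1.25)).
#' @return an `augment_config`.
#' @export
augment_config <- function(mirror = TRUE, rotate = TRUE, max_angle = 15,
                           scale = TRUE, scale_range = c(0.9, 1.1),
                           elastic = FALSE, elastic_alpha = 2,
                           elastic_grid = 4L,
                           noise = TRUE, noise_sd = 0.02,
                           gamma = TRUE, gamma_range = c(0.8, 1.25)) {
  structure(as.list(environment()), class = "augment_config")
}

# trilinear sampling of a 3D array at continuous (1-based) coordinates,
# clamped at the edges
sample_trilinear <- function(vol, coords) {
  d <- dim(vol)
  cl <- lapply(1:3, function(a) pmin(pmax(coords[, a], 1), d[a]))
  lo <- lapply(1:3, function(a) pmin(floor(cl[[a]]), d[a] - 1L))
  fr <- lapply(1:3, function(a) cl[[a]] - lo[[a]])
  out <- 0
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cx == 0) 1 - fr[[1]] else fr[[1]]) *
      (if (cy == 0) 1 - fr[[2]] else fr[[2]]) *
      (if (cz == 0) 1 - fr[[3]] else fr[[3]])
    idx <- cbind(lo[[1]] + cx, lo[[2]] + cy, lo[[3]] + cz)
    out <- out + w * vol[idx]
  }
  out
}

sample_nearest <- function(vol, coords) {
  d <- dim(vol)
  idx <- vapply(1:3, function(a) pmin(pmax(round(coords[, a]), 1), d[a]),
                numeric(nrow(coords)))
  vol[idx]
}

#' Apply a random augmentation to an image/label patch pair
#'
#' Spatial transforms are shared: the image is resampled trilinearly, the
#' label nearest-neighbour. Intensity transforms touch the image only.
#' Mirroring is an exact axis flip (no interpolation), so with mirroring
#' alone the per-class label voxel counts are preserved exactly; with all
#' transforms disabled the patch is returned unchanged.
#'
#' @param image 4D array (x, y, z, channel) or 3D array.
#' @param label 3D integer label array.
#' @param config an [augment_config()].
#' @param seed integer seed; same seed gives identical output.
#' @return list with `image` and `label`.
#' @export
augment_patch <- function(image, label, config, seed = 1L) {
  stopifnot(inherits(config, "augment_config"))
  was_3d <- length(dim(image)) == 3L
  if (was_3d) dim(image) <- c(dim(image), 1L)
  d <- dim(label)
  stopifnot(identical(dim(image)[1:3], d))
  with_seed(seed, {
    if (config$mirror) {
      for (a in 1:3) {
        if (runif(1) < 0.5) {
          idx <- rev(seq_len(d[a]))
          if (a == 1) { image <- image[idx, , , , drop = FALSE]; label <- label[idx, , , drop = FALSE] }
          if (a == 2) { image <- image[, idx, , , drop = FALSE]; label <- label[, idx, , drop = FALSE] }
          if (a == 3) { image <- image[, , idx, , drop = FALSE]; label <- label[, , idx, drop = FALSE] }
        }
      }
    }
    if (config$rotate || config$scale || config$elastic) {
      theta <- if (config$rotate) runif(1, -config$max_angle, config$max_angle) * pi / 180 else 0
      sc <- if (config$scale) runif(1, config$scale_range[1], config$scale_range[2]) else 1
      centre <- (d + 1) / 2
      grid <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                    z = seq_len(d[3])))
      rel <- sweep(grid, 2, centre)
      # inverse map: rotate by -theta, scale by 1/sc
      cth <- cos(-theta); sth <- sin(-theta)
      src <- cbind(rel[, 1] * cth - rel[, 2] * sth,
                   rel[, 1] * sth + rel[, 2] * cth,
                   rel[, 3]) / sc
      src <- sweep(src, 2, centre, `+`)
      if (config$elastic) {
        g <- config$elastic_grid
        for (a in 1:3) {
          ctrl <- array(rnorm(g^3, 0, config$elastic_alpha), dim = rep(g, 3))
          # evaluate the coarse field at each voxel by trilinear interpolation
          cc <- sweep(grid - 1, 2, (d - 1), `/`) * (g - 1) + 1
          src[, a] <- src[, a] + sample_trilinear(ctrl, cc)
        }
      }
      new_img <- image
      for (ch in seq_len(dim(image)[4])) {
        new_img[, , , ch] <- array(sample_trilinear(image[, , , ch], src), dim = d)
      }
      image <- new_img
      label <- array(as.integer(sample_nearest(label, src)), dim = d)
    }
    if (config$noise) {
      image <- image + rnorm(length(image), 0, config$noise_sd)
    }
    if (config$gamma) {
      for (ch in seq_len(dim(image)[4])) {
        x <- image[, , , ch]
        rng <- range(x)
        if (rng[2] > rng[1]) {
          gm <- runif(1, config$gamma_range[1], config$gamma_range[2])
          xn <- (x - rng[1]) / (rng[2] - rng[1])
          image[, , , ch] <- xn^gm * (rng[2] - rng[1]) + rng[1]
        }
      }
    }
  })
  if (was_3d) dim(image) <- d
  list(image = image, label = label)
}
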