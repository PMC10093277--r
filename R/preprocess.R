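# Image standardization: resampling to a common grid, modality-specific
# intensity normalization, and the Otsu brain-anchored axial crop.

#' Resample a 3D volume to a target spacing
#'
#' Voxel centres follow the half-voxel convention: physical coordinate of
#' index i (1-based) is `(i - 0.5) * spacing`. Scalar volumes use trilinear
#' interpolation (with edge clamping); label masks must use
#' `method = "nearest"`.
#'
#' @param vol 3D array with a spacing attribute (see [voxel_spacing()]).
#' @param target_spacing numeric length-3, mm (default c(1, 1, 3)).
#' @param method "linear" or "nearest".
#' @return resampled array with updated spacing attribute.
#' @export
resample_volume <- function(vol, target_spacing = c(1, 1, 3),
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.array(vol), length(dim(vol)) == 3L,
            length(target_spacing) == 3L, all(target_spacing > 0))
  sp <- voxel_spacing(vol)
  d <- dim(vol)
  if (isTRUE(all.equal(sp, as.numeric(target_spacing)))) {
    voxel_spacing(vol) <- target_spacing
    return(vol)
  }
  nd <- pmax(1L, as.integer(round(d * sp / target_spacing)))
  # input index (1-based, continuous) of each output voxel centre per axis
  ax_idx <- lapply(1:3, function(a) {
    ((seq_len(nd[a]) - 0.5) * target_spacing[a]) / sp[a] + 0.5
  })
  if (method == "nearest") {
    ii <- lapply(1:3, function(a) pmin(pmax(round(ax_idx[[a]]), 1L), d[a]))
    out <- vol[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
    dim(out) <- nd
  } else {
    lo <- lapply(1:3, function(a) pmin(pmax(floor(ax_idx[[a]]), 1L), d[a]))
    hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d[a]))
    fr <- lapply(1:3, function(a) {
      f <- ax_idx[[a]] - floor(ax_idx[[a]])
      f[ax_idx[[a]] < 1] <- 0
      f[ax_idx[[a]] > d[a]] <- 0
      # when lo was clamped to d[a], hi == lo and the fraction is inert
      f
    })
    out <- array(0, dim = nd)
    for (cz in 0:1) {
      zi <- if (cz == 0) lo[[3]] else hi[[3]]
      wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
      for (cy in 0:1) {
        yi <- if (cy == 0) lo[[2]] else hi[[2]]
        wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
        for (cx in 0:1) {
          xi <- if (cx == 0) lo[[1]] else hi[[1]]
          wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
          w <- outer(outer(wx, wy), wz)
          if (all(w == 0)) next
          out <- out + w * vol[xi, yi, zi, drop = FALSE]
        }
      }
    }
  }
  voxel_spacing(out) <- target_spacing
  out
}

#' Resample a co-registered CT/PET pair to a common spacing
#'
#' @param ct,pet 3D arrays with spacing attributes (same physical space).
#' @param target_spacing numeric length-3, mm (default c(1, 1, 3)).
#' @return list with resampled `ct` and `pet`.
#' @export
resample_pair <- function(ct, pet, target_spacing = c(1, 1, 3)) {
  list(ct = resample_volume(ct, target_spacing, "linear"),
       pet = resample_volume(pet, target_spacing, "linear"))
}

#' Percentile-clip and z-score normalize a CT volume
#'
#' Clips intensities to the volume's own [0.5, 99.5] percentile interval
#' (linear-interpolation order statistics), then standardises to mean 0,
#' sd 1 using post-clip statistics.
#'
#' @param ct 3D array.
#' @param probs clip percentiles (default c(0.005, 0.995)).
#' @return normalized array; attributes `clip_bounds`, `centre`, `scale`
#'   record the transform.
#' @export
normalize_ct <- function(ct, probs = c(0.005, 0.995)) {
  stopifnot(is.array(ct))
  if (length(unique(as.vector(ct))) < 2L) {
    stopf("degenerate CT volume: fewer than 2 distinct values")
  }
  b <- quantile(ct, probs = probs, names = FALSE, type = 7)
  x <- pmin(pmax(ct, b[1]), b[2])
  mu <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) stopf("degenerate CT volume: sd is 0 after clipping")
  out <- (x - mu) / s
  dim(out) <- dim(ct)
  voxel_spacing(out) <- voxel_spacing(ct)
  attr(out, "clip_bounds") <- b
  attr(out, "centre") <- mu
  attr(out, "scale") <- s
  out
}

#' Min-max normalize a PET volume to [0, 1]
#'
#' @param pet 3D array with max > min.
#' @return normalized array in [0, 1]; attributes record min and range.
#' @export
normalize_pet <- function(pet) {
  stopifnot(is.array(pet))
  lo <- min(pet); hi <- max(pet)
  if (hi <= lo) stopf("degenerate PET volume: max <= min")
  out <- (pet - lo) / (hi - lo)
  dim(out) <- dim(pet)
  voxel_spacing(out) <- voxel_spacing(pet)
  attr(out, "min") <- lo
  attr(out, "range") <- hi - lo
  out
}

#' Otsu threshold of a numeric volume
#'
#' Maximises between-class variance over a 256-bin histogram.
#'
#' @param x numeric array or vector.
#' @param n_bins histogram resolution (default 256).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.vector(x)
  rng <- range(v)
  if (rng[1] == rng[2]) stopf("constant volume: Otsu threshold undefined")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Locate the brain-anchored crop region on a PET volume
#'
#' Applies Otsu thresholding to the PET intensities, scans axial slices from
#' the top of the stack (highest z index) downwards, and takes the first
#' four slices containing above-threshold voxels as the brain top. The
#' in-plane crop centre is the joint centroid of the above-threshold voxels
#' in those four slices; the crop extends `extent[3]` slices downward from
#' the topmost such slice and `extent[1] x extent[2]` in-plane.
#'
#' @param pet 3D PET array (must contain a bright region near the top).
#' @param extent crop extent in voxels (default c(260, 260, 104), i.e.
#'   260 mm x 260 mm x 312 mm on the 1 x 1 x 3 mm grid).
#' @return a `crop_region`: list with `centre` (x, y), `top_slice`, `extent`,
#'   `start` (1-based start indices, possibly out of bounds), `threshold`.
#' @export
locate_brain_crop <- function(pet, extent = c(260L, 260L, 104L)) {
  stopifnot(is.array(pet), length(dim(pet)) == 3L, length(extent) == 3L)
  thr <- otsu_threshold(pet)
  above <- pet > thr
  if (!any(above)) stopf("no above-threshold voxels: brain region not detected")
  d <- dim(pet)
  z_has <- which(apply(above, 3, any))
  z_top_slices <- sort(z_has, decreasing = TRUE)[seq_len(min(4L, length(z_has)))]
  top_slice <- max(z_top_slices)
  sel <- above[, , z_top_slices, drop = FALSE]
  coords <- arrayInd(which(sel), dim(sel))
  centre <- c(mean(coords[, 1]), mean(coords[, 2]))
  start <- c(round(centre[1]) - floor(extent[1] / 2) + 1L,
             round(centre[2]) - floor(extent[2] / 2) + 1L,
             top_slice - extent[3] + 1L)
  structure(list(centre = centre, top_slice = top_slice,
                 extent = as.integer(extent), start = as.integer(start),
                 threshold = thr),
            class = "crop_region")
}

#' @export
print.crop_region <- function(x, ...) {
  cat(sprintf("crop_region: centre (%.1f, %.1f), top slice %d, extent %s, start (%s)\n",
              x$centre[1], x$centre[2], x$top_slice,
              paste(x$extent, collapse = "x"),
              paste(x$start, collapse = ", ")))
  invisible(x)
}

#' Apply a crop region to a volume or mask, padding out-of-bounds voxels
#'
#' @param vol 3D array.
#' @param region a `crop_region` from [locate_brain_crop()].
#' @param pad fill value for out-of-bounds voxels (0 for masks, the modality
#'   floor for images).
#' @return array of shape `region$extent`; attribute `crop_start` records the
#'   offset for [crop_to_original()].
#' @export
apply_crop <- function(vol, region, pad = 0) {
  stopifnot(is.array(vol), inherits(region, "crop_region"))
  d <- dim(vol)
  ext <- region$extent
  out <- array(pad, dim = ext)
  src_lo <- pmax(region$start, 1L)
  src_hi <- pmin(region$start + ext - 1L, d)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - region$start + 1L
    dst_hi <- src_hi - region$start + 1L
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      vol[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  if (is.integer(vol)) storage.mode(out) <- "integer"
  voxel_spacing(out) <- voxel_spacing(vol)
  attr(out, "crop_start") <- region$start
  out
}

#' Map cropped-volume voxel coordinates back to the original grid
#'
#' @param coords integer matrix or vector of (x, y, z) coordinates in the
#'   cropped volume (1-based).
#' @param region the `crop_region` used for cropping.
#' @return coordinates in the original volume.
#' @export
crop_to_original <- function(coords, region) {
  stopifnot(inherits(region, "crop_region"))
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  sweep(coords, 2, region$start - 1L, `+`)
}

#' Full preprocessing of a phantom or scan pair
#'
#' Resamples CT/PET (and optionally the label mask, nearest-neighbour) to the
#' target spacing, normalizes each modality, locates the brain-anchored crop
#' on the normalized PET and applies it to every channel.
#'
#' @param ct,pet 3D arrays with spacing attributes.
#' @param mask optional integer label mask on the same grid.
#' @param target_spacing common resolution, default c(1, 1, 3) mm.
#' @param extent crop extent, default c(260, 260, 104) voxels.
#' @return list with cropped `ct`, `pet`, optional `mask`, and the
#'   `crop_region`.
#' @export
preprocess_pair <- function(ct, pet, mask = NULL,
                            target_spacing = c(1, 1, 3),
                            extent = c(260L, 260L, 104L)) {
  rs <- resample_pair(ct, pet, target_spacing)
  ct_n <- normalize_ct(rs$ct)
  pet_n <- normalize_pet(rs$pet)
  region <- locate_brain_crop(pet_n, extent = extent)
  out <- list(
    ct = apply_crop(ct_n, region, pad = min(ct_n)),
    pet = apply_crop(pet_n, region, pad = 0),
    region = region
  )
  if (!is.null(mask)) {
    mask_rs <- resample_volume(mask, target_spacing, "nearest")
    storage.mode(mask_rs) <- "integer"
    out$mask <- apply_crop(mask_rs, region, pad = 0L)
  }
  out
}
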