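# Lesion-level machinery: connected components, per-lesion uncertainty
# density, DSC-thresholded detection matching, uncertainty-threshold
# false-positive filtering, and the FPI/TPR operating-curve sweep.

LESION_CLASSES <- c("GTVp" = 1L, "GTVn" = 2L)

#' Extract lesions as connected components of a label mask
#'
#' One lesion per connected component per foreground class (1 = GTVp primary
#' tumour, 2 = GTVn lymph node); components of different classes are never
#' merged.
#'
#' @param mask 3D integer array with classes in \{0, 1, 2\}.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return a `lesion_set`: list with `lesions` (each with `class`, `voxels`
#'   linear indices, `volume` in mm3, `centroid` in voxel coordinates),
#'   `dim` and `spacing`.
#' @export
extract_lesions <- function(mask, connectivity = 26L) {
  assert_mask(mask)
  sp <- voxel_spacing(mask)
  vv <- prod(sp)
  d <- dim(mask)
  lesions <- list()
  for (cls in names(LESION_CLASSES)) {
    cl_val <- LESION_CLASSES[[cls]]
    bin <- array(as.integer(mask == cl_val), dim = d)
    if (!any(bin == 1L)) next
    lab <- cc_label_3d(bin, as.integer(connectivity))
    ncomp <- attr(lab, "n_components")
    for (k in seq_len(ncomp)) {
      vox <- which(lab == k)
      coords <- arrayInd(vox, d)
      lesions[[length(lesions) + 1L]] <- list(
        id = sprintf("%s_%02d", cls, k),
        class = cls,
        voxels = vox,
        volume = length(vox) * vv,
        centroid = colMeans(coords)
      )
    }
  }
  structure(list(lesions = lesions, dim = d, spacing = sp),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cls <- vapply(x$lesions, `[[`, "", "class")
  cat(sprintf("lesion_set: %d lesions (%d GTVp, %d GTVn) on %s grid\n",
              length(x$lesions), sum(cls == "GTVp"), sum(cls == "GTVn"),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Rebuild an integer label mask from a lesion set
#' @param set a `lesion_set`.
#' @return 3D integer array with the set's classes painted back in.
#' @export
lesion_set_to_mask <- function(set) {
  stopifnot(inherits(set, "lesion_set"))
  mask <- array(0L, dim = set$dim)
  for (l in set$lesions) mask[l$voxels] <- LESION_CLASSES[[l$class]]
  voxel_spacing(mask) <- set$spacing
  mask
}

#' Uncertainty density of a lesion
#'
#' Mean of the ensemble-variance uncertainty over the lesion's voxels,
#' taken from the lesion's own class channel:
#' `t_uncertain = (1/N) * sum_v I_uncertain(v) * l(v)` with N the lesion
#' voxel count. Because per-voxel variance of a [0,1] probability is at most
#' 0.25, densities live in [0, 0.25].
#'
#' @param lesion a single lesion (element of a `lesion_set$lesions`).
#' @param map an [uncertainty_map()].
#' @return scalar uncertainty density.
#' @export
uncertainty_density <- function(lesion, map) {
  stopifnot(inherits(map, "uncertainty_map"))
  if (length(lesion$voxels) == 0L) stopf("lesion has no voxels")
  channel <- map[[lesion$class]]
  if (is.null(channel)) stopf("uncertainty map lacks channel '%s'", lesion$class)
  if (max(lesion$voxels) > length(channel)) stopf("lesion outside map bounds")
  mean(channel[lesion$voxels])
}

#' Attach uncertainty densities to every lesion of a set
#' @inheritParams uncertainty_density
#' @param set a `lesion_set`.
#' @return the set with `$t_uncertain` filled in per lesion.
#' @export
annotate_uncertainty <- function(set, map) {
  set$lesions <- lapply(set$lesions, function(l) {
    l$t_uncertain <- uncertainty_density(l, map)
    l
  })
  set
}

pairwise_dsc <- function(a, b) {
  2 * length(intersect(a$voxels, b$voxels)) /
    (length(a$voxels) + length(b$voxels))
}

#' Match predicted lesions against ground truth at a DSC threshold
#'
#' Detection is a per-class coverage criterion, not a bijection: a
#' ground-truth lesion is a true positive iff some same-class predicted
#' lesion overlaps it with `DSC > dsc_threshold`; otherwise it is a false
#' negative. A predicted lesion overlapping no ground-truth lesion above the
#' threshold is a false positive.
#'
#' @param pred,gt `lesion_set` objects on the same grid.
#' @param dsc_threshold detection threshold on pairwise Dice (default 0.1).
#' @return a `lesion_match` with per-class `counts` (tp/fp/fn) and a `pairs`
#'   data frame of all same-class pairwise DSC values.
#' @export
match_lesions <- function(pred, gt, dsc_threshold = 0.1) {
  stopifnot(inherits(pred, "lesion_set"), inherits(gt, "lesion_set"))
  if (!identical(pred$dim, gt$dim)) stopf("lesion sets on different grids")
  classes <- names(LESION_CLASSES)
  pairs <- list()
  counts <- data.frame(class = classes, tp = 0L, fp = 0L, fn = 0L)
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    p <- Filter(function(l) l$class == cls, pred$lesions)
    g <- Filter(function(l) l$class == cls, gt$lesions)
    if (length(p) && length(g)) {
      dscm <- matrix(0, length(g), length(p))
      for (i in seq_along(g)) for (j in seq_along(p)) {
        dscm[i, j] <- pairwise_dsc(g[[i]], p[[j]])
        pairs[[length(pairs) + 1L]] <- data.frame(
          class = cls, gt = g[[i]]$id, pred = p[[j]]$id, dsc = dscm[i, j])
      }
      gt_hit <- apply(dscm, 1, max) > dsc_threshold
      pred_hit <- apply(dscm, 2, max) > dsc_threshold
      counts$tp[ci] <- sum(gt_hit)
      counts$fn[ci] <- sum(!gt_hit)
      counts$fp[ci] <- sum(!pred_hit)
    } else {
      counts$fn[ci] <- length(g)
      counts$fp[ci] <- length(p)
    }
  }
  structure(
    list(counts = counts,
         pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
         dsc_threshold = dsc_threshold),
    class = "lesion_match"
  )
}

#' @export
print.lesion_match <- function(x, ...) {
  cat(sprintf("lesion_match (DSC > %g):\n", x$dsc_threshold))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Remove predicted lesions with high uncertainty density
#'
#' Drops every lesion whose `t_uncertain` strictly exceeds `threshold`
#' (so a threshold of 0.5 never removes anything, variance being bounded by
#' 0.25); the survivors are returned untouched.
#'
#' @param set a `lesion_set` of predictions.
#' @param map an [uncertainty_map()] used to compute densities (ignored for
#'   lesions already annotated).
#' @param threshold nonnegative uncertainty-density cutoff.
#' @return the filtered `lesion_set`.
#' @export
filter_by_uncertainty <- function(set, map, threshold) {
  assert_scalar_num(threshold, "threshold", lower = 0)
  set <- annotate_uncertainty(set, map)
  set$lesions <- Filter(function(l) l$t_uncertain <= threshold, set$lesions)
  set
}

#' Sweep the uncertainty threshold and record the FPI/TPR operating curve
#'
#' For each threshold the predicted lesions of every image are filtered by
#' uncertainty density, matched against ground truth at `DSC > 0.1`, and the
#' cohort's false positives per image and detection sensitivity are
#' accumulated per class. Filtering is monotone in the threshold, so both
#' FPI and TPR are non-decreasing along the curve.
#'
#' @param cohort list of images; each element needs `pred` (a `lesion_set`),
#'   `gt` (a `lesion_set`) and `map` (an [uncertainty_map()]).
#' @param thresholds numeric vector (default `seq(0, 0.5, by = 0.025)`,
#'   21 points).
#' @param dsc_threshold detection DSC threshold (default 0.1).
#' @return data frame with columns threshold, class, tp, fp, fn, fpi, tpr.
#' @export
sweep_operating_curve <- function(cohort, thresholds = seq(0, 0.5, by = 0.025),
                                  dsc_threshold = 0.1) {
  if (length(cohort) == 0L) stopf("cohort is empty")
  n_img <- length(cohort)
  annotated <- lapply(cohort, function(img) {
    img$pred <- annotate_uncertainty(img$pred, img$map)
    img
  })
  rows <- list()
  for (th in thresholds) {
    matches <- lapply(annotated, function(img) {
      keep <- img$pred
      keep$lesions <- Filter(function(l) l$t_uncertain <= th, keep$lesions)
      match_lesions(keep, img$gt, dsc_threshold)
    })
    counts <- pool_match_counts(matches)
    for (i in seq_len(nrow(counts))) {
      gt_n <- counts$tp[i] + counts$fn[i]
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = th, class = counts$class[i],
        tp = counts$tp[i], fp = counts$fp[i], fn = counts$fn[i],
        fpi = counts$fp[i] / n_img,
        tpr = if (gt_n > 0) counts$tp[i] / gt_n else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_images") <- n_img
  out
}
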