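# Cohort segmentation metrics: Dice, aggregated Dice, detection sensitivity
# and false positives per image.

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`. When both masks are empty the per-image value
#' is defined as 1 (perfect agreement); such images contribute nothing to the
#' aggregated-Dice accumulators.
#'
#' @param pred,gt binary (logical or 0/1) arrays of identical shape.
#' @return scalar DSC in [0, 1].
#' @export
dice <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stopf("mask shapes differ")
  p <- as.logical(pred)
  g <- as.logical(gt)
  denom <- sum(p) + sum(g)
  if (denom == 0) return(1)
  2 * sum(p & g) / denom
}

#' Aggregated Dice over a cohort
#'
#' Intersections and mask sizes are accumulated over all images before
#' dividing: `2 * sum_i |P_i n G_i| / sum_i (|P_i| + |G_i|)`. Unlike the mean
#' of per-image Dice, large lesions weigh more and empty images are inert.
#'
#' @param pred_list,gt_list lists of binary arrays, one pair per image.
#' @return scalar aggregated DSC.
#' @export
aggregated_dice <- function(pred_list, gt_list) {
  if (length(pred_list) == 0L) stopf("cohort is empty")
  if (length(pred_list) != length(gt_list)) stopf("cohort lists differ in length")
  inter <- 0; denom <- 0
  for (i in seq_along(pred_list)) {
    p <- as.logical(pred_list[[i]])
    g <- as.logical(gt_list[[i]])
    if (!identical(dim(pred_list[[i]]), dim(gt_list[[i]]))) {
      stopf("mask shapes differ for image %d", i)
    }
    inter <- inter + sum(p & g)
    denom <- denom + sum(p) + sum(g)
  }
  if (denom == 0) stopf("aggregated Dice undefined: all masks empty")
  2 * inter / denom
}

#' Lesion detection sensitivity from a match result
#'
#' `TP / (TP + FN)` per class, from a [match_lesions()] result or a list of
#' them (counts are pooled before dividing).
#'
#' @param match a `lesion_match` or list of `lesion_match` objects.
#' @param class optional class name; default reports every class present.
#' @return named numeric vector of sensitivities per class.
#' @export
detection_sensitivity <- function(match, class = NULL) {
  counts <- pool_match_counts(match)
  if (!is.null(class)) counts <- counts[counts$class %in% class, , drop = FALSE]
  if (nrow(counts) == 0L) stopf("no matching classes")
  denom <- counts$tp + counts$fn
  if (any(denom == 0)) {
    stopf("sensitivity undefined for class(es) with no ground-truth lesions: %s",
          paste(counts$class[denom == 0], collapse = ", "))
  }
  setNames(counts$tp / denom, counts$class)
}

#' False positives per image
#'
#' Total false-positive predicted lesions across the cohort divided by the
#' number of images, per class.
#'
#' @param match a `lesion_match` or list of them (one per image).
#' @param n_images number of images in the cohort; defaults to the number of
#'   match results supplied.
#' @return named numeric vector of FPI per class.
#' @export
false_positives_per_image <- function(match, n_images = NULL) {
  if (inherits(match, "lesion_match")) match <- list(match)
  n_images <- n_images %||% length(match)
  assert_scalar_num(n_images, "n_images", lower = 1)
  counts <- pool_match_counts(match)
  setNames(counts$fp / n_images, counts$class)
}

pool_match_counts <- function(match) {
  if (inherits(match, "lesion_match")) match <- list(match)
  stopifnot(length(match) > 0L, all(vapply(match, inherits, TRUE, "lesion_match")))
  tab <- do.call(rbind, lapply(match, function(m) m$counts))
  agg <- aggregate(tab[c("tp", "fp", "fn")], by = list(class = tab$class), FUN = sum)
  agg[order(agg$class), , drop = FALSE]
}
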