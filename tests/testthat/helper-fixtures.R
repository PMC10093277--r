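# Shared fixture builders and independent brute-force oracles. Oracles are
# deliberately naive (nested loops, direct enumeration) and never reuse the
# package's vectorised implementations.

# a binary cube lesion painted into a fresh mask
paint_box <- function(mask, lo, hi, value = 1L) {
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- as.integer(value)
  mask
}

empty_mask <- function(d = c(12L, 12L, 12L), spacing = c(1, 1, 1)) {
  m <- array(0L, dim = d)
  voxel_spacing(m) <- spacing
  m
}

# naive voxel-counting Dice
oracle_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] != 0) na <- na + 1
    if (b[i] != 0) nb <- nb + 1
    if (a[i] != 0 && b[i] != 0) inter <- inter + 1
  }
  if (na + nb == 0) return(1)
  2 * inter / (na + nb)
}

# naive aggregated Dice accumulation
oracle_aggregated_dice <- function(preds, gts) {
  inter <- 0; denom <- 0
  for (i in seq_along(preds)) {
    for (v in seq_along(preds[[i]])) {
      p <- preds[[i]][v] != 0
      g <- gts[[i]][v] != 0
      if (p && g) inter <- inter + 1
      if (p) denom <- denom + 1
      if (g) denom <- denom + 1
    }
  }
  2 * inter / denom
}

# naive all-pairs Harrell C with tie credit 1/2
oracle_harrell_c <- function(risk, time, event) {
  conc <- 0; comp <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    # i must be an event and observed strictly shorter, or equal time with j censored
    comparable <- event[i] == 1 &&
      (time[i] < time[j] || (time[i] == time[j] && event[j] == 0))
    if (!comparable) next
    comp <- comp + 1
    if (risk[i] > risk[j]) conc <- conc + 1
    else if (risk[i] == risk[j]) conc <- conc + 0.5
  }
  if (comp == 0) return(NA_real_)
  conc / comp
}

# brute-force per-class lesion TP/FP/FN by enumerating all pairwise DSCs
# between connected components (components found by repeated neighbour
# expansion, independent of the package's flood fill)
oracle_components <- function(mask, class_value, connectivity = 26L) {
  d <- dim(mask)
  idx <- which(mask == class_value)
  comps <- list()
  remaining <- idx
  while (length(remaining)) {
    comp <- remaining[1]
    frontier <- comp
    remaining <- remaining[-1]
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nbrs <- integer(0)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        manh <- abs(dx) + abs(dy) + abs(dz)
        if (connectivity == 6 && manh > 1) next
        cc <- cbind(co[, 1] + dx, co[, 2] + dy, co[, 3] + dz)
        ok <- cc[, 1] >= 1 & cc[, 1] <= d[1] & cc[, 2] >= 1 & cc[, 2] <= d[2] &
          cc[, 3] >= 1 & cc[, 3] <= d[3]
        cc <- cc[ok, , drop = FALSE]
        nbrs <- c(nbrs, cc[, 1] + d[1] * (cc[, 2] - 1) + d[1] * d[2] * (cc[, 3] - 1))
      }
      frontier <- intersect(unique(nbrs), remaining)
      comp <- c(comp, frontier)
      remaining <- setdiff(remaining, frontier)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

oracle_match_counts <- function(pred_mask, gt_mask, dsc_threshold = 0.1) {
  out <- data.frame(class = c("GTVp", "GTVn"), tp = 0L, fp = 0L, fn = 0L)
  for (ci in 1:2) {
    p_comps <- oracle_components(pred_mask, ci)
    g_comps <- oracle_components(gt_mask, ci)
    g_hit <- rep(FALSE, length(g_comps))
    p_hit <- rep(FALSE, length(p_comps))
    for (gi in seq_along(g_comps)) for (pi in seq_along(p_comps)) {
      inter <- length(intersect(g_comps[[gi]], p_comps[[pi]]))
      dsc <- 2 * inter / (length(g_comps[[gi]]) + length(p_comps[[pi]]))
      if (dsc > dsc_threshold) {
        g_hit[gi] <- TRUE
        p_hit[pi] <- TRUE
      }
    }
    out$tp[ci] <- sum(g_hit)
    out$fn[ci] <- sum(!g_hit)
    out$fp[ci] <- sum(!p_hit)
  }
  out
}

# random small label mask with a few blobs
random_mask <- function(d = c(12L, 12L, 12L), n_blobs = 3L, seed = 1L) {
  set.seed(seed)
  m <- empty_mask(d)
  for (b in seq_len(n_blobs)) {
    lo <- sapply(d, function(n) sample.int(n - 3L, 1))
    sz <- sample(1:3, 3, replace = TRUE)
    m <- paint_box(m, lo, pmin(lo + sz, d), sample(1:2, 1))
  }
  m
}

# simulated cohort for the operating-curve machinery
make_uq_cohort <- function(n_images, seed, fp_fraction = 0.4,
                           grid = c(32L, 32L, 32L)) {
  lapply(seq_len(n_images), function(i) {
    ph <- generate_phantom(phantom_config(
      grid_shape = grid, spacing = c(1, 1, 1), n_tumours = 1L, n_nodes = 1L,
      lesion_volume_range = c(150, 900), plant_brain = FALSE,
      seed = seed * 1000L + i))
    ens <- simulate_ensemble(ph$mask, ensemble_config(
      n_members = 30L, boundary_jitter = 1L,
      fp_blobs = list(list(class = "GTVp", volume = 250,
                           member_fraction = fp_fraction),
                      list(class = "GTVn", volume = 250,
                           member_fraction = fp_fraction)),
      seed = seed * 2000L + i))
    pred_mask <- ensemble_prediction_mask(ens)
    list(phantom = ph, ensemble = ens,
         pred = extract_lesions(pred_mask),
         gt = extract_lesions(ph$mask),
         map = uncertainty_map(ens))
  })
}
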