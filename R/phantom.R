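# Synthetic PET/CT phantoms: multi-lesion label masks with a bright
# brain-like anchor, intensity models per modality, checkpoint-ensemble
# disagreement simulation, and proportional-hazards survival cohorts.

#' Phantom configuration
#'
#' Describes a synthetic head-and-neck PET/CT scene: a bright high-uptake
#' "brain" ellipsoid near the top of the axial stack (the anchor the crop
#' locator expects), plus ellipsoidal primary-tumour (GTVp) and lymph-node
#' (GTVn) lesions placed below it without touching. CT is in
#' Hounsfield-like arbitrary units, PET in nonnegative uptake-like units;
#' tumours and nodes get different PET contrast so the two classes are
#' separable by a segmentation model.
#'
#' @param grid_shape integer length-3 voxel grid (default c(48, 48, 48)).
#' @param spacing mm per axis (default c(1, 1, 3)).
#' @param n_tumours,n_nodes lesion counts per class.
#' @param lesion_volume_range mm3 interval for individual lesion volumes.
#' @param intensity list of intensity-model parameters; see Details.
#' @param plant_brain logical; add the bright top-of-stack anchor.
#' @param seed integer seed; identical config + seed gives identical output.
#' @details The intensity model defaults: CT background 40, lesion contrast
#'   +60, noise sd 10; PET background 0.5, tumour uptake 6, node uptake 4,
#'   brain uptake 8, noise sd 0.3 (values chosen once as plausible
#'   soft-tissue/FDG levels, see the vignette).
#' @return a `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L),
                           spacing = c(1, 1, 3),
                           n_tumours = 1L, n_nodes = 2L,
                           lesion_volume_range = c(400, 4000),
                           intensity = list(), plant_brain = TRUE,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            length(spacing) == 3L, all(spacing > 0),
            n_tumours >= 0, n_nodes >= 0,
            length(lesion_volume_range) == 2L,
            lesion_volume_range[1] > 0,
            lesion_volume_range[1] <= lesion_volume_range[2])
  if (lesion_volume_range[2] > prod(grid_shape * spacing)) {
    stopf("lesion_volume_range exceeds grid capacity")
  }
  defaults <- list(ct_background = 40, ct_contrast = 60, ct_noise_sd = 10,
                   pet_background = 0.5, pet_tumour = 6, pet_node = 4,
                   pet_brain = 8, pet_noise_sd = 0.3)
  intensity <- utils::modifyList(defaults, intensity)
  structure(
    list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         n_tumours = as.integer(n_tumours), n_nodes = as.integer(n_nodes),
         lesion_volume_range = as.numeric(lesion_volume_range),
         intensity = intensity, plant_brain = isTRUE(plant_brain),
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Voxel indices of an ellipsoid of given volume (mm3) centred at `centre`
# (voxel coords), with mild random anisotropy. Returns integer linear indices.
ellipsoid_voxels <- function(centre, volume_mm3, dim, spacing,
                             anisotropy = runif(3, 0.7, 1.4)) {
  # semi-axes in mm: scale the anisotropy profile to the requested volume
  a <- anisotropy / prod(anisotropy)^(1 / 3)
  r <- a * (3 * volume_mm3 / (4 * pi))^(1 / 3)
  half <- ceiling(r / spacing) + 1L
  lo <- pmax(1L, floor(centre - half))
  hi <- pmin(dim, ceiling(centre + half))
  if (any(lo > hi)) return(integer(0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- ((xs - centre[1]) * spacing[1] / r[1])^2
  gy <- ((ys - centre[2]) * spacing[2] / r[2])^2
  gz <- ((zs - centre[3]) * spacing[3] / r[3])^2
  inside <- outer(outer(gx, gy, `+`), gz, `+`) <= 1
  idx <- which(inside)
  coords <- arrayInd(idx, dim(inside))
  coords[, 1] <- coords[, 1] + lo[1] - 1L
  coords[, 2] <- coords[, 2] + lo[2] - 1L
  coords[, 3] <- coords[, 3] + lo[3] - 1L
  as.integer(coords[, 1] + dim[1] * (coords[, 2] - 1L) +
               dim[1] * dim[2] * (coords[, 3] - 1L))
}

# 6-connected binary dilation of a voxel index set, it iterations.
dilate_indices <- function(idx, dim, it = 1L) {
  if (it <= 0L || length(idx) == 0L) return(idx)
  nxy <- dim[1] * dim[2]
  for (i in seq_len(it)) {
    coords <- arrayInd(idx, dim)
    nb <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
               c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
    all_idx <- idx
    for (o in nb) {
      cc <- sweep(coords, 2, o, `+`)
      keep <- cc[, 1] >= 1 & cc[, 1] <= dim[1] &
        cc[, 2] >= 1 & cc[, 2] <= dim[2] &
        cc[, 3] >= 1 & cc[, 3] <= dim[3]
      cc <- cc[keep, , drop = FALSE]
      all_idx <- c(all_idx, cc[, 1] + dim[1] * (cc[, 2] - 1L) + nxy * (cc[, 3] - 1L))
    }
    idx <- unique(all_idx)
  }
  idx
}

# 6-connected erosion: keep voxels whose full 6-neighbourhood is in the set.
erode_indices <- function(idx, dim, it = 1L) {
  if (it <= 0L || length(idx) == 0L) return(idx)
  nxy <- dim[1] * dim[2]
  for (i in seq_len(it)) {
    inset <- logical(prod(dim))
    inset[idx] <- TRUE
    coords <- arrayInd(idx, dim)
    keep <- rep(TRUE, length(idx))
    nb <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
               c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
    for (o in nb) {
      cc <- sweep(coords, 2, o, `+`)
      inb <- cc[, 1] >= 1 & cc[, 1] <= dim[1] &
        cc[, 2] >= 1 & cc[, 2] <= dim[2] &
        cc[, 3] >= 1 & cc[, 3] <= dim[3]
      ok <- inb
      ok[inb] <- inset[cc[inb, 1] + dim[1] * (cc[inb, 2] - 1L) + nxy * (cc[inb, 3] - 1L)]
      keep <- keep & ok
    }
    idx <- idx[keep]
  }
  idx
}

#' Generate a synthetic PET/CT phantom
#'
#' Places the requested number of non-touching ellipsoidal lesions per class
#' (plus the optional bright brain anchor at the top of the stack), then
#' renders CT and PET volumes under the configured contrast + Gaussian noise
#' model.
#'
#' @param config a [phantom_config()].
#' @return list with `ct`, `pet` (3D arrays with spacing attributes), `mask`
#'   (integer labels 0/1/2), and `catalog` (data frame: id, class, centroid,
#'   voxel count, volume in mm3).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    d <- config$grid_shape
    sp <- config$spacing
    vv <- prod(sp)
    mask <- array(0L, dim = d)
    occupied <- integer(0)  # lesion voxels dilated by 1: enforce non-touching

    brain_idx <- integer(0)
    if (config$plant_brain) {
      centre <- c(d[1] / 2 + runif(1, -2, 2), d[2] / 2 + runif(1, -2, 2),
                  d[3] - 3)
      brain_vol <- min(0.08 * prod(d * sp), 60000)
      brain_idx <- ellipsoid_voxels(centre, brain_vol, d, sp,
                                    anisotropy = c(1, 1, 0.8))
      occupied <- dilate_indices(brain_idx, d, 1L)
    }

    specs <- c(rep("GTVp", config$n_tumours), rep("GTVn", config$n_nodes))
    catalog <- list()
    z_hi <- if (config$plant_brain) max(1, floor(d[3] * 0.7)) else d[3] - 2
    for (si in seq_along(specs)) {
      cls <- specs[si]
      placed <- FALSE
      for (try in seq_len(200L)) {
        vol <- runif(1, config$lesion_volume_range[1],
                     config$lesion_volume_range[2])
        centre <- c(runif(1, 4, d[1] - 3), runif(1, 4, d[2] - 3),
                    runif(1, 3, z_hi))
        idx <- ellipsoid_voxels(centre, vol, d, sp)
        if (length(idx) < 4L) next
        if (any(idx %in% occupied)) next
        mask[idx] <- LESION_CLASSES[[cls]]
        occupied <- c(occupied, dilate_indices(idx, d, 1L))
        coords <- arrayInd(idx, d)
        catalog[[length(catalog) + 1L]] <- data.frame(
          id = sprintf("%s_%02d", cls, si), class = cls,
          cx = mean(coords[, 1]), cy = mean(coords[, 2]), cz = mean(coords[, 3]),
          n_voxels = length(idx), volume_mm3 = length(idx) * vv)
        placed <- TRUE
        break
      }
      if (!placed) {
        stopf("could not place %s lesion %d without overlap after 200 tries",
              cls, si)
      }
    }
    catalog <- if (length(catalog)) do.call(rbind, catalog) else
      data.frame(id = character(), class = character(), cx = numeric(),
                 cy = numeric(), cz = numeric(), n_voxels = integer(),
                 volume_mm3 = numeric())

    iy <- config$intensity
    ct <- array(rnorm(prod(d), iy$ct_background, iy$ct_noise_sd), dim = d)
    pet <- array(rnorm(prod(d), iy$pet_background, iy$pet_noise_sd), dim = d)
    lesion_idx <- which(mask > 0L)
    ct[lesion_idx] <- ct[lesion_idx] + iy$ct_contrast
    pet[mask == 1L] <- iy$pet_tumour + rnorm(sum(mask == 1L), 0, iy$pet_noise_sd)
    pet[mask == 2L] <- iy$pet_node + rnorm(sum(mask == 2L), 0, iy$pet_noise_sd)
    if (length(brain_idx)) {
      ct[brain_idx] <- ct[brain_idx] + iy$ct_contrast
      pet[brain_idx] <- iy$pet_brain + rnorm(length(brain_idx), 0, iy$pet_noise_sd)
    }
    pet[pet < 0] <- 0
    voxel_spacing(ct) <- sp
    voxel_spacing(pet) <- sp
    voxel_spacing(mask) <- sp
    list(ct = ct, pet = pet, mask = mask, catalog = catalog,
         brain_voxels = brain_idx)
  })
}

#' Ensemble-disagreement configuration
#'
#' @param n_members checkpoint count (default 30).
#' @param boundary_jitter maximum voxels of random dilation/erosion applied
#'   per member to each true lesion (default 1).
#' @param fp_blobs list of false-positive blob specs, each a list with
#'   `class` ("GTVp"/"GTVn"), `volume` (mm3) and `member_fraction` in (0, 1].
#' @param seed integer seed.
#' @return an `ensemble_config`.
#' @export
ensemble_config <- function(n_members = 30L, boundary_jitter = 1L,
                            fp_blobs = list(), seed = 1L) {
  stopifnot(n_members >= 2, boundary_jitter >= 0)
  for (b in fp_blobs) {
    stopifnot(b$class %in% names(LESION_CLASSES), b$volume > 0,
              b$member_fraction > 0, b$member_fraction <= 1)
  }
  structure(list(n_members = as.integer(n_members),
                 boundary_jitter = as.integer(boundary_jitter),
                 fp_blobs = fp_blobs, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Simulate a checkpoint ensemble's predictions on a phantom
#'
#' Emulates the disagreement structure of a 30-checkpoint posterior sample:
#' every true lesion appears in all members with its boundary independently
#' dilated or eroded by up to `boundary_jitter` voxels per member, while each
#' false-positive blob appears in exactly `round(member_fraction * n_members)`
#' members chosen uniformly without replacement. Members are one-hot
#' per-class probability maps (summing to 1 at every voxel).
#'
#' @param mask ground-truth label mask (classes 0/1/2).
#' @param config an [ensemble_config()].
#' @return an `ensemble_prediction` (5D probability array x,y,z,class,member).
#' @export
simulate_ensemble <- function(mask, config) {
  assert_mask(mask)
  stopifnot(inherits(config, "ensemble_config"))
  d <- dim(mask)
  sp <- voxel_spacing(mask)
  n <- config$n_members
  with_seed(config$seed, {
    gt <- extract_lesions(mask)
    true_idx <- which(mask > 0L)

    # place fp blobs away from true lesions
    blobs <- list()
    for (b in config$fp_blobs) {
      placed <- FALSE
      forbidden <- dilate_indices(true_idx, d, 1L)
      for (try in seq_len(200L)) {
        centre <- c(runif(1, 4, d[1] - 3), runif(1, 4, d[2] - 3),
                    runif(1, 3, d[3] - 2))
        idx <- ellipsoid_voxels(centre, b$volume, d, sp)
        if (length(idx) < 2L) next
        if (any(idx %in% forbidden)) next
        members_in <- sort(sample.int(n, round(b$member_fraction * n)))
        blobs[[length(blobs) + 1L]] <- list(class = b$class, voxels = idx,
                                            members = members_in)
        forbidden <- c(forbidden, dilate_indices(idx, d, 1L))
        placed <- TRUE
        break
      }
      if (!placed) stopf("fp blob collides with existing structures")
    }

    prob <- array(0, dim = c(d, 3L, n))
    for (m in seq_len(n)) {
      mm <- array(0L, dim = d)
      for (l in gt$lesions) {
        vox <- l$voxels
        if (config$boundary_jitter > 0L) {
          r <- sample.int(2L * config$boundary_jitter + 1L, 1L) -
            config$boundary_jitter - 1L
          jit <- if (r > 0) dilate_indices(vox, d, r)
                 else if (r < 0) erode_indices(vox, d, -r)
                 else vox
          if (length(jit) == 0L) jit <- vox  # lesions never vanish entirely
          vox <- jit
        }
        mm[vox] <- LESION_CLASSES[[l$class]]
      }
      for (bl in blobs) {
        if (m %in% bl$members) mm[bl$voxels] <- LESION_CLASSES[[bl$class]]
      }
      for (k in 0:2) prob[, , , k + 1L, m] <- as.numeric(mm == k)
    }
    ens <- new_ensemble_prediction(
      prob, classes = c("background", "GTVp", "GTVn"),
      provenance = data.frame(member = seq_len(n)), spacing = sp)
    attr(ens, "fp_blobs") <- blobs
    ens
  })
}

#' Survival-cohort configuration
#'
#' @param n_patients cohort size (default 500).
#' @param n_noise_features count of standard-normal features independent of
#'   outcome (default 100).
#' @param informative_features named numeric vector of log-hazard
#'   coefficients for planted standard-normal features.
#' @param baseline_rate exponential baseline hazard per day (default 1/1000).
#' @param censoring_rate expected fraction censored, in [0, 1) (default 0.3).
#' @param seed integer seed.
#' @return a `survival_cohort_config`.
#' @export
survival_cohort_config <- function(n_patients = 500L, n_noise_features = 100L,
                                   informative_features = c(planted_1 = 1.0,
                                                            planted_2 = 0.8,
                                                            planted_3 = 0.6),
                                   baseline_rate = 1e-3,
                                   censoring_rate = 0.3, seed = 1L) {
  stopifnot(n_patients >= 2, n_noise_features >= 0,
            all(is.finite(informative_features)),
            baseline_rate > 0,
            censoring_rate >= 0, censoring_rate < 1)
  structure(list(n_patients = as.integer(n_patients),
                 n_noise_features = as.integer(n_noise_features),
                 informative_features = informative_features,
                 baseline_rate = baseline_rate,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "survival_cohort_config")
}

#' Generate a synthetic survival cohort with planted feature-hazard links
#'
#' Event times are drawn from an exponential proportional-hazards model,
#' `T ~ Exp(baseline_rate * exp(sum(beta * x)))`; censoring uses independent
#' uniform administrative times whose horizon is calibrated so the expected
#' censored fraction matches `censoring_rate`. Clinical covariates (gender,
#' age, weight, chemotherapy, tobacco, alcohol, surgery, HPV, performance
#' status) follow realistic head-and-neck cohort frequencies, including NA
#' categories, and are independent of outcome.
#'
#' @param config a [survival_cohort_config()].
#' @return list with `features` (data frame: patient_id, planted + noise +
#'   clinical columns) and `survival` (data frame: patient_id, time in days,
#'   event flag).
#' @export
generate_survival_cohort <- function(config) {
  stopifnot(inherits(config, "survival_cohort_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    beta <- config$informative_features
    X <- matrix(rnorm(n * length(beta)), n, length(beta),
                dimnames = list(NULL, names(beta)))
    noise <- matrix(rnorm(n * config$n_noise_features), n,
                    config$n_noise_features)
    if (config$n_noise_features > 0) {
      colnames(noise) <- sprintf("noise_%03d", seq_len(config$n_noise_features))
    }
    lp <- if (length(beta)) drop(X %*% beta) else rep(0, n)
    hazard <- config$baseline_rate * exp(lp)
    t_event <- rexp(n, rate = hazard)

    if (config$censoring_rate > 0) {
      # uniform administrative censoring C ~ U(0, cmax);
      # P(censored_i | T_i) = min(T_i / cmax, 1); calibrate cmax.
      f <- function(log_cmax) {
        mean(pmin(t_event / exp(log_cmax), 1)) - config$censoring_rate
      }
      log_cmax <- tryCatch(
        stats::uniroot(f, lower = log(min(t_event) / 2),
                       upper = log(max(t_event) * 1e4))$root,
        error = function(e) log(stats::quantile(t_event, 0.9)))
      cens <- runif(n, 0, exp(log_cmax))
      event <- as.integer(t_event <= cens)
      time <- pmin(t_event, cens)
    } else {
      event <- rep(1L, n)
      time <- t_event
    }

    gender <- sample(c("M", "F"), n, TRUE, prob = c(0.82, 0.18))
    chemo <- sample(c("yes", "no"), n, TRUE, prob = c(0.87, 0.13))
    tobacco <- sample(c("yes", "no", "NA"), n, TRUE, prob = c(0.21, 0.21, 0.58))
    alcohol <- sample(c("yes", "no", "NA"), n, TRUE, prob = c(0.21, 0.13, 0.66))
    surgery <- sample(c("yes", "no", "NA"), n, TRUE, prob = c(0.1, 0.49, 0.41))
    hpv <- sample(c("positive", "negative", "NA"), n, TRUE,
                  prob = c(0.53, 0.12, 0.35))
    perf <- sample(c("0", "1", "2", "3", "4", "NA"), n, TRUE,
                   prob = c(0.17, 0.26, 0.02, 0.006, 0.004, 0.54))
    features <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                           X, noise,
                           gender = gender,
                           age = round(rnorm(n, 60, 9), 1),
                           weight = round(rnorm(n, 80, 15), 1),
                           chemotherapy = chemo, tobacco = tobacco,
                           alcohol = alcohol, surgery = surgery,
                           hpv = hpv, performance = perf,
                           check.names = FALSE)
    survival <- data.frame(patient_id = features$patient_id,
                           time = time, event = event)
    list(features = features, survival = survival)
  })
}
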