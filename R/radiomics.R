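# IBSI-style radiomics extractor: the standard 107-feature default set
# (18 first-order, 14 shape, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM).
# Shape mesh quantities use voxel-based approximations; texture matrices use
# merged-direction aggregation (see the methods vignette).

#' Discretise ROI intensities with a fixed bin width
#'
#' Level of voxel v is `floor(x_v / w) - floor(min(x) / w) + 1`.
#'
#' @param x numeric intensities inside the ROI.
#' @param bin_width positive bin width.
#' @return integer levels starting at 1; attribute `n_levels`.
#' @export
discretize_intensities <- function(x, bin_width) {
  assert_scalar_num(bin_width, "bin_width", lower = 1e-12)
  lv <- as.integer(floor(x / bin_width) - floor(min(x) / bin_width) + 1)
  attr(lv, "n_levels") <- max(lv)
  lv
}

firstorder_features <- function(x, voxel_vol, bin_width) {
  n <- length(x)
  lv <- discretize_intensities(x, bin_width)
  p <- tabulate(lv) / n
  p <- p[p > 0]
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  robust <- x[x >= q[1] & x <= q[5]]
  c(
    firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = voxel_vol * sum(x^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Minimum = min(x),
    firstorder_10Percentile = q[1],
    firstorder_90Percentile = q[5],
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = q[3],
    firstorder_InterquartileRange = q[4] - q[2],
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    firstorder_Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2)
  )
}

shape_features <- function(roi, spacing) {
  d <- dim(roi)
  idx <- which(roi)
  nv <- length(idx)
  vv <- prod(spacing)
  vol <- nv * vv
  coords <- arrayInd(idx, d)

  # surface area: exposed faces (neighbour outside ROI or out of bounds)
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  inset <- array(FALSE, dim = d)
  inset[idx] <- TRUE
  sa <- 0
  shifts <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                 c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  exposed <- rep(FALSE, nv)
  for (k in seq_along(shifts)) {
    o <- shifts[[k]]
    cc <- sweep(coords, 2, o, `+`)
    inb <- cc[, 1] >= 1 & cc[, 1] <= d[1] & cc[, 2] >= 1 & cc[, 2] <= d[2] &
      cc[, 3] >= 1 & cc[, 3] <= d[3]
    nb_in <- inb
    nb_in[inb] <- inset[cc[inb, , drop = FALSE]]
    n_exposed <- sum(!nb_in)
    sa <- sa + n_exposed * face_area[ceiling(k / 2)]
    exposed <- exposed | !nb_in
  }

  # physical coordinates for PCA axes and diameters
  phys <- sweep(coords, 2, spacing, `*`)
  surf <- phys[exposed, , drop = FALSE]
  if (nrow(surf) > 2000L) {
    surf <- surf[seq(1, nrow(surf), length.out = 2000L), , drop = FALSE]
  }
  # in-plane max diameters: slice (xy), column (xz), row (yz); the grouping
  # coordinates use the same subsampling as `surf` so rows stay aligned
  exp_coords <- coords[exposed, , drop = FALSE]
  if (nrow(exp_coords) > 2000L) {
    exp_coords <- exp_coords[seq(1, nrow(exp_coords), length.out = 2000L), ,
                             drop = FALSE]
  }
  plane_diam <- function(fix_axis, cols) {
    groups <- split(seq_len(nrow(surf)), exp_coords[, fix_axis])
    m <- 0
    for (g in groups) {
      if (length(g) >= 2L) {
        m <- max(m, max(stats::dist(surf[g, cols, drop = FALSE])))
      }
    }
    m
  }

  cen <- colMeans(phys)
  cv <- crossprod(sweep(phys, 2, cen)) / nrow(phys)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0

  c(
    shape_MeshVolume = vol,
    shape_VoxelVolume = vol,
    shape_SurfaceArea = sa,
    shape_SurfaceVolumeRatio = sa / vol,
    shape_Sphericity = (36 * pi * vol^2)^(1 / 3) / sa,
    shape_Maximum3DDiameter = if (nrow(surf) >= 2) max(stats::dist(surf)) else 0,
    shape_Maximum2DDiameterSlice = plane_diam(3L, 1:2),
    shape_Maximum2DDiameterColumn = plane_diam(2L, c(1L, 3L)),
    shape_Maximum2DDiameterRow = plane_diam(1L, 2:3),
    shape_MajorAxisLength = 4 * sqrt(ev[1]),
    shape_MinorAxisLength = 4 * sqrt(ev[2]),
    shape_LeastAxisLength = 4 * sqrt(ev[3]),
    shape_Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    shape_Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
}

glcm_features <- function(grid, ng) {
  M <- glcm_3d(grid, ng)
  if (sum(M) == 0) M <- matrix(1, 1, 1)  # single isolated voxel
  P <- M / sum(M)
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  k_sum <- 2:(2 * ng)
  pxy_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), 0)
  k_diff <- 0:(ng - 1)
  pxy_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), 0)
  da <- sum(k_diff * pxy_diff)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HX <- ent(px); HY <- ent(py); HXY <- ent(as.vector(P))
  pxpy <- outer(px, py)
  pos <- P > 0 & pxpy > 0
  HXY1 <- -sum(P[pos] * log2(pxpy[pos]))
  HXY2 <- ent(as.vector(pxpy))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  corr <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 1
  mcc <- if (ng > 1) {
    Q <- matrix(0, ng, ng)
    for (a in seq_len(ng)) for (b in seq_len(ng)) {
      Q[a, b] <- sum(ifelse(px[a] > 0 & py > 0,
                            P[a, ] * P[b, ] / (px[a] * py), 0))
    }
    eg <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(eg) > 1 && eg[2] > 0) sqrt(eg[2]) else 0
  } else 1
  c(
    glcm_Autocorrelation = sum(i * j * P),
    glcm_ClusterProminence = sum((i + j - mux - muy)^4 * P),
    glcm_ClusterShade = sum((i + j - mux - muy)^3 * P),
    glcm_ClusterTendency = sum((i + j - mux - muy)^2 * P),
    glcm_Contrast = sum((i - j)^2 * P),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = ent(pxy_diff),
    glcm_DifferenceVariance = sum((k_diff - da)^2 * pxy_diff),
    glcm_Id = sum(P / (1 + abs(i - j))),
    glcm_Idm = sum(P / (1 + (i - j)^2)),
    glcm_Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    glcm_Idn = sum(P / (1 + abs(i - j) / ng)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    glcm_JointAverage = mux,
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = HXY,
    glcm_MCC = mcc,
    glcm_MaximumProbability = max(P),
    glcm_SumAverage = sum(k_sum * pxy_sum),
    glcm_SumEntropy = ent(pxy_sum),
    glcm_SumSquares = sum(((i - mux))^2 * P)
  )
}

# shared machinery for the run-length / size-zone families
rl_family <- function(P, n_voxels, prefix, size_name, gl_name) {
  Nr <- sum(P)
  if (Nr == 0) P <- matrix(1, 1, 1)
  Nr <- sum(P)
  i <- row(P); l <- col(P)
  p <- P / Nr
  mu_g <- sum(i * p); mu_s <- sum(l * p)
  ent_p <- { q <- p[p > 0]; -sum(q * log2(q)) }
  vals <- c(
    sum(p / l^2),                          # small emphasis
    sum(p * l^2),                          # large emphasis
    sum(rowSums(P)^2) / Nr,                # gray-level non-uniformity
    sum(rowSums(P)^2) / Nr^2,              # normalized
    sum(colSums(P)^2) / Nr,                # size non-uniformity
    sum(colSums(P)^2) / Nr^2,              # normalized
    Nr / n_voxels,                         # percentage
    sum((i - mu_g)^2 * p),                 # gray-level variance
    sum((l - mu_s)^2 * p),                 # size variance
    ent_p,                                 # entropy
    sum(p / i^2),                          # low gray-level emphasis
    sum(p * i^2),                          # high gray-level emphasis
    sum(p / (i^2 * l^2)),                  # small + low
    sum(p * i^2 / l^2),                    # small + high
    sum(p * l^2 / i^2),                    # large + low
    sum(p * i^2 * l^2)                     # large + high
  )
  names(vals) <- paste0(prefix, c(
    paste0("Short", size_name, "Emphasis"),
    paste0("Long", size_name, "Emphasis"),
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    paste0(size_name, "LengthNonUniformity"),
    paste0(size_name, "LengthNonUniformityNormalized"),
    paste0(size_name, "Percentage"),
    "GrayLevelVariance",
    paste0(size_name, "Variance"),
    paste0(size_name, "Entropy"),
    paste0("Low", gl_name, "Emphasis"),
    paste0("High", gl_name, "Emphasis"),
    paste0("Short", size_name, "Low", gl_name, "Emphasis"),
    paste0("Short", size_name, "High", gl_name, "Emphasis"),
    paste0("Long", size_name, "Low", gl_name, "Emphasis"),
    paste0("Long", size_name, "High", gl_name, "Emphasis")))
  vals
}

glrlm_features <- function(grid, ng, n_voxels) {
  P <- glrlm_3d(grid, ng)
  v <- rl_family(P, n_voxels, "glrlm_", "Run", "GrayLevelRun")
  names(v) <- c("glrlm_ShortRunEmphasis", "glrlm_LongRunEmphasis",
                "glrlm_GrayLevelNonUniformity",
                "glrlm_GrayLevelNonUniformityNormalized",
                "glrlm_RunLengthNonUniformity",
                "glrlm_RunLengthNonUniformityNormalized",
                "glrlm_RunPercentage", "glrlm_GrayLevelVariance",
                "glrlm_RunVariance", "glrlm_RunEntropy",
                "glrlm_LowGrayLevelRunEmphasis",
                "glrlm_HighGrayLevelRunEmphasis",
                "glrlm_ShortRunLowGrayLevelEmphasis",
                "glrlm_ShortRunHighGrayLevelEmphasis",
                "glrlm_LongRunLowGrayLevelEmphasis",
                "glrlm_LongRunHighGrayLevelEmphasis")
  v
}

glszm_features <- function(grid, ng, n_voxels) {
  # zones: connected components (26-conn) of constant gray level
  d <- dim(grid)
  max_zone <- n_voxels
  counts <- list()
  for (g in seq_len(ng)) {
    bin <- array(as.integer(grid == g), dim = d)
    if (!any(bin == 1L)) next
    lab <- cc_label_3d(bin, 26L)
    sizes <- tabulate(lab[lab > 0])
    counts[[length(counts) + 1L]] <- cbind(g, sizes)
  }
  if (!length(counts)) {
    P <- matrix(1, 1, 1)
  } else {
    zs <- do.call(rbind, counts)
    P <- matrix(0, ng, max(zs[, 2]))
    for (r in seq_len(nrow(zs))) P[zs[r, 1], zs[r, 2]] <- P[zs[r, 1], zs[r, 2]] + 1
  }
  v <- rl_family(P, n_voxels, "glszm_", "Area", "GrayLevelZone")
  names(v) <- c("glszm_SmallAreaEmphasis", "glszm_LargeAreaEmphasis",
                "glszm_GrayLevelNonUniformity",
                "glszm_GrayLevelNonUniformityNormalized",
                "glszm_SizeZoneNonUniformity",
                "glszm_SizeZoneNonUniformityNormalized",
                "glszm_ZonePercentage", "glszm_GrayLevelVariance",
                "glszm_ZoneVariance", "glszm_ZoneEntropy",
                "glszm_LowGrayLevelZoneEmphasis",
                "glszm_HighGrayLevelZoneEmphasis",
                "glszm_SmallAreaLowGrayLevelEmphasis",
                "glszm_SmallAreaHighGrayLevelEmphasis",
                "glszm_LargeAreaLowGrayLevelEmphasis",
                "glszm_LargeAreaHighGrayLevelEmphasis")
  v
}

gldm_features <- function(grid, ng, n_voxels) {
  P <- gldm_3d(grid, ng, 0L)
  P <- P[, colSums(P) > 0 | seq_len(ncol(P)) == 1, drop = FALSE]
  Nz <- sum(P)
  p <- P / Nz
  i <- row(p); dcol <- col(p)  # dependence size = neighbour count + 1
  mu_g <- sum(i * p); mu_d <- sum(dcol * p)
  ent_p <- { q <- p[p > 0]; -sum(q * log2(q)) }
  c(
    gldm_SmallDependenceEmphasis = sum(p / dcol^2),
    gldm_LargeDependenceEmphasis = sum(p * dcol^2),
    gldm_GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    gldm_DependenceNonUniformity = sum(colSums(P)^2) / Nz,
    gldm_DependenceNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    gldm_GrayLevelVariance = sum((i - mu_g)^2 * p),
    gldm_DependenceVariance = sum((dcol - mu_d)^2 * p),
    gldm_DependenceEntropy = ent_p,
    gldm_LowGrayLevelEmphasis = sum(p / i^2),
    gldm_HighGrayLevelEmphasis = sum(p * i^2),
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * dcol^2)),
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / dcol^2),
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(p * dcol^2 / i^2),
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * dcol^2)
  )
}

ngtdm_features <- function(grid, ng, n_voxels) {
  res <- ngtdm_3d(grid, ng)
  n_i <- res$n; s_i <- res$s
  p_i <- n_i / n_voxels
  act <- which(p_i > 0)
  ngp <- length(act)
  coarse_denom <- sum(p_i * s_i)
  contrast <- if (ngp > 1) {
    acc <- 0
    for (a in act) for (b in act) acc <- acc + p_i[a] * p_i[b] * (a - b)^2
    (acc / (ngp * (ngp - 1))) * (sum(s_i) / n_voxels)
  } else 0
  busy_denom <- 0; complexity <- 0; strength_num <- 0
  for (a in act) for (b in act) {
    busy_denom <- busy_denom + abs(a * p_i[a] - b * p_i[b])
    complexity <- complexity +
      abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
    strength_num <- strength_num + (p_i[a] + p_i[b]) * (a - b)^2
  }
  c(
    ngtdm_Busyness = if (ngp > 1 && busy_denom > 0) coarse_denom / busy_denom else 0,
    ngtdm_Coarseness = if (coarse_denom > 0) 1 / coarse_denom else 1e6,
    ngtdm_Complexity = complexity / n_voxels,
    ngtdm_Contrast = contrast,
    ngtdm_Strength = if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  )
}

#' Extract the 107-feature IBSI-style radiomics vector from an ROI
#'
#' First-order features use the raw intensities; texture families use
#' fixed-bin-width discretisation at `spec$bin_width` (25 for CT, 0.5 for
#' PET); shape features use the binary ROI and voxel spacing only.
#' Deterministic for fixed inputs.
#'
#' @param volume 3D intensity array.
#' @param roi logical 3D array (non-empty), same grid; or `NULL` for the
#'   empty-ROI signal, in which case a vector of NAs is returned.
#' @param spec a [roi_spec()] carrying the bin width and group name.
#' @return named numeric vector of length 107 (names `family_Feature`).
#' @export
extract_features <- function(volume, roi, spec) {
  stopifnot(inherits(spec, "roi_spec"))
  nm <- radiomics_feature_names()
  if (is.null(roi) || !any(roi)) {
    return(setNames(rep(NA_real_, length(nm)), nm))
  }
  stopifnot(identical(dim(volume), dim(roi)))
  sp <- voxel_spacing(volume)
  x <- volume[roi]
  n_voxels <- length(x)
  lv <- discretize_intensities(x, spec$bin_width)
  ng <- attr(lv, "n_levels")
  grid <- array(0L, dim = dim(volume))
  grid[roi] <- lv
  out <- c(
    firstorder_features(x, prod(sp), spec$bin_width),
    shape_features(roi, sp),
    glcm_features(grid, ng),
    glrlm_features(grid, ng, n_voxels),
    glszm_features(grid, ng, n_voxels),
    gldm_features(grid, ng, n_voxels),
    ngtdm_features(grid, ng, n_voxels)
  )
  stopifnot(identical(names(out), nm))
  out
}

#' Names of the 107 radiomics features, in extraction order
#' @return character vector of length 107.
#' @export
radiomics_feature_names <- function() {
  c(names(firstorder_features(c(0, 1, 2), 1, 1)),
    c("shape_MeshVolume", "shape_VoxelVolume", "shape_SurfaceArea",
      "shape_SurfaceVolumeRatio", "shape_Sphericity",
      "shape_Maximum3DDiameter", "shape_Maximum2DDiameterSlice",
      "shape_Maximum2DDiameterColumn", "shape_Maximum2DDiameterRow",
      "shape_MajorAxisLength", "shape_MinorAxisLength",
      "shape_LeastAxisLength", "shape_Elongation", "shape_Flatness"),
    c("glcm_Autocorrelation", "glcm_ClusterProminence", "glcm_ClusterShade",
      "glcm_ClusterTendency", "glcm_Contrast", "glcm_Correlation",
      "glcm_DifferenceAverage", "glcm_DifferenceEntropy",
      "glcm_DifferenceVariance", "glcm_Id", "glcm_Idm", "glcm_Idmn",
      "glcm_Idn", "glcm_Imc1", "glcm_Imc2", "glcm_InverseVariance",
      "glcm_JointAverage", "glcm_JointEnergy", "glcm_JointEntropy",
      "glcm_MCC", "glcm_MaximumProbability", "glcm_SumAverage",
      "glcm_SumEntropy", "glcm_SumSquares"),
    c("glrlm_ShortRunEmphasis", "glrlm_LongRunEmphasis",
      "glrlm_GrayLevelNonUniformity",
      "glrlm_GrayLevelNonUniformityNormalized",
      "glrlm_RunLengthNonUniformity",
      "glrlm_RunLengthNonUniformityNormalized", "glrlm_RunPercentage",
      "glrlm_GrayLevelVariance", "glrlm_RunVariance", "glrlm_RunEntropy",
      "glrlm_LowGrayLevelRunEmphasis", "glrlm_HighGrayLevelRunEmphasis",
      "glrlm_ShortRunLowGrayLevelEmphasis",
      "glrlm_ShortRunHighGrayLevelEmphasis",
      "glrlm_LongRunLowGrayLevelEmphasis",
      "glrlm_LongRunHighGrayLevelEmphasis"),
    c("glszm_SmallAreaEmphasis", "glszm_LargeAreaEmphasis",
      "glszm_GrayLevelNonUniformity",
      "glszm_GrayLevelNonUniformityNormalized",
      "glszm_SizeZoneNonUniformity",
      "glszm_SizeZoneNonUniformityNormalized", "glszm_ZonePercentage",
      "glszm_GrayLevelVariance", "glszm_ZoneVariance", "glszm_ZoneEntropy",
      "glszm_LowGrayLevelZoneEmphasis", "glszm_HighGrayLevelZoneEmphasis",
      "glszm_SmallAreaLowGrayLevelEmphasis",
      "glszm_SmallAreaHighGrayLevelEmphasis",
      "glszm_LargeAreaLowGrayLevelEmphasis",
      "glszm_LargeAreaHighGrayLevelEmphasis"),
    c("gldm_SmallDependenceEmphasis", "gldm_LargeDependenceEmphasis",
      "gldm_GrayLevelNonUniformity", "gldm_DependenceNonUniformity",
      "gldm_DependenceNonUniformityNormalized", "gldm_GrayLevelVariance",
      "gldm_DependenceVariance", "gldm_DependenceEntropy",
      "gldm_LowGrayLevelEmphasis", "gldm_HighGrayLevelEmphasis",
      "gldm_SmallDependenceLowGrayLevelEmphasis",
      "gldm_SmallDependenceHighGrayLevelEmphasis",
      "gldm_LargeDependenceLowGrayLevelEmphasis",
      "gldm_LargeDependenceHighGrayLevelEmphasis"),
    c("ngtdm_Busyness", "ngtdm_Coarseness", "ngtdm_Complexity",
      "ngtdm_Contrast", "ngtdm_Strength"))
}

#' Assemble a per-patient radiomics + volume feature table
#'
#' Runs [build_roi()] + [extract_features()] for every requested ROI spec on
#' each patient's CT/PET volumes and predicted mask, prefixes feature names
#' with the ROI group, and appends the six volume features.
#'
#' @param patients list; each element has `ct`, `pet` (3D arrays), `mask`
#'   (label mask) and optionally `patient_id`.
#' @param specs list of [roi_spec()]s (default [all_roi_specs()]).
#' @return data frame, one row per patient.
#' @export
assemble_feature_table <- function(patients, specs = all_roi_specs()) {
  rows <- lapply(seq_along(patients), function(pi) {
    p <- patients[[pi]]
    lesions <- extract_lesions(p$mask)
    feats <- list()
    for (s in specs) {
      vol <- if (s$modality == "CT") p$ct else p$pet
      roi <- build_roi(p$mask, s, lesions)
      fv <- extract_features(vol, roi, s)
      names(fv) <- paste(s$group, names(fv), sep = "_")
      feats[[s$group]] <- fv
    }
    vf <- volume_features(lesions)
    data.frame(patient_id = p$patient_id %||% sprintf("P%04d", pi),
               as.list(c(unlist(unname(feats)), vf)), check.names = FALSE)
  })
  do.call(rbind, rows)
}
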