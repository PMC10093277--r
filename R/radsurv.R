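# Multi-region multi-modal radiomics survival pipeline: ROI construction,
# volume features, Harrell's C, two-step feature selection, tertile risk
# stratification, Kaplan-Meier and the two-group log-rank test.

#' ROI specification for radiomics extraction
#'
#' The ten modality-by-region combinations (CT/PET x all, only_tumour,
#' largest_tumour, only_lymph, largest_lymph) define the feature groups; the
#' intensity-discretisation bin width is tied to the modality: 25 for CT and
#' 0.5 for PET, keeping the bin count above ~30 for reproducibility.
#'
#' @param modality "CT" or "PET".
#' @param region one of "all", "only_tumour", "largest_tumour", "only_lymph",
#'   "largest_lymph".
#' @param bin_width override for the discretisation bin width; defaults to
#'   25 (CT) or 0.5 (PET).
#' @return a `roi_spec`.
#' @export
roi_spec <- function(modality = c("CT", "PET"),
                     region = c("all", "only_tumour", "largest_tumour",
                                "only_lymph", "largest_lymph"),
                     bin_width = NULL) {
  modality <- match.arg(modality)
  region <- match.arg(region)
  bin_width <- bin_width %||% if (modality == "CT") 25 else 0.5
  assert_scalar_num(bin_width, "bin_width", lower = 1e-12)
  structure(list(modality = modality, region = region, bin_width = bin_width,
                 group = sprintf("%s_%s", modality, region)),
            class = "roi_spec")
}

#' All ten modality-by-region ROI specifications
#' @return list of `roi_spec` objects.
#' @export
all_roi_specs <- function() {
  out <- list()
  for (m in c("CT", "PET")) {
    for (r in c("all", "only_tumour", "largest_tumour", "only_lymph",
                "largest_lymph")) {
      out[[sprintf("%s_%s", m, r)]] <- roi_spec(m, r)
    }
  }
  out
}

#' Build a binary ROI mask for a region specification
#'
#' `all` is the union of GTVp and GTVn; `only_tumour`/`only_lymph` are the
#' single classes; `largest_*` is the connected component of that class with
#' maximal volume.
#'
#' @param mask integer label mask (0/1/2).
#' @param spec a [roi_spec()] (only the region matters here).
#' @param lesions optional `lesion_set` already extracted from `mask`.
#' @return logical 3D array, or `NULL` when the requested region is empty
#'   (the empty-ROI signal: the feature row is marked missing downstream).
#' @export
build_roi <- function(mask, spec, lesions = NULL) {
  assert_mask(mask)
  stopifnot(inherits(spec, "roi_spec"))
  region <- spec$region
  if (region == "all") {
    roi <- mask > 0L
  } else if (region == "only_tumour") {
    roi <- mask == 1L
  } else if (region == "only_lymph") {
    roi <- mask == 2L
  } else {
    cls <- if (region == "largest_tumour") "GTVp" else "GTVn"
    lesions <- lesions %||% extract_lesions(mask)
    of_class <- Filter(function(l) l$class == cls, lesions$lesions)
    if (!length(of_class)) return(NULL)
    vols <- vapply(of_class, `[[`, 0, "volume")
    best <- of_class[[which.max(vols)]]
    roi <- array(FALSE, dim = dim(mask))
    roi[best$voxels] <- TRUE
  }
  if (!any(roi)) return(NULL)
  dim(roi) <- dim(mask)
  voxel_spacing(roi) <- voxel_spacing(mask)
  roi
}

#' Six volume-related features of a patient's lesion set
#'
#' Total tumour volume, largest tumour volume, total lymph-node volume,
#' largest lymph-node volume, number of tumours and number of lymph nodes
#' (volumes in mm3; zero for absent classes).
#'
#' @param lesions a `lesion_set`.
#' @return named numeric vector of length 6.
#' @export
volume_features <- function(lesions) {
  stopifnot(inherits(lesions, "lesion_set"))
  out <- c(total_tumour_volume = 0, largest_tumour_volume = 0,
           total_lymph_volume = 0, largest_lymph_volume = 0,
           n_tumours = 0, n_lymph_nodes = 0)
  for (l in lesions$lesions) {
    if (l$class == "GTVp") {
      out["total_tumour_volume"] <- out["total_tumour_volume"] + l$volume
      out["largest_tumour_volume"] <- max(out["largest_tumour_volume"], l$volume)
      out["n_tumours"] <- out["n_tumours"] + 1
    } else {
      out["total_lymph_volume"] <- out["total_lymph_volume"] + l$volume
      out["largest_lymph_volume"] <- max(out["largest_lymph_volume"], l$volume)
      out["n_lymph_nodes"] <- out["n_lymph_nodes"] + 1
    }
  }
  out
}

#' Impute missing feature values with explicit missingness bookkeeping
#'
#' Numeric columns are median-imputed with an added `<name>_missing`
#' indicator column; categorical columns get "NA" as an explicit category.
#' Feature rows from empty ROIs arrive as NA blocks and stay usable for
#' model fitting this way.
#'
#' @param features data frame.
#' @return data frame with no remaining NA values.
#' @export
impute_features <- function(features) {
  out <- as.data.frame(features)
  for (nm in colnames(features)) {
    x <- out[[nm]]
    if (is.numeric(x)) {
      if (anyNA(x)) {
        out[[paste0(nm, "_missing")]] <- as.integer(is.na(x))
        med <- median(x, na.rm = TRUE)
        x[is.na(x)] <- if (is.finite(med)) med else 0
        out[[nm]] <- x
      }
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "NA"
      out[[nm]] <- x
    }
  }
  out
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs in which the patient with the
#' shorter event time received the higher risk score; tied risk scores
#' credit 1/2. A pair is comparable when the shorter observed time belongs
#' to a patient with an event.
#'
#' @param risk numeric risk scores (higher = predicted worse).
#' @param survival data frame with `time` and `event` columns.
#' @return scalar C-index in [0, 1].
#' @export
harrell_c <- function(risk, survival) {
  time <- survival$time
  event <- survival$event
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    if (!event[i]) next
    # patient i had an event; comparable with anyone observed longer
    longer <- which(time > time[i] | (time == time[i] & !event))
    if (!length(longer)) next
    comp <- comp + length(longer)
    conc <- conc + sum(risk[i] > risk[longer]) + 0.5 * sum(risk[i] == risk[longer])
  }
  if (comp == 0) stopf("no comparable pairs: C-index undefined")
  conc / comp
}

#' Rank features by univariate Cox concordance
#'
#' Fits a single-covariate Cox proportional-hazards model per feature and
#' scores the model's linear predictor with Harrell's C on the same data;
#' returns the top `k` in descending C, ties broken lexicographically by
#' feature name. Non-convergent fits are skipped with a warning.
#'
#' @param features data frame of candidate features (numeric columns and
#'   factors/characters both allowed; `patient_id` is ignored).
#' @param survival data frame with `time`, `event`.
#' @param k number of features to return (default 10).
#' @return data frame (feature, cindex) of at most `k` rows, ranked.
#' @export
univariate_rank <- function(features, survival, k = 10L) {
  feats <- as.data.frame(features)
  feats$patient_id <- NULL
  if (ncol(feats) == 0L) stopf("no candidate features")
  surv_obj <- survival::Surv(survival$time, survival$event)
  res <- lapply(colnames(feats), function(nm) {
    x <- feats[[nm]]
    if (is.character(x)) x <- factor(x)
    ci <- tryCatch({
      fit <- survival::coxph(surv_obj ~ x,
                             data = data.frame(x = x),
                             control = survival::coxph.control(iter.max = 50))
      lp <- predict(fit, type = "lp")
      harrell_c(lp, survival)
    }, error = function(e) {
      warning(sprintf("univariate fit failed for '%s': %s", nm,
                      conditionMessage(e)), call. = FALSE)
      NA_real_
    }, warning = function(w) {
      # non-convergence warnings: still score the returned fit if possible
      fit <- suppressWarnings(survival::coxph(surv_obj ~ x,
                                              data = data.frame(x = x)))
      lp <- predict(fit, type = "lp")
      harrell_c(lp, survival)
    })
    data.frame(feature = nm, cindex = ci)
  })
  tab <- do.call(rbind, res)
  tab <- tab[!is.na(tab$cindex), , drop = FALSE]
  tab <- tab[order(-tab$cindex, tab$feature), , drop = FALSE]
  head(tab, k)
}

#' Forward aggregation of ranked features by cross-validated concordance
#'
#' Builds the nested candidate sets f1, f1+f2, ... in rank order, scores each
#' by the mean cross-validated C-index of the boosted Cox learner, and keeps
#' the prefix with maximal mean CV C (smallest prefix on ties).
#'
#' @param ranked character vector of feature names in rank order (or the
#'   data frame returned by [univariate_rank()]).
#' @param features data frame containing those columns.
#' @param survival data frame with `time`, `event`.
#' @param config learner hyperparameters passed to [fit_survival_model()].
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for the fold split and learner.
#' @return list with `selected` (character vector), `cv_cindex` per prefix.
#' @export
forward_aggregate <- function(ranked, features, survival, config = list(),
                              folds = 5L, seed = 1L) {
  if (is.data.frame(ranked)) ranked <- ranked$feature
  if (!length(ranked)) stopf("ranked feature list is empty")
  feats <- as.data.frame(features)
  n <- nrow(feats)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  cv_scores <- numeric(length(ranked))
  for (m in seq_along(ranked)) {
    cols <- ranked[seq_len(m)]
    sc <- vapply(seq_len(folds), function(fd) {
      tr <- fold_id != fd
      model <- fit_survival_model(feats[tr, cols, drop = FALSE],
                                  survival[tr, , drop = FALSE],
                                  config = config, seed = seed + fd)
      pred <- predict(model, feats[!tr, cols, drop = FALSE])
      harrell_c(pred, survival[!tr, , drop = FALSE])
    }, 0)
    cv_scores[m] <- mean(sc)
  }
  best <- which.max(cv_scores)  # which.max takes the first (smallest) on ties
  list(selected = ranked[seq_len(best)], cv_cindex = cv_scores,
       best_prefix = best)
}

#' Tertile risk stratification
#'
#' Cut points at the 33rd and 66th percentiles (linear-interpolation
#' convention) of the training risk scores; boundary ties go to the lower
#' group.
#'
#' @param risk numeric risk scores (>= 3 values unless `cut_points` given).
#' @param cut_points optional precomputed c(q33, q66) from training data.
#' @return factor with levels low/medium/high; attribute `cut_points`.
#' @export
stratify_risk <- function(risk, cut_points = NULL) {
  if (is.null(cut_points)) {
    if (length(risk) < 3L) stopf("need at least 3 patients to stratify")
    cut_points <- quantile(risk, c(0.33, 0.66), names = FALSE, type = 7)
  }
  g <- ifelse(risk <= cut_points[1], "low",
              ifelse(risk <= cut_points[2], "medium", "high"))
  out <- factor(g, levels = c("low", "medium", "high"))
  attr(out, "cut_points") <- cut_points
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' @param survival data frame with `time`, `event` (1 = event, 0 = censored).
#' @return a `km_curve` data frame with one row per distinct event time:
#'   time, n_risk, n_event, survival (right-continuous step values).
#' @export
km_estimate <- function(survival) {
  time <- survival$time
  event <- survival$event
  if (!length(time)) stopf("empty survival subset")
  evt_times <- sort(unique(time[event == 1]))
  s <- 1
  rows <- lapply(evt_times, function(t) {
    n_risk <- sum(time >= t)
    n_event <- sum(time == t & event == 1)
    s <<- s * (1 - n_event / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = n_event, survival = s)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(), n_risk = integer(), n_event = integer(),
               survival = numeric())
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param curve a `km_curve`.
#' @param times numeric vector.
#' @return survival probabilities (right-continuous step function, S(0)=1).
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    below <- curve$time <= t
    if (!any(below)) 1 else curve$survival[max(which(below))]
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square statistic with hypergeometric
#' variance, computed over the pooled distinct event times.
#'
#' @param surv_a,surv_b data frames with `time`, `event` for the two groups.
#' @return list with `statistic` (chi-square, 1 df), `p` (two-sided),
#'   `observed`, `expected` for group A.
#' @export
logrank_test <- function(surv_a, surv_b) {
  if (!nrow(surv_a) || !nrow(surv_b)) stopf("both groups must be non-empty")
  if (sum(surv_a$event) + sum(surv_b$event) == 0) {
    stopf("no events: log-rank test undefined")
  }
  time <- c(surv_a$time, surv_b$time)
  event <- c(surv_a$event, surv_b$event)
  grp <- rep(c(0L, 1L), c(nrow(surv_a), nrow(surv_b)))
  evt_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in evt_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == 0L)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp == 0L)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E, variance = V)
}
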