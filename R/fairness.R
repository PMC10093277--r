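# Fairness and explainability harness: subgroup slicing, Mann-Whitney
# comparisons, label-shuffling permutation tests for cohort metrics, and
# exact Shapley global feature importance for the boosted survival model.

#' Slice a cohort into subgroups of a clinical or size variable
#'
#' Age uses the fixed bins 0-50, 50-60, 60-70, >70 years; continuous size
#' variables use the cohort's own 25/50/75 percentiles (small / medium /
#' large / extra_large); categorical variables get one bin per level, with
#' "NA" (missing) as its own bin. The bins partition the cohort: every row
#' maps to exactly one subgroup.
#'
#' @param cohort data frame.
#' @param variable column name to slice on.
#' @param type "auto" (default), "age", "quartiles", or "categorical".
#' @return named list of integer row-index vectors.
#' @export
slice_subgroups <- function(cohort, variable,
                            type = c("auto", "age", "quartiles",
                                     "categorical")) {
  type <- match.arg(type)
  if (!variable %in% colnames(cohort)) {
    stopf("unknown variable '%s'", variable)
  }
  x <- cohort[[variable]]
  if (type == "auto") {
    type <- if (!is.numeric(x)) "categorical"
      else if (variable == "age") "age" else "quartiles"
  }
  if (type == "categorical") {
    x <- as.character(x)
    x[is.na(x)] <- "NA"
    return(split(seq_along(x), x))
  }
  if (anyNA(x)) stopf("numeric variable '%s' contains NA", variable)
  if (type == "age") {
    breaks <- c(0, 50, 60, 70, Inf)
    labels <- c("0-50", "50-60", "60-70", ">70")
  } else {
    breaks <- c(-Inf, quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7),
                Inf)
    labels <- c("small", "medium", "large", "extra_large")
  }
  g <- cut(x, breaks = breaks, labels = labels, include.lowest = TRUE,
           right = TRUE)
  split(seq_along(x), g, drop = FALSE)
}

#' Mann-Whitney rank-sum test of a subgroup against reference values
#'
#' Two-sided normal approximation with tie correction (no continuity
#' correction); returns the U statistic of the subgroup sample.
#'
#' @param x subgroup metric values.
#' @param y reference metric values.
#' @return list with `U`, `p`.
#' @export
mann_whitney_subgroup <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stopf("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, p = 2 * pnorm(-abs(z)))
}

#' Two-sided permutation test for a cohort-level metric difference
#'
#' The observed statistic is `metric(units in subgroup) - metric(rest)`.
#' The null is built by shuffling the subgroup labels across all units and
#' recomputing the difference; the reported p-value is
#' `(1 + #{|null| >= |obs|}) / (1 + n_permutations)`. Permutations on which
#' the metric is undefined (e.g. no comparable pairs after a split) are
#' resampled and counted in `n_resampled`.
#'
#' @param units list of per-unit records (per patient or per image).
#' @param group_idx integer indices of the subgroup within `units`.
#' @param metric_fn function taking a list of units and returning a scalar.
#' @param n_permutations number of label shuffles (>= 1).
#' @param seed integer seed.
#' @return list with `p`, `observed`, `null` (vector), `n_resampled`.
#' @export
permutation_test_metric <- function(units, group_idx, metric_fn,
                                    n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 1L) stopf("n_permutations must be >= 1")
  n <- length(units)
  k <- length(group_idx)
  if (k == 0L || k == n) stopf("subgroup must be a proper subset of the cohort")
  obs <- metric_fn(units[group_idx]) - metric_fn(units[-group_idx])
  null <- numeric(n_permutations)
  n_resampled <- 0L
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      repeat {
        idx <- sample.int(n, k)
        val <- tryCatch(
          metric_fn(units[idx]) - metric_fn(units[-idx]),
          error = function(e) NA_real_)
        if (is.finite(val)) break
        n_resampled <- n_resampled + 1L
        if (n_resampled > 100L * n_permutations) {
          stopf("metric undefined on almost all permutations")
        }
      }
      null[b] <- val
    }
  })
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_permutations)
  list(p = p, observed = obs, null = null, n_resampled = n_resampled)
}

#' Exact Shapley attributions and global importance for a risk model
#'
#' Computes exact Shapley values by enumerating all feature coalitions
#' (feasible because selected feature sets are small) with a
#' background-marginal value function: `v(S; x)` is the mean model
#' prediction over background rows with the columns in `S` replaced by the
#' explained patient's values. Local additivity holds by construction:
#' attributions sum to `f(x) - base_value` for every patient.
#'
#' @param model a `risk_model` from [fit_survival_model()].
#' @param features data frame containing the model's feature columns (the
#'   patients to explain).
#' @param background optional data frame of background rows (default: up to
#'   `n_background` rows sampled from `features`).
#' @param n_background background sample size (default 50).
#' @param seed integer seed for the background sample.
#' @return list with `attributions` (n x m matrix), `base_value`,
#'   `prediction` (per patient), and `ranking` (data frame: feature,
#'   mean_abs_attribution, sign_trend), sorted by importance.
#' @export
shapley_global_summary <- function(model, features, background = NULL,
                                   n_background = 50L, seed = 1L) {
  stopifnot(inherits(model, "risk_model"))
  fn <- model$feature_names
  m <- length(fn)
  if (m > 14L) stopf("exact Shapley enumeration limited to 14 features (got %d)", m)
  feats <- as.data.frame(features)
  missing <- setdiff(fn, colnames(feats))
  if (length(missing)) {
    stopf("features lack model columns: %s", paste(missing, collapse = ", "))
  }
  X <- as.matrix(feats[, fn, drop = FALSE])
  bg <- if (is.null(background)) {
    if (nrow(X) > n_background) {
      X[with_seed(seed, sample.int(nrow(X), n_background)), , drop = FALSE]
    } else X
  } else {
    as.matrix(as.data.frame(background)[, fn, drop = FALSE])
  }
  B <- nrow(bg)
  n_coal <- 2^m
  coal_members <- lapply(seq_len(n_coal) - 1L, function(bits) {
    which(bitwAnd(bits, 2^(seq_len(m) - 1L)) > 0L)
  })
  wfac <- factorial(seq_len(m) - 1L) * factorial(m - seq_len(m)) / factorial(m)
  # v for every coalition, per patient
  phi <- matrix(0, nrow(X), m, dimnames = list(NULL, fn))
  base_value <- mean(predict(model, as.data.frame(bg)))
  pred <- predict(model, as.data.frame(X))
  # membership indicator per coalition (n_coal x m), used to build one
  # stacked prediction matrix per patient: row block ci = background rows
  # with the coalition's columns replaced by the patient's values
  memb <- matrix(FALSE, n_coal, m)
  for (ci in seq_len(n_coal)) memb[ci, coal_members[[ci]]] <- TRUE
  bg_stack <- bg[rep(seq_len(B), times = n_coal), , drop = FALSE]
  repl <- memb[rep(seq_len(n_coal), each = B), , drop = FALSE]
  for (pi in seq_len(nrow(X))) {
    rows <- bg_stack
    for (j in seq_len(m)) rows[repl[, j], j] <- X[pi, j]
    pr <- predict(model, as.data.frame(rows))
    v <- colMeans(matrix(pr, B, n_coal))
    for (j in seq_len(m)) {
      bit <- 2^(j - 1L)
      without <- which(bitwAnd(seq_len(n_coal) - 1L, bit) == 0L)
      sizes <- lengths(coal_members[without])
      phi[pi, j] <- sum(wfac[sizes + 1L] * (v[without + bit] - v[without]))
    }
  }
  ranking <- data.frame(
    feature = fn,
    mean_abs_attribution = colMeans(abs(phi)),
    sign_trend = vapply(seq_len(m), function(j) {
      if (sd(X[, j]) == 0 || sd(phi[, j]) == 0) 0
      else stats::cor(X[, j], phi[, j])
    }, 0))
  ranking <- ranking[order(-ranking$mean_abs_attribution), ]
  rownames(ranking) <- NULL
  list(attributions = phi, base_value = base_value, prediction = pred,
       ranking = ranking)
}

#' Assemble a subgroup fairness report
#'
#' For each variable, slices the cohort, reports subgroup sizes and
#' percentages, per-subgroup metric values, and (optionally) Mann-Whitney
#' p-values of per-unit metric values against the whole cohort.
#'
#' @param cohort data frame of per-unit covariates.
#' @param variables character vector of columns to slice on.
#' @param unit_metrics optional named list of numeric per-unit metric vectors
#'   (e.g. per-image Dice); tested subgroup-vs-cohort with Mann-Whitney.
#' @param alpha significance level for flags (default 0.05).
#' @return data frame: variable, subgroup, n, percent, then one metric mean,
#'   p and flag column per metric.
#' @export
fairness_report <- function(cohort, variables, unit_metrics = list(),
                            alpha = 0.05) {
  rows <- list()
  n <- nrow(cohort)
  for (v in variables) {
    groups <- slice_subgroups(cohort, v)
    for (g in names(groups)) {
      idx <- groups[[g]]
      row <- data.frame(variable = v, subgroup = g, n = length(idx),
                        percent = 100 * length(idx) / n)
      for (mn in names(unit_metrics)) {
        vals <- unit_metrics[[mn]]
        row[[paste0(mn, "_mean")]] <- mean(vals[idx])
        if (length(idx) < n && length(idx) > 0) {
          mw <- mann_whitney_subgroup(vals[idx], vals)
          row[[paste0(mn, "_p")]] <- mw$p
          row[[paste0(mn, "_significant")]] <- mw$p < alpha
        } else {
          row[[paste0(mn, "_p")]] <- NA_real_
          row[[paste0(mn, "_significant")]] <- NA
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
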