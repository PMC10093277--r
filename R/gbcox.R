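# Gradient-boosted regression trees with a Cox proportional-hazards
# objective (Breslow ties). Mirrors the XGBoost formulation: per-round
# first/second-order gradients of the negative log partial likelihood,
# depth-limited exact-greedy trees, leaf values -G/(H + lambda), shrinkage.

cox_gradients <- function(f, time, event) {
  n <- length(f)
  ord <- order(time)
  ef <- exp(f)
  # risk-set sums R_k = sum_{j: t_j >= t_k} exp(f_j), computed on sorted times
  ef_sorted <- ef[ord]
  rs <- rev(cumsum(rev(ef_sorted)))  # R at each sorted position
  t_sorted <- time[ord]
  ev_sorted <- event[ord]
  # handle ties: all positions with equal time share the risk set of the first
  first_idx <- match(t_sorted, t_sorted)
  rs <- rs[first_idx]
  # a_k = delta_k / R_k accumulated over event times <= t_i
  a <- ev_sorted / rs
  b <- ev_sorted / rs^2
  ca <- cumsum(a)
  cb <- cumsum(b)
  # for patient at sorted position i, sum over events with t_k <= t_i:
  # ties share position of last equal time
  last_idx <- length(t_sorted) + 1L - match(t_sorted, rev(t_sorted))
  Ai <- ca[last_idx]
  Bi <- cb[last_idx]
  g <- numeric(n); h <- numeric(n)
  g[ord] <- -ev_sorted + ef_sorted * Ai
  h[ord] <- pmax(ef_sorted * Ai - ef_sorted^2 * Bi, 1e-12)
  list(g = g, h = h)
}

# Exact greedy depth-limited regression tree on (g, h).
build_tree <- function(X, g, h, idx, depth, max_depth, lambda, min_child) {
  G <- sum(g[idx]); H <- sum(h[idx])
  leaf <- list(leaf = TRUE, value = -G / (H + lambda))
  if (depth >= max_depth || length(idx) < 2L * min_child) return(leaf)
  best <- list(gain = 1e-8)
  base_score <- G^2 / (H + lambda)
  for (j in seq_len(ncol(X))) {
    xj <- X[idx, j]
    o <- order(xj)
    xs <- xj[o]
    gs <- cumsum(g[idx][o])
    hs <- cumsum(h[idx][o])
    # candidate splits between distinct consecutive values
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    for (s in distinct) {
      if (s < min_child || (length(idx) - s) < min_child) next
      GL <- gs[s]; HL <- hs[s]
      GR <- G - GL; HR <- H - HL
      gain <- GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - base_score
      if (gain > best$gain) {
        best <- list(gain = gain, feature = j,
                     threshold = (xs[s] + xs[s + 1]) / 2)
      }
    }
  }
  if (is.null(best$feature)) return(leaf)
  left <- idx[X[idx, best$feature] <= best$threshold]
  right <- setdiff(idx, left)
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = build_tree(X, g, h, left, depth + 1L, max_depth, lambda, min_child),
       right = build_tree(X, g, h, right, depth + 1L, max_depth, lambda, min_child))
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (node$leaf) {
      out[idx] <<- node$value
    } else {
      go_left <- X[idx, node$feature] <= node$threshold
      if (any(go_left)) rec(node$left, idx[go_left])
      if (any(!go_left)) rec(node$right, idx[!go_left])
    }
  }
  if (n) rec(tree, seq_len(n))
  out
}

#' Fit a gradient-boosted Cox survival model
#'
#' Boosted regression trees trained on the first- and second-order gradients
#' of the Cox negative log partial likelihood (Breslow tie handling), with
#' XGBoost-style leaf values and L2 regularisation. Risk scores are the
#' additive log-hazard predictions: higher score means predicted worse
#' outcome.
#'
#' @param features data frame or matrix of numeric predictors (the selected
#'   feature set).
#' @param survival data frame with columns `time` and `event`.
#' @param config list of hyperparameters: `n_rounds` (100), `eta` (0.1),
#'   `max_depth` (2), `lambda` (1), `min_child` (10), `subsample` (1).
#' @param seed integer seed (used when `subsample < 1`).
#' @return a `risk_model` with trees, feature names, per-patient `risk`
#'   scores, and tertile `cut_points` computed on the training risk.
#' @export
fit_survival_model <- function(features, survival, config = list(),
                               seed = 1L) {
  cfg <- utils::modifyList(
    list(n_rounds = 100L, eta = 0.1, max_depth = 2L, lambda = 1,
         min_child = 10L, subsample = 1),
    config)
  X <- as.matrix(as.data.frame(features)[
    , vapply(as.data.frame(features), is.numeric, TRUE), drop = FALSE])
  if (ncol(X) == 0L) stopf("no numeric features to train on")
  if (nrow(X) != nrow(survival)) stopf("features and survival row mismatch")
  time <- survival$time
  event <- survival$event
  if (sum(event) == 0L) stopf("degenerate outcomes: no events")
  n <- nrow(X)
  f <- numeric(n)
  trees <- vector("list", cfg$n_rounds)
  with_seed(seed, {
    for (r in seq_len(cfg$n_rounds)) {
      gh <- cox_gradients(f, time, event)
      idx <- if (cfg$subsample < 1) {
        sort(sample.int(n, max(2L * cfg$min_child, round(cfg$subsample * n))))
      } else seq_len(n)
      tr <- build_tree(X, gh$g, gh$h, idx, 0L, cfg$max_depth, cfg$lambda,
                       cfg$min_child)
      trees[[r]] <- tr
      f <- f + cfg$eta * predict_tree(tr, X)
    }
  })
  risk <- f
  structure(
    list(trees = trees, eta = cfg$eta, feature_names = colnames(X),
         config = cfg, risk = risk,
         cut_points = quantile(risk, c(0.33, 0.66), names = FALSE, type = 7)),
    class = "risk_model"
  )
}

#' Predict risk scores from a fitted boosted Cox model
#'
#' @param object a `risk_model`.
#' @param newdata data frame containing the model's feature columns.
#' @param ... unused.
#' @return numeric risk scores (additive log-hazard scale).
#' @export
predict.risk_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, colnames(nd))
  if (length(missing)) {
    stopf("newdata lacks model features: %s", paste(missing, collapse = ", "))
  }
  X <- as.matrix(nd[, object$feature_names, drop = FALSE])
  f <- numeric(nrow(X))
  for (tr in object$trees) f <- f + object$eta * predict_tree(tr, X)
  f
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("risk_model: %d boosted Cox trees (depth <= %d, eta %g) on %d features\n",
              length(x$trees), x$config$max_depth, x$eta,
              length(x$feature_names)))
  cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}
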