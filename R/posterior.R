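# Posterior weight-space sampling: cyclic learning-rate schedule, checkpoint
# selection over the constant-gradient-step plateau, and the checkpoint
# ensemble's posterior mean / per-voxel variance uncertainty map.

#' Cyclic learning-rate schedule for posterior checkpoint sampling
#'
#' The training budget is split into `n_cycles` cycles of
#' `total_epochs / n_cycles` epochs. Each cycle starts with one epoch at
#' `restart_lr` to escape the current local optimum, then follows polynomial
#' decay `base_lr * (1 - min(tmod, plateau_start) / cycle_epochs)^poly_power`,
#' which becomes constant (a plateau) once `gamma` of the cycle has elapsed.
#' Checkpoints are sampled from the plateau, where SGD oscillates around a
#' local optimum and the saved weights can be treated as posterior samples.
#'
#' @param total_epochs total training budget in epochs (default 1200).
#' @param n_cycles number of learning-rate cycles (default 3).
#' @param gamma fraction of the cycle after which the gradient step is held
#'   constant (default 0.8).
#' @param base_lr polynomial-decay base learning rate (default 0.01).
#' @param restart_lr one-epoch restart learning rate at each cycle start
#'   (default 0.1).
#' @param poly_power polynomial decay exponent (default 0.9).
#' @return an object of class `cycle_schedule`.
#' @examples
#' sched <- cycle_schedule()
#' learning_rate(0, sched)    # 0.1 (cycle restart)
#' learning_rate(320, sched)  # plateau value 0.01 * 0.2^0.9
#' @export
cycle_schedule <- function(total_epochs = 1200L, n_cycles = 3L, gamma = 0.8,
                           base_lr = 0.01, restart_lr = 0.1,
                           poly_power = 0.9) {
  assert_scalar_num(total_epochs, "total_epochs", lower = 0)
  assert_scalar_num(n_cycles, "n_cycles", lower = 1)
  if (total_epochs %% n_cycles != 0) {
    stopf("total_epochs (%d) must be divisible by n_cycles (%d)",
          total_epochs, n_cycles)
  }
  assert_scalar_num(gamma, "gamma")
  if (gamma <= 0 || gamma >= 1) stopf("gamma must be in (0, 1)")
  assert_scalar_num(base_lr, "base_lr", lower = 0)
  assert_scalar_num(restart_lr, "restart_lr", lower = 0)
  assert_scalar_num(poly_power, "poly_power", lower = 0)
  cycle_epochs <- as.integer(total_epochs / n_cycles)
  structure(
    list(
      total_epochs = as.integer(total_epochs),
      n_cycles = as.integer(n_cycles),
      cycle_epochs = cycle_epochs,
      gamma = gamma,
      plateau_start = as.integer(round(gamma * cycle_epochs)),
      base_lr = base_lr,
      restart_lr = restart_lr,
      poly_power = poly_power
    ),
    class = "cycle_schedule"
  )
}

#' @export
print.cycle_schedule <- function(x, ...) {
  cat(sprintf(
    "cycle_schedule: %d epochs = %d cycles x %d; plateau from epoch %d (gamma=%g)\n",
    x$total_epochs, x$n_cycles, x$cycle_epochs, x$plateau_start, x$gamma))
  cat(sprintf("  restart lr %g (1 epoch), poly decay %g * (1 - min(t, %d)/%d)^%g\n",
              x$restart_lr, x$base_lr, x$plateau_start, x$cycle_epochs,
              x$poly_power))
  invisible(x)
}

#' Learning rate at a given epoch of the cyclic schedule
#'
#' Vectorised over `t`. Within each cycle, with `tmod = t %% cycle_epochs`:
#' `restart_lr` when `tmod == 0`, else
#' `base_lr * (1 - min(tmod, plateau_start) / cycle_epochs)^poly_power`.
#' Note the decay denominator is the full cycle length, so the plateau value
#' is strictly positive (`0.01 * 0.2^0.9` at the defaults).
#'
#' @param t epoch index (0-based), `0 <= t < total_epochs`.
#' @param schedule a [cycle_schedule()].
#' @return learning rate(s), same length as `t`.
#' @export
learning_rate <- function(t, schedule) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  if (!is.numeric(t) || any(!is.finite(t))) stopf("'t' must be numeric")
  if (any(t < 0) || any(t >= schedule$total_epochs)) {
    stopf("epoch t out of range [0, %d)", schedule$total_epochs)
  }
  tmod <- t %% schedule$cycle_epochs
  lr <- schedule$base_lr *
    (1 - pmin(tmod, schedule$plateau_start) / schedule$cycle_epochs) ^
    schedule$poly_power
  lr[tmod == 0] <- schedule$restart_lr
  lr
}

#' Randomly select checkpoint epochs from each cycle's plateau
#'
#' Draws `per_cycle` distinct epochs uniformly without replacement from the
#' constant-learning-rate plateau of every cycle (epochs `e` with
#' `e %% cycle_epochs >= plateau_start`), returning them sorted. At the
#' defaults this yields the 30 checkpoints (10 per cycle over 3 cycles) whose
#' weights constitute the multi-model posterior sample.
#'
#' @param schedule a [cycle_schedule()].
#' @param per_cycle checkpoints saved per cycle (default 10).
#' @param seed integer seed for the draw.
#' @return integer vector of `n_cycles * per_cycle` distinct epochs, sorted.
#' @export
checkpoint_epochs <- function(schedule, per_cycle = 10L, seed = 1L) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  plateau_len <- schedule$cycle_epochs - schedule$plateau_start
  assert_scalar_num(per_cycle, "per_cycle", lower = 1)
  if (per_cycle > plateau_len) {
    stopf("per_cycle (%d) exceeds plateau length (%d)", per_cycle, plateau_len)
  }
  per_cycle <- as.integer(per_cycle)
  with_seed(seed, {
    out <- lapply(seq_len(schedule$n_cycles) - 1L, function(cyc) {
      plateau <- cyc * schedule$cycle_epochs +
        seq.int(schedule$plateau_start, schedule$cycle_epochs - 1L)
      if (per_cycle == plateau_len) plateau else sort(sample(plateau, per_cycle))
    })
    as.integer(unlist(out))
  })
}

new_ensemble_prediction <- function(prob, classes, provenance = NULL,
                                    spacing = c(1, 1, 1)) {
  stopifnot(length(dim(prob)) == 5L)
  structure(
    list(prob = prob, classes = classes,
         provenance = provenance, spacing = as.numeric(spacing)),
    class = "ensemble_prediction"
  )
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  d <- dim(x$prob)
  cat(sprintf("ensemble_prediction: %d members, %d classes (%s), grid %dx%dx%d\n",
              d[5], d[4], paste(x$classes, collapse = "/"), d[1], d[2], d[3]))
  invisible(x)
}

n_members <- function(ensemble) dim(ensemble$prob)[5]

validate_ensemble <- function(ensemble, min_members = 1L) {
  if (!inherits(ensemble, "ensemble_prediction")) {
    stopf("expected an 'ensemble_prediction'")
  }
  if (n_members(ensemble) < min_members) {
    stopf("ensemble must have at least %d member(s), has %d",
          min_members, n_members(ensemble))
  }
  invisible(ensemble)
}

#' Posterior mean of a checkpoint ensemble
#'
#' Voxel-wise arithmetic mean of the member probability maps: the predicted
#' posterior is the average of the predictions of the n checkpoint models.
#'
#' @param ensemble an `ensemble_prediction` (see [simulate_ensemble()]).
#' @return a 4D array (x, y, z, class) of mean probabilities; per-voxel class
#'   probabilities still sum to 1.
#' @export
posterior_mean <- function(ensemble) {
  validate_ensemble(ensemble, min_members = 1L)
  d <- dim(ensemble$prob)
  m <- rowMeans(array(ensemble$prob, dim = c(prod(d[1:4]), d[5])))
  out <- array(m, dim = d[1:4])
  dimnames(out) <- list(NULL, NULL, NULL, ensemble$classes)
  attr(out, "spacing") <- ensemble$spacing
  out
}

#' Detection-oriented label mask from an ensemble
#'
#' Assigns a voxel to a foreground class when the posterior-mean probability
#' of that class reaches `min_fraction` (taking the stronger foreground class
#' on overlap). The default 0.25 is deliberately permissive: the mask is the
#' proposal stage of the false-positive-reduction pipeline, so structures
#' predicted by only a minority of checkpoints are kept and left for the
#' uncertainty-density filter to remove. `min_fraction = 0.5` recovers the
#' majority-vote (argmax-like) segmentation.
#'
#' @param ensemble an `ensemble_prediction`.
#' @param min_fraction minimum posterior-mean class probability (default
#'   0.25).
#' @return integer label mask (0 background, 1 GTVp, 2 GTVn).
#' @export
ensemble_prediction_mask <- function(ensemble, min_fraction = 0.25) {
  validate_ensemble(ensemble, min_members = 1L)
  pm <- posterior_mean(ensemble)
  d <- dim(pm)
  out <- array(0L, dim = d[1:3])
  fg <- which(ensemble$classes != "background")
  best_p <- array(0, dim = d[1:3])
  for (k in fg) {
    pk <- pm[, , , k]
    take <- pk >= min_fraction & pk > best_p
    out[take] <- k - 1L
    best_p[take] <- pk[take]
  }
  voxel_spacing(out) <- ensemble$spacing
  out
}

#' Ensemble variance uncertainty map
#'
#' Per-voxel population variance (divide by n) of the member probabilities,
#' computed separately for each foreground class. Values lie in [0, 0.25]
#' (Popoviciu's bound for a [0,1] variable) and are exactly zero wherever all
#' members agree; high values flag voxels the checkpoint ensemble disagrees
#' on, which concentrate on lesion boundaries and false-positive blobs.
#'
#' @param ensemble an `ensemble_prediction` with at least 2 members.
#' @param foreground_classes character names of the foreground channels
#'   (default `c("GTVp", "GTVn")`).
#' @return an `uncertainty_map`: named list of 3D variance arrays, one per
#'   foreground class.
#' @export
uncertainty_map <- function(ensemble, foreground_classes = c("GTVp", "GTVn")) {
  validate_ensemble(ensemble, min_members = 2L)
  d <- dim(ensemble$prob)
  n <- d[5]
  missing_cls <- setdiff(foreground_classes, ensemble$classes)
  if (length(missing_cls)) {
    stopf("classes not in ensemble: %s", paste(missing_cls, collapse = ", "))
  }
  maps <- lapply(foreground_classes, function(cl) {
    k <- match(cl, ensemble$classes)
    p <- array(ensemble$prob[, , , k, ], dim = c(prod(d[1:3]), n))
    mu <- rowMeans(p)
    v <- rowMeans(p * p) - mu * mu
    v[v < 0] <- 0  # guard tiny negative rounding
    out <- array(v, dim = d[1:3])
    attr(out, "spacing") <- ensemble$spacing
    out
  })
  names(maps) <- foreground_classes
  structure(maps, class = "uncertainty_map", spacing = ensemble$spacing)
}
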