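# End-to-end orchestration: a validated run configuration, deterministic
# stage execution with a manifest, and the desk-scale demo workflow
# phantom -> preprocess -> toy-train -> posterior -> fp-reduction ->
# radiomics -> survival -> fairness.

#' Default demo run configuration
#'
#' Every stochastic stage has an explicit seed derived from the master seed,
#' and all sizes are desk-scale so the whole pipeline runs in minutes on one
#' CPU.
#'
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param out_dir run directory.
#' @return a plain list suitable for [validate_config()].
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("petuq_run_")) {
  seed <- as.integer(seed)
  list(
    out_dir = out_dir,
    seed = seed,
    stages = list(phantom = TRUE, preprocess = TRUE, train = TRUE,
                  posterior = TRUE, fp_reduce = TRUE, seg_eval = TRUE,
                  radiomics = TRUE, survival = TRUE, fairness = TRUE),
    phantom = list(n_images = 4L, grid_shape = c(32L, 32L, 32L),
                   n_tumours = 1L, n_nodes = 1L,
                   lesion_volume_range = c(300, 1500),
                   n_members = 30L, boundary_jitter = 1L,
                   fp_volume = 400, fp_member_fraction = 0.4),
    preprocess = list(target_spacing = c(1, 1, 3),
                      crop_extent = c(48L, 48L, 16L)),
    train = list(patch = 12L, base_width = 4L, depth = 2L,
                 cycle_epochs = 50L, n_cycles = 3L, n_patches = 4L),
    survival = list(n_patients = 200L, n_noise_features = 30L,
                    censoring_rate = 0.3),
    fairness = list(n_permutations = 200L)
  )
}

#' Validate and normalize a run configuration
#'
#' Checks every field it knows about and returns either a normalized
#' `run_config` (defaults filled in from [demo_config()]) or, when the
#' configuration is invalid, a character vector of all violations found
#' (not just the first), with class `config_errors`.
#'
#' @param config list, or path to a JSON file.
#' @return a `run_config` list, or a `config_errors` character vector.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopf("config must be a list or a JSON file path")
  errors <- character()
  note <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  full <- utils::modifyList(demo_config(seed = config$seed %||% 1L), config)
  chk_num <- function(x, name, lower = -Inf, len = 1L) {
    if (!is.numeric(x) || length(x) != len || any(!is.finite(x))) {
      note("'%s' must be numeric of length %d", name, len)
    } else if (any(x < lower)) {
      note("'%s' must be >= %s", name, lower)
    }
  }
  chk_num(full$seed, "seed")
  chk_num(full$phantom$n_images, "phantom$n_images", lower = 1)
  chk_num(full$phantom$grid_shape, "phantom$grid_shape", lower = 8, len = 3L)
  chk_num(full$phantom$n_members, "phantom$n_members", lower = 2)
  if (is.numeric(full$phantom$fp_member_fraction) &&
      length(full$phantom$fp_member_fraction) == 1L) {
    if (full$phantom$fp_member_fraction <= 0 ||
        full$phantom$fp_member_fraction > 1) {
      note("'phantom$fp_member_fraction' must be in (0, 1]")
    }
  } else {
    note("'phantom$fp_member_fraction' must be a numeric scalar")
  }
  chk_num(full$preprocess$target_spacing, "preprocess$target_spacing",
          lower = 1e-6, len = 3L)
  chk_num(full$preprocess$crop_extent, "preprocess$crop_extent", lower = 1,
          len = 3L)
  chk_num(full$train$cycle_epochs, "train$cycle_epochs", lower = 1)
  chk_num(full$train$n_cycles, "train$n_cycles", lower = 1)
  chk_num(full$survival$n_patients, "survival$n_patients", lower = 10)
  if (is.numeric(full$survival$censoring_rate) &&
      length(full$survival$censoring_rate) == 1L) {
    if (full$survival$censoring_rate < 0 || full$survival$censoring_rate >= 1) {
      note("'survival$censoring_rate' must be in [0, 1)")
    }
  } else {
    note("'survival$censoring_rate' must be a numeric scalar")
  }
  chk_num(full$fairness$n_permutations, "fairness$n_permutations", lower = 1)
  if (length(errors)) {
    return(structure(errors, class = "config_errors"))
  }
  full$seed <- as.integer(full$seed)
  structure(full, class = "run_config")
}

stage_seed <- function(config, stage) {
  offsets <- c(phantom = 101L, preprocess = 202L, train = 303L,
               posterior = 404L, fp_reduce = 505L, seg_eval = 606L,
               radiomics = 707L, survival = 808L, fairness = 909L)
  (config$seed * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the end-to-end demo pipeline
#'
#' Executes the enabled stages in dependency order, writing per-stage
#' artifacts (CSV/JSON/NIfTI) under the run directory plus a manifest
#' recording the configuration, per-stage seeds, outputs and their MD5
#' checksums. Re-running with the same config and seeds reproduces the
#' artifacts bit for bit. Completed stages (manifest present and outputs
#' intact) are skipped unless `force = TRUE`.
#'
#' @param config a `run_config` from [validate_config()] (or a raw list,
#'   validated on entry).
#' @param force re-run stages whose outputs already exist.
#' @return the run directory, invisibly; the manifest is
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (!inherits(config, "run_config")) {
    config <- validate_config(config)
    if (inherits(config, "config_errors")) {
      stopf("invalid config:\n%s", paste("-", config, collapse = "\n"))
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!force && file.exists(manifest_path)) {
    prev <- tryCatch(jsonlite::read_json(manifest_path),
                     error = function(e) NULL)
    outs <- unlist(lapply(prev$stages %||% list(), `[[`, "outputs"))
    if (length(outs) && all(file.exists(file.path(out_dir, outs)))) {
      return(invisible(out_dir))
    }
  }
  manifest <- list(config = unclass(config), stages = list())
  timings <- list()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    t0 <- Sys.time()
    outputs <- fun()
    timings[[name]] <<- round(as.numeric(
      difftime(Sys.time(), t0, units = "secs")), 3)
    files <- unlist(outputs, use.names = FALSE)
    sums <- unname(tools::md5sum(files[file.exists(files)]))
    # note: no wall-clock data in the manifest; it must be byte-identical
    # across repeated runs with the same config
    manifest$stages[[name]] <<- list(
      seed = stage_seed(config, name),
      outputs = basename(files),
      md5 = sums)
    invisible(NULL)
  }

  run_stage("phantom", function() {
    seed <- stage_seed(config, "phantom")
    pc <- config$phantom
    cohort <- lapply(seq_len(pc$n_images), function(i) {
      cfg <- phantom_config(grid_shape = pc$grid_shape,
                            n_tumours = pc$n_tumours, n_nodes = pc$n_nodes,
                            lesion_volume_range = pc$lesion_volume_range,
                            seed = seed + i)
      ph <- generate_phantom(cfg)
      ec <- ensemble_config(
        n_members = pc$n_members, boundary_jitter = pc$boundary_jitter,
        fp_blobs = list(list(class = "GTVn", volume = pc$fp_volume,
                             member_fraction = pc$fp_member_fraction)),
        seed = seed + 1000L + i)
      ph$ensemble <- simulate_ensemble(ph$mask, ec)
      ph
    })
    state$cohort <- cohort
    files <- character()
    for (i in seq_along(cohort)) {
      f_mask <- file.path(out_dir, sprintf("phantom_%02d_mask.nii.gz", i))
      write_nifti(cohort[[i]]$mask, f_mask, datatype = "uint8")
      files <- c(files, f_mask)
    }
    f_cat <- file.path(out_dir, "phantom_catalog.csv")
    cat_all <- do.call(rbind, lapply(seq_along(cohort), function(i) {
      cbind(image = i, cohort[[i]]$catalog)
    }))
    write.csv(cat_all, f_cat, row.names = FALSE)
    c(files, f_cat)
  })

  run_stage("preprocess", function() {
    ph <- state$cohort[[1L]]
    pp <- preprocess_pair(ph$ct, ph$pet, ph$mask,
                          target_spacing = config$preprocess$target_spacing,
                          extent = config$preprocess$crop_extent)
    f_ct <- file.path(out_dir, "preprocessed_ct.nii.gz")
    f_pet <- file.path(out_dir, "preprocessed_pet.nii.gz")
    f_json <- file.path(out_dir, "preprocess_sidecar.json")
    write_nifti(pp$ct, f_ct)
    write_nifti(pp$pet, f_pet)
    write_json_out(list(
      crop_centre = pp$region$centre, top_slice = pp$region$top_slice,
      extent = pp$region$extent, start = pp$region$start,
      otsu_threshold = pp$region$threshold,
      ct_clip = as.numeric(attr(pp$ct, "clip_bounds") %||% NA)), f_json)
    state$preprocessed <- pp
    c(f_ct, f_pet, f_json)
  })

  run_stage("train", function() {
    seed <- stage_seed(config, "train")
    tc <- config$train
    sched <- cycle_schedule(tc$cycle_epochs * tc$n_cycles, tc$n_cycles)
    patch_cfg <- phantom_config(grid_shape = rep(tc$patch, 3L),
                                spacing = c(1, 1, 1), n_tumours = 1L,
                                n_nodes = 1L,
                                lesion_volume_range = c(30, 150),
                                plant_brain = FALSE, seed = seed)
    patches <- lapply(seq_len(tc$n_patches), function(i) {
      cfg <- patch_cfg; cfg$seed <- as.integer(seed + i)
      ph <- generate_phantom(cfg)
      x <- array(0, dim = c(dim(ph$ct), 2L))
      x[, , , 1] <- normalize_ct(ph$ct)
      x[, , , 2] <- normalize_pet(ph$pet)
      list(x = x, y = ph$mask)
    })
    net <- build_network(net_config(depth = tc$depth, base_width = tc$base_width,
                                    patch_size = rep(tc$patch, 3L)),
                         seed = seed)
    fit <- train_toy(net, patches, sched,
                     ckpt_epochs = checkpoint_epochs(sched, seed = seed),
                     seed = seed)
    state$fit <- fit
    state$train_patches <- patches
    f_loss <- file.path(out_dir, "train_loss.csv")
    write.csv(data.frame(epoch = seq_along(fit$loss) - 1L, loss = fit$loss),
              f_loss, row.names = FALSE)
    f_manifest <- file.path(out_dir, "checkpoints.json")
    write_json_out(lapply(fit$checkpoints, function(ck) {
      list(cycle = ck$cycle, epoch = ck$epoch)
    }), f_manifest)
    c(f_loss, f_manifest)
  })

  run_stage("posterior", function() {
    seed <- stage_seed(config, "posterior")
    tc <- config$train
    cfg <- phantom_config(grid_shape = rep(tc$patch, 3L), spacing = c(1, 1, 1),
                          n_tumours = 1L, n_nodes = 1L,
                          lesion_volume_range = c(30, 150),
                          plant_brain = FALSE, seed = seed)
    ph <- generate_phantom(cfg)
    x <- array(0, dim = c(dim(ph$ct), 2L))
    x[, , , 1] <- normalize_ct(ph$ct)
    x[, , , 2] <- normalize_pet(ph$pet)
    ens <- ensemble_predict(state$fit$network, state$fit$checkpoints, x)
    pm <- posterior_mean(ens)
    um <- uncertainty_map(ens)
    f_mean <- file.path(out_dir, "posterior_mean_gtvp.nii.gz")
    f_unc <- file.path(out_dir, "uncertainty_gtvp.nii.gz")
    write_nifti(pm[, , , 2], f_mean)
    write_nifti(um$GTVp, f_unc)
    state$held_out <- list(phantom = ph, ensemble = ens)
    c(f_mean, f_unc)
  })

  run_stage("fp_reduce", function() {
    cohort <- lapply(state$cohort, function(ph) {
      pred_mask <- ensemble_prediction_mask(ph$ensemble)
      list(pred = extract_lesions(pred_mask),
           gt = extract_lesions(ph$mask),
           map = uncertainty_map(ph$ensemble))
    })
    curve <- sweep_operating_curve(cohort)
    state$fp_cohort <- cohort
    f <- file.path(out_dir, "operating_curve.csv")
    write.csv(curve, f, row.names = FALSE)
    f
  })

  run_stage("seg_eval", function() {
    preds <- lapply(state$cohort, function(ph) {
      pm <- posterior_mean(ph$ensemble)
      # ties.method must be deterministic: boundary voxels can tie exactly
      array(max.col(matrix(pm, prod(dim(ph$mask)), 3L),
                    ties.method = "first") - 1L,
            dim = dim(ph$mask))
    })
    gts <- lapply(state$cohort, `[[`, "mask")
    report <- list()
    for (cls in 1:2) {
      nm <- names(LESION_CLASSES)[cls]
      report[[paste0("dsc_agg_", nm)]] <- aggregated_dice(
        lapply(preds, function(p) p == cls), lapply(gts, function(g) g == cls))
    }
    matches <- lapply(seq_along(preds), function(i) {
      pm <- preds[[i]]
      storage.mode(pm) <- "integer"
      match_lesions(extract_lesions(pm), extract_lesions(gts[[i]]))
    })
    sens <- detection_sensitivity(matches)
    fpi <- false_positives_per_image(matches)
    report$sensitivity <- as.list(sens)
    report$fpi <- as.list(fpi)
    f <- file.path(out_dir, "seg_report.json")
    write_json_out(report, f)
    f
  })

  run_stage("radiomics", function() {
    patients <- lapply(seq_along(state$cohort), function(i) {
      ph <- state$cohort[[i]]
      list(ct = ph$ct, pet = ph$pet, mask = ph$mask,
           patient_id = sprintf("P%04d", i))
    })
    tab <- assemble_feature_table(patients)
    state$radiomics <- tab
    f <- file.path(out_dir, "radiomics_features.csv")
    write.csv(tab, f, row.names = FALSE)
    f
  })

  run_stage("survival", function() {
    seed <- stage_seed(config, "survival")
    sc <- config$survival
    cohort <- generate_survival_cohort(survival_cohort_config(
      n_patients = sc$n_patients, n_noise_features = sc$n_noise_features,
      censoring_rate = sc$censoring_rate, seed = seed))
    num_cols <- names(cohort$features)[vapply(cohort$features, is.numeric, TRUE)]
    ranked <- univariate_rank(cohort$features[num_cols], cohort$survival, k = 10L)
    sel <- forward_aggregate(ranked, cohort$features, cohort$survival,
                             config = list(n_rounds = 40L), folds = 3L,
                             seed = seed)
    model <- fit_survival_model(cohort$features[sel$selected], cohort$survival,
                                seed = seed)
    groups <- stratify_risk(model$risk)
    km <- lapply(levels(groups), function(g) {
      km_estimate(cohort$survival[groups == g, , drop = FALSE])
    })
    names(km) <- levels(groups)
    lr_lm <- logrank_test(cohort$survival[groups == "low", ],
                          cohort$survival[groups == "medium", ])
    lr_mh <- logrank_test(cohort$survival[groups == "medium", ],
                          cohort$survival[groups == "high", ])
    state$surv <- list(cohort = cohort, model = model, groups = groups,
                       selected = sel$selected)
    f_sel <- file.path(out_dir, "survival_model.json")
    write_json_out(list(
      ranked = ranked, selected = sel$selected,
      cv_cindex = sel$cv_cindex,
      train_cindex = harrell_c(model$risk, cohort$survival),
      cut_points = model$cut_points,
      group_sizes = as.list(table(groups)),
      logrank_low_vs_medium = lr_lm[c("statistic", "p")],
      logrank_medium_vs_high = lr_mh[c("statistic", "p")]), f_sel)
    f_km <- file.path(out_dir, "km_curves.csv")
    km_tab <- do.call(rbind, lapply(names(km), function(g) {
      if (!nrow(km[[g]])) return(NULL)
      cbind(group = g, as.data.frame(km[[g]]))
    }))
    write.csv(km_tab, f_km, row.names = FALSE)
    f_risk <- file.path(out_dir, "risk_scores.csv")
    write.csv(data.frame(patient_id = cohort$features$patient_id,
                         risk = model$risk, group = as.character(groups)),
              f_risk, row.names = FALSE)
    c(f_sel, f_km, f_risk)
  })

  run_stage("fairness", function() {
    seed <- stage_seed(config, "fairness")
    sv <- state$surv
    cohort <- sv$cohort
    units <- lapply(seq_len(nrow(cohort$survival)), function(i) {
      list(risk = sv$model$risk[i], time = cohort$survival$time[i],
           event = cohort$survival$event[i])
    })
    cindex_fn <- function(u) {
      harrell_c(vapply(u, `[[`, 0, "risk"),
                data.frame(time = vapply(u, `[[`, 0, "time"),
                           event = vapply(u, `[[`, 0, "event")))
    }
    report <- fairness_report(cohort$features,
                              c("gender", "chemotherapy", "hpv", "age"))
    perm <- list()
    for (v in c("gender", "chemotherapy")) {
      groups <- slice_subgroups(cohort$features, v)
      for (g in names(groups)) {
        idx <- groups[[g]]
        if (length(idx) < 10 || length(idx) > length(units) - 10) next
        pt <- permutation_test_metric(
          units, idx, cindex_fn,
          n_permutations = config$fairness$n_permutations,
          seed = seed + length(perm))
        perm[[paste(v, g, sep = ":")]] <- list(
          p = pt$p, observed = pt$observed, n = length(idx))
      }
    }
    explain_rows <- seq_len(min(40L, nrow(cohort$features)))
    shap <- shapley_global_summary(
      sv$model, cohort$features[explain_rows, sv$selected, drop = FALSE],
      n_background = 25L, seed = seed)
    f_rep <- file.path(out_dir, "fairness_report.csv")
    write.csv(report, f_rep, row.names = FALSE)
    f_perm <- file.path(out_dir, "fairness_permutation.json")
    write_json_out(perm, f_perm)
    f_shap <- file.path(out_dir, "shap_ranking.csv")
    write.csv(shap$ranking, f_shap, row.names = FALSE)
    c(f_rep, f_perm, f_shap)
  })

  write_json_out(manifest, manifest_path)
  write_json_out(timings, file.path(out_dir, "timings.json"))
  invisible(out_dir)
}
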