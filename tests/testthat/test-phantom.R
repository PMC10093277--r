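test_that("phantom generation honours counts, determinism and the catalog", {
  cfg0 <- phantom_config(n_tumours = 0L, n_nodes = 0L, plant_brain = FALSE,
                         seed = 1L)
  ph0 <- generate_phantom(cfg0)
  expect_true(all(ph0$mask == 0L))

  cfg <- phantom_config(n_tumours = 2L, n_nodes = 3L, seed = 21L,
                        grid_shape = c(56L, 56L, 56L))
  ph <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph$ct, ph2$ct)
  expect_identical(ph$pet, ph2$pet)
  expect_identical(ph$mask, ph2$mask)

  ls <- extract_lesions(ph$mask)
  cls <- vapply(ls$lesions, `[[`, "", "class")
  expect_equal(sum(cls == "GTVp"), 2L)
  expect_equal(sum(cls == "GTVn"), 3L)

  # catalog records voxel-count-consistent volumes
  expect_equal(sum(ph$catalog$n_voxels), sum(ph$mask > 0))
  expect_equal(ph$catalog$volume_mm3,
               ph$catalog$n_voxels * prod(cfg$spacing))

  # intensity model: lesions are brighter than background in both modalities
  les <- ph$mask > 0
  expect_gt(mean(ph$ct[les]), mean(ph$ct[!les & !seq_along(ph$ct) %in% ph$brain_voxels]))
  expect_gt(mean(ph$pet[ph$mask == 1L]), mean(ph$pet[ph$mask == 0L]))

  # impossible placements error out
  too_many <- phantom_config(grid_shape = c(16L, 16L, 16L), n_tumours = 40L,
                             lesion_volume_range = c(400, 800), seed = 1L)
  expect_error(generate_phantom(too_many), "could not place")
})

test_that("ensemble simulation matches its membership contract", {
  ph <- generate_phantom(phantom_config(seed = 31L, plant_brain = FALSE,
                                        grid_shape = c(32L, 32L, 32L),
                                        spacing = c(1, 1, 1),
                                        lesion_volume_range = c(150, 600)))
  # no disagreement: all members identical, variance zero everywhere
  ens0 <- simulate_ensemble(ph$mask, ensemble_config(
    n_members = 5L, boundary_jitter = 0L, seed = 2L))
  for (m in 2:5) expect_identical(ens0$prob[, , , , m], ens0$prob[, , , , 1])
  um0 <- uncertainty_map(ens0)
  expect_true(all(um0$GTVp == 0) && all(um0$GTVn == 0))

  # fp blob with member_fraction 0.5 of 30 appears in exactly 15 members
  ens <- simulate_ensemble(ph$mask, ensemble_config(
    n_members = 30L, boundary_jitter = 0L,
    fp_blobs = list(list(class = "GTVn", volume = 300,
                         member_fraction = 0.5)),
    seed = 3L))
  blob <- attr(ens, "fp_blobs")[[1]]
  present <- vapply(seq_len(30), function(m) {
    any(ens$prob[, , , 3, m][blob$voxels] == 1)
  }, TRUE)
  expect_equal(sum(present), 15L)
  expect_identical(which(present), as.integer(blob$members))

  # per-voxel probabilities sum to 1 for every member
  sums <- apply(ens$prob, 5, function(p) {
    max(abs(rowSums(matrix(p, prod(dim(ph$mask)), 3)) - 1))
  })
  expect_true(all(sums < 1e-6))

  # variance inside the partial-member fp blob exceeds the true-lesion
  # interior (full membership, jittered boundary only)
  ens_j <- simulate_ensemble(ph$mask, ensemble_config(
    n_members = 30L, boundary_jitter = 1L,
    fp_blobs = list(list(class = "GTVn", volume = 300,
                         member_fraction = 0.4)),
    seed = 4L))
  um <- uncertainty_map(ens_j)
  blob <- attr(ens_j, "fp_blobs")[[1]]
  interior <- petuq:::erode_indices(which(ph$mask > 0), dim(ph$mask), 1L)
  v_all <- um$GTVp + um$GTVn
  expect_gt(mean(v_all[blob$voxels]), mean(v_all[interior]))

  # determinism
  ens_j2 <- simulate_ensemble(ph$mask, ensemble_config(
    n_members = 30L, boundary_jitter = 1L,
    fp_blobs = list(list(class = "GTVn", volume = 300,
                         member_fraction = 0.4)),
    seed = 4L))
  expect_identical(ens_j$prob, ens_j2$prob)
})

test_that("survival cohorts respect censoring, shape and planted signal", {
  cfg0 <- survival_cohort_config(n_patients = 120L, censoring_rate = 0,
                                 seed = 5L)
  co0 <- generate_survival_cohort(cfg0)
  expect_true(all(co0$survival$event == 1L))
  expect_true(all(co0$survival$time > 0))

  co <- generate_survival_cohort(survival_cohort_config(
    n_patients = 300L, seed = 6L))
  expect_equal(nrow(co$features), 300L)
  expect_equal(nrow(co$survival), 300L)
  expect_identical(co$features$patient_id, co$survival$patient_id)

  big <- generate_survival_cohort(survival_cohort_config(
    n_patients = 500L, informative_features = c(planted_1 = 1.0), seed = 7L))
  expect_gt(harrell_c(big$features$planted_1, big$survival), 0.5)
  # censoring rate lands near its target in a 500-patient draw
  expect_lt(abs(mean(1 - big$survival$event) - 0.3), 0.08)
})

test_that("planted-signal concordance does not decrease with the coefficient", {
  coefs <- c(0.3, 0.8, 1.5)
  mean_c <- vapply(coefs, function(b) {
    cs <- vapply(1:10, function(s) {
      co <- generate_survival_cohort(survival_cohort_config(
        n_patients = 500L, n_noise_features = 0L,
        informative_features = c(planted_1 = b), seed = 100L + s))
      harrell_c(co$features$planted_1, co$survival)
    }, 0)
    mean(cs)
  }, 0)
  expect_true(all(diff(mean_c) > 0))
})
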