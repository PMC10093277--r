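test_that("connected components split by class and connectivity", {
  d <- c(10L, 10L, 6L)
  expect_length(extract_lesions(empty_mask(d))$lesions, 0L)

  m <- empty_mask(d)
  m <- paint_box(m, c(1, 1, 1), c(2, 2, 2), 1L)
  m <- paint_box(m, c(6, 6, 4), c(7, 7, 5), 1L)
  ls <- extract_lesions(m)
  expect_length(ls$lesions, 2L)
  expect_true(all(vapply(ls$lesions, `[[`, "", "class") == "GTVp"))

  # touching blobs of different classes stay separate lesions
  m2 <- empty_mask(d)
  m2 <- paint_box(m2, c(1, 1, 1), c(2, 2, 2), 1L)
  m2 <- paint_box(m2, c(3, 1, 1), c(4, 2, 2), 2L)
  expect_length(extract_lesions(m2)$lesions, 2L)

  # diagonal-touching pair: one component under 26-connectivity, two under 6
  m3 <- empty_mask(c(3L, 3L, 1L))
  m3[1, 1, 1] <- 1L
  m3[2, 2, 1] <- 1L
  expect_length(extract_lesions(m3, connectivity = 26L)$lesions, 1L)
  expect_length(extract_lesions(m3, connectivity = 6L)$lesions, 2L)

  # volume bookkeeping uses the voxel volume
  m4 <- empty_mask(d, spacing = c(1, 1, 3))
  m4 <- paint_box(m4, c(1, 1, 1), c(2, 2, 2), 2L)
  l <- extract_lesions(m4)$lesions[[1]]
  expect_equal(l$volume, 8 * 3)
})

test_that("uncertainty density is the lesion-mean of the class channel", {
  d <- c(6L, 6L, 4L)
  m <- empty_mask(d)
  m <- paint_box(m, c(2, 2, 2), c(4, 4, 3), 1L)
  ls <- extract_lesions(m)
  flat <- array(0.2, dim = d)
  map <- structure(list(GTVp = flat, GTVn = flat * 0), class = "uncertainty_map")
  expect_equal(uncertainty_density(ls$lesions[[1]], map), 0.2)
  zero <- structure(list(GTVp = flat * 0, GTVn = flat * 0),
                    class = "uncertainty_map")
  expect_equal(uncertainty_density(ls$lesions[[1]], zero), 0)

  # 3-voxel lesion with channel values {0.1, 0.2, 0.3} -> 0.2
  m3 <- empty_mask(d)
  m3[1:3] <- 1L
  l3 <- extract_lesions(m3)$lesions[[1]]
  ch <- array(0, dim = d); ch[1:3] <- c(0.1, 0.2, 0.3)
  map3 <- structure(list(GTVp = ch, GTVn = ch * 0), class = "uncertainty_map")
  expect_equal(uncertainty_density(l3, map3), 0.2)
})

test_that("detection matching applies the DSC > 0.1 rule per class", {
  d <- c(12L, 12L, 6L)
  gt <- paint_box(empty_mask(d), c(2, 2, 2), c(5, 5, 4), 1L)
  m <- match_lesions(extract_lesions(gt), extract_lesions(gt))
  expect_equal(m$counts[m$counts$class == "GTVp", c("tp", "fp", "fn")],
               data.frame(tp = 1L, fp = 0L, fn = 0L), ignore_attr = TRUE)

  pred <- paint_box(empty_mask(d), c(8, 8, 1), c(10, 10, 2), 1L)
  m2 <- match_lesions(extract_lesions(pred), extract_lesions(gt))
  expect_equal(m2$counts[m2$counts$class == "GTVp", c("tp", "fp", "fn")],
               data.frame(tp = 0L, fp = 1L, fn = 1L), ignore_attr = TRUE)

  # constructed overlap below/above the threshold:
  # gt 38 voxels, pred 38 voxels, overlap 1 -> DSC = 2/76 ~ 0.026 < 0.1
  gt3 <- empty_mask(d); gt3[1:38] <- 1L
  pr3 <- empty_mask(d); pr3[38:75] <- 1L
  m3 <- match_lesions(extract_lesions(pr3), extract_lesions(gt3))
  expect_equal(m3$counts$fn[m3$counts$class == "GTVp"], 1L)
  # overlap 19 of 38+38 -> DSC 0.5 > 0.1
  pr4 <- empty_mask(d); pr4[20:57] <- 1L
  m4 <- match_lesions(extract_lesions(pr4), extract_lesions(gt3))
  expect_equal(m4$counts$tp[m4$counts$class == "GTVp"], 1L)
  expect_equal(max(m4$pairs$dsc), 0.5)
})

test_that("matching agrees with the brute-force all-pairs oracle", {
  for (seed in 1:40) {
    pred <- random_mask(seed = seed * 2L)
    gt <- random_mask(seed = seed * 2L + 1L)
    m <- match_lesions(extract_lesions(pred), extract_lesions(gt))
    o <- oracle_match_counts(pred, gt)
    expect_equal(m$counts$tp, o$tp)
    expect_equal(m$counts$fp, o$fp)
    expect_equal(m$counts$fn, o$fn)
  }
})

test_that("uncertainty filtering is a monotone subset operation", {
  cohort <- make_uq_cohort(2, seed = 5)
  img <- cohort[[1]]
  ann <- annotate_uncertainty(img$pred, img$map)
  dens <- vapply(ann$lesions, `[[`, 0, "t_uncertain")
  keep_all <- filter_by_uncertainty(img$pred, img$map, max(dens))
  expect_length(keep_all$lesions, length(ann$lesions))
  if (all(dens > 0)) {
    none <- filter_by_uncertainty(img$pred, img$map, 0)
    expect_length(none$lesions, 0L)
  }
  # subset property across thresholds
  ths <- sort(runif(5, 0, 0.3))
  kept <- lapply(ths, function(th) {
    ids <- vapply(filter_by_uncertainty(img$pred, img$map, th)$lesions,
                  `[[`, "", "id")
    ids
  })
  for (i in seq_len(length(ths) - 1)) {
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  }
})

test_that("operating-curve sweep has 21 points, monotone, inert at 0.5", {
  cohort <- make_uq_cohort(3, seed = 9)
  curve <- sweep_operating_curve(cohort)
  expect_equal(length(unique(curve$threshold)), 21L)
  expect_equal(sort(unique(curve$threshold)), seq(0, 0.5, by = 0.025))
  for (cls in unique(curve$class)) {
    sub <- curve[curve$class == cls, ]
    sub <- sub[order(sub$threshold), ]
    expect_true(all(diff(sub$fpi) >= 0))
    tprs <- sub$tpr[!is.na(sub$tpr)]
    expect_true(all(diff(tprs) >= 0))
  }
  # densities are bounded by 0.25, so threshold 0.5 equals no filtering
  unfiltered <- lapply(cohort, function(img) match_lesions(img$pred, img$gt))
  fpi_un <- false_positives_per_image(unfiltered, length(cohort))
  sens_un <- detection_sensitivity(unfiltered)
  at_half <- curve[curve$threshold == 0.5, ]
  for (cls in names(fpi_un)) {
    expect_equal(at_half$fpi[at_half$class == cls], unname(fpi_un[cls]))
    expect_equal(at_half$tpr[at_half$class == cls], unname(sens_un[cls]))
  }
})
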