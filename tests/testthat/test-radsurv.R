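test_that("ROI construction covers the five region types", {
  d <- c(14L, 14L, 8L)
  m <- empty_mask(d)
  m <- paint_box(m, c(1, 1, 1), c(2, 2, 2), 1L)       # tumour, 8 voxels
  m <- paint_box(m, c(5, 5, 1), c(8, 8, 2), 1L)       # tumour, 32 voxels
  m <- paint_box(m, c(11, 11, 5), c(12, 12, 6), 2L)   # node, 8 voxels
  lesions <- extract_lesions(m)

  roi_all <- build_roi(m, roi_spec("CT", "all"), lesions)
  expect_equal(sum(roi_all), 48L)
  roi_t <- build_roi(m, roi_spec("CT", "only_tumour"), lesions)
  roi_l <- build_roi(m, roi_spec("PET", "only_lymph"), lesions)
  expect_equal(sum(roi_t), 40L)
  expect_equal(sum(roi_l), 8L)
  # classes partition the union
  expect_equal(sum(roi_t & roi_l), 0L)
  expect_equal(sum(roi_t | roi_l), sum(roi_all))

  roi_lt <- build_roi(m, roi_spec("CT", "largest_tumour"), lesions)
  expect_equal(sum(roi_lt), 32L)

  # degenerate equalities with a single tumour and no nodes
  m1 <- paint_box(empty_mask(d), c(4, 4, 4), c(6, 6, 6), 1L)
  l1 <- extract_lesions(m1)
  expect_equal(build_roi(m1, roi_spec("CT", "only_tumour"), l1),
               build_roi(m1, roi_spec("CT", "largest_tumour"), l1))
  expect_equal(build_roi(m1, roi_spec("CT", "only_tumour"), l1),
               build_roi(m1, roi_spec("CT", "all"), l1))
  # empty region signal
  expect_null(build_roi(m1, roi_spec("CT", "largest_lymph"), l1))
})

test_that("volume features follow the catalog arithmetic", {
  d <- c(14L, 14L, 8L)
  expect_equal(unname(volume_features(extract_lesions(empty_mask(d)))),
               rep(0, 6))
  m <- empty_mask(d, spacing = c(1, 1, 1))
  m <- paint_box(m, c(1, 1, 1), c(2, 5, 1), 1L)   # 10 voxels
  m <- paint_box(m, c(5, 5, 1), c(8, 9, 1), 1L)   # 20 voxels
  vf <- volume_features(extract_lesions(m))
  expect_equal(unname(vf["total_tumour_volume"]), 30)
  expect_equal(unname(vf["largest_tumour_volume"]), 20)
  expect_equal(unname(vf["n_tumours"]), 2)

  ph <- generate_phantom(phantom_config(seed = 41L, n_tumours = 2L,
                                        n_nodes = 1L))
  vf2 <- volume_features(extract_lesions(ph$mask))
  cat_t <- ph$catalog[ph$catalog$class == "GTVp", ]
  expect_equal(unname(vf2["total_tumour_volume"]), sum(cat_t$volume_mm3))
  expect_equal(unname(vf2["largest_tumour_volume"]), max(cat_t$volume_mm3))
})

test_that("imputation leaves no NA and flags missingness", {
  df <- data.frame(a = c(1, NA, 3), b = c("x", NA, "y"), c = 4:6)
  out <- impute_features(df)
  expect_false(anyNA(out))
  expect_equal(out$a, c(1, 2, 3))
  expect_equal(out$a_missing, c(0L, 1L, 0L))
  expect_equal(out$b, c("x", "NA", "y"))
  expect_false("c_missing" %in% colnames(out))
})

test_that("Harrell's C matches hand cases and the pair oracle", {
  surv <- data.frame(time = c(5, 4, 3, 2, 1), event = 1L)
  expect_equal(harrell_c(1:5, surv), 1)
  expect_equal(harrell_c(rep(2, 5), surv), 0.5)

  toy <- data.frame(time = c(2, 4, 4, 7, 9), event = c(1L, 0L, 1L, 1L, 0L))
  risk <- c(3.0, 1.0, 2.5, 2.5, 0.5)
  expect_equal(harrell_c(risk, toy),
               oracle_harrell_c(risk, toy$time, toy$event))

  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:50, 1)
    time <- sample(1:20, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    risk <- sample(1:10, n, replace = TRUE)  # ties on purpose
    o <- oracle_harrell_c(risk, time, event)
    if (is.na(o)) {
      expect_error(harrell_c(risk, data.frame(time = time, event = event)),
                   "comparable")
    } else {
      expect_equal(harrell_c(risk, data.frame(time = time, event = event)), o)
    }
  }
})

test_that("univariate ranking orders by C with deterministic ties", {
  co <- generate_survival_cohort(survival_cohort_config(
    n_patients = 250L, n_noise_features = 5L,
    informative_features = c(planted_1 = 1.2), seed = 51L))
  num <- co$features[vapply(co$features, is.numeric, TRUE)]
  r <- univariate_rank(num, co$survival, k = 3L)
  expect_equal(r$feature[1], "planted_1")
  expect_true(all(diff(r$cindex) <= 0))

  # k beyond the candidate count returns everything ranked
  r_all <- univariate_rank(num[, 1:3], co$survival, k = 10L)
  expect_equal(nrow(r_all), 3L)

  # duplicated columns tie and sort lexicographically
  dup <- data.frame(b_copy = num$planted_1, a_copy = num$planted_1)
  r_dup <- univariate_rank(dup, co$survival, k = 2L)
  expect_equal(r_dup$cindex[1], r_dup$cindex[2])
  expect_equal(r_dup$feature, c("a_copy", "b_copy"))
})

test_that("forward aggregation keeps the best prefix", {
  co <- generate_survival_cohort(survival_cohort_config(
    n_patients = 250L, n_noise_features = 9L,
    informative_features = c(planted_1 = 1.2), seed = 52L))
  ranked <- c("planted_1", sprintf("noise_%03d", 1:9))
  sel <- forward_aggregate(ranked, co$features, co$survival,
                           config = list(n_rounds = 30L), folds = 3L,
                           seed = 1L)
  expect_true("planted_1" %in% sel$selected)
  expect_gte(sel$cv_cindex[sel$best_prefix], sel$cv_cindex[1])

  one <- forward_aggregate("planted_1", co$features, co$survival,
                           config = list(n_rounds = 10L), folds = 3L, seed = 1L)
  expect_equal(one$selected, "planted_1")
})

test_that("boosted Cox model is seeded-deterministic and rank-consistent", {
  co <- generate_survival_cohort(survival_cohort_config(
    n_patients = 200L, n_noise_features = 2L, seed = 53L))
  X <- co$features[c("planted_1", "planted_2", "planted_3")]
  m1 <- fit_survival_model(X, co$survival, seed = 9L)
  m2 <- fit_survival_model(X, co$survival, seed = 9L)
  expect_identical(m1$risk, m2$risk)

  # C-index is a rank statistic: invariant under strictly increasing maps
  expect_equal(harrell_c(m1$risk, co$survival),
               harrell_c(exp(m1$risk / 2) + 5, co$survival))

  all_cens <- data.frame(time = co$survival$time, event = 0L)
  expect_error(fit_survival_model(X, all_cens, seed = 1L), "no events")
})

test_that("tertile stratification follows the 33/66 percentile rule", {
  g9 <- stratify_risk(as.numeric(1:9))
  expect_equal(unname(table(g9)), array(c(3L, 3L, 3L)), ignore_attr = TRUE)
  expect_equal(as.character(g9), rep(c("low", "medium", "high"), each = 3))

  g_same <- stratify_risk(rep(1.5, 8))
  expect_true(all(g_same == "low"))

  set.seed(4)
  g100 <- stratify_risk(runif(100))
  expect_true(all(table(g100) >= 30 & table(g100) <= 37))

  # cut points from training scores reused on new data
  cuts <- attr(stratify_risk(1:100), "cut_points")
  g_new <- stratify_risk(c(1, 50, 99), cut_points = cuts)
  expect_equal(as.character(g_new), c("low", "medium", "high"))
})

test_that("Kaplan-Meier product-limit matches hand computation and survfit", {
  toy <- data.frame(time = c(1, 2, 3), event = c(1L, 0L, 1L))
  km <- km_estimate(toy)
  expect_equal(km_survival_at(km, 1), 2 / 3)
  expect_equal(km_survival_at(km, 2.5), 2 / 3)
  expect_equal(km_survival_at(km, 3), 0)

  flat <- km_estimate(data.frame(time = c(2, 5, 9), event = 0L))
  expect_equal(nrow(flat), 0L)
  expect_equal(km_survival_at(flat, c(1, 10)), c(1, 1))

  # no censoring: equals the empirical survival function
  tt <- c(3, 1, 4, 1, 5)
  km2 <- km_estimate(data.frame(time = tt, event = 1L))
  expect_equal(km_survival_at(km2, sort(unique(tt))),
               vapply(sort(unique(tt)), function(u) mean(tt > u), 0))

  # oracle: survival::survfit on random censored data
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    df <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.6))
    if (sum(df$event) == 0) next
    km3 <- km_estimate(df)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    at_events <- summary(sf, times = km3$time)
    expect_equal(km3$survival, at_events$surv, tolerance = 1e-12)
    expect_true(all(diff(km3$survival) <= 0))
    expect_true(all(km3$survival >= 0 & km3$survival <= 1))
  }
})

test_that("log-rank reproduces the O-E table and survdiff", {
  a <- data.frame(time = c(1, 3, 5), event = c(1L, 1L, 0L))
  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # hand-worked 6-patient example
  # group A: (1,event), (4,event), (6,cens); group B: (2,event), (5,cens), (7,event)
  ga <- data.frame(time = c(1, 4, 6), event = c(1L, 1L, 0L))
  gb <- data.frame(time = c(2, 5, 7), event = c(1L, 0L, 1L))
  # event times 1,2,4,7; at t=1: nA=3,n=6,d=1 -> E+=0.5, V=0.25
  # t=2: nA=2,n=5 -> E+=0.4, V=0.24; t=4: nA=2,n=4 -> E+=0.5, V=0.25
  # t=7: nA=0,n=1 -> E+=0, V=0; O=2
  lr <- logrank_test(ga, gb)
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 0.5 + 0.4 + 0.5)
  expect_equal(lr$variance, 0.25 + 0.24 + 0.25)
  expect_equal(lr$statistic, (2 - 1.4)^2 / 0.74)

  # oracle: survival::survdiff on random data
  for (seed in 1:10) {
    set.seed(seed)
    df <- data.frame(time = rexp(50, 0.1), event = rbinom(50, 1, 0.7),
                     grp = rep(0:1, 25))
    sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
    mine <- logrank_test(df[df$grp == 0, ], df[df$grp == 1, ])
    expect_equal(mine$statistic, sd_fit$chisq, tolerance = 1e-10)
  }
  expect_error(logrank_test(data.frame(time = 1, event = 0L),
                            data.frame(time = 2, event = 0L)), "no events")
})
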