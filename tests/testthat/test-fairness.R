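test_that("subgroup slicing partitions the cohort", {
  set.seed(8)
  n <- 488L
  cohort <- data.frame(
    age = runif(n, 30, 85),
    gender = sample(c("M", "F"), n, TRUE),
    hpv = sample(c("positive", "negative", NA), n, TRUE),
    tumour_size = rexp(n, 0.1) + runif(n, 0, 1e-6)  # effectively distinct
  )
  # quartile bookkeeping: 4 bins of 122 = 25%
  qs <- slice_subgroups(cohort, "tumour_size")
  expect_equal(unname(lengths(qs)), rep(122L, 4L))
  expect_equal(sort(unlist(qs)), seq_len(n), ignore_attr = TRUE)

  # binary variable: two bins summing to n
  gs <- slice_subgroups(cohort, "gender")
  expect_length(gs, 2L)
  expect_equal(sum(lengths(gs)), n)

  # NA gets its own bin
  hs <- slice_subgroups(cohort, "hpv")
  expect_true("NA" %in% names(hs))
  expect_equal(sum(lengths(hs)), n)

  # age uses the fixed clinical bins
  as_ <- slice_subgroups(cohort, "age")
  expect_equal(names(as_), c("0-50", "50-60", "60-70", ">70"))
  expect_equal(sum(lengths(as_)), n)
  expect_true(all(cohort$age[as_[["0-50"]]] <= 50))
  expect_true(all(cohort$age[as_[[">70"]]] > 70))

  expect_error(slice_subgroups(cohort, "nope"), "unknown variable")
})

test_that("Mann-Whitney matches hand ranks and the stats oracle", {
  # identical samples: no rank separation
  x <- c(1, 2, 3, 4)
  expect_gt(mann_whitney_subgroup(x, x)$p, 0.99)

  # hand-worked 4 vs 4: U = #{(i,j): x_i > y_j} (+0.5 per tie)
  y <- c(1.5, 2.5, 10, 11)
  # pairwise: x=1:0; x=2: >1.5 ->1; x=3: >1.5,2.5 ->2; x=4: ->2; U = 5
  res <- mann_whitney_subgroup(x, y)
  expect_equal(res$U, 5)

  for (seed in 1:20) {
    set.seed(seed)
    a <- sample(1:15, 12, replace = TRUE)  # ties present
    b <- sample(1:15, 9, replace = TRUE)
    mine <- mann_whitney_subgroup(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = FALSE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney_subgroup(numeric(0), 1:3), "non-empty")
})

test_that("permutation test contract: determinism, sign symmetry, errors", {
  set.seed(10)
  units <- as.list(rnorm(24))
  mfn <- function(u) mean(unlist(u))
  idx <- 1:8
  p1 <- permutation_test_metric(units, idx, mfn, n_permutations = 200,
                                seed = 3L)
  p2 <- permutation_test_metric(units, idx, mfn, n_permutations = 200,
                                seed = 3L)
  expect_identical(p1$p, p2$p)
  expect_error(permutation_test_metric(units, idx, mfn, n_permutations = 0),
               ">= 1")
  expect_error(permutation_test_metric(units, seq_along(units), mfn,
                                       n_permutations = 10), "proper subset")

  # relabeling the two groups flips the observed sign and leaves the
  # two-sided p distributionally unchanged
  pa <- permutation_test_metric(units, idx, mfn, n_permutations = 2000,
                                seed = 4L)
  pb <- permutation_test_metric(units, setdiff(seq_along(units), idx), mfn,
                                n_permutations = 2000, seed = 5L)
  expect_equal(pa$observed, -pb$observed)
  expect_lt(abs(pa$p - pb$p), 0.06)

  # undefined metrics on permuted splits are resampled, not fatal
  flaky_units <- as.list(c(1, 2, 3, -1, -2, -3, 5, 6))
  flaky <- function(u) {
    v <- unlist(u)
    if (all(v < 0)) stop("undefined on this split")
    mean(v)
  }
  pf <- permutation_test_metric(flaky_units, 1:3, flaky,
                                n_permutations = 200, seed = 6L)
  expect_true(is.finite(pf$p))
})

test_that("Shapley attributions are exactly additive and rank the signal", {
  co <- generate_survival_cohort(survival_cohort_config(
    n_patients = 150L, n_noise_features = 2L,
    informative_features = c(strong = 2.0, weak = 0.2), seed = 71L))
  X <- co$features[c("strong", "weak", "noise_001")]
  X$flat <- 1  # constant feature
  model <- fit_survival_model(X, co$survival, seed = 2L)
  sh <- shapley_global_summary(model, X, n_background = 30L, seed = 1L)

  # local additivity: attributions + base value = model output
  recon <- rowSums(sh$attributions) + sh$base_value
  expect_lt(max(abs(recon - sh$prediction)), 1e-10)

  # constant feature contributes nothing
  expect_lt(max(abs(sh$attributions[, "flat"])), 1e-12)

  # dominant planted feature ranks first by mean |attribution|
  expect_equal(sh$ranking$feature[1], "strong")
  # and its trend is positive (higher value -> higher risk)
  expect_gt(sh$ranking$sign_trend[sh$ranking$feature == "strong"], 0)

  expect_error(shapley_global_summary(model, X[, 1:2, drop = FALSE]),
               "lack model columns")
})

test_that("fairness report bookkeeping reconciles with the cohort", {
  set.seed(12)
  n <- 60L
  cohort <- data.frame(gender = sample(c("M", "F"), n, TRUE),
                       chemotherapy = sample(c("yes", "no"), n, TRUE))
  dsc <- runif(n)
  rep <- fairness_report(cohort, c("gender", "chemotherapy"),
                         unit_metrics = list(dsc = dsc))
  for (v in unique(rep$variable)) {
    sub <- rep[rep$variable == v, ]
    expect_equal(sum(sub$n), n)
    expect_equal(sum(sub$percent), 100)
  }
  expect_true(all(is.finite(rep$dsc_p)))
})
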