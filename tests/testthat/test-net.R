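test_that("forward pass obeys shape, softmax and attention-range contracts", {
  cfg <- net_config(depth = 2L, base_width = 4L, patch_size = c(16L, 16L, 16L))
  net <- build_network(cfg, seed = 3L)
  x <- array(0, dim = c(16L, 16L, 16L, 2L))
  fw <- net_forward(net, x, keep_cache = TRUE)
  expect_equal(dim(fw$prob), c(16L, 16L, 16L, 3L))
  expect_lt(max(abs(rowSums(matrix(fw$prob, 16^3, 3)) - 1)), 1e-12)
  # deep supervision: one auxiliary output at half resolution
  expect_length(fw$aux, 1L)
  expect_equal(dim(fw$aux[[1]]), c(8L, 8L, 8L, 3L))
  # attention coefficients and SE gates live in (0, 1)
  for (s in 1:2) {
    att <- fw$cache$ga[[s]]$att
    expect_true(all(att > 0 & att < 1))
  }
  se_gate <- fw$cache$enc[[1]]$se$s
  expect_true(all(se_gate > 0 & se_gate < 1))

  # toggles all off: plain U-Net without attention/residual parameters
  plain_cfg <- net_config(depth = 2L, base_width = 4L,
                          patch_size = c(16L, 16L, 16L), residual = FALSE,
                          se = FALSE, grid_attention = FALSE,
                          deep_supervision = FALSE)
  plain <- build_network(plain_cfg, seed = 3L)
  expect_null(plain$params$dec[[1]]$ga)
  expect_null(plain$params$enc[[1]]$se)
  fw_plain <- net_forward(plain, x)
  expect_equal(dim(fw_plain$prob), c(16L, 16L, 16L, 3L))
  expect_length(fw_plain$aux, 0L)

  expect_error(net_config(depth = 3L, patch_size = c(12L, 12L, 12L)),
               "divisible")
})

test_that("dice+CE loss matches closed forms and the brute-force soft Dice", {
  d <- c(6L, 6L, 6L)
  set.seed(5)
  target <- array(sample(0:2, prod(d), TRUE), dim = d)
  onehot <- array(0, dim = c(d, 3L))
  for (k in 0:2) onehot[, , , k + 1] <- as.numeric(target == k)
  expect_lt(as.numeric(dice_ce_loss(onehot, target)), 1e-5)

  uniform <- array(1 / 3, dim = c(d, 3L))
  lu <- dice_ce_loss(uniform, target)
  expect_equal(attr(lu, "ce")[1], log(3))

  # brute-force per-class soft Dice oracle
  raw <- array(runif(prod(d) * 3), dim = c(d, 3L))
  s <- raw[, , , 1] + raw[, , , 2] + raw[, , , 3]
  for (k in 1:3) raw[, , , k] <- raw[, , , k] / s
  eps <- 1e-5
  oracle <- 0
  for (k in 2:3) {
    pk <- raw[, , , k]; yk <- as.numeric(target == (k - 1))
    oracle <- oracle + 1 - (2 * sum(pk * yk) + eps) / (sum(pk) + sum(yk) + eps)
  }
  expect_equal(soft_dice_loss(raw, target), oracle / 2)

  bad <- raw * 1.5
  expect_error(dice_ce_loss(bad, target), "sum to 1")
})

test_that("analytic gradients match finite differences", {
  cfg <- net_config(depth = 1L, base_width = 3L, patch_size = c(8L, 8L, 8L))
  net <- build_network(cfg, seed = 7L)
  set.seed(7)
  x <- array(rnorm(8^3 * 2), dim = c(8L, 8L, 8L, 2L))
  y <- array(sample(0:2, 8^3, TRUE), dim = c(8L, 8L, 8L))
  fw <- net_forward(net, x, keep_cache = TRUE)
  gr <- petuq:::net_backward(net, fw, y)
  loss_at <- function(params) {
    n2 <- net; n2$params <- params
    f <- net_forward(n2, x)
    as.numeric(dice_ce_loss(c(list(f$prob), f$aux), y))
  }
  eps <- 1e-6
  checks <- list(
    list(get = function(p) p$enc[[1]]$W1[2, 7],
         set = function(p, v) { p$enc[[1]]$W1[2, 7] <- v; p },
         g = gr$enc[[1]]$W1[2, 7]),
    list(get = function(p) p$enc[[1]]$Wres[1, 2],
         set = function(p, v) { p$enc[[1]]$Wres[1, 2] <- v; p },
         g = gr$enc[[1]]$Wres[1, 2]),
    list(get = function(p) p$bott$se$W2[3, 1],
         set = function(p, v) { p$bott$se$W2[3, 1] <- v; p },
         g = gr$bott$se$W2[3, 1]),
    list(get = function(p) p$dec[[1]]$ga$Wphi[1, 4],
         set = function(p, v) { p$dec[[1]]$ga$Wphi[1, 4] <- v; p },
         g = gr$dec[[1]]$ga$Wphi[1, 4]),
    list(get = function(p) p$head[[1]]$W[3, 2],
         set = function(p, v) { p$head[[1]]$W[3, 2] <- v; p },
         g = gr$head[[1]]$W[3, 2])
  )
  for (ck in checks) {
    v0 <- ck$get(net$params)
    fd <- (loss_at(ck$set(net$params, v0 + eps)) -
             loss_at(ck$set(net$params, v0 - eps))) / (2 * eps)
    expect_lt(abs(ck$g - fd) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("augmentation honours identity, mirroring and determinism", {
  set.seed(9)
  img <- array(rnorm(8^3 * 2), dim = c(8L, 8L, 8L, 2L))
  lab <- array(sample(0:2, 8^3, TRUE), dim = c(8L, 8L, 8L))

  off <- augment_config(mirror = FALSE, rotate = FALSE, scale = FALSE,
                        elastic = FALSE, noise = FALSE, gamma = FALSE)
  out0 <- augment_patch(img, lab, off, seed = 1L)
  expect_identical(out0$image, img)
  expect_identical(out0$label, lab)

  mir <- augment_config(mirror = TRUE, rotate = FALSE, scale = FALSE,
                        elastic = FALSE, noise = FALSE, gamma = FALSE)
  outm <- augment_patch(img, lab, mir, seed = 2L)
  expect_equal(as.vector(table(outm$label)), as.vector(table(lab)))

  full <- augment_config(elastic = TRUE)
  a1 <- augment_patch(img, lab, full, seed = 5L)
  a2 <- augment_patch(img, lab, full, seed = 5L)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$label, a2$label)
  expect_false(identical(a1$image, img))
  expect_true(all(a1$label %in% 0:2))
})

test_that("a tiny training run reduces the loss and moves checkpoints apart", {
  mkp <- function(seed) {
    ph <- generate_phantom(phantom_config(
      grid_shape = c(8L, 8L, 8L), spacing = c(1, 1, 1), n_tumours = 1L,
      n_nodes = 0L, lesion_volume_range = c(8, 30), plant_brain = FALSE,
      seed = seed))
    x <- array(0, dim = c(8L, 8L, 8L, 2L))
    x[, , , 1] <- (ph$ct - mean(ph$ct)) / sd(ph$ct)
    x[, , , 2] <- normalize_pet(ph$pet)
    list(x = x, y = ph$mask)
  }
  patches <- lapply(1:3, mkp)
  net <- build_network(net_config(depth = 1L, base_width = 3L,
                                  patch_size = c(8L, 8L, 8L)), seed = 1L)
  # zero-epoch schedule: training is a no-op with no checkpoints
  noop <- train_toy(net, patches, cycle_schedule(0L, 1L),
                    ckpt_epochs = integer(0), seed = 1L)
  expect_length(noop$checkpoints, 0L)
  expect_identical(noop$network$params, net$params)
  sched <- cycle_schedule(20L, 1L, gamma = 0.8)
  fit <- train_toy(net, patches, sched,
                   ckpt_epochs = c(17L, 18L, 19L), seed = 2L)
  expect_lt(mean(tail(fit$loss, 5)), mean(head(fit$loss, 5)))
  expect_length(fit$checkpoints, 3L)
  # saved checkpoints differ in parameter space
  d12 <- sum(abs(fit$checkpoints[[1]]$params$enc[[1]]$W1 -
                   fit$checkpoints[[2]]$params$enc[[1]]$W1))
  expect_gt(d12, 0)
  # determinism of the whole training loop
  net_b <- build_network(net_config(depth = 1L, base_width = 3L,
                                    patch_size = c(8L, 8L, 8L)), seed = 1L)
  fit_b <- train_toy(net_b, patches, sched,
                     ckpt_epochs = c(17L, 18L, 19L), seed = 2L)
  expect_identical(fit$loss, fit_b$loss)
  expect_identical(fit$network$params, fit_b$network$params)
  # ensemble prediction over checkpoints yields a valid ensemble
  ens <- ensemble_predict(fit$network, fit$checkpoints, patches[[1]]$x)
  expect_equal(dim(ens$prob)[5], 3L)
  um <- uncertainty_map(ens)
  expect_true(all(um$GTVp >= 0 & um$GTVp <= 0.25 + 1e-12))
})
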