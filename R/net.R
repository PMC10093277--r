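# Toy-scale modified 3D U-Net: residual conv blocks, squeeze-and-excitation
# channel attention, grid attention gates on the skip connections, deep
# supervision with a Dice + cross-entropy loss, trained by SGD with momentum
# under the cyclic learning-rate schedule. Convolution/pooling kernels live
# in src/convnet.cpp; everything 1x1 is a plain matrix product here.

#' Network configuration
#'
#' @param in_channels input channels (2: CT + PET).
#' @param n_classes output classes (3: background / GTVp / GTVn).
#' @param depth encoder depth (number of poolings); patch size must be
#'   divisible by `2^depth`.
#' @param base_width feature channels at full resolution (doubled per level).
#' @param patch_size integer length-3 (toy default 32^3; the full-scale
#'   configuration would be c(192, 192, 64)).
#' @param residual,se,grid_attention,deep_supervision architecture toggles.
#' @param se_reduction squeeze-and-excitation bottleneck ratio (default 2 at
#'   toy widths).
#' @return a `net_config`.
#' @export
net_config <- function(in_channels = 2L, n_classes = 3L, depth = 2L,
                       base_width = 4L, patch_size = c(32L, 32L, 32L),
                       residual = TRUE, se = TRUE, grid_attention = TRUE,
                       deep_supervision = TRUE, se_reduction = 2L) {
  stopifnot(n_classes >= 2, depth >= 1, base_width >= 1,
            length(patch_size) == 3L)
  if (any(patch_size %% (2^depth) != 0)) {
    stopf("patch size must be divisible by 2^depth = %d", 2^depth)
  }
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 patch_size = as.integer(patch_size),
                 residual = isTRUE(residual), se = isTRUE(se),
                 grid_attention = isTRUE(grid_attention),
                 deep_supervision = isTRUE(deep_supervision),
                 se_reduction = as.integer(se_reduction)),
            class = "net_config")
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

init_conv_block <- function(c_in, c_out, cfg) {
  p <- list(
    W1 = he_init(c_out, 27L * c_in, 27L * c_in), b1 = numeric(c_out),
    W2 = he_init(c_out, 27L * c_out, 27L * c_out), b2 = numeric(c_out)
  )
  if (cfg$residual && c_in != c_out) {
    p$Wres <- he_init(c_out, c_in, c_in)
  }
  if (cfg$se) {
    cr <- max(1L, c_out %/% cfg$se_reduction)
    p$se <- list(W1 = he_init(cr, c_out, c_out), b1 = numeric(cr),
                 W2 = he_init(c_out, cr, cr), b2 = numeric(c_out))
  }
  p
}

init_ga <- function(c_skip, c_gate) {
  c_int <- max(1L, c_skip %/% 2L)
  list(Wtheta = he_init(c_int, c_skip, c_skip),
       Wphi = he_init(c_int, c_gate, c_gate), bphi = numeric(c_int),
       Wpsi = he_init(1L, c_int, c_int), bpsi = 0)
}

#' Build the segmentation network
#'
#' Initialises all weights (He initialisation) for the configured
#' architecture. With every toggle off this reduces to a plain U-Net:
#' two-convolution blocks, max-pool downsampling, nearest-neighbour
#' upsampling, plain concatenated skips, softmax head.
#'
#' @param config a [net_config()].
#' @param seed integer seed for weight initialisation.
#' @return a `seg_network` holding the parameter tree and config.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  widths <- config$base_width * 2^(seq_len(config$depth) - 1L)
  bott_width <- config$base_width * 2^config$depth
  with_seed(seed, {
    params <- list(enc = list(), dec = list(), head = list())
    c_prev <- config$in_channels
    for (s in seq_len(config$depth)) {
      params$enc[[s]] <- init_conv_block(c_prev, widths[s], config)
      c_prev <- widths[s]
    }
    params$bott <- init_conv_block(c_prev, bott_width, config)
    for (s in rev(seq_len(config$depth))) {
      c_gate <- if (s == config$depth) bott_width else widths[s + 1L]
      dec <- list(block = init_conv_block(c_gate + widths[s], widths[s], config))
      if (config$grid_attention) dec$ga <- init_ga(widths[s], c_gate)
      params$dec[[s]] <- dec
      params$head[[s]] <- list(W = he_init(config$n_classes, widths[s], widths[s]),
                               b = numeric(config$n_classes))
    }
    structure(list(params = params, config = config, widths = widths,
                   bott_width = bott_width),
              class = "seg_network")
  })
}

#' @export
print.seg_network <- function(x, ...) {
  cfg <- x$config
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf(
    "seg_network: depth %d, widths %s (bottleneck %d), %d -> %d channels, %s parameters\n",
    cfg$depth, paste(x$widths, collapse = "/"), x$bott_width,
    cfg$in_channels, cfg$n_classes, format(np, big.mark = ",")))
  cat(sprintf("  residual=%s SE=%s grid-attention=%s deep-supervision=%s\n",
              cfg$residual, cfg$se, cfg$grid_attention, cfg$deep_supervision))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

# 1x1 convolution: (nx,ny,nz,Cin) x t(W[Cout,Cin]) -> (nx,ny,nz,Cout)
lin1x1 <- function(x, W, b = NULL) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4]) %*% t(W)
  if (!is.null(b)) m <- sweep(m, 2, b, `+`)
  array(m, dim = c(d[1:3], nrow(W)))
}

lin1x1_bw <- function(x, W, dy) {
  d <- dim(x)
  N <- prod(d[1:3])
  dym <- matrix(dy, N, nrow(W))
  xm <- matrix(x, N, d[4])
  list(dx = array(dym %*% W, dim = d),
       dW = t(dym) %*% xm,
       db = colSums(dym))
}

conv_block_fw <- function(x, p, cfg) {
  cache <- list(x = x)
  a1 <- conv3d_fw(x, p$W1, p$b1)
  r1 <- relu(a1)
  cache$a1 <- a1; cache$r1 <- r1
  a2 <- conv3d_fw(r1, p$W2, p$b2)
  if (cfg$residual) {
    skipv <- if (!is.null(p$Wres)) lin1x1(x, p$Wres) else x
    z <- a2 + skipv
  } else {
    z <- a2
  }
  r2 <- relu(z)
  cache$z <- z; cache$r2 <- r2
  out <- r2
  if (cfg$se) {
    d <- dim(r2)
    N <- prod(d[1:3])
    m <- colMeans(matrix(r2, N, d[4]))
    h_pre <- drop(p$se$W1 %*% m) + p$se$b1
    h <- relu(h_pre)
    s_pre <- drop(p$se$W2 %*% h) + p$se$b2
    s <- sigmoid(s_pre)
    out <- array(sweep(matrix(r2, N, d[4]), 2, s, `*`), dim = d)
    cache$se <- list(m = m, h_pre = h_pre, h = h, s = s)
  }
  cache$out <- out
  cache
}

conv_block_bw <- function(dout, cache, p, cfg) {
  grads <- list()
  r2 <- cache$r2
  d <- dim(r2)
  N <- prod(d[1:3])
  if (cfg$se) {
    se <- cache$se
    r2m <- matrix(r2, N, d[4])
    dom <- matrix(dout, N, d[4])
    dr2m <- sweep(dom, 2, se$s, `*`)
    ds <- colSums(dom * r2m)
    ds_pre <- ds * se$s * (1 - se$s)
    grads$se <- list(W2 = outer(ds_pre, se$h), b2 = ds_pre)
    dh <- drop(t(p$se$W2) %*% ds_pre)
    dh_pre <- dh * (se$h_pre > 0)
    grads$se$W1 <- outer(dh_pre, se$m)
    grads$se$b1 <- dh_pre
    dm <- drop(t(p$se$W1) %*% dh_pre)
    dr2m <- sweep(dr2m, 2, dm / N, `+`)
    dr2 <- array(dr2m, dim = d)
  } else {
    dr2 <- dout
  }
  dz <- dr2 * (cache$z > 0)
  da2 <- dz
  bw2 <- conv3d_bw(cache$r1, p$W2, da2)
  grads$W2 <- bw2$dW; grads$b2 <- bw2$db
  dr1 <- bw2$dx
  da1 <- dr1 * (cache$a1 > 0)
  bw1 <- conv3d_bw(cache$x, p$W1, da1)
  grads$W1 <- bw1$dW; grads$b1 <- bw1$db
  dx <- bw1$dx
  if (cfg$residual) {
    if (!is.null(p$Wres)) {
      bwr <- lin1x1_bw(cache$x, p$Wres, dz)
      grads$Wres <- bwr$dW
      dx <- dx + bwr$dx
    } else {
      dx <- dx + dz
    }
  }
  list(dx = dx, grads = grads)
}

ga_fw <- function(x, g, p) {
  theta <- lin1x1(x, p$Wtheta)
  phi <- lin1x1(g, p$Wphi, p$bphi)
  phi_up <- upsample2_fw(phi)
  q_pre <- theta + phi_up
  q <- relu(q_pre)
  a_pre <- lin1x1(q, p$Wpsi, p$bpsi)
  att <- sigmoid(a_pre)
  gated <- x * as.vector(att)  # att has 1 channel; recycles over channels
  list(gated = gated, cache = list(x = x, g = g, q_pre = q_pre, q = q,
                                   att = att))
}

ga_bw <- function(dgated, cache, p) {
  d <- dim(cache$x)
  N <- prod(d[1:3])
  att_v <- as.vector(cache$att)
  dx <- dgated * att_v
  datt <- array(rowSums(matrix(dgated * cache$x, N, d[4])), dim = c(d[1:3], 1L))
  da_pre <- datt * att_v * (1 - att_v)
  bw_psi <- lin1x1_bw(cache$q, p$Wpsi, da_pre)
  dq <- bw_psi$dx * (cache$q_pre > 0)
  bw_theta <- lin1x1_bw(cache$x, p$Wtheta, dq)
  dx <- dx + bw_theta$dx
  dphi_up <- dq
  dphi <- upsample2_bw(dphi_up)
  bw_phi <- lin1x1_bw(cache$g, p$Wphi, dphi)
  list(dx = dx, dg = bw_phi$dx,
       grads = list(Wtheta = bw_theta$dW, Wphi = bw_phi$dW, bphi = bw_phi$db,
                    Wpsi = bw_psi$dW, bpsi = bw_psi$db))
}

softmax4 <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, prod(d[1:3]), d[4])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  array(e / rowSums(e), dim = d)
}

concat4 <- function(a, b) {
  d <- dim(a)
  stopifnot(identical(dim(b)[1:3], d[1:3]))
  out <- array(0, dim = c(d[1:3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

#' Forward pass of the segmentation network
#'
#' @param network a `seg_network`.
#' @param x input array (nx, ny, nz, in_channels).
#' @param keep_cache retain intermediate activations for backprop.
#' @return list with `prob` (full-resolution class probabilities summing to 1
#'   per voxel), `aux` (coarser deep-supervision probability maps, one per
#'   decoder level > 1), `logits`, and optionally `cache`.
#' @export
net_forward <- function(network, x, keep_cache = FALSE) {
  cfg <- network$config
  p <- network$params
  stopifnot(length(dim(x)) == 4L, dim(x)[4] == cfg$in_channels)
  cache <- list(enc = list(), pool = list(), dec = list(), ga = list())
  cur <- x
  for (s in seq_len(cfg$depth)) {
    cb <- conv_block_fw(cur, p$enc[[s]], cfg)
    cache$enc[[s]] <- cb
    pl <- maxpool3d_fw(cb$out)
    cache$pool[[s]] <- pl
    cur <- pl$out
  }
  cb <- conv_block_fw(cur, p$bott, cfg)
  cache$bott <- cb
  g <- cb$out
  dec_out <- vector("list", cfg$depth)
  for (s in rev(seq_len(cfg$depth))) {
    skip <- cache$enc[[s]]$out
    if (cfg$grid_attention) {
      gaf <- ga_fw(skip, g, p$dec[[s]]$ga)
      cache$ga[[s]] <- gaf$cache
      skip_used <- gaf$gated
    } else {
      skip_used <- skip
    }
    up <- upsample2_fw(g)
    cat_in <- concat4(up, skip_used)
    cb <- conv_block_fw(cat_in, p$dec[[s]]$block, cfg)
    cache$dec[[s]] <- cb
    dec_out[[s]] <- cb$out
    g <- cb$out
  }
  logits <- lin1x1(dec_out[[1L]], p$head[[1L]]$W, p$head[[1L]]$b)
  prob <- softmax4(logits)
  aux <- list()
  if (cfg$deep_supervision && cfg$depth >= 2L) {
    for (s in 2:cfg$depth) {
      lg <- lin1x1(dec_out[[s]], p$head[[s]]$W, p$head[[s]]$b)
      aux[[s - 1L]] <- softmax4(lg)
      cache$aux_logits[[s - 1L]] <- lg
    }
  }
  out <- list(prob = prob, aux = aux, logits = logits)
  if (keep_cache) out$cache <- cache
  out
}

#' Multi-class soft Dice loss of a probability map against integer labels
#'
#' Averaged over foreground classes only: for class k,
#' `1 - (2 sum(p_k y_k) + eps) / (sum(p_k) + sum(y_k) + eps)`.
#'
#' @param prob 4D probability array (x, y, z, class).
#' @param target integer labels in 0..(n_classes-1), 3D.
#' @param eps smoothing constant (default 1e-5).
#' @return scalar soft Dice loss.
#' @export
soft_dice_loss <- function(prob, target, eps = 1e-5) {
  d <- dim(prob)
  K <- d[4]
  loss <- 0
  for (k in 2:K) {
    pk <- prob[, , , k]
    yk <- as.numeric(target == (k - 1L))
    loss <- loss + 1 - (2 * sum(pk * yk) + eps) / (sum(pk) + sum(yk) + eps)
  }
  loss / (K - 1)
}

#' Dice + cross-entropy loss with deep supervision
#'
#' Each supervision level contributes (soft multi-class Dice + mean per-voxel
#' cross-entropy); levels are combined with the given nonnegative weights
#' (default: halving per coarser level, normalised to sum 1). Targets for
#' coarser levels are the labels nearest-neighbour-downsampled by powers of
#' two.
#'
#' @param probs list of probability maps, finest first (as produced by
#'   [net_forward()]: `c(list(prob), aux)`).
#' @param target full-resolution integer label array.
#' @param level_weights optional nonnegative weights, one per level.
#' @return scalar loss (attributes `dice` and `ce` hold the per-level parts).
#' @export
dice_ce_loss <- function(probs, target, level_weights = NULL) {
  if (!is.list(probs)) probs <- list(probs)
  L <- length(probs)
  if (is.null(level_weights)) {
    level_weights <- 0.5^(seq_len(L) - 1L)
    level_weights <- level_weights / sum(level_weights)
  }
  stopifnot(length(level_weights) == L, all(level_weights >= 0))
  dice_parts <- numeric(L); ce_parts <- numeric(L)
  for (l in seq_len(L)) {
    pr <- probs[[l]]
    d <- dim(pr)
    sums <- rowSums(matrix(pr, prod(d[1:3]), d[4]))
    if (max(abs(sums - 1)) > 1e-6) {
      stopf("probabilities do not sum to 1 per voxel at level %d", l)
    }
    tgt <- downsample_labels(target, 2^(l - 1L))
    if (!identical(dim(tgt), d[1:3])) stopf("target shape mismatch at level %d", l)
    dice_parts[l] <- soft_dice_loss(pr, tgt)
    N <- prod(d[1:3])
    pm <- matrix(pr, N, d[4])
    pv <- pmax(pm[cbind(seq_len(N), as.integer(tgt) + 1L)], 1e-12)
    ce_parts[l] <- -mean(log(pv))
  }
  total <- sum(level_weights * (dice_parts + ce_parts))
  attr(total, "dice") <- dice_parts
  attr(total, "ce") <- ce_parts
  total
}

downsample_labels <- function(target, factor) {
  if (factor == 1) return(target)
  d <- dim(target)
  idx <- lapply(d, function(n) seq(1L, n, by = factor))
  target[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# gradient of (dice + ce) wrt logits for one level
dice_ce_grad_logits <- function(prob, target, eps = 1e-5) {
  d <- dim(prob)
  K <- d[4]
  N <- prod(d[1:3])
  y <- array(0, dim = d)
  for (k in seq_len(K)) y[, , , k] <- as.numeric(target == (k - 1L))
  # CE: dL/dlogit = (p - y) / N
  g_ce <- (prob - y) / N
  # soft Dice wrt p, then softmax jacobian
  dLdp <- array(0, dim = d)
  for (k in 2:K) {
    pk <- prob[, , , k]
    yk <- y[, , , k]
    num <- 2 * sum(pk * yk) + eps
    den <- sum(pk) + sum(yk) + eps
    dLdp[, , , k] <- -(2 * yk * den - num) / den^2 / (K - 1)
  }
  pm <- matrix(prob, N, K)
  gm <- matrix(dLdp, N, K)
  dot <- rowSums(pm * gm)
  g_dice <- array(pm * (gm - dot), dim = d)
  g_ce + g_dice
}

net_backward <- function(network, fw, target, level_weights = NULL) {
  cfg <- network$config
  p <- network$params
  L <- 1L + length(fw$aux)
  if (is.null(level_weights)) {
    level_weights <- 0.5^(seq_len(L) - 1L)
    level_weights <- level_weights / sum(level_weights)
  }
  grads <- list(enc = vector("list", cfg$depth),
                dec = vector("list", cfg$depth),
                head = vector("list", cfg$depth))
  cache <- fw$cache
  # head gradients and the gradient entering each decoder output
  d_dec <- vector("list", cfg$depth)
  dlogit1 <- level_weights[1] * dice_ce_grad_logits(fw$prob, target)
  bwh <- lin1x1_bw(cache$dec[[1L]]$out, p$head[[1L]]$W, dlogit1)
  grads$head[[1L]] <- list(W = bwh$dW, b = bwh$db)
  d_dec[[1L]] <- bwh$dx
  if (cfg$deep_supervision && cfg$depth >= 2L) {
    for (s in 2:cfg$depth) {
      tgt <- downsample_labels(target, 2^(s - 1L))
      dlg <- level_weights[s] * dice_ce_grad_logits(fw$aux[[s - 1L]], tgt)
      bwh <- lin1x1_bw(cache$dec[[s]]$out, p$head[[s]]$W, dlg)
      grads$head[[s]] <- list(W = bwh$dW, b = bwh$db)
      d_dec[[s]] <- bwh$dx
    }
  }
  # walk the decoder from fine to coarse, accumulating into the gating path
  dg <- NULL  # gradient flowing into the coarser level's output
  for (s in seq_len(cfg$depth)) {
    dout <- d_dec[[s]] %||% 0
    if (!is.null(dg)) dout <- dout + dg
    bb <- conv_block_bw(dout, cache$dec[[s]], p$dec[[s]]$block, cfg)
    grads$dec[[s]]$block <- bb$grads
    n_up <- dim(cache$dec[[s]]$x)[4] - dim(cache$enc[[s]]$out)[4]
    dcat <- bb$dx
    dup <- dcat[, , , seq_len(n_up), drop = FALSE]
    dskip_used <- dcat[, , , n_up + seq_len(dim(dcat)[4] - n_up), drop = FALSE]
    dg_coarse <- upsample2_bw(dup)
    if (cfg$grid_attention) {
      gab <- ga_bw(dskip_used, cache$ga[[s]], p$dec[[s]]$ga)
      grads$dec[[s]]$ga <- gab$grads
      dskip <- gab$dx
      dg_coarse <- dg_coarse + gab$dg
    } else {
      dskip <- dskip_used
    }
    # the skip gradient enters the encoder block at level s (accumulated
    # later with the pooled-path gradient)
    grads$dec[[s]]$dskip <- dskip
    dg <- dg_coarse
  }
  # bottleneck
  bb <- conv_block_bw(dg, cache$bott, p$bott, cfg)
  grads$bott <- bb$grads
  dpool <- bb$dx
  for (s in rev(seq_len(cfg$depth))) {
    dthrough <- maxpool3d_bw(dpool, cache$pool[[s]]$argmax,
                             dim(cache$enc[[s]]$out))
    dout <- dthrough + grads$dec[[s]]$dskip
    grads$dec[[s]]$dskip <- NULL
    bb <- conv_block_bw(dout, cache$enc[[s]], p$enc[[s]], cfg)
    grads$enc[[s]] <- bb$grads
    dpool <- bb$dx
  }
  grads
}

# Walk two parameter trees in parallel, matching children by name where
# names exist (gradient lists are built in a different order than the
# parameter lists) and by position otherwise.
map_params <- function(a, b, f) {
  if (is.list(a)) {
    keys <- names(a)
    out <- a
    for (i in seq_along(a)) {
      if (is.null(a[[i]])) next
      key <- if (!is.null(keys) && nzchar(keys[i])) keys[i] else i
      bb <- if (is.list(b)) {
        if (is.character(key)) b[[key]]
        else if (key <= length(b)) b[[key]] else NULL
      } else NULL
      out[[i]] <- map_params(a[[i]], bb, f)
    }
    out
  } else {
    f(a, b)
  }
}

#' Train the toy network under the cyclic schedule, saving checkpoints
#'
#' SGD with momentum over single-patch minibatches, learning rate from
#' [learning_rate()] per epoch, weights deep-copied at the epochs designated
#' by [checkpoint_epochs()]. Training stops with an error if the loss goes
#' non-finite.
#'
#' @param network a `seg_network`.
#' @param patches list of training cases, each `list(x = 4D input,
#'   y = 3D integer labels)`.
#' @param schedule a [cycle_schedule()] (toy scale, e.g.
#'   `cycle_schedule(150, 3)`).
#' @param ckpt_epochs integer epochs at which to save checkpoints (default:
#'   [checkpoint_epochs()] on the schedule).
#' @param momentum SGD momentum (default 0.9).
#' @param clip_norm global gradient-norm clip per update (default 12,
#'   following the reference pipeline's convention); `Inf` disables it.
#' @param augment optional augmentation config for [augment_patch()].
#' @param seed integer seed controlling shuffling and augmentation.
#' @param verbose print per-cycle progress.
#' @return list with `network` (trained), `checkpoints` (list of parameter
#'   trees + epochs), `loss` (per-epoch mean loss).
#' @export
train_toy <- function(network, patches, schedule,
                      ckpt_epochs = checkpoint_epochs(schedule, seed = seed),
                      momentum = 0.9, clip_norm = 12, augment = NULL,
                      seed = 1L, verbose = FALSE) {
  stopifnot(inherits(network, "seg_network"), length(patches) > 0L)
  vel <- map_params(network$params, NULL, function(a, b) a * 0)
  losses <- numeric(schedule$total_epochs)
  checkpoints <- list()
  if (schedule$total_epochs == 0L) {
    return(list(network = network, checkpoints = checkpoints, loss = losses))
  }
  with_seed(seed, {
    for (t in seq_len(schedule$total_epochs) - 1L) {
      lr <- learning_rate(t, schedule)
      ord <- sample(length(patches))
      ep_loss <- 0
      for (i in ord) {
        pt <- patches[[i]]
        if (!is.null(augment)) {
          ag <- augment_patch(pt$x, pt$y, augment,
                              seed = sample.int(.Machine$integer.max, 1))
          pt <- list(x = ag$image, y = ag$label)
        }
        fw <- net_forward(network, pt$x, keep_cache = TRUE)
        loss <- dice_ce_loss(c(list(fw$prob), fw$aux), pt$y)
        if (!is.finite(loss)) {
          stopf("training diverged at epoch %d (loss %s)", t, loss)
        }
        ep_loss <- ep_loss + as.numeric(loss)
        grads <- net_backward(network, fw, pt$y)
        if (is.finite(clip_norm)) {
          gnorm <- sqrt(sum(rapply(grads, function(g) sum(g^2),
                                   how = "unlist"), na.rm = TRUE))
          if (gnorm > clip_norm) {
            scl <- clip_norm / gnorm
            grads <- map_params(grads, NULL, function(g, b) g * scl)
          }
        }
        vel <- map_params(vel, grads, function(v, g) {
          if (is.null(g)) v else momentum * v + g
        })
        network$params <- map_params(network$params, vel, function(p, v) {
          if (is.null(v)) p else p - lr * v
        })
      }
      losses[t + 1L] <- ep_loss / length(patches)
      if (t %in% ckpt_epochs) {
        checkpoints[[length(checkpoints) + 1L]] <-
          list(epoch = t, cycle = t %/% schedule$cycle_epochs + 1L,
               params = network$params)
      }
      if (verbose && (t + 1L) %% schedule$cycle_epochs == 0L) {
        message(sprintf("epoch %d: mean loss %.4f (lr %.4g)", t,
                        losses[t + 1L], lr))
      }
    }
  })
  list(network = network, checkpoints = checkpoints, loss = losses)
}

#' Predict class probabilities for a full patch
#'
#' @param network a `seg_network` (optionally with swapped-in checkpoint
#'   parameters).
#' @param x input array (nx, ny, nz, channels).
#' @return 4D probability array.
#' @export
net_predict <- function(network, x) {
  net_forward(network, x, keep_cache = FALSE)$prob
}

#' Run every saved checkpoint over a patch to form the posterior ensemble
#'
#' @param network the trained `seg_network` (architecture + config).
#' @param checkpoints checkpoint list from [train_toy()].
#' @param x input array.
#' @return an `ensemble_prediction` whose members are the per-checkpoint
#'   probability maps.
#' @export
ensemble_predict <- function(network, checkpoints, x) {
  stopifnot(length(checkpoints) >= 1L)
  d <- dim(x)[1:3]
  K <- network$config$n_classes
  prob <- array(0, dim = c(d, K, length(checkpoints)))
  for (m in seq_along(checkpoints)) {
    network$params <- checkpoints[[m]]$params
    prob[, , , , m] <- net_predict(network, x)
  }
  new_ensemble_prediction(
    prob, classes = c("background", "GTVp", "GTVn")[seq_len(K)],
    provenance = data.frame(
      member = seq_along(checkpoints),
      cycle = vapply(checkpoints, `[[`, 0L, "cycle"),
      epoch = vapply(checkpoints, `[[`, 0L, "epoch")))
}
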