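#' Generator (U-Net) configuration
#'
#' The generator is an adapted U-Net: an input convolution to `base_channels`
#' with leaky-ReLU, `depth` down-sampling blocks (two 3x3 convolutions with
#' leaky-ReLU, channels doubled at the second; optional parameter-free
#' additive residual skip), average-pooling of stride two between blocks, a
#' bottleneck convolution preserving the feature count, and a mirrored
#' up-sampling path (bilinear x2 upsampling, concatenation with the skip at
#' the same level, two convolutions), closed by a linear output convolution.
#'
#' @param base_channels Channels after the input convolution (reference
#'   configuration: 32).
#' @param depth Number of down/up levels (reference: 3).
#' @param in_channels,out_channels I/O channels (2 = real+imag for the
#'   pixel-limited system; 1 = phase for the diffraction-limited system).
#' @param kernel Convolution kernel side (3).
#' @param lrelu_slope Negative slope of the leaky ReLU (0.1).
#' @param residual Additive skip inside each down block (default TRUE).
#' @param init_sd Truncated-normal initialization SD (truncated at 2 sd);
#'   `NULL` (default) uses the He fan-in scale `sqrt(2 / fan_in)` per layer.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(base_channels = 32L, depth = 3L,
                             in_channels = 2L, out_channels = in_channels,
                             kernel = 3L, lrelu_slope = 0.1,
                             residual = TRUE, init_sd = NULL) {
  stopifnot(depth >= 1, base_channels >= 1, kernel %% 2 == 1)
  structure(list(base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), lrelu_slope = lrelu_slope,
                 residual = residual,
                 init_sd = if (is.null(init_sd)) NA_real_ else init_sd),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' A convolution to `base_channels`, `n_blocks` blocks of two convolutions
#' (the first preserving, the second doubling channels while halving each
#' lateral dimension), channel-wise global average pooling to a vector of
#' length `base_channels * 2^n_blocks`, two fully connected layers (width
#' preserved, then reduced to 1) with leaky-ReLU, and a sigmoid.
#'
#' @param base_channels Channels after the input convolution (32).
#' @param n_blocks Number of discriminator blocks (5).
#' @param fc_width Width of the first fully connected layer; must equal
#'   `base_channels * 2^n_blocks` (1024 in the reference configuration).
#' @param kernel Convolution kernel side (3).
#' @param lrelu_slope Leaky-ReLU negative slope.
#' @param init_sd Truncated-normal initialization SD; `NULL` (default) uses
#'   the He fan-in scale per layer.
#' @return An object of class `discriminator_config`.
#' @export
discriminator_config <- function(base_channels = 32L, n_blocks = 5L,
                                 fc_width = base_channels * 2L^n_blocks,
                                 kernel = 3L, lrelu_slope = 0.1,
                                 init_sd = NULL) {
  if (fc_width != base_channels * 2^n_blocks) {
    stop("fc_width must equal base_channels * 2^n_blocks")
  }
  structure(list(base_channels = as.integer(base_channels),
                 n_blocks = as.integer(n_blocks),
                 fc_width = as.integer(fc_width),
                 kernel = as.integer(kernel), lrelu_slope = lrelu_slope,
                 init_sd = if (is.null(init_sd)) NA_real_ else init_sd),
            class = "discriminator_config")
}

#' Composite-loss weights
#'
#' @param alpha Adversarial weight (reference value 0.00275).
#' @param gamma Total-variation weight (0.015).
#' @param beta SSIM weight (0.01 for the phase-channel system, 0 for the
#'   real/imaginary system).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.00275, gamma = 0.015, beta = 0) {
  stopifnot(alpha >= 0, gamma >= 0, beta >= 0)
  structure(list(alpha = alpha, gamma = gamma, beta = beta),
            class = "loss_weights")
}

#' Training-state configuration
#'
#' @param gen_lr,disc_lr Adam learning rates (1e-4 generator, 1e-5
#'   discriminator).
#' @param batch_train,batch_val Batch sizes (10 training, 25 validation).
#' @param gen_updates_per_disc Generator updates per discriminator update (4).
#' @param rng_seed Root seed for initialization, shuffling and augmentation.
#' @return An object of class `train_state`.
#' @export
train_state <- function(gen_lr = 1e-4, disc_lr = 1e-5, batch_train = 10L,
                        batch_val = 25L, gen_updates_per_disc = 4L,
                        rng_seed = 1L) {
  stopifnot(gen_lr > 0, disc_lr > 0, batch_train >= 1, batch_val >= 1,
            gen_updates_per_disc >= 1)
  structure(list(gen_lr = gen_lr, disc_lr = disc_lr,
                 batch_train = as.integer(batch_train),
                 batch_val = as.integer(batch_val),
                 gen_updates_per_disc = as.integer(gen_updates_per_disc),
                 rng_seed = as.integer(rng_seed)),
            class = "train_state")
}

gen_channels <- function(cfg) {
  f <- cfg$base_channels
  list(down = lapply(seq_len(cfg$depth), function(d) {
    c(in1 = f * 2^(d - 1), out1 = f * 2^(d - 1), out2 = f * 2^d)
  }),
  bridge = f * 2^cfg$depth,
  up = lapply(seq_len(cfg$depth), function(d) {
    c(incat = f * 2^(d + 1), mid = f * 2^d, out = f * 2^(d - 1))
  }))
}

#' Initialize generator parameters
#'
#' Convolution weights from a truncated normal distribution (SD
#' `cfg$init_sd`, truncated at two SDs), biases zero.
#'
#' @param cfg A [generator_config].
#' @return Nested list of weight arrays.
#' @export
init_generator <- function(cfg) {
  ch <- gen_channels(cfg)
  k <- cfg$kernel
  sd0 <- if (is.na(cfg$init_sd)) NULL else cfg$init_sd
  list(
    conv_in = conv_par(cfg$in_channels, cfg$base_channels, k, sd0),
    down = lapply(ch$down, function(d) list(
      c1 = conv_par(d["in1"], d["out1"], k, sd0),
      c2 = conv_par(d["out1"], d["out2"], k, sd0))),
    bridge = conv_par(ch$bridge, ch$bridge, k, sd0),
    up = lapply(ch$up, function(u) list(
      c1 = conv_par(u["incat"], u["mid"], k, sd0),
      c2 = conv_par(u["mid"], u["out"], k, sd0))),
    final = conv_par(cfg$base_channels, cfg$out_channels, k, sd0)
  )
}

#' Initialize discriminator parameters
#'
#' @param cfg A [discriminator_config].
#' @param in_channels Image channels seen by the discriminator.
#' @return Nested list of weight arrays.
#' @export
init_discriminator <- function(cfg, in_channels) {
  f <- cfg$base_channels; k <- cfg$kernel
  sd0 <- if (is.na(cfg$init_sd)) NULL else cfg$init_sd
  list(
    conv_in = conv_par(in_channels, f, k, sd0),
    blocks = lapply(seq_len(cfg$n_blocks), function(b) list(
      c1 = conv_par(f * 2^(b - 1), f * 2^(b - 1), k, sd0),
      c2 = conv_par(f * 2^(b - 1), f * 2^b, k, sd0))),
    fc1 = dense_par(cfg$fc_width, cfg$fc_width, sd0),
    fc2 = dense_par(cfg$fc_width, 1L, sd0)
  )
}

#' Generator forward pass
#'
#' @param x Input array `(H, W, in_channels, N)` (a single `(H, W, C)` patch
#'   is promoted to a batch of one); `H` and `W` must be divisible by
#'   `2^depth`.
#' @param cfg A [generator_config].
#' @param params Parameters from [init_generator()].
#' @param keep_cache Keep intermediate activations for a backward pass.
#' @return The output array `(H, W, out_channels, N)`; with
#'   `keep_cache = TRUE` a list `(out, cache)`.
#' @export
generator_forward <- function(x, cfg, params, keep_cache = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  d <- dim(x)
  div <- 2^cfg$depth
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf("H and W must be divisible by %d; pad to (%d, %d)",
                 div, ceiling(d[1] / div) * div, ceiling(d[2] / div) * div))
  }
  if (d[3] != cfg$in_channels) stop("channel count does not match config")
  sl <- cfg$lrelu_slope
  cc <- list(x = x)
  a0 <- conv_f(x, params$conv_in); cc$a0 <- a0
  cur <- lrelu(a0, sl)
  skips <- vector("list", cfg$depth)
  cc$down <- vector("list", cfg$depth)
  for (dd in seq_len(cfg$depth)) {
    blk <- params$down[[dd]]
    bin <- cur
    a1 <- conv_f(bin, blk$c1); z1 <- lrelu(a1, sl)
    a2 <- conv_f(z1, blk$c2); z2 <- lrelu(a2, sl)
    out_d <- if (cfg$residual) z2 + rep2_ch(bin) else z2
    skips[[dd]] <- out_d
    cc$down[[dd]] <- list(bin = bin, a1 = a1, z1 = z1, a2 = a2)
    cur <- avgpool2_f(out_d)
  }
  ab <- conv_f(cur, params$bridge); cc$bridge <- list(bin = cur, a = ab)
  cur <- lrelu(ab, sl)
  cc$up <- vector("list", cfg$depth)
  for (dd in rev(seq_len(cfg$depth))) {
    blk <- params$up[[dd]]
    upx <- upsample2_f(cur)
    cat_ <- concat_ch(upx, skips[[dd]])
    a1 <- conv_f(cat_, blk$c1); z1 <- lrelu(a1, sl)
    a2 <- conv_f(z1, blk$c2); z2 <- lrelu(a2, sl)
    cc$up[[dd]] <- list(cat = cat_, a1 = a1, z1 = z1, a2 = a2)
    cur <- z2
  }
  cc$final_in <- cur
  out <- conv_f(cur, params$final)
  if (keep_cache) list(out = out, cache = cc) else out
}

generator_backward <- function(dout, cfg, params, cache) {
  sl <- cfg$lrelu_slope
  g <- list(down = vector("list", cfg$depth), up = vector("list", cfg$depth))
  bf <- conv_b(cache$final_in, params$final, dout)
  g$final <- list(w = bf$dw, b = bf$db)
  dcur <- bf$dx
  dskips <- vector("list", cfg$depth)
  for (dd in seq_len(cfg$depth)) {
    blk <- params$up[[dd]]; cc <- cache$up[[dd]]
    da2 <- lrelu_bwd(cc$a2, dcur, sl)
    b2 <- conv_b(cc$z1, blk$c2, da2)
    da1 <- lrelu_bwd(cc$a1, b2$dx, sl)
    b1 <- conv_b(cc$cat, blk$c1, da1)
    g$up[[dd]] <- list(c1 = list(w = b1$dw, b = b1$db),
                       c2 = list(w = b2$dw, b = b2$db))
    nup <- dim(cc$cat)[3] / 2 # upsampled half and skip half have equal widths
    dcat <- b1$dx
    dup <- dcat[, , seq_len(nup), , drop = FALSE]
    dskips[[dd]] <- dcat[, , nup + seq_len(nup), , drop = FALSE]
    dcur <- upsample2_b(dup)
  }
  dab <- lrelu_bwd(cache$bridge$a, dcur, sl)
  bb <- conv_b(cache$bridge$bin, params$bridge, dab)
  g$bridge <- list(w = bb$dw, b = bb$db)
  dcur <- bb$dx
  for (dd in rev(seq_len(cfg$depth))) {
    blk <- params$down[[dd]]; cc <- cache$down[[dd]]
    dout_d <- avgpool2_b(dcur, dim(cc$bin)[1:2]) + dskips[[dd]]
    dz2 <- dout_d
    da2 <- lrelu_bwd(cc$a2, dz2, sl)
    b2 <- conv_b(cc$z1, blk$c2, da2)
    da1 <- lrelu_bwd(cc$a1, b2$dx, sl)
    b1 <- conv_b(cc$bin, blk$c1, da1)
    dcur <- b1$dx
    if (cfg$residual) dcur <- dcur + rep2_ch_b(dout_d)
    g$down[[dd]] <- list(c1 = list(w = b1$dw, b = b1$db),
                         c2 = list(w = b2$dw, b = b2$db))
  }
  da0 <- lrelu_bwd(cache$a0, dcur, sl)
  b0 <- conv_b(cache$x, params$conv_in, da0)
  g$conv_in <- list(w = b0$dw, b = b0$db)
  g[c("conv_in", "down", "bridge", "up", "final")]
}

#' Discriminator forward pass
#'
#' @param x Array `(H, W, C, N)` (or a single `(H, W, C)` patch); `H` and `W`
#'   must be divisible by `2^n_blocks`.
#' @param cfg A [discriminator_config].
#' @param params Parameters from [init_discriminator()].
#' @param keep_cache Keep activations for a backward pass.
#' @return Numeric vector of per-patch probabilities in (0, 1); with
#'   `keep_cache = TRUE` a list `(prob, cache)`.
#' @export
discriminator_forward <- function(x, cfg, params, keep_cache = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  d <- dim(x)
  div <- 2^cfg$n_blocks
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf("H and W must be divisible by %d", div))
  }
  sl <- cfg$lrelu_slope
  cc <- list(x = x)
  a0 <- conv_f(x, params$conv_in); cc$a0 <- a0
  cur <- lrelu(a0, sl)
  cc$blocks <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    blk <- params$blocks[[b]]
    bin <- cur
    a1 <- conv_f(bin, blk$c1); z1 <- lrelu(a1, sl)
    a2 <- conv_f(z1, blk$c2, stride = 2L); z2 <- lrelu(a2, sl)
    cc$blocks[[b]] <- list(bin = bin, a1 = a1, z1 = z1, a2 = a2)
    cur <- z2
  }
  cc$gap_in_dim <- dim(cur)[1:2]
  v <- gap_f(cur)                      # (fc_width, N)
  cc$v <- v
  af1 <- dense_f(v, params$fc1); cc$af1 <- af1
  z1 <- lrelu(af1, sl)
  cc$zf1 <- z1
  af2 <- dense_f(z1, params$fc2); cc$af2 <- af2
  z2 <- lrelu(af2, sl)
  cc$zf2 <- z2
  prob <- as.numeric(1 / (1 + exp(-z2)))
  if (keep_cache) list(prob = prob, cache = cc) else prob
}

discriminator_backward <- function(dprob, cfg, params, cache, need_dx = FALSE) {
  sl <- cfg$lrelu_slope
  p <- 1 / (1 + exp(-cache$zf2))
  dz2 <- matrix(dprob, 1) * p * (1 - p)
  daf2 <- lrelu_bwd(cache$af2, dz2, sl)
  b2 <- dense_b(cache$zf1, params$fc2, daf2)
  daf1 <- lrelu_bwd(cache$af1, b2$dx, sl)
  b1 <- dense_b(cache$v, params$fc1, daf1)
  dcur <- gap_b(b1$dx, cache$gap_in_dim)
  g <- list(blocks = vector("list", cfg$n_blocks))
  for (b in rev(seq_len(cfg$n_blocks))) {
    blk <- params$blocks[[b]]; cc <- cache$blocks[[b]]
    da2 <- lrelu_bwd(cc$a2, dcur, sl)
    c2 <- conv_b(cc$z1, blk$c2, da2, stride = 2L)
    da1 <- lrelu_bwd(cc$a1, c2$dx, sl)
    c1 <- conv_b(cc$bin, blk$c1, da1)
    g$blocks[[b]] <- list(c1 = list(w = c1$dw, b = c1$db),
                          c2 = list(w = c2$dw, b = c2$db))
    dcur <- c1$dx
  }
  da0 <- lrelu_bwd(cache$a0, dcur, sl)
  b0 <- conv_b(cache$x, params$conv_in, da0)
  g$conv_in <- list(w = b0$dw, b = b0$db)
  g$fc1 <- list(w = b1$dw, b = b1$db)
  g$fc2 <- list(w = b2$dw, b = b2$db)
  g <- g[c("conv_in", "blocks", "fc1", "fc2")]
  if (need_dx) list(grads = g, dx = b0$dx) else list(grads = g)
}

#' L1 (mean absolute) image loss
#'
#' Expectation over pixels and channels (and batch) of the absolute
#' difference between the generated and label images.
#'
#' @param gen_out,label Arrays of identical shape.
#' @return Scalar.
#' @export
l1_loss <- function(gen_out, label) {
  if (!identical(dim(gen_out), dim(label))) stop("shape mismatch")
  mean(abs(gen_out - label))
}

#' Anisotropic total-variation loss
#'
#' Sum over pixels of the absolute forward differences in both lateral
#' directions, averaged over channels (and batch). `reduction = "mean"`
#' additionally divides by the pixel count, giving a per-pixel magnitude
#' that keeps the regularization weight meaningful across patch sizes
#' (the default used in training).
#'
#' @param x Array `(H, W)`, `(H, W, C)` or `(H, W, C, N)`.
#' @param reduction `"sum"` (literal channel-mean of the summed differences)
#'   or `"mean"` (per-pixel normalized).
#' @return Scalar.
#' @export
tv_loss <- function(x, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1, 1)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  d <- dim(x)
  tvs <- sum(abs(x[-1, , , , drop = FALSE] - x[-d[1], , , , drop = FALSE])) +
    sum(abs(x[, -1, , , drop = FALSE] - x[, -d[2], , , drop = FALSE]))
  out <- tvs / (d[3] * d[4])
  if (reduction == "mean") out <- out / (d[1] * d[2]) else out
}

tv_grad <- function(x, reduction = "sum") {
  d <- dim(x)
  g <- array(0, d)
  sy <- sign(x[-1, , , , drop = FALSE] - x[-d[1], , , , drop = FALSE])
  g[-1, , , ] <- g[-1, , , , drop = FALSE] + sy
  g[-d[1], , , ] <- g[-d[1], , , , drop = FALSE] - sy
  sx <- sign(x[, -1, , , drop = FALSE] - x[, -d[2], , , drop = FALSE])
  g[, -1, , ] <- g[, -1, , , drop = FALSE] + sx
  g[, -d[2], , ] <- g[, -d[2], , , drop = FALSE] - sx
  g <- g / (d[3] * d[4])
  if (reduction == "mean") g / (d[1] * d[2]) else g
}

# global SSIM and its gradient w.r.t. x, per (channel, sample), averaged
ssim_global_batch <- function(x, z, c1, c2, grad = FALSE) {
  d <- dim(x)
  np <- d[1] * d[2]; nc <- d[3] * d[4]
  xm <- matrix(x, np, nc); zm <- matrix(z, np, nc)
  mx <- colMeans(xm); mz <- colMeans(zm)
  xc <- sweep(xm, 2, mx); zc <- sweep(zm, 2, mz)
  vx <- colMeans(xc^2); vz <- colMeans(zc^2)
  cxz <- colMeans(xc * zc)
  a1 <- 2 * mx * mz + c1; a2 <- 2 * cxz + c2
  b1 <- mx^2 + mz^2 + c1; b2 <- vx + vz + c2
  s <- a1 * a2 / (b1 * b2)
  if (!grad) return(mean(s))
  gm <- sweep(zc, 2, a1 / (b1 * b2), `*`)
  gm <- sweep(gm, 2, mz * a2 / (b1 * b2), `+`)
  gm <- gm - sweep(xc, 2, s / b2, `*`)
  gm <- sweep(gm, 2, s * mx / b1, `-`)
  gm <- gm * 2 / np
  list(value = mean(s), grad = array(gm / nc, d))
}

#' Composite generator loss
#'
#' `L1 + gamma * TV + alpha * (1 - D(G(x)))^2`, plus `beta * (1 - SSIM)` when
#' `beta > 0` (with `ssim_literal_sign = TRUE` the SSIM term enters as
#' `+beta * SSIM` instead). Returns the total with the individual terms as
#' attributes.
#'
#' @param gen_out,label Arrays of identical shape.
#' @param d_of_gen Discriminator output(s) on `gen_out`, in `[0, 1]`.
#' @param w A [loss_weights].
#' @param tv_reduction Passed to [tv_loss()].
#' @param ssim_literal_sign Use the literal `+beta * SSIM` form.
#' @param ssim_c1,ssim_c2 SSIM stabilizers for the loss term.
#' @return Scalar loss with attribute `terms` (named vector of l1, tv, adv,
#'   ssim contributions).
#' @export
generator_loss <- function(gen_out, label, d_of_gen, w,
                           tv_reduction = "sum", ssim_literal_sign = FALSE,
                           ssim_c1 = 1e-4, ssim_c2 = 9e-4) {
  if (!identical(dim(gen_out), dim(label))) stop("shape mismatch")
  if (any(d_of_gen < 0 | d_of_gen > 1)) stop("d_of_gen must be in [0, 1]")
  l1 <- l1_loss(gen_out, label)
  tv <- w$gamma * tv_loss(gen_out, tv_reduction)
  adv <- w$alpha * mean((1 - d_of_gen)^2)
  ss <- 0
  if (w$beta > 0) {
    x4 <- gen_out; if (length(dim(x4)) < 4) dim(x4) <- c(dim(x4), 1, 1)[1:4]
    z4 <- label; dim(z4) <- dim(x4)
    sval <- ssim_global_batch(x4, z4, ssim_c1, ssim_c2)
    ss <- if (ssim_literal_sign) w$beta * sval else w$beta * (1 - sval)
  }
  total <- l1 + tv + adv + ss
  attr(total, "terms") <- c(l1 = l1, tv = tv, adv = adv, ssim = ss)
  total
}

#' Discriminator loss
#'
#' `D(G(x))^2 + (1 - D(z))^2`, averaged over the batch.
#'
#' @param d_fake Discriminator output(s) on generated images, in `[0, 1]`.
#' @param d_real Discriminator output(s) on label images, in `[0, 1]`.
#' @return Scalar in `[0, 2]`.
#' @export
discriminator_loss <- function(d_fake, d_real) {
  if (any(d_fake < 0 | d_fake > 1) || any(d_real < 0 | d_real > 1)) {
    stop("discriminator outputs must be in [0, 1]")
  }
  mean(d_fake^2) + mean((1 - d_real)^2)
}

rot90_batch <- function(a, k) {
  k <- k %% 4
  if (k == 0) return(a)
  for (i in seq_len(k)) {
    a <- aperm(a, c(2, 1, 3, 4))[rev(seq_len(dim(a)[2])), , , , drop = FALSE]
  }
  a
}

#' Random flip / 90-degree-rotation augmentation
#'
#' Each patch of the batch is independently flipped (left-right) with
#' probability 0.5 and rotated by a uniformly chosen multiple of 90 degrees;
#' input and label of a pair receive identical transforms. Draws from the
#' current RNG state, so a fixed seed reproduces the augmentation exactly.
#'
#' @param batch List with arrays `input` and `label` of shape
#'   `(H, W, C, N)`, `H == W`.
#' @return The augmented batch (same structure).
#' @export
augment <- function(batch) {
  d <- dim(batch$input)
  if (d[1] != d[2]) stop("augmentation requires square patches")
  flips <- stats::runif(d[4]) < 0.5
  rots <- sample(0:3, d[4], replace = TRUE)
  for (n in seq_len(d[4])) {
    for (fld in c("input", "label")) {
      a <- batch[[fld]][, , , n, drop = FALSE]
      if (flips[n]) a <- a[, rev(seq_len(d[2])), , , drop = FALSE]
      a <- rot90_batch(a, rots[n])
      batch[[fld]][, , , n] <- a
    }
  }
  attr(batch, "flips") <- flips
  attr(batch, "rots") <- rots
  batch
}

slice_batch <- function(ds, idx) {
  list(input = ds$input[, , , idx, drop = FALSE],
       label = ds$label[, , , idx, drop = FALSE])
}

#' Train the super-resolution GAN
#'
#' Alternates Adam updates of the generator and discriminator at the
#' configured ratio (4 generator updates per discriminator update), with the
#' composite generator loss and the least-squares discriminator loss,
#' flip/rotation augmentation, and periodic validation. Inputs and labels
#' are normalized per channel (statistics of the training labels; stored with
#' the model and reapplied by [gan_infer()]). The checkpoint with the lowest
#' validation generator loss is returned.
#'
#' @param pairs A `patch_dataset` from [make_training_set()], or any list
#'   with `input` and `label` arrays `(H, W, C, N)`.
#' @param gcfg,dcfg Network configurations.
#' @param w A [loss_weights].
#' @param state A [train_state].
#' @param steps Number of generator updates.
#' @param val_frac Fraction of pairs held out for validation.
#' @param val_every Validation cadence in generator updates (default 250).
#' @param tv_reduction TV normalization used during training (default
#'   `"mean"`; see [tv_loss()]).
#' @param ssim_literal_sign Passed to [generator_loss()].
#' @param init Optional list with `gen` and `disc` parameter trees to warm
#'   start from (e.g. a previous model's `final_gen` / `final_disc`).
#' @param verbose Print a line per validation.
#' @return An object of class `sr_model`: best generator/discriminator
#'   parameters, configs, normalization statistics, and a `history`
#'   data.frame (step, train loss, validation loss and terms, mean
#'   discriminator output on generated validation images).
#' @export
gan_train <- function(pairs, gcfg, dcfg, w = loss_weights(),
                      state = train_state(), steps = 2000,
                      val_frac = 0.15, val_every = 250,
                      tv_reduction = "mean", ssim_literal_sign = FALSE,
                      init = NULL, verbose = FALSE) {
  stopifnot(!is.null(pairs$input), !is.null(pairs$label))
  d <- dim(pairs$input)
  if (length(d) != 4) stop("pairs$input must be (H, W, C, N)")
  ntot <- d[4]
  if (ntot < 4) stop("dataset too small")
  set.seed(state$rng_seed)

  # per-channel normalization from the training labels
  nc <- d[3]
  nmean <- numeric(nc); nsd <- numeric(nc)
  for (ch in seq_len(nc)) {
    v <- pairs$label[, , ch, ]
    nmean[ch] <- mean(v); nsd[ch] <- max(stats::sd(v), 1e-8)
    pairs$label[, , ch, ] <- (pairs$label[, , ch, ] - nmean[ch]) / nsd[ch]
    pairs$input[, , ch, ] <- (pairs$input[, , ch, ] - nmean[ch]) / nsd[ch]
  }

  nval <- max(2L, round(val_frac * ntot))
  val_idx <- sample(ntot, nval)
  tr_idx <- setdiff(seq_len(ntot), val_idx)
  if (is.null(init)) {
    gp <- init_generator(gcfg)
    dp <- init_discriminator(dcfg, nc)
  } else {
    gp <- init$gen
    dp <- init$disc
  }
  gst <- adam_init(gp); dst <- adam_init(dp)

  validate <- function(gp, dp) {
    tot <- 0; terms <- c(l1 = 0, tv = 0, adv = 0, ssim = 0); dsum <- 0; nb <- 0
    for (i0 in seq(1, nval, by = state$batch_val)) {
      ii <- val_idx[i0:min(i0 + state$batch_val - 1, nval)]
      vb <- slice_batch(pairs, ii)
      out <- generator_forward(vb$input, gcfg, gp)
      dg <- discriminator_forward(out, dcfg, dp)
      l <- generator_loss(out, vb$label, dg, w, tv_reduction,
                          ssim_literal_sign)
      tot <- tot + as.numeric(l); terms <- terms + attr(l, "terms")
      dsum <- dsum + mean(dg); nb <- nb + 1
    }
    list(loss = tot / nb, terms = terms / nb, d_gen = dsum / nb)
  }

  best <- list(loss = Inf, gen = gp, disc = dp, step = 0L)
  hist <- list()
  record <- function(step, train_loss) {
    v <- validate(gp, dp)
    hist[[length(hist) + 1]] <<- data.frame(
      step = step, train_loss = train_loss, val_loss = v$loss,
      val_l1 = v$terms["l1"], val_tv = v$terms["tv"],
      val_adv = v$terms["adv"], val_ssim = v$terms["ssim"],
      val_d_gen = v$d_gen, row.names = NULL)
    if (v$loss < best$loss) {
      best <<- list(loss = v$loss, gen = gp, disc = dp, step = step)
    }
    if (verbose) {
      message(sprintf("step %6d  val %.5f  L1 %.5f  D(G) %.3f",
                      step, v$loss, v$terms["l1"], v$d_gen))
    }
  }
  record(0L, NA_real_)

  last_train <- NA_real_
  for (it in seq_len(steps)) {
    ii <- sample(tr_idx, min(state$batch_train, length(tr_idx)))
    b <- augment(slice_batch(pairs, ii))
    gf <- generator_forward(b$input, gcfg, gp, keep_cache = TRUE)
    df <- discriminator_forward(gf$out, dcfg, dp, keep_cache = TRUE)
    loss <- generator_loss(gf$out, b$label, df$prob, w, tv_reduction,
                           ssim_literal_sign)
    if (!is.finite(loss)) {
      stop(sprintf("generator loss diverged at step %d (%.3g)", it, loss))
    }
    last_train <- as.numeric(loss)
    nb <- length(ii)
    dgen <- sign(gf$out - b$label) / length(gf$out)
    dgen <- dgen + w$gamma * tv_grad(gf$out, tv_reduction)
    dprob <- -2 * w$alpha * (1 - df$prob) / nb
    db <- discriminator_backward(dprob, dcfg, dp, df$cache, need_dx = TRUE)
    dgen <- dgen + db$dx
    if (w$beta > 0) {
      sg <- ssim_global_batch(gf$out, b$label, 1e-4, 9e-4, grad = TRUE)
      sgn <- if (ssim_literal_sign) 1 else -1
      dgen <- dgen + sgn * w$beta * sg$grad
    }
    ggr <- generator_backward(dgen, gcfg, gp, gf$cache)
    up <- adam_step(gp, ggr, gst, state$gen_lr)
    gp <- up$params; gst <- up$state

    if (it %% state$gen_updates_per_disc == 0) {
      ii <- sample(tr_idx, min(state$batch_train, length(tr_idx)))
      b <- augment(slice_batch(pairs, ii))
      fake <- generator_forward(b$input, gcfg, gp)
      dfk <- discriminator_forward(fake, dcfg, dp, keep_cache = TRUE)
      drl <- discriminator_forward(b$label, dcfg, dp, keep_cache = TRUE)
      dl <- discriminator_loss(dfk$prob, drl$prob)
      if (!is.finite(dl)) stop(sprintf("discriminator loss diverged at step %d", it))
      nb <- length(ii)
      gfk <- discriminator_backward(2 * dfk$prob / nb, dcfg, dp, dfk$cache)$grads
      grl <- discriminator_backward(-2 * (1 - drl$prob) / nb, dcfg, dp,
                                    drl$cache)$grads
      dgr <- tree_map2(`+`, gfk, grl)
      upd <- adam_step(dp, dgr, dst, state$disc_lr)
      dp <- upd$params; dst <- upd$state
    }
    if (it %% val_every == 0 || it == steps) record(it, last_train)
  }
  hist <- do.call(rbind, hist)
  structure(list(gen = best$gen, disc = best$disc, gcfg = gcfg, dcfg = dcfg,
                 weights = w, state = state,
                 norm = list(mean = nmean, sd = nsd),
                 history = hist, best_step = best$step,
                 final_gen = gp, final_disc = dp),
            class = "sr_model")
}

#' @export
print.sr_model <- function(x, ...) {
  cat(sprintf(
    "<sr_model> generator %s params, discriminator %s params, best step %d (val loss %.5f)\n",
    format(n_params(x$gen), big.mark = ","),
    format(n_params(x$disc), big.mark = ","),
    x$best_step, min(x$history$val_loss)))
  invisible(x)
}

#' Tiled inference with a trained generator
#'
#' Normalizes the image with the model's stored statistics, runs the
#' generator over tiles of side `tile` with the given overlap, blends
#' overlapping tiles with linear feathering (discarding a `trim` margin of
#' each tile where the zero-padded convolutions distort the prediction,
#' except along the image boundary), and de-normalizes. With `tile = NULL`
#' the whole image is processed in one pass.
#'
#' @param model An `sr_model`.
#' @param image Array `(H, W, C)` (or a matrix for single-channel models).
#' @param tile Tile side (divisible by `2^depth`), or NULL.
#' @param overlap Tile overlap in pixels (0 gives exact tile concatenation).
#' @param trim Margin of each tile excluded from blending (at most
#'   `overlap / 2`; default `floor(overlap / 2)`).
#' @return Array `(H, W, C)` of the same spatial size as the input.
#' @export
gan_infer <- function(model, image, tile = NULL, overlap = 16,
                      trim = floor(overlap / 2)) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1)
  d <- dim(image)
  cfg <- model$gcfg
  div <- 2^cfg$depth
  for (ch in seq_len(d[3])) {
    image[, , ch] <- (image[, , ch] - model$norm$mean[ch]) / model$norm$sd[ch]
  }
  run <- function(img) {
    out <- generator_forward(array(img, c(dim(img), 1)), cfg, model$gen)
    array(out, dim(img))
  }
  if (is.null(tile)) {
    out <- run(image)
  } else {
    if (tile < div || tile %% div != 0) {
      stop(sprintf("tile must be a positive multiple of %d", div))
    }
    if (overlap < 0 || overlap >= tile) stop("need 0 <= overlap < tile")
    pos <- function(n) {
      if (tile >= n) return(1L)
      p <- seq(1L, n - tile + 1L, by = tile - overlap)
      if (p[length(p)] != n - tile + 1L) p <- c(p, n - tile + 1L)
      p
    }
    if (trim > overlap / 2) stop("trim must be at most overlap / 2")
    ramp <- max(overlap - 2 * trim, 1)
    acc <- array(0, d); wsum <- matrix(0, d[1], d[2])
    for (r in pos(d[1])) for (c in pos(d[2])) {
      rr <- r:(r + tile - 1); ccx <- c:(c + tile - 1)
      o <- run(image[rr, ccx, , drop = FALSE])
      wprof <- function(p0, n) {
        # feather over the untrimmed overlap; keep full weight at image edges
        w <- pmin(pmin(seq_len(tile) - trim, tile - trim + 1 - seq_len(tile)),
                  ramp) / ramp
        w <- pmax(w, 0)
        if (p0 == 1) w[seq_len(trim + ramp)] <- 1
        if (p0 + tile - 1 == n) w[tile - trim - ramp + seq_len(trim + ramp)] <- 1
        w
      }
      wt <- outer(wprof(r, d[1]), wprof(c, d[2]))
      for (ch in seq_len(d[3])) {
        acc[rr, ccx, ch] <- acc[rr, ccx, ch] + o[, , ch] * wt
      }
      wsum[rr, ccx] <- wsum[rr, ccx] + wt
    }
    out <- acc / array(wsum, d)
  }
  for (ch in seq_len(d[3])) {
    out[, , ch] <- out[, , ch] * model$norm$sd[ch] + model$norm$mean[ch]
  }
  out
}
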