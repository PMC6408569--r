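test_that("leaky ReLU follows its piecewise definition", {
  expect_identical(lrelu(5), 5)
  expect_identical(lrelu(-1), -0.1)
  expect_identical(lrelu(0), 0)
  x <- array(c(-2, -0.5, 0, 0.5, 2, -10), c(3, 2, 1, 1))
  expect_equal(as.vector(lrelu(x)), c(-0.2, -0.05, 0, 0.5, 2, -1))
})

test_that("network configurations enforce their structural invariants", {
  expect_error(discriminator_config(base_channels = 8, n_blocks = 5,
                                    fc_width = 100), "fc_width")
  d <- discriminator_config(base_channels = 8, n_blocks = 5)
  expect_identical(d$fc_width, 256L)
  expect_error(generator_config(depth = 0))
})

test_that("generator widths double along the down path and mirror back", {
  cfg <- generator_config(base_channels = 32, depth = 3, in_channels = 2)
  set.seed(1)
  p <- init_generator(cfg)
  down_out <- vapply(p$down, function(b) dim(b$c2$w)[4], integer(1))
  expect_identical(down_out, c(64L, 128L, 256L))
  expect_identical(dim(p$bridge$w)[3:4], c(256L, 256L))
  up_out <- vapply(p$up, function(b) dim(b$c2$w)[4], integer(1))
  expect_identical(up_out, c(32L, 64L, 128L))
  expect_identical(dim(p$final$w)[4], 2L)
})

test_that("parameter count equals the closed-form layer sum", {
  cfg <- generator_config(base_channels = 8, depth = 2, in_channels = 2)
  set.seed(2)
  p <- init_generator(cfg)
  f <- 8; k <- 3
  conv_n <- function(ci, co) k * k * ci * co + co
  expected <- conv_n(2, f) +
    conv_n(f, f) + conv_n(f, 2 * f) +           # down 1
    conv_n(2 * f, 2 * f) + conv_n(2 * f, 4 * f) + # down 2
    conv_n(4 * f, 4 * f) +                      # bridge
    conv_n(8 * f, 4 * f) + conv_n(4 * f, 2 * f) + # up 2
    conv_n(4 * f, 2 * f) + conv_n(2 * f, f) +   # up 1
    conv_n(f, 2)                                # output projection
  expect_equal(cohsr:::n_params(p), expected)
  dcfg <- discriminator_config(base_channels = 4, n_blocks = 3)
  dp <- init_discriminator(dcfg, 1)
  fw <- 4 * 2^3
  expected_d <- conv_n(1, 4) +
    sum(vapply(1:3, function(b) conv_n(4 * 2^(b - 1), 4 * 2^(b - 1)) +
                 conv_n(4 * 2^(b - 1), 4 * 2^b), numeric(1))) +
    (fw * fw + fw) + (fw + 1)
  expect_equal(cohsr:::n_params(dp), expected_d)
})

test_that("generator forward preserves patch geometry and rejects bad sizes", {
  cfg <- generator_config(base_channels = 4, depth = 3, in_channels = 2)
  set.seed(3)
  p <- init_generator(cfg)
  x <- array(rnorm(128 * 128 * 2), c(128, 128, 2, 1))
  y <- generator_forward(x, cfg, p)
  expect_identical(dim(y), c(128L, 128L, 2L, 1L))
  bad <- array(0, c(100, 100, 2, 1))
  expect_error(generator_forward(bad, cfg, p), "divisible by 8")
})

test_that("discriminator output lies in (0,1) and pools at the documented size", {
  cfg <- discriminator_config(base_channels = 4, n_blocks = 5)
  set.seed(4)
  p <- init_discriminator(cfg, 2)
  x <- array(rnorm(128 * 128 * 2 * 3), c(128, 128, 2, 3))
  res <- discriminator_forward(x, cfg, p, keep_cache = TRUE)
  expect_true(all(res$prob > 0 & res$prob < 1))
  # five halvings of 128 leave a 4 x 4 map entering the pooling layer
  expect_identical(res$cache$gap_in_dim, c(4L, 4L))
  # channels after the last block: base * 2^5
  expect_identical(dim(res$cache$blocks[[5]]$a2)[3], 128L)
  expect_error(discriminator_forward(array(0, c(48, 48, 2, 1)), cfg, p),
               "divisible")
})

test_that("generator is translation-equivariant in the interior", {
  cfg <- generator_config(base_channels = 4, depth = 1, in_channels = 1)
  set.seed(5)
  p <- init_generator(cfg)
  x <- array(rnorm(48 * 48), c(48, 48, 1, 1))
  sh <- 2 # one full pooling period
  xs <- x[c((sh + 1):48, 1:sh), , , , drop = FALSE]
  y <- generator_forward(x, cfg, p)
  ys <- generator_forward(xs, cfg, p)
  yshift <- y[c((sh + 1):48, 1:sh), , , , drop = FALSE]
  interior <- 17:32
  expect_lt(max(abs(ys[interior, interior, , ] - yshift[interior, interior, , ])),
            1e-4)
})

test_that("loss terms vanish on perfect output and match brute-force arithmetic", {
  # constant perfect output: every term (L1, TV, adversarial) vanishes
  lab <- array(0.7, c(2, 2, 1, 1))
  w <- loss_weights()
  l0 <- generator_loss(lab, lab, 1, w)
  expect_equal(as.numeric(l0), 0)
  # perfect but non-constant output: only the TV regularizer remains
  set.seed(6)
  lab2 <- array(rnorm(4), c(2, 2, 1, 1))
  l0b <- generator_loss(lab2, lab2, 1, w, tv_reduction = "sum")
  expect_equal(as.numeric(l0b), w$gamma * tv_loss(lab2, "sum"))
  # hand-set 2x2 patch, independent recomputation
  g <- array(c(0.2, -0.4, 0.9, 0.1), c(2, 2, 1, 1))
  z <- array(c(0.0, 0.5, 1.0, -0.3), c(2, 2, 1, 1))
  d <- 0.3
  l <- generator_loss(g, z, d, w, tv_reduction = "sum")
  l1_manual <- mean(abs(c(0.2, -0.9, -0.1, 0.4)))
  tv_manual <- abs(-0.4 - 0.2) + abs(0.1 - 0.9) +  # vertical forward diffs
    abs(0.9 - 0.2) + abs(0.1 - (-0.4))             # horizontal forward diffs
  adv_manual <- (1 - d)^2
  expect_equal(as.numeric(l),
               l1_manual + w$gamma * tv_manual + w$alpha * adv_manual)
  tm <- attr(l, "terms")
  expect_equal(unname(tm["l1"]), l1_manual)
  expect_equal(unname(tm["tv"]), w$gamma * tv_manual)
  # beta = 0 reduces the extended loss to the base form
  wb <- loss_weights(beta = 0.01)
  lb <- generator_loss(g, z, d, wb, tv_reduction = "sum")
  expect_gt(abs(as.numeric(lb) - as.numeric(l)), 0)
  expect_equal(as.numeric(generator_loss(g, z, d, loss_weights(beta = 0),
                                         tv_reduction = "sum")),
               as.numeric(l))
})

test_that("discriminator loss spans [0, 2] with the documented landmark values", {
  expect_equal(discriminator_loss(0, 1), 0)
  expect_equal(discriminator_loss(1, 0), 2)
  expect_equal(discriminator_loss(0.5, 0.5), 0.5)
  set.seed(7)
  for (i in 1:20) {
    l <- discriminator_loss(runif(1), runif(1))
    expect_gte(l, 0); expect_lte(l, 2)
  }
  expect_error(discriminator_loss(1.2, 0.5), "\\[0, 1\\]")
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(8)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  z <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  eps <- 1e-6
  # TV subgradient (away from ties)
  g <- cohsr:::tv_grad(x, "mean")
  i <- c(3, 4, 1, 2)
  xp <- x; xp[3, 4, 1, 2] <- xp[3, 4, 1, 2] + eps
  num <- (tv_loss(xp, "mean") - tv_loss(x, "mean")) / eps
  expect_equal(g[3, 4, 1, 2], num, tolerance = 1e-4)
  # global SSIM gradient
  sb <- cohsr:::ssim_global_batch(x, z, 1e-4, 9e-4, grad = TRUE)
  xp <- x; xp[2, 5, 2, 1] <- xp[2, 5, 2, 1] + eps
  num <- (cohsr:::ssim_global_batch(xp, z, 1e-4, 9e-4) - sb$value) / eps
  expect_equal(sb$grad[2, 5, 2, 1], num, tolerance = 1e-5)
})

test_that("augmentation is reproducible, unbiased and invertible", {
  set.seed(10)
  mkbatch <- function(n, s = 8) list(
    input = array(rnorm(s * s * 1 * n), c(s, s, 1, n)),
    label = array(rnorm(s * s * 1 * n), c(s, s, 1, n)))
  b <- mkbatch(6)
  set.seed(123); a1 <- augment(b)
  set.seed(123); a2 <- augment(b)
  expect_identical(a1, a2)
  # flip and rotation frequencies over many draws
  set.seed(11)
  big <- mkbatch(8000, 4)
  ab <- augment(big)
  expect_lt(abs(mean(attr(ab, "flips")) - 0.5), 0.02)
  rot_frac <- tabulate(attr(ab, "rots") + 1, 4) / 8000
  expect_true(all(abs(rot_frac - 0.25) < 0.02))
  # input and label receive identical transforms: a pair equal before stays equal
  eq <- list(input = big$input[, , , 1:5, drop = FALSE],
             label = big$input[, , , 1:5, drop = FALSE])
  set.seed(12)
  ae <- augment(eq)
  expect_identical(ae$input, ae$label)
  # rotating onward by the complement restores the original
  set.seed(13)
  one <- mkbatch(1)
  a <- augment(one)
  k <- attr(a, "rots")[1]
  restored <- cohsr:::rot90_batch(a$input, (4 - k) %% 4)
  if (attr(a, "flips")[1]) restored <- restored[, rev(seq_len(8)), , , drop = FALSE]
  expect_equal(restored, one$input)
  expect_error(augment(list(input = array(0, c(4, 6, 1, 1)),
                            label = array(0, c(4, 6, 1, 1)))), "square")
})

test_that("a short adversarial run trains, logs and reproduces bit-exactly", {
  ds <- tiny_patchset(n = 12, patch = 32)
  gcfg <- generator_config(base_channels = 2, depth = 1, in_channels = 2)
  dcfg <- discriminator_config(base_channels = 2, n_blocks = 5)
  st <- train_state(rng_seed = 3, batch_train = 4, batch_val = 4)
  m1 <- gan_train(ds, gcfg, dcfg, loss_weights(), st, steps = 24, val_every = 12)
  expect_s3_class(m1, "sr_model")
  expect_true(all(is.finite(m1$history$val_loss)))
  expect_identical(m1$history$step, c(0L, 12L, 24L))
  m2 <- gan_train(ds, gcfg, dcfg, loss_weights(), st, steps = 24, val_every = 12)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$gen, m2$gen)
  # at initialization the data-fidelity (L1) term dominates the composite loss
  t0 <- m1$history[1, ]
  expect_gt(t0$val_l1, t0$val_adv)
  expect_gt(t0$val_l1, t0$val_tv)
  expect_error(gan_train(list(input = ds$input[, , , 1:2],
                              label = ds$label[, , , 1:2]),
                         gcfg, dcfg, steps = 4), "too small")
})

test_that("tiled inference matches whole-image inference", {
  set.seed(20)
  gcfg <- generator_config(base_channels = 4, depth = 2, in_channels = 2)
  model <- structure(list(gen = init_generator(gcfg), gcfg = gcfg,
                          norm = list(mean = c(0, 0), sd = c(1, 1))),
                     class = "sr_model")
  img <- array(rnorm(96 * 96 * 2), c(96, 96, 2))
  whole <- gan_infer(model, img)
  expect_identical(dim(whole), dim(img))
  tiled <- gan_infer(model, img, tile = 48, overlap = 32)
  expect_lt(sqrt(mean((whole - tiled)^2)), 1e-3)
  # zero overlap is exact tile concatenation
  t0 <- gan_infer(model, img, tile = 48, overlap = 0)
  concat <- img * 0
  for (r in c(1, 49)) for (c in c(1, 49)) {
    concat[r:(r + 47), c:(c + 47), ] <-
      gan_infer(model, img[r:(r + 47), c:(c + 47), , drop = FALSE])
  }
  expect_equal(t0, concat)
  expect_error(gan_infer(model, img, tile = 3), "multiple")
})
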