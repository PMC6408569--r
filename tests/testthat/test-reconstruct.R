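test_that("Tamura-of-gradient matches a brute-force recomputation and is scale invariant", {
  expect_identical(tamura_of_gradient(matrix(3.7, 8, 8)), 0)
  # hand-made 4x4 image against an elementwise independent recomputation
  img <- matrix(c(1, 2, 0, 4,
                  3, 1, 2, 0,
                  0, 5, 1, 2,
                  2, 0, 3, 1), 4, 4, byrow = TRUE)
  g <- matrix(0, 2, 2)
  for (i in 2:3) for (j in 2:3) {
    gy <- (img[i + 1, j] - img[i - 1, j]) / 2
    gx <- (img[i, j + 1] - img[i, j - 1]) / 2
    g[i - 1, j - 1] <- sqrt(gx^2 + gy^2)
  }
  expect_equal(tamura_of_gradient(img), sqrt(sd(g) / mean(g)))
  # sharp vs blurred ordering (4-px block checkerboard: sparse sharp edges)
  blk <- (outer(0:31 %/% 4, 0:31 %/% 4, `+`) %% 2) * 1
  k <- outer(dnorm(-2:2), dnorm(-2:2)); k <- k / sum(k)
  blur <- matrix(0, 32, 32)
  for (i in 3:30) for (j in 3:30) {
    blur[i, j] <- sum(blk[(i - 2):(i + 2), (j - 2):(j + 2)] * k)
  }
  expect_gt(tamura_of_gradient(blk), tamura_of_gradient(blur[3:30, 3:30]))
  # invariance to positive rescaling
  set.seed(1)
  for (s in c(0.1, 3, 40)) {
    m <- matrix(runif(100), 10)
    expect_equal(tamura_of_gradient(s * m), tamura_of_gradient(m))
  }
  expect_error(tamura_of_gradient(matrix(1, 2, 2)), "3x3")
})

test_that("autofocus recovers a known sample-to-sensor distance", {
  opt <- optical_params(0.55, 0.002, z2 = 300, pixel_pitch = 1.12)
  obj <- amplitude_object(size = 128, seed = 2)
  z0 <- 303
  holo <- Mod(propagate(obj, z0, pad = 1)$values)^2
  fr <- autofocus(holo, 200, 400, 5, opt)
  expect_s3_class(fr, "focus_result")
  expect_lt(abs(fr$best_z - z0), 5)
  expect_length(fr$metric_values, length(fr$z_grid))
  # degenerate single-height grid returns that height
  fr1 <- autofocus(holo, 290, 291, 5, opt)
  expect_identical(fr1$best_z, 290)
  # metric curve is maximal at (or adjacent to) the returned height
  expect_lt(abs(fr$z_grid[which.max(fr$metric_values)] - fr$best_z), 5)
  expect_error(autofocus(holo, 400, 300, 5, opt), "z_min")
})

test_that("autofocus recovers the height within the grid step for most seeded objects", {
  opt <- optical_params(0.55, 0.002, z2 = 300, pixel_pitch = 1.12)
  step <- 5
  hits <- vapply(1:20, function(s) {
    obj <- amplitude_object(size = 128, seed = s, amp = c(0.6, 1))
    z0 <- 300 + (s - 10) * 0.7
    holo <- Mod(propagate(obj, z0, pad = 1)$values)^2
    fr <- autofocus(holo, 250, 350, step, opt)
    abs(fr$best_z - z0) <= step
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("SVD background subtraction removes the shared rank-1 component", {
  set.seed(4)
  n <- 48
  pattern <- outer(sin(seq(0, 6, length.out = n)), cos(seq(0, 5, length.out = n))) + 2
  pc <- pattern - mean(pattern)
  # disjoint per-image signals (decorrelated from the pattern so residual
  # correlation isolates the removal quality) plus the common fixed pattern
  ims <- lapply(1:4, function(k) {
    sig <- matrix(0, n, n)
    sig[((k - 1) * 12 + 1):(k * 12), ] <- matrix(0.4 * runif(12 * n), 12)
    sig <- sig - pc * sum(sig * pc) / sum(pc^2)
    10 * pattern + sig - min(sig)
  })
  st <- hologram_stack(ims, heights = 300 + 25 * (0:3), 1.12, 0.55)
  out <- svd_background_subtract(st)
  for (im in out$intensities) {
    expect_lt(abs(cor(as.vector(im), as.vector(pattern))), 0.05)
  }
  # identical images collapse to near-constant output
  st2 <- hologram_stack(rep(list(pattern), 3), c(300, 325, 350), 1.12, 0.55)
  out2 <- svd_background_subtract(st2)
  expect_lt(sd(out2$intensities[[1]]), 1e-8 * mean(pattern))
  # the mean of each image is preserved
  expect_equal(mean(out$intensities[[2]]), mean(ims[[2]]), tolerance = 1e-2)
  expect_error(svd_background_subtract(
    hologram_stack(ims[1:2], c(300, 325), 1.12, 0.55)), "at least 3")
})

test_that("removed component agrees with an independent power-iteration oracle", {
  set.seed(9)
  ims <- lapply(1:4, function(k) matrix(runif(30 * 30) + k, 30))
  st <- hologram_stack(ims, 300 + 20 * (0:3), 1.12, 0.55)
  m <- vapply(ims, as.vector, numeric(900))
  # dominant singular triplet by power iteration on the 4x4 Gram matrix
  g <- crossprod(m)
  v <- rep(1, 4)
  for (i in 1:200) { v <- g %*% v; v <- v / sqrt(sum(v^2)) }
  u <- m %*% v; s1 <- sqrt(sum(u^2)); u <- u / s1
  resid <- m - s1 * tcrossprod(u, v)
  resid <- sweep(resid, 2, colMeans(m) - colMeans(resid), `+`)
  resid[resid < 0] <- 0
  out <- svd_background_subtract(st)
  for (k in 1:4) {
    expect_equal(as.vector(out$intensities[[k]]), resid[, k], tolerance = 1e-6)
  }
})

test_that("multi-height recovery reproduces a pure-amplitude object", {
  obj <- amplitude_object(size = 128, seed = 5)
  st <- simulate_stack(obj, default_heights())
  errs <- vapply(c(1, 10, 50), function(ni) {
    rec <- multiheight_phase_recovery(st, n_iter = ni, tol = 0)
    mean(abs(Mod(rec$values) - Mod(obj$values))) / mean(Mod(obj$values))
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  # the logged error trend improves over iterations
  expect_lt(errs[3], errs[1])
  expect_lte(errs[3], errs[2])
})

test_that("recovery is self-consistent with every measured height", {
  obj <- amplitude_object(size = 96, seed = 6)
  hts <- default_heights()
  st <- simulate_stack(obj, hts)
  mism <- function(rec) {
    vapply(seq_along(hts), function(k) {
      fk <- propagate(rec, hts[k], pad = 1)
      mean(abs(Mod(fk$values) - sqrt(st$intensities[[k]])))
    }, numeric(1))
  }
  m1 <- mism(multiheight_phase_recovery(st, n_iter = 1))
  m50 <- mism(multiheight_phase_recovery(st, n_iter = 50))
  expect_true(all(m50 < m1))
})

test_that("data fidelity is non-increasing on noise-free stacks", {
  obj <- amplitude_object(size = 96, seed = 7)
  st <- simulate_stack(obj, default_heights())
  rec <- multiheight_phase_recovery(st, n_iter = 30, tol = 0)
  fid <- attr(rec, "fidelity")
  expect_length(fid, 30)
  expect_true(all(diff(fid) <= 1e-6))
})

test_that("zero-iteration recovery is the back-propagated first measurement", {
  obj <- amplitude_object(size = 64, seed = 8)
  st <- simulate_stack(obj, 320)
  rec <- multiheight_phase_recovery(st, n_iter = 0)
  ref <- propagate(complex_field(sqrt(st$intensities[[1]]) + 0i,
                                 st$pixel_pitch, st$wavelength), -320, pad = 1)
  expect_equal(rec$values, ref$values, tolerance = 1e-12)
  # mismatched shapes are rejected at construction
  expect_error(hologram_stack(list(matrix(1, 4, 4), matrix(1, 5, 5)),
                              c(300, 325), 1.12, 0.55), "shape")
})
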