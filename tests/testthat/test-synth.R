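test_that("object generation is a pure function of spec and seed", {
  spec <- synth_spec("tissue_blobs", size = 64, seed = 7)
  o1 <- make_object(spec)
  o2 <- make_object(spec)
  expect_identical(o1$values, o2$values)
  spec2 <- spec; spec2$seed <- 8
  expect_false(identical(make_object(spec2)$values, o1$values))
  # generators leave the caller's RNG state untouched
  set.seed(42); before <- .Random.seed
  invisible(make_object(spec))
  expect_identical(.Random.seed, before)
})

test_that("degenerate ranges give a unit-amplitude zero-phase field", {
  spec <- synth_spec("tissue_blobs", size = 32, amplitude_range = c(1, 1),
                     phase_range = c(0, 0), seed = 1)
  o <- make_object(spec)
  expect_equal(Mod(o$values), matrix(1, 32, 32))
  expect_equal(Arg(o$values), matrix(0, 32, 32))
})

test_that("resolution-target line pairs concentrate power at the pair frequency", {
  pitch <- 0.5; lp <- 3
  spec <- synth_spec("resolution_target", size = 96, pixel_pitch = pitch,
                     line_px = lp, seed = 1)
  o <- make_object(spec)
  amp <- Mod(o$values)
  rs <- radial_spectrum(amp - mean(amp), 24, pixel_pitch = pitch)
  f0 <- 1 / (2 * lp * pitch)  # one line pair per 2 * line_px pixels
  width <- rs$freq[2] - rs$freq[1]
  expect_lt(abs(rs$freq[which.max(rs$power)] - f0), width)
})

test_that("free-space propagation of an empty field gives unit intensity", {
  spec <- synth_spec("tissue_blobs", size = 48, amplitude_range = c(1, 1),
                     phase_range = c(0, 0), seed = 1)
  st <- simulate_stack(make_object(spec), c(200, 300, 400))
  for (im in st$intensities) expect_equal(im, matrix(1, 48, 48), tolerance = 1e-10)
  expect_error(simulate_stack(make_object(spec), numeric(0)), "height")
})

test_that("simulated stacks conserve energy before noise", {
  obj <- amplitude_object(size = 96, seed = 3)
  st <- simulate_stack(obj, default_heights())
  e0 <- sum(Mod(obj$values)^2)
  for (im in st$intensities) expect_lt(abs(sum(im) - e0) / e0, 1e-3)
})

test_that("background injection is removed by the SVD step", {
  obj <- amplitude_object(size = 64, seed = 4)
  clean <- simulate_stack(obj, default_heights())
  set.seed(11)
  f <- cohsr:::fft_freq(64, 1)
  filt <- exp(-outer(f^2, f^2, `+`) * (pi * 4)^2)
  bg <- Re(stats::fft(stats::fft(matrix(rnorm(64^2), 64)) * filt,
                      inverse = TRUE)) / 64^2
  bg <- 0.3 * (bg - mean(bg)) / sd(bg) + 0.6
  dirty <- hologram_stack(lapply(clean$intensities, function(i) i + bg),
                          clean$heights, clean$pixel_pitch, clean$wavelength)
  rm_bg <- svd_background_subtract(dirty)
  corr_before <- mean(vapply(dirty$intensities, function(i)
    abs(cor(as.vector(i), as.vector(bg))), numeric(1)))
  corr_after <- mean(vapply(rm_bg$intensities, function(i)
    abs(cor(as.vector(i), as.vector(bg))), numeric(1)))
  expect_gt(corr_before / corr_after, 10)
})

test_that("the simulated stack is accepted end-to-end by phase recovery", {
  obj <- amplitude_object(size = 96, seed = 5)
  st <- simulate_stack(obj, default_heights())
  rec <- multiheight_phase_recovery(st, n_iter = 50)
  err <- mean(abs(Mod(rec$values) - Mod(obj$values))) / mean(Mod(obj$values))
  expect_lt(err, 0.05)
})

test_that("sub-pixel sets carry a consistent ground-truth shift table", {
  obj <- make_object(synth_spec("tissue_blobs", size = 96, pixel_pitch = 0.75,
                                seed = 6))
  one <- simulate_subpixel_set(obj, raster = c(1, 1), factor = 2, height = 250)
  expect_length(one$lr, 1)
  expect_equal(unname(one$table$shifts), matrix(0, 1, 2))
  sim <- simulate_subpixel_set(obj, raster = c(2, 2), factor = 2, height = 250)
  est <- estimate_shift_table(sim$lr, grid_shape = c(2, 2))
  expect_lt(sqrt(mean((est$shifts - sim$table$shifts)^2)), 0.05)
  expect_error(simulate_subpixel_set(obj, raster = c(5, 5), factor = 2,
                                     height = 250), "multiple")
})

test_that("training sets have the documented geometry and reproduce exactly", {
  ds <- tiny_patchset(n = 3, patch = 32)
  expect_identical(dim(ds$input), c(32L, 32L, 2L, 3L))
  expect_identical(dim(ds$label), dim(ds$input))
  expect_identical(ds$channels, c("real", "imag"))
  ds2 <- tiny_patchset(n = 3, patch = 32)
  expect_identical(ds$input, ds2$input)
  expect_identical(ds$label, ds2$label)
})

test_that("the coherent aperture cutoff removes out-of-band energy", {
  lam <- 0.532; na_low <- 0.13
  spec <- synth_spec("tissue_blobs", size = 180, pixel_pitch = 1.625,
                     phase_range = c(0, 0.8), seed = 9, wavelength = lam)
  ds <- make_training_set(spec, 2, "na_lowpass", patch = 64, na_low = na_low,
                          register = FALSE)
  fc <- na_low / lam
  for (i in 1:2) {
    lr <- ds$input[, , 1, i] ; hr <- ds$label[, , 1, i]
    rs_lr <- radial_spectrum(lr - mean(lr), 24, pixel_pitch = spec$pixel_pitch)
    rs_hr <- radial_spectrum(hr - mean(hr), 24, pixel_pitch = spec$pixel_pitch)
    beyond <- rs_lr$freq > fc
    e_lr_beyond <- sum((rs_lr$power * rs_lr$count)[beyond])
    e_hr_total <- sum(rs_hr$power * rs_hr$count)
    expect_lt(e_lr_beyond / e_hr_total, 0.01)
  }
  expect_identical(ds$channels, "phase")
})
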