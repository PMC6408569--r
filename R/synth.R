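# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

# smooth zero-mean unit-sd Gaussian random field (FFT-filtered white noise)
smooth_field <- function(size, scale_px) {
  n <- matrix(stats::rnorm(size^2), size, size)
  f <- fft_freq(size, 1)
  filt <- exp(-outer(f^2, f^2, `+`) * (pi * scale_px)^2)
  u <- Re(ifft2(fft2(n) * filt))
  (u - mean(u)) / stats::sd(u)
}

#' Specification for a synthetic complex object
#'
#' Describes the object emulated in place of stained tissue sections: its
#' kind, grid, amplitude/phase ranges, and the acquisition imperfections
#' (additive intensity noise, fixed-pattern background) applied downstream.
#'
#' @param object_kind `"tissue_blobs"` (smoothed random transmission typical
#'   of connected tissue), `"resolution_target"` (line-pair bars of known
#'   spacing) or `"phase_gratings"` (sinusoidal pure-phase gratings).
#' @param size Grid side in pixels.
#' @param pixel_pitch Grid pitch in um (default 0.3733, the 6x6
#'   super-resolved sensor grid).
#' @param amplitude_range,phase_range Transmission amplitude interval within
#'   `[0, 1]` and phase interval in radians.
#' @param noise_sigma Additive Gaussian intensity-noise SD (shot-noise proxy).
#' @param background_strength Scale of the shared fixed-pattern background.
#' @param seed RNG seed; every generator is a pure function of (spec, seed).
#' @param feature_scale Characteristic feature size in um for tissue blobs
#'   (default 10, a typical cell-scale correlation length).
#' @param line_px Line width in pixels for resolution targets (a line pair
#'   spans `2 * line_px` pixels).
#' @param wavelength Illumination wavelength in um.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(object_kind = c("tissue_blobs", "resolution_target",
                                       "phase_gratings"),
                       size = 256, pixel_pitch = 0.3733,
                       amplitude_range = c(0.85, 1), phase_range = c(0, 1),
                       noise_sigma = 0.01, background_strength = 0.05,
                       seed = 1, feature_scale = 10, line_px = 3,
                       wavelength = 0.55) {
  object_kind <- match.arg(object_kind)
  stopifnot(size >= 8, pixel_pitch > 0, wavelength > 0)
  stopifnot(length(amplitude_range) == 2, length(phase_range) == 2)
  if (amplitude_range[1] < 0 || amplitude_range[2] > 1 ||
      diff(amplitude_range) < 0) {
    stop("amplitude_range must be an increasing interval within [0, 1]")
  }
  if (diff(phase_range) < 0) stop("phase_range must be increasing")
  stopifnot(noise_sigma >= 0, background_strength >= 0)
  structure(list(object_kind = object_kind, size = as.integer(size),
                 pixel_pitch = pixel_pitch,
                 amplitude_range = amplitude_range, phase_range = phase_range,
                 noise_sigma = noise_sigma,
                 background_strength = background_strength,
                 seed = seed, feature_scale = feature_scale,
                 line_px = as.integer(line_px), wavelength = wavelength),
            class = "synth_spec")
}

#' Generate a synthetic complex object
#'
#' Produces a seeded complex transmission field from a [synth_spec]:
#' tissue-like smoothed random amplitude and phase, line-pair resolution
#' targets, or sinusoidal phase gratings. Amplitude and phase stay within the
#' spec's ranges; the same seed gives a bit-identical field.
#'
#' @param spec A [synth_spec].
#' @return A [complex_field].
#' @export
make_object <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  s <- spec$size
  ar <- spec$amplitude_range; pr <- spec$phase_range
  with_seed(spec$seed, {
    if (spec$object_kind == "tissue_blobs") {
      # scattered cell-like blobs on a clear background: absorbing and
      # phase-shifting Gaussian bumps with a shared set of centres, so the
      # object has the sparse edge structure of a smear/section
      scale_px <- spec$feature_scale / spec$pixel_pitch
      fov_cells <- (s / scale_px)^2
      nb <- max(3L, round(0.25 * fov_cells))
      cy <- stats::runif(nb, 1, s); cx <- stats::runif(nb, 1, s)
      rr <- scale_px * stats::runif(nb, 0.25, 0.5)
      wa <- stats::runif(nb, 0.4, 1); wp <- stats::runif(nb, 0.4, 1)
      xs <- seq_len(s)
      a_acc <- matrix(0, s, s); p_acc <- matrix(0, s, s)
      for (k in seq_len(nb)) {
        # periodic distances keep blobs consistent with periodic propagation
        dy2 <- (pmin(abs(xs - cy[k]), s - abs(xs - cy[k])))^2
        dx2 <- (pmin(abs(xs - cx[k]), s - abs(xs - cx[k])))^2
        bump <- exp(-outer(dy2, dx2, `+`) / (2 * rr[k]^2))
        a_acc <- a_acc + wa[k] * bump
        p_acc <- p_acc + wp[k] * bump
      }
      amp <- ar[2] - diff(ar) * pmin(a_acc, 1)
      ph <- pr[1] + diff(pr) * pmin(p_acc, 1)
    } else if (spec$object_kind == "resolution_target") {
      period <- 2L * spec$line_px
      bars <- ((col(matrix(0, s, s)) - 1) %% period) < spec$line_px
      amp <- matrix(ar[1], s, s)
      amp[bars] <- ar[2]
      ph <- matrix(pr[1], s, s)
    } else { # phase_gratings
      period <- 2L * spec$line_px
      xg <- (col(matrix(0, s, s)) - 1) / period
      ph <- pr[1] + diff(pr) * (0.5 + 0.5 * sin(2 * pi * xg))
      amp <- matrix(ar[2], s, s)
    }
    complex_field(amp * exp(1i * ph), spec$pixel_pitch, spec$wavelength)
  })
}

#' Simulate a multi-height hologram stack
#'
#' Propagates a complex object to each sample-to-sensor height with the
#' angular-spectrum method and records the intensity, optionally adding a
#' shared fixed-pattern background (smooth seeded random field scaled by
#' `background_strength`) and additive Gaussian noise (`noise_sigma`), a
#' shot-noise proxy (a Poisson mode is available). Intensities are clipped at
#' zero. Propagation is periodic (`pad = 1`) so the simulated stack is exactly
#' energy-conserving and self-consistent with the reconstruction chain.
#'
#' @param obj A [complex_field].
#' @param heights Strictly increasing sample-to-sensor distances (um).
#' @param noise_sigma Additive Gaussian intensity-noise SD.
#' @param background_strength Scale of the shared background pattern.
#' @param seed RNG seed for background and noise.
#' @param poisson If TRUE, replace the Gaussian noise with Poisson counting
#'   noise at `1 / noise_sigma^2` photons per unit intensity.
#' @return A [hologram_stack].
#' @export
simulate_stack <- function(obj, heights, noise_sigma = 0,
                           background_strength = 0, seed = 1,
                           poisson = FALSE) {
  stopifnot(inherits(obj, "complex_field"))
  if (length(heights) == 0) stop("at least one height is required")
  if (any(diff(heights) <= 0)) stop("heights must be strictly increasing")
  with_seed(seed, {
    s <- nrow(obj$values)
    bg <- if (background_strength > 0) {
      background_strength * smooth_field(s, s / 16)
    } else matrix(0, s, s)
    ims <- lapply(heights, function(h) {
      i <- Mod(propagate(obj, h, pad = 1)$values)^2 + bg
      if (noise_sigma > 0) {
        if (poisson) {
          n_ph <- 1 / noise_sigma^2
          i <- stats::rpois(length(i), pmax(i, 0) * n_ph) / n_ph
          i <- matrix(i, s, s)
        } else {
          i <- i + matrix(stats::rnorm(s^2, 0, noise_sigma), s, s)
        }
      }
      i[i < 0] <- 0
      i
    })
    hologram_stack(ims, heights, obj$pixel_pitch, obj$wavelength)
  })
}

#' Simulate sub-pixel shifted low-resolution acquisitions
#'
#' Propagates the object to the sensor plane, then emulates a mechanical
#' sub-pixel raster scan: for each lateral position the high-resolution
#' intensity is sampled with `factor x factor` pixel binning at the raster's
#' sub-pixel offset (offsets `(i-1)/rows`, `(j-1)/cols` low-res pixels,
#' row-major; sampling wraps periodically, consistent with the periodic
#' propagation). Returns the LR images together with the ground-truth shift
#' table (image k equals the reference translated by the negated offset).
#'
#' @param obj A [complex_field] whose side is divisible by `factor`.
#' @param raster Integer (rows, cols) of lateral positions.
#' @param factor Pixel-binning factor (>= 1); `factor / rows` and
#'   `factor / cols` must be integers so offsets land on the HR grid.
#' @param height Sample-to-sensor distance (um).
#' @param noise_sigma Additive Gaussian intensity-noise SD per LR image.
#' @param seed RNG seed for the noise.
#' @return List with elements `lr` (list of LR matrices), `table`
#'   (a [shift_table]) and `hr_intensity` (the noise-free HR intensity).
#' @export
simulate_subpixel_set <- function(obj, raster = c(6, 6), factor = 6,
                                  height = 300, noise_sigma = 0, seed = 1) {
  stopifnot(inherits(obj, "complex_field"))
  if (factor < 1 || factor != round(factor)) stop("factor must be an integer >= 1")
  raster <- as.integer(raster); factor <- as.integer(factor)
  s <- nrow(obj$values)
  if (s %% factor != 0) stop("object side must be divisible by factor")
  i_hr <- Mod(propagate(obj, height, pad = 1)$values)^2
  m <- s %/% factor
  offs <- expand.grid(c = seq_len(raster[2]), r = seq_len(raster[1]))
  shifts <- matrix(0, nrow(offs), 2)
  with_seed(seed, {
    lr <- vector("list", nrow(offs))
    for (k in seq_len(nrow(offs))) {
      sr <- (offs$r[k] - 1) / raster[1]
      sc <- (offs$c[k] - 1) / raster[2]
      or_ <- sr * factor; oc <- sc * factor
      if (abs(or_ - round(or_)) > 1e-9 || abs(oc - round(oc)) > 1e-9) {
        stop("factor must be a multiple of the raster dimensions")
      }
      rows <- ((seq_len(s) - 1 + round(or_)) %% s) + 1
      cols <- ((seq_len(s) - 1 + round(oc)) %% s) + 1
      shifted <- i_hr[rows, cols]
      binned <- bin_box(shifted, factor)
      if (noise_sigma > 0) {
        binned <- binned + matrix(stats::rnorm(m^2, 0, noise_sigma), m, m)
        binned[binned < 0] <- 0
      }
      lr[[k]] <- binned
      shifts[k, ] <- c(-sr, -sc)
    }
    list(lr = lr, table = shift_table(shifts, rev(raster)),
         hr_intensity = i_hr)
  })
}

# factor x factor box binning (image side divisible by factor)
bin_box <- function(img, factor) {
  if (factor == 1) return(img)
  s <- nrow(img); m <- s %/% factor
  a <- array(img, c(factor, m, factor, m))
  apply(a, c(2, 4), mean)
}

#' Build a registered LR/HR training patch set
#'
#' Emulates the two training-data pipelines: generates seeded complex
#' objects, degrades the reconstructed field either by `pixel_binning`
#' (factor-binning of the real and imaginary channels, then bicubic
#' upsampling back to the HR grid; channels real+imag) or by `na_lowpass`
#' (hard circular aperture at `na_low / wavelength` in the field spectrum,
#' the ideal coherent transfer function of a low-NA objective; channel:
#' phase), registers each pair on the phase channel with [register_pair()]
#' (which crops `crop` px from every side), and extracts centred
#' `patch x patch` patches.
#'
#' @param spec A [synth_spec]; `spec$size` must exceed `patch + 2 * crop`.
#' @param n_pairs Number of patches (one per generated object).
#' @param degradation `"pixel_binning"` or `"na_lowpass"`.
#' @param patch Patch side in pixels (default 128).
#' @param factor Binning factor for `pixel_binning`.
#' @param na_low Aperture NA for `na_lowpass`.
#' @param crop Border crop applied by registration (default 50).
#' @param register Run the correlation-based registration (identity for the
#'   synthetically aligned pairs; set FALSE to skip the search and crop only).
#' @return A list of class `patch_dataset` with arrays `input` and `label` of
#'   shape `(patch, patch, channels, n_pairs)` and metadata fields.
#' @export
make_training_set <- function(spec, n_pairs,
                              degradation = c("pixel_binning", "na_lowpass"),
                              patch = 128, factor = 2, na_low = 0.13,
                              crop = 50, register = TRUE) {
  degradation <- match.arg(degradation)
  stopifnot(inherits(spec, "synth_spec"), n_pairs >= 1)
  s <- spec$size
  if (s - 2 * crop < patch) stop("spec$size must be at least patch + 2 * crop")
  nc <- if (degradation == "pixel_binning") 2L else 1L
  input <- array(0, c(patch, patch, nc, n_pairs))
  label <- array(0, c(patch, patch, nc, n_pairs))
  for (i in seq_len(n_pairs)) {
    ospec <- spec
    ospec$seed <- spec$seed + 1000L * i
    obj <- make_object(ospec)
    v <- obj$values
    if (degradation == "pixel_binning") {
      if (s %% factor != 0) stop("spec$size must be divisible by factor")
      lr_re <- upsample_to_target(bin_box(Re(v), factor), factor)
      lr_im <- upsample_to_target(bin_box(Im(v), factor), factor)
      lr_ph <- atan2(lr_im, lr_re)
      hr_ch <- list(Re(v), Im(v))
      lr_ch <- list(lr_re, lr_im)
    } else {
      fy <- fft_freq(s, spec$pixel_pitch)
      mask <- outer(fy^2, fy^2, `+`) <= (na_low / spec$wavelength)^2
      lr_v <- ifft2(fft2(v) * mask)
      lr_ph <- Arg(lr_v)
      hr_ch <- list(Arg(v))
      lr_ch <- list(lr_ph)
    }
    hr_ph <- Arg(v)
    if (register) {
      pr <- register_pair(lr_ph, hr_ph, max_rot = 1, rot_step = 0.5,
                          crop = crop)
      tr <- pr$transform
    } else {
      tr <- cbind(diag(2), c(0, 0))
    }
    ctr <- (crop + 1):(s - crop)
    # resample the label only for alignments clearly above the estimator's
    # refinement noise; warping an already-aligned pair would only inject
    # interpolation error
    need_warp <- register &&
      (abs(pr$rotation_deg) > 0.05 || any(abs(tr[, 3]) > 0.05))
    p0 <- floor((length(ctr) - patch) / 2)
    sel <- ctr[p0 + seq_len(patch)]
    for (ch in seq_len(nc)) {
      hrm <- hr_ch[[ch]]
      if (need_warp) {
        hrm <- warp_rigid(hrm, pr$rotation_deg, tr[1, 3], tr[2, 3], mean(hrm))
      }
      input[, , ch, i] <- lr_ch[[ch]][sel, sel]
      label[, , ch, i] <- hrm[sel, sel]
    }
  }
  structure(list(input = input, label = label, degradation = degradation,
                 channels = if (nc == 2) c("real", "imag") else "phase",
                 patch = patch, factor = factor, na_low = na_low,
                 pixel_pitch = spec$pixel_pitch, seed = spec$seed),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  d <- dim(x$input)
  cat(sprintf("<patch_dataset> %d patches %d x %d, channels: %s (%s)\n",
              d[4], d[1], d[2], paste(x$channels, collapse = "+"),
              x$degradation))
  invisible(x)
}
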