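# shared fixtures, all generated in code

# band-limited random field (spatial frequencies below f_max cycles/px)
bandlimited_field <- function(n, f_max = 0.2, seed = 1, pitch = 1,
                              wavelength = 0.5) {
  set.seed(seed)
  v <- matrix(rnorm(n * n), n)
  fv <- stats::fft(v)
  f <- cohsr:::fft_freq(n, 1)
  mask <- outer(f^2, f^2, `+`) < f_max^2
  v <- Re(stats::fft(fv * mask, inverse = TRUE)) / n^2
  complex_field(v + 0i, pitch, wavelength)
}

# default multi-height acquisition geometry (8 heights, on-chip scale)
default_heights <- function() seq(300, 475, by = 25)

# absorption-dominant test object (stained-smear regime)
amplitude_object <- function(size = 128, seed = 1, pitch = 1.12,
                             amp = c(0.7, 1), phase = c(0, 0)) {
  make_object(synth_spec("tissue_blobs", size = size, pixel_pitch = pitch,
                         amplitude_range = amp, phase_range = phase,
                         seed = seed))
}

# periodic pixel-aperture (f x f box) filtering of an intensity image: the
# quantity a pixelated sensor measures on the dense grid
aperture_filter <- function(img, f) {
  s <- nrow(img)
  k <- matrix(0, s, s); k[1:f, 1:f] <- 1 / f^2
  Re(stats::fft(stats::fft(img) * Conj(stats::fft(k)), inverse = TRUE)) / s^2
}

# exact periodic sub-pixel translation (band-limited interpolation)
fft_translate <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  ky <- cohsr:::fft_freq(h, 1); kx <- cohsr:::fft_freq(w, 1)
  ph <- exp(-2i * pi * (outer(ky, rep(0, w), `+`) * dy +
                          outer(rep(0, h), kx, `+`) * dx))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (h * w)
}

tiny_patchset <- function(n = 16, patch = 32, seed = 42) {
  spec <- synth_spec("tissue_blobs", size = patch + 116L, pixel_pitch = 0.3733,
                     amplitude_range = c(0.6, 1), phase_range = c(0, 1),
                     seed = seed)
  make_training_set(spec, n, "pixel_binning", patch = patch, factor = 2,
                    register = FALSE)
}
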