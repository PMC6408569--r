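#' Complex optical field on a regular pixel grid
#'
#' A `complex_field` is a 2-D complex-valued array sampled on a square pixel
#' grid, together with the physical pixel pitch and the illumination
#' wavelength. It represents the scalar field at the object plane or at any
#' propagated plane. All physical lengths in the package are in micrometres.
#'
#' @param values Complex (or real, coerced to complex) matrix, at least 2x2.
#' @param pixel_pitch Pixel pitch in um (> 0).
#' @param wavelength Illumination wavelength in um (> 0).
#' @return An object of class `complex_field`.
#' @examples
#' f <- complex_field(matrix(1 + 0i, 8, 8), pixel_pitch = 1, wavelength = 0.55)
#' @export
complex_field <- function(values, pixel_pitch, wavelength) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("field must be at least 2x2")
  }
  if (!is.complex(values)) {
    if (!is.numeric(values)) stop("`values` must be numeric or complex")
    values <- values + 0i
  }
  stopifnot(is.numeric(pixel_pitch), length(pixel_pitch) == 1L, pixel_pitch > 0)
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0)
  structure(
    list(values = values, pixel_pitch = pixel_pitch, wavelength = wavelength),
    class = "complex_field"
  )
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf(
    "<complex_field> %d x %d px, pitch %.4g um, wavelength %.4g um\n",
    nrow(x$values), ncol(x$values), x$pixel_pitch, x$wavelength
  ))
  invisible(x)
}

#' @export
dim.complex_field <- function(x) dim(x$values)

#' Optical configuration of an in-line holographic system
#'
#' Container for the physical parameters of the imaging geometry: the
#' illumination wavelength and bandwidth, the refractive index of the
#' propagation medium, the source-to-sample distance `z1` (metadata only; the
#' effectively plane-wave illumination of an on-chip geometry does not enter
#' the reconstruction), the sample-to-sensor distance `z2` and the sensor
#' pixel pitch.
#'
#' @param wavelength Illumination wavelength lambda (um).
#' @param bandwidth Spectral bandwidth delta-lambda (um), must satisfy
#'   `bandwidth < wavelength`.
#' @param refractive_index Refractive index n of the medium (>= here simply
#'   > 0; n = 1 for air).
#' @param z1 Source-to-sample distance (um). Stored as metadata.
#' @param z2 Sample-to-sensor distance (um).
#' @param pixel_pitch Sensor pixel pitch (um).
#' @return An object of class `optical_params`.
#' @examples
#' optical_params(0.550, 0.002, 1, z1 = 5e4, z2 = 300, pixel_pitch = 2.24)
#' @export
optical_params <- function(wavelength, bandwidth, refractive_index = 1,
                           z1 = NA_real_, z2 = 300, pixel_pitch = 2.24) {
  vals <- c(wavelength = wavelength, bandwidth = bandwidth,
            refractive_index = refractive_index, z2 = z2,
            pixel_pitch = pixel_pitch)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all optical parameters must be finite and strictly positive")
  }
  if (bandwidth >= wavelength) stop("bandwidth must be smaller than wavelength")
  structure(
    list(wavelength = wavelength, bandwidth = bandwidth,
         refractive_index = refractive_index, z1 = z1, z2 = z2,
         pixel_pitch = pixel_pitch),
    class = "optical_params"
  )
}

# discrete FFT frequencies (cycles per um) on the half-open grid
# [-1/(2 d), 1/(2 d)); standard fftfreq layout.
fft_freq <- function(n, d) {
  c(seq.int(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L)) / (n * d)
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Free-space angular-spectrum propagation
#'
#' Propagates a complex field over an axial distance `dz` through a homogeneous
#' medium of refractive index `n` using the (exact, non-paraxial) angular
#' spectrum of plane waves. The transfer function used is
#' `exp(+1i * 2*pi * (n/lambda) * dz * sqrt(1 - (lambda*fx/n)^2 - (lambda*fy/n)^2))`;
#' evanescent components (`fx^2 + fy^2 > (n/lambda)^2`) are suppressed to zero.
#' With this sign convention backward propagation (`-dz`) is the complex
#' conjugate transfer function, so `propagate(propagate(f, z), -z)` returns
#' `f` for band-limited fields.
#'
#' @param field A [complex_field].
#' @param dz Propagation distance in um (may be 0 or negative).
#' @param n Refractive index of the medium (>= 1).
#' @param pad Zero-padding factor applied before the transform to suppress
#'   periodic wrap-around; the default 2 doubles the linear grid size, `pad = 1`
#'   disables padding (the operator is then exactly unitary on non-evanescent
#'   fields).
#' @return A [complex_field] of identical shape and pitch.
#' @examples
#' f <- complex_field(matrix(1 + 0i, 32, 32), 1, 0.55)
#' g <- propagate(f, 300)
#' @export
propagate <- function(field, dz, n = 1, pad = 2) {
  stopifnot(inherits(field, "complex_field"))
  if (!all(is.finite(Re(field$values))) || !all(is.finite(Im(field$values)))) {
    stop("field contains non-finite values; refusing to propagate")
  }
  stopifnot(is.numeric(dz), length(dz) == 1L, is.finite(dz))
  if (n < 1) stop("refractive index must be >= 1")
  if (dz == 0) return(field)

  v <- field$values
  h0 <- nrow(v); w0 <- ncol(v)
  if (pad > 1) {
    hp <- ceiling(h0 * pad); wp <- ceiling(w0 * pad)
    big <- matrix(0 + 0i, hp, wp)
    r0 <- floor((hp - h0) / 2); c0 <- floor((wp - w0) / 2)
    big[r0 + seq_len(h0), c0 + seq_len(w0)] <- v
    v <- big
  }
  lam <- field$wavelength / n            # wavelength in the medium
  fy <- fft_freq(nrow(v), field$pixel_pitch)
  fx <- fft_freq(ncol(v), field$pixel_pitch)
  arg <- 1 - outer((lam * fy)^2, (lam * fx)^2, `+`)
  prop_ok <- arg > 0
  kz <- sqrt(pmax(arg, 0))
  tf <- matrix(0 + 0i, nrow(v), ncol(v))
  tf[prop_ok] <- exp((2i * pi * dz / lam) * kz[prop_ok])
  out <- ifft2(fft2(v) * tf)
  if (pad > 1) out <- out[r0 + seq_len(h0), c0 + seq_len(w0)]
  complex_field(out, field$pixel_pitch, field$wavelength)
}

#' Temporal coherence length of a finite-bandwidth source
#'
#' Computes `sqrt(2*ln(2)/pi) * lambda^2 / (n * dlambda)`, the coherence
#' length that bounds the fringe visibility, and hence the effective
#' aperture, of an on-chip holographic microscope.
#'
#' @param wavelength Centre wavelength lambda (um).
#' @param bandwidth Bandwidth delta-lambda (um), > 0.
#' @param n Refractive index (default 1).
#' @return Coherence length in um.
#' @examples
#' coherence_length(0.550, 0.002)  # ~100.47 um
#' @export
coherence_length <- function(wavelength, bandwidth, n = 1) {
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0")
  if (!is.numeric(wavelength) || wavelength <= 0) stop("wavelength must be > 0")
  sqrt(2 * log(2) / pi) * wavelength^2 / (n * bandwidth)
}

#' Coherence-limited effective numerical aperture
#'
#' The largest hologram fringe angle with appreciable modulation is the one
#' whose path-length difference to the axial ray equals the coherence length,
#' giving `NA = n * sqrt(1 - (z2 / (z2 + coh_len))^2)`.
#'
#' @param z2 Sample-to-sensor distance (um), > 0.
#' @param coh_len Temporal coherence length (um), > 0.
#' @param n Refractive index (default 1).
#' @return Effective numerical aperture, in (0, n).
#' @examples
#' effective_na(300, coherence_length(0.550, 0.002))  # ~0.6624
#' @export
effective_na <- function(z2, coh_len, n = 1) {
  if (!is.numeric(z2) || z2 <= 0) stop("z2 must be > 0")
  if (!is.numeric(coh_len) || coh_len <= 0) stop("coherence length must be > 0")
  n * sqrt(1 - (z2 / (z2 + coh_len))^2)
}

#' Diffraction/coherence-limited resolution
#'
#' The achievable half-pitch resolution `lambda / NA` of a coherent imaging
#' system with effective numerical aperture `na`.
#'
#' @param wavelength Wavelength (um).
#' @param na Numerical aperture, > 0.
#' @return Resolution in um.
#' @examples
#' resolution_limit(0.55, 0.6624)  # ~0.83 um
#' @export
resolution_limit <- function(wavelength, na) {
  if (!is.numeric(na) || na <= 0) stop("numerical aperture must be > 0")
  if (!is.numeric(wavelength) || wavelength <= 0) stop("wavelength must be > 0")
  wavelength / na
}
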