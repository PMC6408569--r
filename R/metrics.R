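#' Structural similarity index (SSIM)
#'
#' Computes `((2*mu_x*mu_z + c1) * (2*sigma_xz + c2)) /
#' ((mu_x^2 + mu_z^2 + c1) * (sigma_x^2 + sigma_z^2 + c2))`, either globally
#' (one set of image-wide moments) or, by default, over local Gaussian
#' windows (11 px, sigma 1.5) with the window map averaged, which is the
#' conventional reporting form. The stabilizers default to `c1 = (0.01 L)^2`,
#' `c2 = (0.03 L)^2` with `L` the joint data range.
#'
#' @param x,z Numeric matrices of identical shape.
#' @param window Odd window side in pixels, or `"global"`.
#' @param sigma Gaussian window standard deviation (px).
#' @param data_range Value range `L`; defaults to the joint range of `x`, `z`
#'   (1 if both are constant).
#' @param c1,c2 Stabilizing constants; override `data_range` when given.
#' @return Scalar in (-1, 1].
#' @export
ssim <- function(x, z, window = 11, sigma = 1.5, data_range = NULL,
                 c1 = NULL, c2 = NULL) {
  stopifnot(is.matrix(x), is.matrix(z))
  if (!identical(dim(x), dim(z))) stop("images must share one shape")
  if (any(!is.finite(x)) || any(!is.finite(z))) stop("images must be finite")
  if (is.null(data_range)) {
    data_range <- max(max(x, z) - min(x, z), .Machine$double.eps)
  }
  if (is.null(c1)) c1 <- (0.01 * data_range)^2
  if (is.null(c2)) c2 <- (0.03 * data_range)^2
  if (identical(window, "global")) {
    mx <- mean(x); mz <- mean(z)
    vx <- mean((x - mx)^2); vz <- mean((z - mz)^2)
    cxz <- mean((x - mx) * (z - mz))
    return(((2 * mx * mz + c1) * (2 * cxz + c2)) /
             ((mx^2 + mz^2 + c1) * (vx + vz + c2)))
  }
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0) stop("window must be an odd integer >= 3")
  # images smaller than the window fall back to the largest odd window (or
  # the global form below 3 px)
  if (any(dim(x) < window)) {
    window <- min(dim(x))
    if (window %% 2 == 0) window <- window - 1L
    if (window < 3) {
      return(ssim(x, z, window = "global", data_range = data_range,
                  c1 = c1, c2 = c2))
    }
  }
  g <- exp(-((seq_len(window) - (window + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  smooth <- function(m) {
    kr <- band_matrix(nrow(m), g)
    kc <- band_matrix(ncol(m), g)
    kr %*% m %*% t(kc)
  }
  mx <- smooth(x); mz <- smooth(z)
  vx <- smooth(x * x) - mx^2
  vz <- smooth(z * z) - mz^2
  cxz <- smooth(x * z) - mx * mz
  map <- ((2 * mx * mz + c1) * (2 * cxz + c2)) /
    ((mx^2 + mz^2 + c1) * (vx + vz + c2))
  mean(map)
}

# (n - k + 1) x n "valid" correlation matrix with kernel g
band_matrix <- function(n, g) {
  k <- length(g)
  m <- matrix(0, n - k + 1, n)
  for (i in seq_len(n - k + 1)) m[i, i:(i + k - 1)] <- g
  m
}

#' Radially averaged spatial-frequency spectrum
#'
#' Computes the magnitude-squared 2-D discrete spectrum of an image, bins it
#' by radial spatial frequency, and returns the mean power per bin together
#' with the bin-centre frequencies in cycles per micrometre.
#'
#' @param img Finite numeric matrix.
#' @param n_bins Number of radial bins (>= 2).
#' @param pixel_pitch Pixel pitch in um (sets the frequency axis scale).
#' @return A data.frame with columns `freq` (bin centres, cycles/um), `power`
#'   (mean power in the bin) and `count` (number of spectral samples).
#' @export
radial_spectrum <- function(img, n_bins, pixel_pitch = 1) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (any(!is.finite(img))) stop("image must be finite")
  if (n_bins < 2) stop("n_bins must be >= 2")
  p <- Mod(fft2(img))^2
  fy <- fft_freq(nrow(img), pixel_pitch)
  fx <- fft_freq(ncol(img), pixel_pitch)
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  breaks <- seq(0, max(fr), length.out = n_bins + 1)
  bin <- findInterval(fr, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  power <- vapply(seq_len(n_bins), function(b) {
    v <- p[bin == b]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  count <- tabulate(bin, nbins = n_bins)
  data.frame(freq = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
             power = power, count = count)
}
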