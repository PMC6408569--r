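#' Multi-height hologram stack
#'
#' A set of in-line hologram intensity images of one sample recorded at
#' several sample-to-sensor distances, with shared pixel pitch and
#' wavelength. The sample plane is at z = 0; heights are positive sensor-side
#' distances and must be strictly increasing.
#'
#' @param intensities List of non-negative numeric matrices of identical shape.
#' @param heights Numeric vector of sample-to-sensor distances (um), one per
#'   image, strictly increasing.
#' @param pixel_pitch Pixel pitch (um).
#' @param wavelength Wavelength (um).
#' @return An object of class `hologram_stack`.
#' @export
hologram_stack <- function(intensities, heights, pixel_pitch, wavelength) {
  if (!is.list(intensities) || length(intensities) == 0) {
    stop("`intensities` must be a non-empty list of matrices")
  }
  if (length(heights) != length(intensities)) {
    stop("one height per intensity image is required")
  }
  if (any(diff(heights) <= 0)) stop("heights must be strictly increasing")
  d1 <- dim(intensities[[1]])
  for (im in intensities) {
    if (!is.matrix(im) || !is.numeric(im)) stop("intensities must be numeric matrices")
    if (!identical(dim(im), d1)) stop("all intensity images must share one shape")
    if (any(!is.finite(im)) || any(im < 0)) stop("intensities must be finite and >= 0")
  }
  stopifnot(pixel_pitch > 0, wavelength > 0)
  structure(
    list(intensities = intensities, heights = as.numeric(heights),
         pixel_pitch = pixel_pitch, wavelength = wavelength),
    class = "hologram_stack"
  )
}

#' @export
print.hologram_stack <- function(x, ...) {
  cat(sprintf(
    "<hologram_stack> %d heights (%.4g..%.4g um), %d x %d px, pitch %.4g um\n",
    length(x$heights), min(x$heights), max(x$heights),
    nrow(x$intensities[[1]]), ncol(x$intensities[[1]]), x$pixel_pitch
  ))
  invisible(x)
}

#' Tamura coefficient of the gradient (edge-sparsity focus metric)
#'
#' Computes `sqrt(sd(g) / mean(g))` where `g` is the magnitude of the
#' central-difference gradient of the image, evaluated on the interior
#' (gradient-defined) pixels. Sharp, sparse-edged images score high; defocused
#' images score low, which makes the metric a robust autofocus criterion for
#' holographic amplitude images. Invariant to multiplication of the image by a
#' positive constant.
#'
#' @param img Finite numeric matrix, at least 3x3.
#' @return Non-negative scalar; 0 for a constant image (zero mean gradient).
#' @export
tamura_of_gradient <- function(img) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (nrow(img) < 3 || ncol(img) < 3) stop("image must be at least 3x3")
  if (any(!is.finite(img))) stop("image contains non-finite values")
  h <- nrow(img); w <- ncol(img)
  gy <- (img[3:h, 2:(w - 1)] - img[1:(h - 2), 2:(w - 1)]) / 2
  gx <- (img[2:(h - 1), 3:w] - img[2:(h - 1), 1:(w - 2)]) / 2
  g <- sqrt(gx^2 + gy^2)
  m <- mean(g)
  if (m == 0) return(0)
  sqrt(stats::sd(g) / m)
}

# ToG of the back-propagated amplitude at height z (internal autofocus score)
tog_at_z <- function(field0, z, n, pad) {
  tamura_of_gradient(Mod(propagate(field0, -z, n = n, pad = pad)$values))
}

#' Autofocus a raw hologram by edge-sparsity maximization
#'
#' Assigns zero phase to the measured hologram amplitude (`sqrt(intensity)`),
#' back-propagates it over a grid of candidate sample-to-sensor distances with
#' the angular-spectrum method, scores the amplitude of each refocused field
#' with [tamura_of_gradient()], and refines the best coarse height by
#' golden-section search down to `refine_tol` (default 0.5 um).
#'
#' @param holo Non-negative numeric matrix (hologram intensity).
#' @param z_min,z_max Search interval bounds (um), `z_min < z_max`.
#' @param step Coarse grid spacing (um), > 0.
#' @param optics An [optical_params] (supplies wavelength, refractive index,
#'   pixel pitch).
#' @param refine_tol Width of the refined bracket at termination (um).
#' @param pad Padding factor passed to [propagate()] (default 1, periodic;
#'   use 2 for isolated fields of apertured real acquisitions).
#' @return A list of class `focus_result` with `best_z`, `z_grid`,
#'   `metric_values` (coarse grid scores; `best_z` refined inside the grid).
#' @export
autofocus <- function(holo, z_min, z_max, step, optics, refine_tol = 0.5,
                      pad = 1) {
  stopifnot(is.matrix(holo), all(holo >= 0))
  if (!(z_min < z_max)) stop("z_min must be < z_max")
  if (step <= 0) stop("step must be > 0")
  z_grid <- seq(z_min, z_max, by = step)
  if (length(z_grid) == 0) stop("empty height grid")
  f0 <- complex_field(sqrt(holo) + 0i, optics$pixel_pitch, optics$wavelength)
  n <- optics$refractive_index
  metric <- vapply(z_grid, function(z) tog_at_z(f0, z, n, pad), numeric(1))
  k <- which.max(metric)
  best_z <- z_grid[k]
  if (length(z_grid) > 1) {
    lo <- z_grid[max(1, k - 1)]; hi <- z_grid[min(length(z_grid), k + 1)]
    if (hi > lo) {
      phi <- (sqrt(5) - 1) / 2
      a <- lo; b <- hi
      x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
      f1 <- tog_at_z(f0, x1, n, pad); f2 <- tog_at_z(f0, x2, n, pad)
      while ((b - a) > refine_tol) {
        if (f1 < f2) {
          a <- x1; x1 <- x2; f1 <- f2
          x2 <- a + phi * (b - a); f2 <- tog_at_z(f0, x2, n, pad)
        } else {
          b <- x2; x2 <- x1; f2 <- f1
          x1 <- b - phi * (b - a); f1 <- tog_at_z(f0, x1, n, pad)
        }
      }
      cand_z <- if (f1 > f2) x1 else x2
      cand_m <- max(f1, f2)
      if (cand_m >= metric[k]) best_z <- cand_z
    }
  }
  structure(list(best_z = best_z, z_grid = z_grid, metric_values = metric),
            class = "focus_result")
}

#' SVD-based fixed-pattern background subtraction
#'
#' Images of a stack share sample-independent background structure (dust and
#' interference from optical surfaces) that confounds autofocusing. Each image
#' is vectorized into a column of a pixels-by-images matrix, the dominant
#' (rank-1) singular component shared across the stack is removed, and each
#' image is re-offset to its original mean. Negative residual intensities are
#' clipped to zero.
#'
#' @param stack A [hologram_stack] with at least 3 images.
#' @return A [hologram_stack] with the common component removed.
#' @export
svd_background_subtract <- function(stack) {
  stopifnot(inherits(stack, "hologram_stack"))
  k <- length(stack$intensities)
  if (k < 3) stop("rank-1 background removal needs at least 3 images")
  d <- dim(stack$intensities[[1]])
  m <- vapply(stack$intensities, as.vector, numeric(prod(d)))
  sv <- svd(m, nu = 1, nv = 1)
  bg <- sv$d[1] * tcrossprod(sv$u[, 1], sv$v[, 1])
  out <- m - bg
  means_in <- colMeans(m)
  out <- sweep(out, 2, means_in - colMeans(out), `+`)
  out[out < 0] <- 0
  ims <- lapply(seq_len(k), function(i) matrix(out[, i], d[1], d[2]))
  hologram_stack(ims, stack$heights, stack$pixel_pitch, stack$wavelength)
}

#' Iterative multi-height phase recovery
#'
#' Recovers the complex field of the sample from intensity-only measurements
#' at several heights. The field is initialized as `sqrt(I_1)` with zero phase
#' at the first height; each sweep propagates it forward through heights
#' 1..K and then backward K..1. At each visited height the phase is retained
#' while the amplitude is updated to the average of the current amplitude and
#' the square root of the measured intensity. After the final sweep the field
#' is back-propagated to the sample plane (z = 0). The twin image and
#' self-interference terms, which do not satisfy all height constraints
#' simultaneously, are progressively suppressed.
#'
#' @param stack A [hologram_stack] whose heights are the (autofocused)
#'   acquisition distances.
#' @param n_iter Number of forward+backward sweeps (>= 0). With `n_iter = 0`
#'   the initialization `sqrt(I_1)` is simply back-propagated.
#' @param average_backward Also apply the amplitude update on the backward
#'   pass (default TRUE).
#' @param tol Early-stop threshold on the improvement of the data-fidelity
#'   (mean over heights of mean absolute amplitude mismatch) between sweeps.
#' @param pad Padding factor for the internal propagations (default 1,
#'   periodic boundaries: the repeated propagations of the sweep then conserve
#'   the field support exactly; use 2 for apertured real acquisitions).
#' @return A [complex_field] at the sample plane, with attribute `fidelity`:
#'   the per-sweep data-fidelity curve.
#' @export
multiheight_phase_recovery <- function(stack, n_iter = 50,
                                       average_backward = TRUE, tol = 1e-6,
                                       pad = 1) {
  stopifnot(inherits(stack, "hologram_stack"))
  if (n_iter < 0) stop("n_iter must be >= 0")
  amps <- lapply(stack$intensities, sqrt)
  k <- length(amps)
  n <- 1
  f <- complex_field(amps[[1]] + 0i, stack$pixel_pitch, stack$wavelength)
  h <- stack$heights
  fid <- numeric(0)
  if (n_iter > 0) {
    for (it in seq_len(n_iter)) {
      mis <- numeric(k)
      # forward pass 1 -> K
      if (k > 1) for (j in 2:k) {
        f <- propagate(f, h[j] - h[j - 1], n = n, pad = pad)
        mis[j] <- mean(abs(Mod(f$values) - amps[[j]]))
        f$values <- (Mod(f$values) + amps[[j]]) / 2 * exp(1i * Arg(f$values))
      }
      # backward pass K -> 1
      if (k > 1) for (j in (k - 1):1) {
        f <- propagate(f, h[j] - h[j + 1], n = n, pad = pad)
        if (j == 1) mis[1] <- mean(abs(Mod(f$values) - amps[[1]]))
        if (average_backward || j == 1) {
          f$values <- (Mod(f$values) + amps[[j]]) / 2 * exp(1i * Arg(f$values))
        }
      }
      if (k == 1) {
        mis[1] <- mean(abs(Mod(f$values) - amps[[1]]))
        f$values <- (Mod(f$values) + amps[[1]]) / 2 * exp(1i * Arg(f$values))
      }
      fid <- c(fid, mean(mis))
      if (it > 1 && (fid[it - 1] - fid[it]) < tol) break
    }
  }
  out <- propagate(f, -h[1], n = n, pad = pad)
  attr(out, "fidelity") <- fid
  out
}
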