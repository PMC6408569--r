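#' Write / read a complex field as a two-page float TIFF
#'
#' Page 1 holds the real part, page 2 the imaginary part (32-bit float).
#' Pixel pitch and wavelength are carried in a YAML sidecar (`<path>.yaml`).
#'
#' @param field A [complex_field].
#' @param path Output `.tif` path.
#' @return `write_field_tiff` returns `path` invisibly; `read_field_tiff`
#'   returns a [complex_field].
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  # TIFF float samples are stored in [0, 1]; keep the affine ranges in the
  # sidecar so the round trip is exact up to float-32 quantization
  norm01 <- function(v) {
    rng <- range(v)
    span <- if (diff(rng) > 0) diff(rng) else 1
    list(img = (v - rng[1]) / span, min = rng[1], span = span)
  }
  re <- norm01(Re(field$values)); im <- norm01(Im(field$values))
  tiff::writeTIFF(list(re$img, im$img), path, bits.per.sample = 32L,
                  reduce = FALSE)
  yaml::write_yaml(list(pixel_pitch_um = field$pixel_pitch,
                        wavelength_um = field$wavelength,
                        real_min = re$min, real_span = re$span,
                        imag_min = im$min, imag_span = im$span),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop("expected a two-page (real, imaginary) TIFF")
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) stop("missing field metadata sidecar: ", side)
  meta <- yaml::read_yaml(side)
  re <- pages[[1]] * meta$real_span + meta$real_min
  im <- pages[[2]] * meta$imag_span + meta$imag_min
  complex_field(re + 1i * im, meta$pixel_pitch_um, meta$wavelength_um)
}

#' Write / read a multi-height hologram stack
#'
#' The stack is stored as one float TIFF per height plus a YAML manifest
#' listing image paths, heights (um), pixel pitch and wavelength.
#'
#' @param stack A [hologram_stack].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for the images.
#' @return `write_stack` returns the manifest path invisibly; `read_stack`
#'   takes a manifest path and returns a [hologram_stack].
#' @export
write_stack <- function(stack, dir, prefix = "holo") {
  stopifnot(inherits(stack, "hologram_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(stack$heights))
  for (i in seq_along(stack$heights)) {
    paths[i] <- sprintf("%s_h%02d.tif", prefix, i)
    # store intensities scaled into [0, 1] with the scale in the manifest
    tiff::writeTIFF(stack$intensities[[i]] / max(stack$intensities[[i]], 1e-12),
                    file.path(dir, paths[i]), bits.per.sample = 32L)
  }
  manifest <- list(
    images = lapply(seq_along(paths), function(i) list(
      path = paths[i], height_um = stack$heights[i],
      scale = max(stack$intensities[[i]], 1e-12))),
    pixel_pitch_um = stack$pixel_pitch,
    wavelength_um = stack$wavelength
  )
  mpath <- file.path(dir, "stack.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  mpath <- if (dir.exists(dir)) file.path(dir, "stack.yaml") else dir
  if (!file.exists(mpath)) stop("stack manifest not found: ", mpath)
  m <- yaml::read_yaml(mpath)
  base <- dirname(mpath)
  ims <- lapply(m$images, function(e) {
    p <- file.path(base, e$path)
    if (!file.exists(p)) stop("missing stack image: ", p)
    tiff::readTIFF(p) * e$scale
  })
  hologram_stack(ims, vapply(m$images, `[[`, numeric(1), "height_um"),
                 m$pixel_pitch_um, m$wavelength_um)
}
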