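#' Bicubic upsampling to a target grid
#'
#' Bicubically interpolates an image onto a grid `factor` times denser in each
#' dimension (Catmull-Rom kernel, edge-clamped). The source coordinate of
#' output pixel `o` is `o / factor` (top-left convention), so `factor = 1` is
#' the identity and decimating the output at the aligned phase returns the
#' original samples exactly.
#'
#' @param lr Numeric matrix.
#' @param factor Scale factor >= 1 (need not be an integer).
#' @return Numeric matrix of shape `round(dim(lr) * factor)`.
#' @export
upsample_to_target <- function(lr, factor) {
  stopifnot(is.matrix(lr), is.numeric(lr))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1) {
    stop("factor must be a scalar >= 1")
  }
  if (factor == 1) return(lr)
  resize_bicubic(lr, factor)
}

# global normalized cross-correlation peak between two mean-removed images,
# over all cyclic translations (FFT correlation)
ncc_peak <- function(a, b) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  na <- sqrt(sum(a0^2)); nb <- sqrt(sum(b0^2))
  if (na == 0 || nb == 0) return(0)
  cc <- Re(ifft2(fft2(a0) * Conj(fft2(b0)))) * length(a0)
  max(cc) / (na * nb)
}

#' Register a low/high-resolution image pair
#'
#' Estimates the rotation and sub-pixel translation that align the
#' high-resolution image to the (already upsampled) low-resolution image by
#' maximizing correlation: a coarse rotation sweep (`+/- max_rot` degrees in
#' `rot_step` steps, translation by phase correlation at each angle) followed
#' by parabolic refinement of the angle. The recovered rigid transform is
#' applied to the HR image (bicubic resampling) and both images are cropped by
#' `crop` pixels on every side to discard resampling boundaries and any
#' residual relative shift. Pairs whose post-alignment normalized correlation
#' falls below `min_corr` are flagged `valid = FALSE`.
#'
#' @param lr_up Numeric matrix: LR image upsampled to the HR grid.
#' @param hr Numeric matrix of the same shape.
#' @param max_rot,rot_step Rotation search range and step (degrees).
#' @param min_corr Validity threshold on the aligned normalized correlation.
#' @param crop Pixels cropped from each side of both outputs (default 50).
#' @return A list of class `image_pair`: `lr`, `hr` (aligned, cropped),
#'   `transform` (2x3 rigid matrix mapping output to original HR pixel
#'   coordinates), `rotation_deg`, `shift` (dy, dx), `corr`, `valid`.
#' @export
register_pair <- function(lr_up, hr, max_rot = 5, rot_step = 0.25,
                          min_corr = 0.5, crop = 50) {
  stopifnot(is.matrix(lr_up), is.matrix(hr))
  if (!identical(dim(lr_up), dim(hr))) stop("images must share one shape")
  h <- nrow(hr); w <- ncol(hr)
  if (h <= 2 * crop || w <= 2 * crop) stop("images too small for the requested crop")
  crop_idx <- function(m) m[(crop + 1):(h - crop), (crop + 1):(w - crop), drop = FALSE]
  degenerate <- stats::sd(lr_up) == 0 || stats::sd(hr) == 0
  if (degenerate) {
    tr <- cbind(diag(2), c(0, 0))
    return(structure(list(lr = crop_idx(lr_up), hr = crop_idx(hr),
                          transform = tr, rotation_deg = 0,
                          shift = c(dy = 0, dx = 0), corr = 0, valid = FALSE),
                     class = "image_pair"))
  }
  fillv <- mean(hr)
  angles <- if (max_rot > 0) seq(-max_rot, max_rot, by = rot_step) else 0
  scores <- vapply(angles, function(th) {
    hr_r <- if (th == 0) hr else warp_rigid(hr, th, 0, 0, fillv)
    ncc_peak(lr_up, hr_r)
  }, numeric(1))
  k <- which.max(scores)
  theta <- angles[k]
  if (length(angles) >= 3 && k > 1 && k < length(angles)) {
    # parabolic refinement of the correlation-vs-angle curve
    y1 <- scores[k - 1]; y2 <- scores[k]; y3 <- scores[k + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) theta <- theta + 0.5 * rot_step * (y1 - y3) / den
  }
  hr_rot <- if (theta == 0) hr else warp_rigid(hr, theta, 0, 0, fillv)
  d <- phase_corr_shift(lr_up, hr_rot)
  # hr_rot equals lr_up translated by +d, so sample hr_rot at p + d
  th <- theta * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_warp <- as.numeric(rot %*% d)
  hr_al <- warp_rigid(hr, theta, t_warp[1], t_warp[2], fillv)
  corr <- stats::cor(as.vector(crop_idx(lr_up)), as.vector(crop_idx(hr_al)))
  if (!is.finite(corr)) corr <- 0
  structure(list(
    lr = crop_idx(lr_up), hr = crop_idx(hr_al),
    transform = cbind(rot, t_warp),
    rotation_deg = theta, shift = c(dy = d[[1]], dx = d[[2]]),
    corr = corr, valid = corr >= min_corr
  ), class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %d x %d, rot %.3f deg, shift (%.2f, %.2f), corr %.3f, %s\n",
              nrow(x$lr), ncol(x$lr), x$rotation_deg, x$shift[1], x$shift[2],
              x$corr, if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

# translation (origin of b in a's frame is -offset; b = a shifted by offset)
# between raster neighbours, unwrapped so the offset along `direction`
# ("down": positive row, "right": positive col) is non-negative.
neighbor_offset <- function(a, b, direction, min_overlap_frac = 1 / 64) {
  # masked (overlap-normalized) cross-correlation via FFTs: for every cyclic
  # offset d, the Pearson correlation of the overlapping samples of a and the
  # shifted b. Robust at small overlaps where whitened phase correlation is
  # not. The returned value is the offset of b's origin in a's frame.
  th <- max(nrow(a), nrow(b)); tw <- max(ncol(a), ncol(b))
  # double-size canvas: cyclic correlation then equals linear correlation
  ch <- 2L * th; cw <- 2L * tw
  grow <- function(m) {
    out <- matrix(0, ch, cw)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m - mean(m)
    out
  }
  mask <- function(m) {
    out <- matrix(0, ch, cw)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- 1
    out
  }
  ma <- mask(a); mb <- mask(b)
  a <- grow(a); b <- grow(b)
  fa <- fft2(a); fa2 <- fft2(a^2); fma <- fft2(ma)
  fbc <- Conj(fft2(b)); fb2c <- Conj(fft2(b^2)); fmbc <- Conj(fft2(mb))
  xc <- function(f1, f2c) Re(ifft2(f1 * f2c))
  n_ov <- xc(fma, fmbc)
  s_ab <- xc(fa, fbc)
  s_a <- xc(fa, fmbc); s_b <- xc(fma, fbc)
  s_aa <- xc(fa2, fmbc); s_bb <- xc(fma, fb2c)
  n_ok <- pmax(n_ov, 1)
  num <- s_ab - s_a * s_b / n_ok
  den <- sqrt(pmax(s_aa - s_a^2 / n_ok, 0) * pmax(s_bb - s_b^2 / n_ok, 0))
  ncc <- num / pmax(den, 1e-12)
  ncc[n_ov < th * tw * min_overlap_frac] <- -Inf
  # admissible offsets for a raster neighbour: along-raster at least 1/8 tile
  # (and positive), perpendicular within 1/4 tile either way
  rows0 <- seq_len(ch) - 1L; cols0 <- seq_len(cw) - 1L
  if (direction == "right") {
    okc <- cols0 >= floor(tw / 8) & cols0 <= tw - 1L
    okr <- rows0 <= floor(th / 4) | rows0 >= ch - floor(th / 4)
  } else {
    okr <- rows0 >= floor(th / 8) & rows0 <= th - 1L
    okc <- cols0 <= floor(tw / 4) | cols0 >= cw - floor(tw / 4)
  }
  ncc[!okr, ] <- -Inf
  ncc[, !okc] <- -Inf
  p <- which.max(ncc)
  pr <- (p - 1) %% ch; pc <- (p - 1) %/% ch
  # sub-pixel parabolic refinement along each axis (cyclic neighbours)
  refine <- function(i0, vals) {
    y1 <- vals[1]; y2 <- vals[2]; y3 <- vals[3]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && den < 0) i0 + 0.5 * (y1 - y3) / den else i0
  }
  wrap <- function(i, n) ((i %% n) + n) %% n
  prr <- refine(pr, ncc[wrap(c(pr - 1, pr, pr + 1), ch) + 1, pc + 1])
  pcr <- refine(pc, ncc[pr + 1, wrap(c(pc - 1, pc, pc + 1), cw) + 1])
  if (direction == "down") {
    if (pcr > cw / 2) pcr <- pcr - cw
  } else {
    if (prr > ch / 2) prr <- prr - ch
  }
  structure(c(prr, pcr), score = ncc[p])
}

#' Stitch overlapping tiles into a mosaic
#'
#' Estimates the translation between raster neighbours by phase correlation,
#' places all tiles on a common canvas anchored at the first tile (averaging
#' the placements implied by the left and top neighbours when both exist), and
#' blends overlap regions by averaging.
#'
#' @param tiles List of numeric matrices, row-major order of the raster.
#' @param nominal_grid Integer (rows, cols) of the tile raster.
#' @param min_corr Minimum overlap correlation below which a neighbour pair
#'   is reported as non-overlapping (default 0.5).
#' @return Numeric matrix mosaic, with attribute `offsets` (n x 2 matrix of
#'   estimated tile origins, possibly fractional; placement uses rounded
#'   values).
#' @export
stitch_tiles <- function(tiles, nominal_grid, min_corr = 0.5) {
  nominal_grid <- as.integer(nominal_grid)
  stopifnot(length(tiles) == prod(nominal_grid))
  if (length(tiles) == 1) return(tiles[[1]])
  nr <- nominal_grid[1]; nc <- nominal_grid[2]
  idx <- function(r, c) (r - 1) * nc + c
  org <- matrix(NA_real_, length(tiles), 2)
  org[1, ] <- c(0, 0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r == 1 && c == 1) next
    cands <- list()
    if (c > 1) {
      off <- neighbor_offset(tiles[[idx(r, c - 1)]], tiles[[idx(r, c)]], "right")
      if (attr(off, "score") < min_corr) {
        stop(sprintf(
          "tiles (%d,%d) and (%d,%d) do not overlap (best correlation %.2f)",
          r, c - 1, r, c, attr(off, "score")))
      }
      cands <- c(cands, list(org[idx(r, c - 1), ] + off))
    }
    if (r > 1) {
      off <- neighbor_offset(tiles[[idx(r - 1, c)]], tiles[[idx(r, c)]], "down")
      if (attr(off, "score") < min_corr) {
        stop(sprintf(
          "tiles (%d,%d) and (%d,%d) do not overlap (best correlation %.2f)",
          r - 1, c, r, c, attr(off, "score")))
      }
      cands <- c(cands, list(org[idx(r - 1, c), ] + off))
    }
    org[idx(r, c), ] <- colMeans(do.call(rbind, cands))
  }
  org_r <- round(sweep(org, 2, apply(org, 2, min)))
  dims <- t(vapply(tiles, dim, integer(2)))
  hcan <- max(org_r[, 1] + dims[, 1]); wcan <- max(org_r[, 2] + dims[, 2])
  acc <- matrix(0, hcan, wcan); cnt <- matrix(0, hcan, wcan)
  for (i in seq_along(tiles)) {
    rr <- org_r[i, 1] + seq_len(dims[i, 1]); cc <- org_r[i, 2] + seq_len(dims[i, 2])
    acc[rr, cc] <- acc[rr, cc] + tiles[[i]]
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  out <- acc / pmax(cnt, 1)
  attr(out, "offsets") <- org
  out
}

#' Locate a low-resolution tile's field of view inside a mosaic
#'
#' Scans candidate crops of the mosaic at the given stride, scoring each by
#' normalized (Pearson) correlation against the upsampled LR tile, then
#' refines the best coarse location with a stride-1 local search. Returns the
#' best-scoring crop.
#'
#' @param lr_tile Numeric matrix (not all zero).
#' @param mosaic Numeric matrix, at least as large as the tile's HR footprint.
#' @param stride Coarse scan stride in pixels.
#' @param factor Upsampling factor mapping the LR tile to mosaic scale.
#' @return The best-matching mosaic crop (same shape as the upsampled tile),
#'   with attributes `top_left` (row, col, 1-based) and `score`.
#' @export
match_fov <- function(lr_tile, mosaic, stride, factor = 1) {
  stopifnot(is.matrix(lr_tile), is.matrix(mosaic))
  if (all(lr_tile == 0)) stop("all-zero tile cannot be matched")
  tile <- upsample_to_target(lr_tile, factor)
  th <- nrow(tile); tw <- ncol(tile)
  hm <- nrow(mosaic); wm <- ncol(mosaic)
  if (hm < th || wm < tw) stop("mosaic is smaller than the tile footprint")
  if (hm == th && wm == tw) return(mosaic)
  tv <- as.vector(tile)
  score_at <- function(r, c) {
    cr <- mosaic[r:(r + th - 1), c:(c + tw - 1)]
    if (stats::sd(cr) == 0) return(-Inf)
    stats::cor(tv, as.vector(cr))
  }
  rs <- unique(c(seq(1, hm - th + 1, by = stride), hm - th + 1))
  cs <- unique(c(seq(1, wm - tw + 1, by = stride), wm - tw + 1))
  best <- c(-Inf, 1, 1)
  for (r in rs) for (c in cs) {
    s <- score_at(r, c)
    if (s > best[1]) best <- c(s, r, c)
  }
  rs2 <- max(1, best[2] - stride + 1):min(hm - th + 1, best[2] + stride - 1)
  cs2 <- max(1, best[3] - stride + 1):min(wm - tw + 1, best[3] + stride - 1)
  for (r in rs2) for (c in cs2) {
    s <- score_at(r, c)
    if (s > best[1]) best <- c(s, r, c)
  }
  out <- mosaic[best[2]:(best[2] + th - 1), best[3]:(best[3] + tw - 1)]
  attr(out, "top_left") <- c(row = best[2], col = best[3])
  attr(out, "score") <- best[1]
  out
}
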