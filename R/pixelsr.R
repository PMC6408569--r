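#' Sub-pixel shift table for a lateral-position raster
#'
#' Holds the (dy, dx) displacement of every low-resolution acquisition
#' relative to the first, in units of low-resolution pixels. Displacements are
#' defined so that image k equals the reference translated by (dy, dx):
#' `I_k(y, x) = I_1(y - dy, x - dx)`.
#'
#' @param shifts Numeric n x 2 matrix of (dy, dx) pairs, |shift| < 2 LR px.
#' @param grid_shape Integer (rows, cols) of the lateral-position raster, with
#'   `rows * cols == n`.
#' @return An object of class `shift_table`.
#' @export
shift_table <- function(shifts, grid_shape = c(nrow(shifts), 1L)) {
  if (is.null(dim(shifts))) shifts <- matrix(shifts, ncol = 2)
  stopifnot(is.numeric(shifts), ncol(shifts) == 2)
  if (any(abs(shifts) >= 2)) {
    stop("sub-pixel shifts must satisfy |dy|, |dx| < 2 LR pixels")
  }
  grid_shape <- as.integer(grid_shape)
  if (prod(grid_shape) != nrow(shifts)) {
    stop("grid_shape must satisfy rows * cols == number of shifts")
  }
  colnames(shifts) <- c("dy", "dx")
  structure(list(shifts = shifts, grid_shape = grid_shape),
            class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("<shift_table> %d positions (%d x %d raster)\n",
              nrow(x$shifts), x$grid_shape[1], x$grid_shape[2]))
  invisible(x)
}

#' Write / read a shift table as CSV
#'
#' Columns: `index,row,col,dy_px,dx_px` (row/col are 1-based raster indices).
#' @param table A [shift_table].
#' @param path Output CSV path.
#' @return `write_shift_table` returns `path` invisibly; `read_shift_table`
#'   returns a [shift_table].
#' @export
write_shift_table <- function(table, path) {
  stopifnot(inherits(table, "shift_table"))
  g <- table$grid_shape
  idx <- seq_len(nrow(table$shifts))
  df <- data.frame(index = idx,
                   row = ((idx - 1) %/% g[2]) + 1,
                   col = ((idx - 1) %% g[2]) + 1,
                   dy_px = table$shifts[, 1], dx_px = table$shifts[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shift_table
#' @export
read_shift_table <- function(path) {
  df <- utils::read.csv(path)
  shift_table(cbind(df$dy_px, df$dx_px),
              grid_shape = c(max(df$row), max(df$col)))
}

# Sub-pixel translation between two images by phase correlation with local
# matrix-DFT upsampling (factor `up`) around the integer peak. Returns (dy,dx)
# such that img = ref translated by +(dy,dx).
phase_corr_shift <- function(ref, img, up = 100) {
  fr <- fft2(ref - mean(ref)); fi <- fft2(img - mean(img))
  cp <- fr * Conj(fi)
  mag <- Mod(cp)
  cp <- cp / pmax(mag, .Machine$double.eps * max(mag))
  cc <- Re(ifft2(cp))
  h <- nrow(cc); w <- ncol(cc)
  p <- which.max(cc)
  pr <- (p - 1) %% h; pc <- (p - 1) %/% h
  if (pr > h / 2) pr <- pr - h
  if (pc > w / 2) pc <- pc - w
  # refine: evaluate the correlation surface at sub-pixel positions around
  # (pr, pc) via an explicit (matrix-multiply) inverse DFT of the cross power
  ky <- c(seq.int(0L, floor((h - 1) / 2)), seq.int(-ceiling((h - 1) / 2), -1L))
  kx <- c(seq.int(0L, floor((w - 1) / 2)), seq.int(-ceiling((w - 1) / 2), -1L))
  yv <- pr + seq(-1, 1, by = 1 / up)
  xv <- pc + seq(-1, 1, by = 1 / up)
  er <- exp((2i * pi / h) * outer(yv, ky))
  ec <- exp((2i * pi / w) * outer(xv, kx))
  surf <- Re(er %*% cp %*% t(ec))
  q <- which.max(surf)
  qy <- yv[(q - 1) %% length(yv) + 1]
  qx <- xv[(q - 1) %/% length(yv) + 1]
  c(dy = -qy, dx = -qx)
}

#' Estimate the sub-pixel shift table of a low-resolution image set
#'
#' Registers every image of the set against the first by phase correlation,
#' refined to sub-pixel precision by a local matrix-DFT evaluation of the
#' correlation surface upsampled by `up` (default 100x). The first entry is
#' (0, 0) by construction.
#'
#' @param lr_set List of >= 2 numeric matrices of identical shape with
#'   overlapping content.
#' @param grid_shape Optional (rows, cols) raster layout recorded in the
#'   returned table; defaults to a single column.
#' @param up Local upsampling factor of the correlation surface.
#' @return A [shift_table].
#' @export
estimate_shift_table <- function(lr_set, grid_shape = NULL, up = 100) {
  if (!is.list(lr_set) || length(lr_set) < 2) {
    stop("need at least 2 images to estimate a shift table")
  }
  d1 <- dim(lr_set[[1]])
  for (im in lr_set) {
    if (!identical(dim(im), d1)) stop("all images must share one shape")
    if (stats::sd(im) == 0) stop("featureless (constant) image is unregistrable")
  }
  ref <- lr_set[[1]]
  shifts <- t(vapply(lr_set, function(im) {
    if (identical(im, ref)) c(dy = 0, dx = 0) else phase_corr_shift(ref, im, up)
  }, numeric(2)))
  if (is.null(grid_shape)) grid_shape <- c(length(lr_set), 1L)
  shift_table(shifts, grid_shape)
}

# iterative neighbour-mean fill of unobserved sites (cnt == 0)
fill_holes <- function(acc, cnt) {
  out <- acc
  out[cnt == 0] <- NA_real_
  while (anyNA(out)) {
    h <- nrow(out); w <- ncol(out)
    pad <- matrix(NA_real_, h + 2, w + 2)
    pad[2:(h + 1), 2:(w + 1)] <- out
    nb <- array(c(pad[1:h, 2:(w + 1)], pad[3:(h + 2), 2:(w + 1)],
                  pad[2:(h + 1), 1:w], pad[2:(h + 1), 3:(w + 2)]),
                c(h, w, 4))
    cntnb <- apply(!is.na(nb), c(1, 2), sum)
    mnb <- apply(nb, c(1, 2), function(v) mean(v, na.rm = TRUE))
    fillable <- is.na(out) & cntnb > 0
    out[fillable] <- mnb[fillable]
  }
  out
}

#' Shift-and-add pixel super-resolution
#'
#' Synthesizes a high-resolution image on a `factor`-times denser grid from a
#' set of sub-pixel-shifted low-resolution images. Each LR pixel value is
#' placed at its shifted location on the dense grid (nearest-site gridding by
#' default, bilinear splatting optionally), accumulated, and normalized by the
#' per-site hit count; unobserved sites are filled by iterative neighbour
#' interpolation. The output pixel pitch is the input pitch divided by
#' `factor`. Grid convention: output pixel `x` corresponds to the top-left
#' corner of the contributing LR-pixel footprint (the footprint centre lies
#' `(factor - 1) / 2` HR pixels down/right of it).
#'
#' @param lr_set List of numeric matrices (identical shape).
#' @param table A [shift_table] covering `lr_set`.
#' @param factor Integer upsampling factor >= 1. A factor exceeding the raster
#'   density is allowed (under-determined sites are interpolated) but warned
#'   about.
#' @param method `"nearest"` (default) or `"bilinear"` splatting.
#' @param pitch Optional LR pixel pitch (um); if given, the output carries
#'   attribute `pixel_pitch = pitch / factor`.
#' @return Numeric matrix of shape `dim(lr) * factor`.
#' @export
shift_and_add <- function(lr_set, table, factor, method = c("nearest", "bilinear"),
                          pitch = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(table, "shift_table"))
  if (length(lr_set) != nrow(table$shifts)) {
    stop("shift table must have one entry per LR image")
  }
  if (factor < 1 || factor != round(factor)) stop("factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor > 1 && length(lr_set) < factor^2) {
    warning(sprintf(
      "factor %d from %d images is under-determined; holes will be interpolated",
      factor, length(lr_set)))
  }
  d <- dim(lr_set[[1]])
  ho <- d[1] * factor; wo <- d[2] * factor
  acc <- matrix(0, ho, wo); cnt <- matrix(0, ho, wo)
  i0 <- seq_len(d[1]) - 1; j0 <- seq_len(d[2]) - 1
  for (k in seq_along(lr_set)) {
    dy <- table$shifts[k, 1]; dx <- table$shifts[k, 2]
    if (method == "nearest") {
      r <- round((i0 - dy) * factor) + 1
      cc <- round((j0 - dx) * factor) + 1
      rv <- r >= 1 & r <= ho; cv <- cc >= 1 & cc <= wo
      acc[r[rv], cc[cv]] <- acc[r[rv], cc[cv]] + lr_set[[k]][rv, cv]
      cnt[r[rv], cc[cv]] <- cnt[r[rv], cc[cv]] + 1
    } else {
      ry <- (i0 - dy) * factor; rx <- (j0 - dx) * factor
      fy <- floor(ry); fx <- floor(rx)
      wy <- ry - fy; wx <- rx - fx
      for (oy in 0:1) for (ox in 0:1) {
        r <- fy + oy + 1; cc <- fx + ox + 1
        wr <- if (oy == 0) 1 - wy else wy
        wc <- if (ox == 0) 1 - wx else wx
        rv <- r >= 1 & r <= ho; cv <- cc >= 1 & cc <= wo
        wmat <- outer(wr[rv], wc[cv])
        acc[r[rv], cc[cv]] <- acc[r[rv], cc[cv]] + wmat * lr_set[[k]][rv, cv]
        cnt[r[rv], cc[cv]] <- cnt[r[rv], cc[cv]] + wmat
      }
    }
  }
  hit <- cnt > 0
  acc[hit] <- acc[hit] / cnt[hit]
  out <- if (all(hit)) acc else fill_holes(acc, cnt)
  if (!is.null(pitch)) attr(out, "pixel_pitch") <- pitch / factor
  out
}
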