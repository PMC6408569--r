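# Minimal dense/conv network toolkit with explicit backward passes.
# Tensors are (H, W, C, N) arrays; convolutions run through the compiled
# im2col+GEMM kernels, everything else is vectorized R.

#' Leaky rectified linear unit
#'
#' `x` for `x > 0`, `slope * x` otherwise, elementwise.
#'
#' @param x Numeric scalar or array.
#' @param slope Negative-branch slope (default 0.1).
#' @return Same shape as `x`.
#' @export
lrelu <- function(x, slope = 0.1) {
  nn_lrelu_fwd(x, slope)
}

lrelu_bwd <- function(pre, dy, slope = 0.1) {
  nn_lrelu_bwd(pre, dy, slope)
}

# truncated normal initialization (truncation at +/- 2 sd)
trunc_normal <- function(n, sd = 0.05) {
  stats::qnorm(stats::runif(n, stats::pnorm(-2), stats::pnorm(2))) * sd
}

# He-scaled fan-in SD keeps activation variance stable through the stack;
# an explicit init_sd overrides it
conv_par <- function(ci, co, k = 3, init_sd = NULL) {
  sd0 <- if (is.null(init_sd)) sqrt(2 / (k * k * ci)) else init_sd
  list(w = array(trunc_normal(k * k * ci * co, sd0), c(k, k, ci, co)),
       b = numeric(co))
}

dense_par <- function(ni, no, init_sd = NULL) {
  sd0 <- if (is.null(init_sd)) sqrt(2 / ni) else init_sd
  list(w = matrix(trunc_normal(ni * no, sd0), no, ni), b = numeric(no))
}

conv_f <- function(x, par, stride = 1L) {
  nn_conv2d_fwd(x, par$w, par$b, as.integer(stride))
}

conv_b <- function(x, par, dy, stride = 1L) {
  nn_conv2d_bwd(x, par$w, dy, as.integer(stride))
}

avgpool2_f <- function(x) {
  d <- dim(x)
  o1 <- seq(1, d[1], 2); o2 <- seq(1, d[2], 2)
  (x[o1, o2, , , drop = FALSE] + x[o1 + 1, o2, , , drop = FALSE] +
     x[o1, o2 + 1, , , drop = FALSE] + x[o1 + 1, o2 + 1, , , drop = FALSE]) / 4
}

avgpool2_b <- function(dy, hw) {
  d <- dim(dy)
  dx <- array(0, c(hw[1], hw[2], d[3], d[4]))
  o1 <- seq(1, hw[1], 2); o2 <- seq(1, hw[2], 2)
  q <- dy / 4
  dx[o1, o2, , ] <- q; dx[o1 + 1, o2, , ] <- q
  dx[o1, o2 + 1, , ] <- q; dx[o1 + 1, o2 + 1, , ] <- q
  dx
}

# (2n x n) bilinear x2 interpolation matrix, half-pixel-centre convention
upmat2 <- function(n) {
  m <- matrix(0, 2 * n, n)
  for (o in 0:(2 * n - 1)) {
    s <- (o + 0.5) / 2 - 0.5
    f <- floor(s); w <- s - f
    f0 <- min(max(f, 0), n - 1); f1 <- min(max(f + 1, 0), n - 1)
    m[o + 1, f0 + 1] <- m[o + 1, f0 + 1] + (1 - w)
    m[o + 1, f1 + 1] <- m[o + 1, f1 + 1] + w
  }
  m
}

# apply row map U and column map V to each (H, W) slice of a (H, W, C, N) array
linmap2 <- function(x, u, v) {
  d <- dim(x)
  a <- u %*% matrix(x, d[1], d[2] * d[3] * d[4])
  ho <- nrow(u)
  a <- aperm(array(a, c(ho, d[2], d[3], d[4])), c(2, 1, 3, 4))
  b <- v %*% matrix(a, d[2], ho * d[3] * d[4])
  aperm(array(b, c(nrow(v), ho, d[3], d[4])), c(2, 1, 3, 4))
}

upsample2_f <- function(x) {
  d <- dim(x)
  linmap2(x, upmat2(d[1]), upmat2(d[2]))
}

upsample2_b <- function(dy) {
  d <- dim(dy)
  linmap2(dy, t(upmat2(d[1] / 2)), t(upmat2(d[2] / 2)))
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# duplicate channels (parameter-free residual projection C -> 2C)
rep2_ch <- function(a) concat_ch(a, a)

rep2_ch_b <- function(dy) {
  c2 <- dim(dy)[3]
  dy[, , seq_len(c2 / 2), , drop = FALSE] +
    dy[, , c2 / 2 + seq_len(c2 / 2), , drop = FALSE]
}

gap_f <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

gap_b <- function(dy, hw) {
  array(rep(as.vector(dy), each = hw[1] * hw[2]) / (hw[1] * hw[2]),
        c(hw[1], hw[2], dim(dy)))
}

dense_f <- function(x, par) par$w %*% x + par$b

dense_b <- function(x, par, dy) {
  list(dx = crossprod(par$w, dy), dw = tcrossprod(dy, x), db = rowSums(dy))
}

# --- parameter-tree utilities (params, grads and Adam moments share shape) ---

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(el) tree_map(f, el)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_sum <- function(f, a) {
  if (is.list(a)) sum(vapply(a, function(el) tree_sum(f, el), numeric(1)))
  else f(a)
}

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, st$m, grads)
  st$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, st$v, grads)
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   st$m, st$v)
  list(params = tree_map2(`-`, params, upd), state = st)
}

n_params <- function(params) tree_sum(length, params)
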