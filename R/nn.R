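# Minimal neural-network primitives used by the reorientation encoder and the
# deformation U-Net: thin R wrappers over the Rcpp convolution kernels with
# hand-derived backward passes, plus an Adam optimizer over parameter lists.
# Everything is double precision and single threaded, so results are
# bit-reproducible for a fixed seed.

conv3d <- function(x, w, b, stride = 1L, pad = 1L) {
  xd <- dim(x); k <- dim(w)[1]; ci <- dim(w)[4]; co <- dim(w)[5]
  stopifnot(xd[4] == ci)
  od <- (xd[1:3] + 2L * pad - k) %/% stride + 1L
  y <- .cpp_conv3d_fwd(as.numeric(x), as.integer(xd[1:3]), as.numeric(w),
                       k, ci, co, as.numeric(b), stride, pad)
  array(y, c(od, co))
}

conv3d_bwd <- function(x, w, gy, stride = 1L, pad = 1L) {
  xd <- dim(x); k <- dim(w)[1]; ci <- dim(w)[4]; co <- dim(w)[5]
  r <- .cpp_conv3d_bwd(as.numeric(x), as.integer(xd[1:3]), as.numeric(w),
                       k, ci, co, as.numeric(gy), stride, pad)
  list(gx = array(r$gx, xd), gw = array(r$gw, dim(w)), gb = r$gb)
}

conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  xd <- dim(x); k <- dim(w)[1]; ci <- dim(w)[3]; co <- dim(w)[4]
  stopifnot(xd[3] == ci)
  od <- (xd[1:2] + 2L * pad - k) %/% stride + 1L
  y <- .cpp_conv2d_fwd(as.numeric(x), as.integer(xd[1:2]), as.numeric(w),
                       k, ci, co, as.numeric(b), stride, pad)
  array(y, c(od, co))
}

conv2d_bwd <- function(x, w, gy, stride = 1L, pad = 1L) {
  xd <- dim(x); k <- dim(w)[1]; ci <- dim(w)[3]; co <- dim(w)[4]
  r <- .cpp_conv2d_bwd(as.numeric(x), as.integer(xd[1:2]), as.numeric(w),
                       k, ci, co, as.numeric(gy), stride, pad)
  list(gx = array(r$gx, xd), gw = array(r$gw, dim(w)), gb = r$gb)
}

relu <- function(x) pmax(x, 0)

# 2x average pooling, 3D (D,H,W,C) and 2D (H,W,C); dims must be even.
avgpool2_3d <- function(x) {
  d <- dim(x)
  i <- seq(1L, d[1], 2L); j <- seq(1L, d[2], 2L); k <- seq(1L, d[3], 2L)
  (x[i, j, k, , drop = FALSE] + x[i + 1L, j, k, , drop = FALSE] +
     x[i, j + 1L, k, , drop = FALSE] + x[i + 1L, j + 1L, k, , drop = FALSE] +
     x[i, j, k + 1L, , drop = FALSE] + x[i + 1L, j, k + 1L, , drop = FALSE] +
     x[i, j + 1L, k + 1L, , drop = FALSE] +
     x[i + 1L, j + 1L, k + 1L, , drop = FALSE]) / 8
}

avgpool2_3d_bwd <- function(g, in_dim) {
  u <- array(0, in_dim)
  d <- dim(g)
  i <- seq(1L, in_dim[1], 2L); j <- seq(1L, in_dim[2], 2L)
  k <- seq(1L, in_dim[3], 2L)
  g8 <- g / 8
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
    u[i + di, j + dj, k + dk, ] <- g8
  u
}

avgpool2_2d <- function(x) {
  d <- dim(x)
  i <- seq(1L, d[1], 2L); j <- seq(1L, d[2], 2L)
  (x[i, j, , drop = FALSE] + x[i + 1L, j, , drop = FALSE] +
     x[i, j + 1L, , drop = FALSE] + x[i + 1L, j + 1L, , drop = FALSE]) / 4
}

avgpool2_2d_bwd <- function(g, in_dim) {
  u <- array(0, in_dim)
  i <- seq(1L, in_dim[1], 2L); j <- seq(1L, in_dim[2], 2L)
  g4 <- g / 4
  for (di in 0:1) for (dj in 0:1) u[i + di, j + dj, ] <- g4
  u
}

# 2x nearest-neighbour upsampling, 2D (H,W,C).
upsample2_2d <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample2_2d_bwd <- function(g) {
  d <- dim(g)
  i <- seq(1L, d[1], 2L); j <- seq(1L, d[2], 2L)
  g[i, j, , drop = FALSE] + g[i + 1L, j, , drop = FALSE] +
    g[i, j + 1L, , drop = FALSE] + g[i + 1L, j + 1L, , drop = FALSE]
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

# Adam over a named list of parameter arrays.
adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

zero_like <- function(params) lapply(params, function(p) p * 0)
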