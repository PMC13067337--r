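# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# Filled ellipsoid mask (semi-axes in voxels, centred).
ellipsoid_mask <- function(n, semi, center = rep((n + 1) / 2, 3)) {
  ax <- seq_len(n)
  arr <- array(FALSE, c(n, n, n))
  for (k in ax) {
    r2 <- outer(((ax - center[1]) / semi[1])^2,
                ((ax - center[2]) / semi[2])^2, "+") +
      ((k - center[3]) / semi[3])^2
    arr[, , k] <- r2 <= 1
  }
  arr
}

# Annular (ring) 2D mask.
ring_mask <- function(n, cx, cy, r_in, r_out) {
  d2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cy)^2, "+")
  d2 >= r_in^2 & d2 <= r_out^2
}

# Filled disk 2D mask.
disk_mask <- function(h, w, cx, cy, r) {
  outer((seq_len(h) - cx)^2, (seq_len(w) - cy)^2, "+") <= r^2
}

# Scalar-loop trilinear interpolation oracle (independent of the package's
# resampler): samples vol at normalized coords grid, zero outside.
trilinear_oracle <- function(vol, grid, out_shape) {
  d <- dim(vol)
  out <- numeric(nrow(grid))
  for (t in seq_len(nrow(grid))) {
    x <- grid[t, 1] * (d[1] - 1) / 2 + (d[1] - 1) / 2
    y <- grid[t, 2] * (d[2] - 1) / 2 + (d[2] - 1) / 2
    z <- grid[t, 3] * (d[3] - 1) / 2 + (d[3] - 1) / 2
    i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
    acc <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      i <- i0 + di; j <- j0 + dj; k <- k0 + dk
      if (i < 0 || i > d[1] - 1 || j < 0 || j > d[2] - 1 ||
          k < 0 || k > d[3] - 1) next
      w <- (if (di) x - i0 else 1 - (x - i0)) *
        (if (dj) y - j0 else 1 - (y - j0)) *
        (if (dk) z - k0 else 1 - (z - k0))
      acc <- acc + w * vol[i + 1, j + 1, k + 1]
    }
    out[t] <- acc
  }
  array(out, out_shape)
}

# Independent elementwise 3x3 matrix product.
matmul_oracle <- function(a, b) {
  m <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    for (k in 1:3) m[i, j] <- m[i, j] + a[i, k] * b[k, j]
  m
}

# Small default phantom (cached per session).
small_phantom <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7, ...) {
    key <- paste0(seed, "_", paste(deparse(list(...)), collapse = ""))
    if (is.null(cache[[key]]))
      cache[[key]] <- make_phantom(scaled_phantom_config(48, seed = seed,
                                                         ...))
    cache[[key]]
  }
})
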