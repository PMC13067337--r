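test_that("euler_to_matrix composes the printed rotation factors", {
  expect_equal(euler_to_matrix(euler_angles(0, 0, 0)), diag(3))
  # first factor with cos = 0, sin = 1
  expect_equal(euler_to_matrix(euler_angles(90, 0, 0)),
               matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3),
               tolerance = 1e-12)
  # product verified against an independent elementwise multiplication
  a <- 30 * pi / 180; b <- 45 * pi / 180; g <- 60 * pi / 180
  Ry <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
  Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  expect_lt(max(abs(euler_to_matrix(euler_angles(30, 45, 60)) -
                      matmul_oracle(matmul_oracle(Ry, Rx), Rz))), 1e-12)
  # alternative y-x-y convention ends in a y-rotation factor
  expect_lt(max(abs(euler_to_matrix(euler_angles(30, 45, 60), "yxy") -
                      matmul_oracle(matmul_oracle(Ry, Rx),
                                    matrix(c(cos(g), 0, -sin(g), 0, 1, 0,
                                             sin(g), 0, cos(g)), 3, 3)))),
            1e-12)
})

test_that("rotation matrices are orthonormal with unit determinant", {
  set.seed(101)
  for (i in 1:200) {
    ang <- runif(3, -180, 180)
    for (conv in c("as_printed_yxz", "yxy")) {
      m <- euler_to_matrix(euler_angles(ang[1], ang[2], ang[3]), conv)
      expect_lt(max(abs(crossprod(m) - diag(3))), 1e-9)
      expect_lt(abs(det(m) - 1), 1e-9)
    }
  }
})

test_that("angles canonicalize into [-180, 180] and reject non-finite", {
  expect_equal(as.numeric(euler_angles(190, -362, 0)), c(-170, -2, 0))
  expect_error(euler_angles(NaN, 0, 0), "finite")
})

test_that("matrix_to_world is the identity for isotropic voxels and makes
           anisotropic rotations rigid in mm", {
  R <- euler_to_matrix(euler_angles(33, -70, 12))
  expect_identical(matrix_to_world(R, c(2, 2, 2)), R)
  expect_equal(matrix_to_world(diag(3), c(1, 1, 2)), diag(3))
  expect_error(matrix_to_world(R, c(1, 0, 1)), "positive")
  # rod along the sagittal axis, voxel spacing 2 mm there; after a 90-deg
  # in-plane rotation its mm length must be preserved within 2%
  n <- 33
  vol <- array(0, c(n, n, n))
  vol[17, 17, 13:21] <- 1  # extent (21-13) voxels x 2 mm = 16 mm
  v <- cf_volume(vol, c(1, 1, 2))
  rot <- cardiofuse:::rotate_volume_matrix(v, cardiofuse:::rot_about_axis(1L, 90))
  idx <- which(rot$data > 0.5, arr.ind = TRUE)
  len_mm <- (max(idx[, 2]) - min(idx[, 2])) * 1  # now along coronal, 1 mm
  expect_lt(abs(len_mm - 16) / 16, 0.02)
})

test_that("affine_grid maps the identity to normalized coords and inverts", {
  g <- affine_grid(diag(3), c(3, 4, 5))
  expect_equal(unclass(g)[, ], cardiofuse:::normalized_coords(c(3, 4, 5)),
               ignore_attr = TRUE)
  R <- euler_to_matrix(euler_angles(25, 40, -80))
  gid <- affine_grid(R %*% t(R), c(4, 4, 4))
  expect_lt(max(abs(unclass(gid) -
                      cardiofuse:::normalized_coords(c(4, 4, 4)))), 1e-9)
  # centre voxel of an odd-sized volume is a fixed point
  g2 <- affine_grid(R, c(5, 5, 5))
  centre_row <- (prod(c(5, 5, 5)) + 1) / 2
  expect_lt(max(abs(g2[centre_row, ])), 1e-12)
  expect_error(affine_grid(R, c(0, 4, 4)), "positive")
})

test_that("resample_3d matches the scalar-loop trilinear oracle", {
  set.seed(5)
  vol <- array(runif(16^3), c(16, 16, 16))
  R <- euler_to_matrix(euler_angles(runif(1, -90, 90), runif(1, -90, 90),
                                    runif(1, -90, 90)))
  g <- affine_grid(R, c(16, 16, 16))
  got <- resample_3d(cf_volume(vol), g)$data
  want <- trilinear_oracle(vol, unclass(g), c(16, 16, 16))
  expect_lt(max(abs(got - want)), 1e-6)
  # identity grid reproduces the input exactly at lattice points
  gid <- affine_grid(diag(3), c(16, 16, 16))
  expect_lt(max(abs(resample_3d(cf_volume(vol), gid)$data - vol)), 1e-12)
  # nearest mode keeps binary masks binary
  msk <- vol > 0.5
  out <- resample_3d(cf_volume(msk * 1), g, mode = "nearest")$data
  expect_true(all(out %in% c(0, 1)))
  expect_error(resample_3d(cf_volume(vol), structure(matrix(0, 10, 3),
                                                     out_shape = c(2, 2, 2))),
               "shape")
})

test_that("rotate_volume round trips and conserves interior mass", {
  ell <- ellipsoid_mask(33, c(6, 6, 12))
  v <- cf_volume(ell * 1)
  expect_equal(rotate_volume(v, c(0, 0, 0))$data, v$data)
  ang <- euler_angles(25, -40, 65)
  fwd <- rotate_volume(v, ang)
  R <- euler_to_matrix(ang)
  back <- cardiofuse:::rotate_volume_matrix(fwd, t(R))
  expect_gte(dice(back$data > 0.5, ell), 0.98)
  # 180-degree involution about one axis
  r180 <- rotate_volume(rotate_volume(v, c(0, 180, 0)), c(0, 180, 0))
  interior <- 5:29
  expect_lt(max(abs(r180$data[interior, interior, interior] -
                      v$data[interior, interior, interior])), 1e-4)
  # smooth interior blob mass conserved within 1%
  ax <- seq_len(33)
  blob <- array(0, c(33, 33, 33))
  for (k in ax) blob[, , k] <-
    exp(-(outer((ax - 17)^2, (ax - 17)^2, "+") + (k - 17)^2) / 30)
  bv <- cf_volume(blob)
  rb <- rotate_volume(bv, c(35, 50, -20))
  expect_lt(abs(sum(rb$data) - sum(blob)) / sum(blob), 0.01)
  # single bright centre voxel stays the brightest voxel
  spot <- array(0, c(15, 15, 15)); spot[8, 8, 8] <- 1
  rs <- rotate_volume(cf_volume(spot), c(52, -33, 17))
  expect_equal(which.max(rs$data), which.max(spot))
})

test_that("warp_2d matches shift and scalar-loop oracles", {
  set.seed(6)
  img <- matrix(runif(12 * 10), 12, 10)
  expect_equal(warp_2d(img, cardiofuse:::zero_field(img)), img)
  # constant field (1, 0): output(p) = image(p + (1,0)) = rows shifted up
  f <- cardiofuse:::zero_field(img); f[, , 1] <- 1
  got <- warp_2d(img, f)
  want <- rbind(img[-1, ], 0)
  expect_lt(max(abs(got - want)), 1e-12)
  # random field vs per-pixel loop oracle
  fr <- array(runif(12 * 10 * 2, -2, 2), c(12, 10, 2))
  got <- warp_2d(img, fr)
  want <- matrix(0, 12, 10)
  for (i in 1:12) for (j in 1:10) {
    x <- i + fr[i, j, 1]; y <- j + fr[i, j, 2]
    i0 <- floor(x); j0 <- floor(y); fx <- x - i0; fy <- y - j0
    acc <- 0
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      if (ii >= 1 && ii <= 12 && jj >= 1 && jj <= 10)
        acc <- acc + (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
          img[ii, jj]
    }
    want[i, j] <- acc
  }
  expect_lt(max(abs(got - want)), 1e-6)
  expect_error(warp_2d(img, array(0, c(3, 3, 2))), "shape")
})
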