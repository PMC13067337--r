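#' Euler angles in degrees
#'
#' Reorientation parameters (alpha, beta, gamma) in degrees, each canonicalized
#' into \[-180, 180\]. The corresponding rotation matrix is the product of
#' three elementary rotations; see [euler_to_matrix()].
#'
#' @param alpha_deg,beta_deg,gamma_deg angles in degrees.
#' @return A named numeric vector of class `cf_euler`.
#' @export
euler_angles <- function(alpha_deg = 0, beta_deg = 0, gamma_deg = 0) {
  a <- c(alpha_deg = alpha_deg, beta_deg = beta_deg, gamma_deg = gamma_deg)
  if (any(!is.finite(a))) stop("Euler angles must be finite")
  a <- ((a + 180) %% 360) - 180
  structure(as.numeric(a),
            names = c("alpha_deg", "beta_deg", "gamma_deg"),
            class = "cf_euler")
}

as_euler <- function(x) {
  if (inherits(x, "cf_euler")) return(x)
  x <- as.numeric(x)
  euler_angles(x[1], x[2], x[3])
}

deg2rad <- function(d) d * pi / 180

# Elementary rotations about coordinate axes 1 ("x"), 2 ("y"), 3 ("z"),
# acting on coordinate vectors ordered (axis1, axis2, axis3).
rot_about_axis <- function(axis, deg) {
  t <- deg2rad(deg); c_ <- cos(t); s_ <- sin(t)
  switch(axis,
    matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),        # about axis 1
    matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),        # about axis 2
    matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))        # about axis 3
}

#' Euler angles to rotation matrix
#'
#' Composes the three elementary rotation factors in their printed order.
#' The default convention `"as_printed_yxz"` multiplies Ry(alpha) Rx(beta)
#' Rz(gamma) - the third factor has z-rotation structure. The alternative
#' `"yxy"` uses Ry(gamma) as the third factor instead.
#'
#' @param angles a `cf_euler` object or numeric length-3 (degrees).
#' @param convention `"as_printed_yxz"` (default) or `"yxy"`.
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @export
euler_to_matrix <- function(angles, convention = c("as_printed_yxz", "yxy")) {
  angles <- as_euler(angles)
  convention <- match.arg(convention)
  Ry <- rot_about_axis(2L, angles[1])
  Rx <- rot_about_axis(1L, angles[2])
  R3 <- if (convention == "as_printed_yxz") rot_about_axis(3L, angles[3])
        else rot_about_axis(2L, angles[3])
  Ry %*% Rx %*% R3
}

check_rotation_matrix <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  if (max(abs(crossprod(m) - diag(3))) > tol || abs(det(m) - 1) > tol)
    stop("not a proper rotation matrix")
  invisible(m)
}

#' Re-express a rotation for anisotropic voxels
#'
#' The sampling grid works in normalized volume coordinates; for anisotropic
#' voxel spacing a rotation applied there would shear in millimetre space.
#' This re-expresses the matrix as `diag(1/s) %*% m %*% diag(s)` so the
#' rotation is rigid in world (mm) coordinates. For isotropic spacing the
#' input is returned unchanged.
#'
#' @param matrix 3x3 rotation matrix.
#' @param spacing per-axis voxel spacing in mm (positive).
#' @return 3x3 matrix for the normalized-grid sampler.
#' @export
matrix_to_world <- function(matrix, spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive")
  if (max(abs(spacing - spacing[1])) < 1e-12) return(matrix)
  diag(1 / spacing) %*% matrix %*% diag(spacing)
}

# Normalized coordinates of every voxel of a volume of dims d: N x 3 matrix in
# column-major voxel order; [-1, 1] spans the centres of first/last voxels.
normalized_coords <- function(d) {
  ax <- lapply(d, function(n) {
    if (n == 1L) 0 else seq(-1, 1, length.out = n)
  })
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

#' Sampling grid for a rotation about the volume centre
#'
#' For each output voxel `v` with normalized coordinate `n(v)`, the grid holds
#' the source coordinate `g(v) = M %*% n(v)`. No translation component: the
#' geometric centre is a fixed point.
#'
#' @param matrix 3x3 matrix (typically a rotation, possibly anisotropy
#'   corrected via [matrix_to_world()]).
#' @param out_shape integer length-3 output dimensions.
#' @return A `cf_grid3d`: N x 3 matrix of normalized source coordinates with
#'   attribute `out_shape`.
#' @export
affine_grid <- function(matrix, out_shape) {
  out_shape <- as.integer(out_shape)
  if (length(out_shape) != 3L || any(out_shape < 1L))
    stop("out_shape must be 3 positive integers")
  g <- normalized_coords(out_shape) %*% t(matrix)
  structure(g, out_shape = out_shape, class = c("cf_grid3d", class(g)))
}

#' Resample a 3D volume on a sampling grid
#'
#' Trilinear (or nearest-neighbour) interpolation of `volume` at the grid's
#' normalized source coordinates; samples outside the volume read 0. The
#' output keeps the input spacing.
#'
#' @param volume a [cf_volume()] (or bare 3D array).
#' @param grid a grid from [affine_grid()].
#' @param mode `"trilinear"` or `"nearest"`.
#' @return A `cf_volume` of shape `attr(grid, "out_shape")`.
#' @export
resample_3d <- function(volume, grid, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  volume <- as_volume(volume)
  out_shape <- attr(grid, "out_shape")
  if (is.null(out_shape) || nrow(grid) != prod(out_shape))
    stop("grid shape does not match the requested output shape")
  g <- unclass(grid)
  attr(g, "out_shape") <- NULL
  v <- .cpp_resample3d(as.numeric(volume$data), dim(volume$data), g,
                       mode == "nearest")
  cf_volume(array(v, dim = out_shape), volume$spacing)
}

#' Rotate a volume by Euler angles about its centre
#'
#' Composition of [euler_to_matrix()], [matrix_to_world()], [affine_grid()]
#' and [resample_3d()]: the volume content is rotated by `R(angles)`, rigidly
#' in millimetre space, about the geometric centre.
#'
#' @inheritParams resample_3d
#' @inheritParams euler_to_matrix
#' @param angles `cf_euler` or numeric length-3 (degrees).
#' @return Rotated `cf_volume`.
#' @export
rotate_volume <- function(volume, angles, mode = c("trilinear", "nearest"),
                          convention = "as_printed_yxz") {
  volume <- as_volume(volume)
  R <- euler_to_matrix(angles, convention)
  rotate_volume_matrix(volume, R, mode)
}

#' Rotate a volume by a rotation matrix about its centre
#'
#' Applies the content rotation `R` (the sampling grid uses the inverse,
#' i.e. the transpose), rigid in millimetre space. Useful for re-applying a
#' composed rotation such as `align_long_axis()$rotation` to further
#' volumes (masks, coronary trees) on the same grid. Uses a fused kernel
#' that computes the sampling grid on the fly; equivalent to
#' `resample_3d(volume, affine_grid(matrix_to_world(t(R), spacing), dim),
#' mode)`.
#'
#' @param volume a [cf_volume()].
#' @param R 3x3 rotation matrix.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return Rotated `cf_volume`.
#' @export
rotate_volume_matrix <- function(volume, R, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  volume <- as_volume(volume)
  G <- matrix_to_world(t(R), volume$spacing)
  d <- dim(volume$data)
  v <- .cpp_rotate_resample3d(as.numeric(volume$data), d, G,
                              mode == "nearest")
  cf_volume(array(v, d), volume$spacing)
}

#' Warp a 2D image by a dense displacement field
#'
#' `output(p) = image(p + field(p))` with bilinear (or nearest) interpolation
#' and zero fill outside the image. Displacements are in pixels; component 1
#' acts along the first array dimension.
#'
#' @param image 2D matrix.
#' @param field `(H, W, 2)` displacement array.
#' @param mode `"bilinear"` or `"nearest"`.
#' @return Warped 2D matrix.
#' @export
warp_2d <- function(image, field, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  if (!is.matrix(image)) stop("image must be a 2D matrix")
  fd <- dim(field)
  if (length(fd) != 3L || fd[3] != 2L || any(fd[1:2] != dim(image)))
    stop("field shape must be (nrow(image), ncol(image), 2)")
  out <- .cpp_warp2d(as.numeric(image), dim(image), as.numeric(field),
                     mode == "nearest")
  matrix(out, nrow(image), ncol(image))
}

# Zero displacement field for an image.
zero_field <- function(image) array(0, dim = c(dim(image), 2L))

# Displacement field of a rigid 2D transform (rotation about the image centre
# in degrees, then shift in pixels). output(p) = image(T^{-1} p) convention:
# the field stores source minus target positions.
rigid_field_2d <- function(dim2, rotation_deg, shift) {
  H <- dim2[1]; W <- dim2[2]
  cx <- (H + 1) / 2; cy <- (W + 1) / 2
  t <- deg2rad(rotation_deg); c_ <- cos(t); s_ <- sin(t)
  px <- matrix(seq_len(H), H, W) - cx
  py <- matrix(seq_len(W), H, W, byrow = TRUE) - cy
  # inverse rotation then inverse shift
  sx <- c_ * (px - shift[1]) + s_ * (py - shift[2])
  sy <- -s_ * (px - shift[1]) + c_ * (py - shift[2])
  array(c(sx - px, sy - py), dim = c(H, W, 2L))
}

# Vectorized bilinear sampling of a 2D image at fractional pixel coordinates
# (1-based); samples outside the image read 0.
bilinear_at <- function(image, sx, sy) {
  h <- nrow(image); w <- ncol(image)
  i0 <- floor(sx); j0 <- floor(sy)
  fx <- sx - i0; fy <- sy - j0
  get <- function(i, j) {
    ok <- i >= 1 & i <= h & j >= 1 & j <= w
    v <- numeric(length(i))
    v[ok] <- image[cbind(i[ok], j[ok])]
    v
  }
  get(i0, j0) * (1 - fx) * (1 - fy) + get(i0 + 1, j0) * fx * (1 - fy) +
    get(i0, j0 + 1) * (1 - fx) * fy + get(i0 + 1, j0 + 1) * fx * fy
}

# Bilinear resample of a 2D image onto a new pixel grid (used to bring CMR
# slices onto the CTCA in-plane grid). Image centres are aligned.
resample_2d_to <- function(image, old_spacing, out_dim, new_spacing) {
  if (length(old_spacing) == 1L) old_spacing <- rep(old_spacing, 2L)
  if (length(new_spacing) == 1L) new_spacing <- rep(new_spacing, 2L)
  H <- out_dim[1]; W <- out_dim[2]
  if (all(dim(image) == c(H, W)) &&
      max(abs(new_spacing - old_spacing)) < 1e-12) return(image)
  cx0 <- (nrow(image) + 1) / 2; cy0 <- (ncol(image) + 1) / 2
  sx <- (rep(seq_len(H), times = W) - (H + 1) / 2) *
    new_spacing[1] / old_spacing[1] + cx0
  sy <- (rep(seq_len(W), each = H) - (W + 1) / 2) *
    new_spacing[2] / old_spacing[2] + cy0
  matrix(bilinear_at(image, sx, sy), H, W)
}
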