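#' Keep the highest-contrast tail of a CMR time series
#'
#' Perfusion contrast accumulates over the acquisition, so the last `k` time
#' frames carry the highest contrast; the final frame is the reference.
#'
#' @param stack a [cf_cmr_stack()].
#' @param k number of frames to keep (1..n_frames).
#' @return A [cf_cmr_stack()] with `k` frames per slice.
#' @export
select_contrast_frames <- function(stack, k) {
  stopifnot(inherits(stack, "cf_cmr_stack"))
  if (k < 1L || k > stack$n_frames)
    stop("k must be between 1 and n_frames (", stack$n_frames, ")")
  keep <- (stack$n_frames - k + 1L):stack$n_frames
  cf_cmr_stack(stack$frames[, , , keep, drop = FALSE],
               stack$slice_spacing_mm, stack$pixel_spacing_mm)
}

# MSE between a rigidly transformed frame and the reference.
rigid_mse <- function(frame, ref, rot, shift) {
  fld <- rigid_field_2d(dim(frame), rot, shift)
  mean((warp_2d(frame, fld) - ref)^2)
}

# Coarse-to-fine grid search for the rigid transform aligning frame to ref.
fit_rigid_2d <- function(frame, ref, rot_range = 10, shift_range = 4) {
  best <- c(rot = 0, du = 0, dv = 0)
  best_mse <- rigid_mse(frame, ref, 0, c(0, 0))
  for (rot in seq(-rot_range, rot_range, by = 2.5))
    for (du in seq(-shift_range, shift_range, by = 1))
      for (dv in seq(-shift_range, shift_range, by = 1)) {
        m <- rigid_mse(frame, ref, rot, c(du, dv))
        if (m < best_mse) { best_mse <- m; best <- c(rot, du, dv) }
      }
  for (rot in best[1] + seq(-1, 1, by = 0.25))
    for (du in best[2] + seq(-0.75, 0.75, by = 0.25))
      for (dv in best[3] + seq(-0.75, 0.75, by = 0.25)) {
        m <- rigid_mse(frame, ref, rot, c(du, dv))
        if (m < best_mse) { best_mse <- m; best <- c(rot, du, dv) }
      }
  best
}

#' Rigid motion correction of a CMR time series
#'
#' Rigidly registers every frame of each slice to that slice's final frame
#' (the highest-contrast reference) by minimizing MSE over rotation and
#' shift with a coarse-to-fine grid search plus local refinement. The final
#' frame's transform is the identity; constant (degenerate) frames get the
#' identity with a warning.
#'
#' @param stack a [cf_cmr_stack()] (>= 2 frames).
#' @return list with `stack` (motion-corrected) and `transforms` (tibble:
#'   slice, frame, rotation_deg, du, dv).
#' @export
rigid_motion_correct <- function(stack) {
  stopifnot(inherits(stack, "cf_cmr_stack"))
  if (stack$n_frames < 2L) stop("need at least 2 frames")
  out <- stack$frames
  rows <- list()
  for (s in seq_len(stack$n_slices)) {
    ref <- stack$frames[, , s, stack$n_frames]
    for (f in seq_len(stack$n_frames)) {
      frame <- stack$frames[, , s, f]
      if (f == stack$n_frames) {
        tr <- c(0, 0, 0)
      } else if (sd(frame) < 1e-9 || sd(ref) < 1e-9) {
        warning("constant frame; identity transform used")
        tr <- c(0, 0, 0)
      } else {
        tr <- fit_rigid_2d(frame, ref)
        out[, , s, f] <- warp_2d(frame, rigid_field_2d(dim(frame), tr[1],
                                                       tr[2:3]))
      }
      rows[[length(rows) + 1L]] <-
        tibble::tibble(slice = s, frame = f, rotation_deg = tr[1],
                       du = tr[2], dv = tr[3])
    }
  }
  list(stack = cf_cmr_stack(out, stack$slice_spacing_mm,
                            stack$pixel_spacing_mm),
       transforms = do.call(rbind, rows))
}

#' Detect the LV centre by circular Hough transform
#'
#' Builds a Sobel edge map, lets every strong edge pixel vote for circle
#' centres over the candidate radius range, and returns the
#' highest-accumulator circle.
#'
#' @param image 2D matrix.
#' @param radius_range_px length-2 candidate circle radii in pixels.
#' @param edge_quantile edge-strength quantile above which pixels vote.
#' @return list with `center` (row, col), `radius`, `votes`.
#' @export
detect_lv_center <- function(image, radius_range_px = c(5, 20),
                             edge_quantile = 0.9) {
  stopifnot(is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  if (radius_range_px[1] < 1 || radius_range_px[2] > min(h, w) / 2)
    stop("radius range must lie within the image")
  pad <- function(m) {  # replicate edges: no spurious border gradients
    m2 <- matrix(0, h + 2, w + 2)
    m2[2:(h + 1), 2:(w + 1)] <- m
    m2[1, ] <- m2[2, ]; m2[h + 2, ] <- m2[h + 1, ]
    m2[, 1] <- m2[, 2]; m2[, w + 2] <- m2[, w + 1]
    m2
  }
  p <- pad(image)
  ix <- 2:(h + 1); jx <- 2:(w + 1)
  gx <- (p[ix + 1, jx - 1] + 2 * p[ix + 1, jx] + p[ix + 1, jx + 1]) -
        (p[ix - 1, jx - 1] + 2 * p[ix - 1, jx] + p[ix - 1, jx + 1])
  gy <- (p[ix - 1, jx + 1] + 2 * p[ix, jx + 1] + p[ix + 1, jx + 1]) -
        (p[ix - 1, jx - 1] + 2 * p[ix, jx - 1] + p[ix + 1, jx - 1])
  mag <- sqrt(gx^2 + gy^2)
  thr <- stats::quantile(mag, edge_quantile)
  if (max(mag) < 1e-9) stop("no circular structure")
  ep <- which(mag >= pmax(thr, 1e-9), arr.ind = TRUE)
  if (!nrow(ep)) stop("no circular structure")
  angles <- seq(0, 2 * pi, length.out = 73L)[-73L]
  ca <- cos(angles); sa <- sin(angles)
  radii <- seq(ceiling(radius_range_px[1]), floor(radius_range_px[2]), by = 1)
  best <- list(votes = -1)
  for (r in radii) {
    cx <- round(rep(ep[, 1], each = length(angles)) - r * rep(ca,
                                                              nrow(ep)))
    cy <- round(rep(ep[, 2], each = length(angles)) - r * rep(sa,
                                                              nrow(ep)))
    ok <- cx >= 1 & cx <= h & cy >= 1 & cy <= w
    if (!any(ok)) next
    acc <- tabulate(cx[ok] + (cy[ok] - 1L) * h, nbins = h * w)
    peak <- which.max(acc)
    if (acc[peak] > best$votes)
      best <- list(center = c((peak - 1L) %% h + 1L, (peak - 1L) %/% h + 1L),
                   radius = r, votes = acc[peak])
  }
  if (best$votes < 0.25 * 2 * pi * best$radius)
    stop("no circular structure")
  best
}

#' Crop a 2D image to a fixed field of view
#'
#' Returns an exactly `fov`-shaped crop centred on `center`; regions outside
#' the image are zero padded. The crop origin is stored in
#' `attr(, "origin")` so the crop can be pasted back losslessly.
#'
#' @param image 2D matrix.
#' @param center length-2 centre (row, col), may be fractional (rounded).
#' @param fov length-2 output shape `(h, w)`.
#' @return `fov`-shaped matrix.
#' @export
crop_to_fov <- function(image, center, fov = c(105, 75)) {
  stopifnot(is.matrix(image))
  if (any(fov < 1)) stop("fov must be positive")
  fov <- as.integer(fov)
  start <- round(center) - (fov %/% 2L)
  out <- matrix(0, fov[1], fov[2])
  src_i <- (start[1] + 1L):(start[1] + fov[1])
  src_j <- (start[2] + 1L):(start[2] + fov[2])
  ok_i <- src_i >= 1L & src_i <= nrow(image)
  ok_j <- src_j >= 1L & src_j <= ncol(image)
  out[which(ok_i), which(ok_j)] <- image[src_i[ok_i], src_j[ok_j]]
  attr(out, "origin") <- start + 1L
  out
}

# Paste a crop back into a canvas of the original shape (inverse of
# crop_to_fov inside the window).
uncrop <- function(crop, full_dim) {
  origin <- attr(crop, "origin")
  out <- matrix(0, full_dim[1], full_dim[2])
  ii <- origin[1]:(origin[1] + nrow(crop) - 1L)
  jj <- origin[2]:(origin[2] + ncol(crop) - 1L)
  ok_i <- ii >= 1L & ii <= full_dim[1]
  ok_j <- jj >= 1L & jj <= full_dim[2]
  out[ii[ok_i], jj[ok_j]] <- crop[which(ok_i), which(ok_j)]
  out
}

# Exact Euclidean distance map: distance from every pixel to the nearest TRUE
# pixel (two-pass 1D lower-envelope transform).
edt2d <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  INF <- (h + w)^2
  d <- matrix(ifelse(mask, 0, INF), h, w)
  for (j in seq_len(w)) d[, j] <- .cpp_edt1d(d[, j])
  for (i in seq_len(h)) d[i, ] <- .cpp_edt1d(d[i, ])
  sqrt(d)
}

# Softened mask for registration: signed distance to the boundary, clamped
# to a narrow band (px) and mapped to [0, 1] with the far background at 0 -
# matching the resampler's zero fill, so out-of-bounds reads look like
# background rather than boundary.
signed_distance <- function(mask, band_px = 5) {
  if (!any(mask)) stop("empty mask")
  sdm <- edt2d(!mask) - edt2d(mask)
  (pmin(pmax(sdm, -band_px), band_px) / band_px + 1) / 2
}

# Cubic B-spline kernel and its first/second derivatives.
bspline3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

bspline3_d1 <- function(t) {
  a <- abs(t)
  d <- ifelse(a < 1, (-12 * a + 9 * a^2) / 6,
              ifelse(a < 2, -((2 - a)^2) / 2, 0))
  d * sign(t)
}

bspline3_d2 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, 3 * a - 2, ifelse(a < 2, 2 - a, 0))
}

# Basis matrices mapping control coefficients (spacing delta, 1-based pixel
# coords) to dense per-pixel values / first / second derivatives.
bspline_basis <- function(n, delta, deriv = 0L) {
  centers <- seq(1 - 2 * delta, n + 2 * delta, by = delta)
  fn <- switch(deriv + 1L, bspline3, bspline3_d1, bspline3_d2)
  outer(seq_len(n), centers,
        function(x, c_) fn((x - c_) / delta)) / delta^deriv
}

# Block-mean downsample of a 2D image by an integer factor.
downsample2 <- function(img, f) {
  if (f == 1L) return(img)
  h <- (nrow(img) %/% f) * f; w <- (ncol(img) %/% f) * f
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  m <- matrix(0, h %/% f, w %/% f)
  for (di in seq_len(f)) for (dj in seq_len(f))
    m <- m + img[seq(di, h, f), seq(dj, w, f)]
  m / f^2
}

# Bilinearly upsample a dense displacement field to a new shape, scaling the
# displacement values by the resolution ratio.
upsample_field <- function(field, new_dim) {
  old <- dim(field)[1:2]
  ratio <- new_dim / old
  # centre-aligned bilinear magnification; displacements scale with resolution
  f1 <- resample_2d_to(field[, , 1], c(1, 1), new_dim,
                       c(old[1] / new_dim[1], old[2] / new_dim[2]))
  f2 <- resample_2d_to(field[, , 2], c(1, 1), new_dim,
                       c(old[1] / new_dim[1], old[2] / new_dim[2]))
  array(c(f1 * ratio[1], f2 * ratio[2]), c(new_dim, 2L))
}

#' Classical multiresolution nonrigid mask registration
#'
#' Free-form deformation with a cubic B-spline control grid, optimized over
#' an image pyramid. Binary masks are softened to signed distance maps (a
#' binary MSE objective has zero gradient almost everywhere) and the
#' objective is `MSE(warped moving SDM, fixed SDM) + grid_reg * bending
#' energy` of the control-grid displacements. Used to harmonize the
#' modality-dependent LV wall thickness and build pseudo-label CMR targets.
#' If optimization fails to improve mask overlap the identity field is
#' returned, so the warped Dice never falls below the initial Dice.
#'
#' @param moving_mask,fixed_mask same-shaped non-empty binary matrices.
#' @param levels pyramid levels (default 6).
#' @param grid_reg bending-energy weight (default 0.6).
#' @param control_spacing_px B-spline control point spacing at each level.
#' @param iters gradient steps per level.
#' @param lr Adam step size for the control coefficients (pixels).
#' @return Dense displacement field `(h, w, 2)` of class `cf_field2d`.
#' @export
classical_nonrigid_register <- function(moving_mask, fixed_mask, levels = 6L,
                                        grid_reg = 0.6,
                                        control_spacing_px = 4L,
                                        iters = 30L, lr = 0.4) {
  if (!identical(dim(moving_mask), dim(fixed_mask)))
    stop("mask shape mismatch")
  moving_mask <- moving_mask > 0.5
  fixed_mask <- fixed_mask > 0.5
  if (!any(moving_mask) || !any(fixed_mask)) stop("empty mask")
  mov_sdm <- signed_distance(moving_mask)
  fix_sdm <- signed_distance(fixed_mask)
  full_dim <- dim(moving_mask)

  base <- NULL  # accumulated field from coarser levels, at current level res
  for (lev in seq_len(levels)) {
    f <- 2L^(levels - lev)
    if (any(dim(moving_mask) %/% f < 8L)) next
    mov_l <- downsample2(mov_sdm, f)
    fix_l <- downsample2(fix_sdm, f)
    dl <- dim(mov_l)
    base <- if (is.null(base)) array(0, c(dl, 2L)) else upsample_field(base, dl)
    delta <- max(2L, control_spacing_px)
    Bx <- bspline_basis(dl[1], delta)
    By <- bspline_basis(dl[2], delta)
    Bx1 <- bspline_basis(dl[1], delta, 1L)
    By1 <- bspline_basis(dl[2], delta, 1L)
    Bx2 <- bspline_basis(dl[1], delta, 2L)
    By2 <- bspline_basis(dl[2], delta, 2L)
    Cu <- matrix(0, ncol(Bx), ncol(By))
    Cv <- matrix(0, ncol(Bx), ncol(By))
    opt <- adam_state(list(Cu = Cu, Cv = Cv))
    params <- list(Cu = Cu, Cv = Cv)
    npx <- prod(dl)
    for (it in seq_len(iters)) {
      U <- Bx %*% params$Cu %*% t(By)
      V <- Bx %*% params$Cv %*% t(By)
      field <- base + array(c(U, V), c(dl, 2L))
      warped <- warp_2d(mov_l, field)
      resid <- warped - fix_l
      gwarp <- 2 * resid / npx
      gfield <- array(.cpp_warp2d_bwd(as.numeric(mov_l), dl,
                                      as.numeric(field),
                                      as.numeric(gwarp)), c(dl, 2L))
      gCu <- t(Bx) %*% gfield[, , 1] %*% By
      gCv <- t(Bx) %*% gfield[, , 2] %*% By
      # bending energy: mean squared second derivatives of the dense field
      # (u_xx^2 + 2 u_xy^2 + u_yy^2), gradient via the derivative bases
      bend_grad <- function(C) {
        (t(Bx2) %*% (Bx2 %*% C %*% t(By)) %*% By +
           2 * t(Bx1) %*% (Bx1 %*% C %*% t(By1)) %*% By1 +
           t(Bx) %*% (Bx %*% C %*% t(By2)) %*% By2) * (2 / npx)
      }
      # small decay keeps control points without data support at rest, and
      # the large eps stops Adam from amplifying numerically-zero gradients
      gCu <- gCu + grid_reg * bend_grad(params$Cu) + 5e-2 * params$Cu / npx
      gCv <- gCv + grid_reg * bend_grad(params$Cv) + 5e-2 * params$Cv / npx
      # constant step size in *full-resolution* pixels: coarse-level
      # displacements are scaled up by every prolongation
      upd <- adam_step(params, list(Cu = gCu, Cv = gCv), opt, lr / f)
      params <- upd$params
      opt <- upd$state
    }
    U <- Bx %*% params$Cu %*% t(By)
    V <- Bx %*% params$Cv %*% t(By)
    base <- base + array(c(U, V), c(dl, 2L))
  }
  field <- if (is.null(base)) array(0, c(full_dim, 2L))
           else if (all(dim(base)[1:2] == full_dim)) base
           else upsample_field(base, full_dim)

  dice0 <- dice(moving_mask, fixed_mask)
  warped_mask <- warp_2d(moving_mask * 1, field) > 0.5
  if (dice(warped_mask, fixed_mask) < dice0)
    field <- array(0, c(full_dim, 2L))
  structure(field, class = c("cf_field2d", "array"))
}

#' Generate a pseudo-label CMR slice
#'
#' Registers the CMR LV wall mask to the CTCA wall mask with the classical
#' nonrigid method, then applies the field to the CMR intensity slice; the
#' warped slice supervises the learned deformation network.
#'
#' @param cmr_slice CMR intensity matrix.
#' @param cmr_wall_mask,ctca_wall_mask binary wall masks on the same grid as
#'   `cmr_slice`.
#' @param ... passed to [classical_nonrigid_register()].
#' @return list with `image` (warped CMR) and `field`.
#' @export
make_pseudo_label_cmr <- function(cmr_slice, cmr_wall_mask, ctca_wall_mask,
                                  ...) {
  if (!identical(dim(cmr_slice), dim(cmr_wall_mask)) ||
      !identical(dim(cmr_slice), dim(ctca_wall_mask)))
    stop("slice and masks must share one grid")
  field <- classical_nonrigid_register(cmr_wall_mask, ctca_wall_mask, ...)
  list(image = warp_2d(cmr_slice, field), field = field)
}

#' Deformation network configuration
#'
#' A compact 2-level U-Net maps the concatenated (fixed CTCA, moving CMR)
#' slice pair to a dense 2D displacement field. The training loss is
#' `MSE(warped CMR, pseudo-label CMR) + smoothness_weight * mean squared
#' field gradient`; the explicit smoothness term suppresses folded fields,
#' which a pure MSE objective admits.
#'
#' @param base_width channels of the first encoder level.
#' @param smoothness_weight field-gradient penalty weight (>= 0).
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param flow_scale fixed multiplier on the network's field output (px).
#'   Displacements of several pixels are needed while conv weights move
#'   slowly under Adam; scaling the head keeps convergence inside a short
#'   epoch budget.
#' @param seed RNG seed.
#' @return A `cf_sdn_config` list.
#' @export
sdn_config <- function(base_width = 8L, smoothness_weight = 0.01,
                       learning_rate = 1e-4, epochs = 30L, flow_scale = 8,
                       seed = 0L) {
  if (smoothness_weight < 0) stop("smoothness_weight must be >= 0")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (flow_scale <= 0) stop("flow_scale must be positive")
  structure(list(base_width = as.integer(base_width),
                 smoothness_weight = smoothness_weight,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 flow_scale = flow_scale,
                 seed = as.integer(seed)), class = "cf_sdn_config")
}

#' Initialize a deformation network
#'
#' The final field-producing convolution starts at zero so the network
#' begins at the identity transform.
#'
#' @param config a [sdn_config()].
#' @return A `cf_sdn_model`.
#' @export
init_sdn <- function(config = sdn_config()) {
  stopifnot(inherits(config, "cf_sdn_config"))
  set.seed(config$seed)
  W <- config$base_width
  params <- list(
    enc1_w = he_init(c(3, 3, 2, W), 9 * 2), enc1_b = numeric(W),
    enc2_w = he_init(c(3, 3, W, 2 * W), 9 * W), enc2_b = numeric(2 * W),
    bott_w = he_init(c(3, 3, 2 * W, 2 * W), 9 * 2 * W),
    bott_b = numeric(2 * W),
    dec2_w = he_init(c(3, 3, 4 * W, 2 * W), 9 * 4 * W),
    dec2_b = numeric(2 * W),
    dec1_w = he_init(c(3, 3, 3 * W, W), 9 * 3 * W), dec1_b = numeric(W),
    out_w = array(0, c(3, 3, W, 2)), out_b = numeric(2))
  structure(list(params = params, config = config,
                 version = as.character(packageVersion("cardiofuse"))),
            class = "cf_sdn_model")
}

sdn_forward <- function(model, x) {
  p <- model$params
  e1 <- relu(conv2d(x, p$enc1_w, p$enc1_b))
  p1 <- avgpool2_2d(e1)
  e2 <- relu(conv2d(p1, p$enc2_w, p$enc2_b))
  p2 <- avgpool2_2d(e2)
  bt <- relu(conv2d(p2, p$bott_w, p$bott_b))
  u2 <- upsample2_2d(bt)
  c2 <- array(c(u2, e2), c(dim(e2)[1:2], dim(u2)[3] + dim(e2)[3]))
  d2 <- relu(conv2d(c2, p$dec2_w, p$dec2_b))
  u1 <- upsample2_2d(d2)
  c1 <- array(c(u1, e1), c(dim(e1)[1:2], dim(u1)[3] + dim(e1)[3]))
  d1 <- relu(conv2d(c1, p$dec1_w, p$dec1_b))
  fs <- if (is.null(model$config$flow_scale)) 1 else model$config$flow_scale
  field <- conv2d(d1, p$out_w, p$out_b) * fs
  list(field = field,
       cache = list(x = x, e1 = e1, p1 = p1, e2 = e2, p2 = p2, bt = bt,
                    c2 = c2, d2 = d2, c1 = c1, d1 = d1))
}

sdn_backward <- function(model, cache, gfield) {
  p <- model$params
  fs <- if (is.null(model$config$flow_scale)) 1 else model$config$flow_scale
  bo <- conv2d_bwd(cache$d1, p$out_w, gfield * fs)
  gd1 <- bo$gx * (cache$d1 > 0)
  b1 <- conv2d_bwd(cache$c1, p$dec1_w, gd1)
  w1 <- dim(cache$c1)[3] - dim(cache$e1)[3]
  gu1 <- b1$gx[, , seq_len(w1), drop = FALSE]
  ge1_skip <- b1$gx[, , w1 + seq_len(dim(cache$e1)[3]), drop = FALSE]
  gd2 <- upsample2_2d_bwd(gu1) * (cache$d2 > 0)
  b2 <- conv2d_bwd(cache$c2, p$dec2_w, gd2)
  w2 <- dim(cache$c2)[3] - dim(cache$e2)[3]
  gu2 <- b2$gx[, , seq_len(w2), drop = FALSE]
  ge2_skip <- b2$gx[, , w2 + seq_len(dim(cache$e2)[3]), drop = FALSE]
  gbt <- upsample2_2d_bwd(gu2) * (cache$bt > 0)
  bb <- conv2d_bwd(cache$p2, p$bott_w, gbt)
  ge2 <- (avgpool2_2d_bwd(bb$gx, dim(cache$e2)) + ge2_skip) * (cache$e2 > 0)
  be <- conv2d_bwd(cache$p1, p$enc2_w, ge2)
  ge1 <- (avgpool2_2d_bwd(be$gx, dim(cache$e1)) + ge1_skip) * (cache$e1 > 0)
  ba <- conv2d_bwd(cache$x, p$enc1_w, ge1)
  list(enc1_w = ba$gw, enc1_b = ba$gb,
       enc2_w = be$gw, enc2_b = be$gb,
       bott_w = bb$gw, bott_b = bb$gb,
       dec2_w = b2$gw, dec2_b = b2$gb,
       dec1_w = b1$gw, dec1_b = b1$gb,
       out_w = bo$gw, out_b = bo$gb)
}

# Mean squared forward-difference penalty on a field and its gradient.
field_smoothness <- function(field) {
  du_i <- field[-1, , , drop = FALSE] - field[-nrow(field), , , drop = FALSE]
  du_j <- field[, -1, , drop = FALSE] - field[, -ncol(field), , drop = FALSE]
  (sum(du_i^2) + sum(du_j^2)) / length(field)
}

field_smoothness_grad <- function(field) {
  g <- array(0, dim(field))
  n <- nrow(field); m <- ncol(field)
  di <- field[-1, , , drop = FALSE] - field[-n, , , drop = FALSE]
  g[-n, , ] <- g[-n, , , drop = FALSE] - di
  g[-1, , ] <- g[-1, , , drop = FALSE] + di
  dj <- field[, -1, , drop = FALSE] - field[, -m, , drop = FALSE]
  g[, -m, ] <- g[, -m, , drop = FALSE] - dj
  g[, -1, ] <- g[, -1, , drop = FALSE] + dj
  2 * g / length(field)
}

#' Train the nonrigid deformation network
#'
#' Each sample is a (fixed CTCA slice, moving CMR slice, pseudo-label CMR)
#' triplet on one grid. The U-Net predicts a dense displacement field; the
#' loss warps the CMR slice with it and compares to the pseudo-label, plus
#' the smoothness penalty. All randomness is seeded.
#'
#' @param dataset list of samples, each a list with `ctca`, `cmr`, `pseudo`
#'   (equal-shaped matrices; sides divisible by 4).
#' @param config a [sdn_config()].
#' @return list with `model` and `history` (tibble: epoch, loss).
#' @export
train_sdn <- function(dataset, config = sdn_config()) {
  if (!length(dataset)) stop("empty dataset")
  shp <- dim(dataset[[1]]$ctca)
  for (s in dataset)
    if (!identical(dim(s$ctca), shp) || !identical(dim(s$cmr), shp) ||
        !identical(dim(s$pseudo), shp))
      stop("all slices must share one shape")
  if (any(shp %% 4L != 0L)) stop("slice sides must be divisible by 4")
  model <- init_sdn(config)
  opt <- adam_state(model$params)
  hist <- vector("list", max(config$epochs, 0L))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(dataset))
    lo <- numeric(length(ord))
    for (t in seq_along(ord)) {
      s <- dataset[[ord[t]]]
      x <- array(c(s$ctca, s$cmr), c(shp, 2L))
      fw <- sdn_forward(model, x)
      warped <- warp_2d(s$cmr, fw$field)
      resid <- warped - s$pseudo
      loss <- mean(resid^2) +
        config$smoothness_weight * field_smoothness(fw$field)
      if (!is.finite(loss))
        stop("NaN loss at epoch ", ep, "; aborting training")
      lo[t] <- loss
      gwarp <- 2 * resid / length(resid)
      gfield <- array(.cpp_warp2d_bwd(as.numeric(s$cmr), shp,
                                      as.numeric(fw$field),
                                      as.numeric(gwarp)), c(shp, 2L)) +
        config$smoothness_weight * field_smoothness_grad(fw$field)
      grads <- sdn_backward(model, fw$cache, gfield)
      upd <- adam_step(model$params, grads, opt, config$learning_rate)
      model$params <- upd$params
      opt <- upd$state
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, loss = mean(lo))
  }
  history <- if (length(hist)) do.call(rbind, hist)
             else tibble::tibble(epoch = integer(), loss = numeric())
  list(model = model, history = history)
}

#' Register a CMR slice to a CTCA slice with a trained network
#'
#' Deterministic inference: predicts the displacement field from the
#' concatenated slice pair and warps the CMR slice.
#'
#' @param model a trained `cf_sdn_model`.
#' @param ctca_slice,cmr_slice equal-shaped matrices.
#' @return list with `image` (warped CMR) and `field` (`cf_field2d`).
#' @export
register_cmr <- function(model, ctca_slice, cmr_slice) {
  if (!inherits(model, "cf_sdn_model")) stop("uninitialized model")
  if (!identical(dim(ctca_slice), dim(cmr_slice)))
    stop("slice shape mismatch")
  x <- array(c(ctca_slice, cmr_slice), c(dim(ctca_slice), 2L))
  fw <- sdn_forward(model, x)
  list(image = warp_2d(cmr_slice, fw$field),
       field = structure(fw$field, class = c("cf_field2d", "array")))
}

#' Jacobian determinant of a 2D displacement field
#'
#' Determinant of `I + grad(u)` by forward differences; values below zero
#' indicate folding.
#'
#' @param field `(h, w, 2)` displacement array.
#' @return `(h-1) x (w-1)` matrix of determinants.
#' @export
field_jacobian <- function(field) {
  u <- field[, , 1]; v <- field[, , 2]
  ux <- u[-1, ] - u[-nrow(u), ]; uy <- u[, -1] - u[, -ncol(u)]
  vx <- v[-1, ] - v[-nrow(v), ]; vy <- v[, -1] - v[, -ncol(v)]
  n <- nrow(u) - 1L; m <- ncol(u) - 1L
  (1 + ux[, seq_len(m)]) * (1 + vy[seq_len(n), ]) -
    uy[seq_len(n), ] * vx[, seq_len(m)]
}
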