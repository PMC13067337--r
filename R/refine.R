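#' Estimate the LV long axis and its deviation angles
#'
#' The long-axis direction is the principal second-moment axis of the 3D LV
#' mask (in millimetre coordinates), oriented toward the apex - the mask
#' voxel with maximal sagittal index, ties broken by proximity to the RL line
#' through the LV centre. The LV centre is the in-slice centroid on the
#' crosshair short-axis slice (the sagittal slice through the mask centroid).
#' Deviations are the angles between the axis projection and the RL
#' direction: `dev_axial_deg` in the axial plane (components coronal,
#' sagittal), `dev_coronal_deg` in the coronal plane (components axial,
#' sagittal). Sign convention: positive = counterclockwise in the displayed
#' plane with the sagittal axis pointing right.
#'
#' @param lv_mask LV mask as a [cf_volume()] (logical or 0/1).
#' @return A `cf_axis` list: `center`, `apex` (voxel coordinates),
#'   `dev_axial_deg`, `dev_coronal_deg`, `direction`, `extent_ratio`.
#' @export
estimate_axis <- function(lv_mask) {
  lv_mask <- as_volume(lv_mask)
  m <- lv_mask$data > 0.5
  if (!any(m)) stop("empty LV mask")
  # soft (partial-volume) mask values weight the moments: for a binary mask
  # this is the plain voxel-count moment analysis, for an interpolated mask
  # it suppresses resampling quantization
  wts <- pmin(pmax(as.numeric(lv_mask$data[lv_mask$data > 0.01]), 0), 1)
  idx_w <- which(lv_mask$data > 0.01, arr.ind = TRUE)
  idx <- which(m, arr.ind = TRUE)
  centroid <- colSums(idx_w * wts) / sum(wts)

  k0 <- round(centroid[3])
  in_slice <- idx[idx[, 3] == k0, , drop = FALSE]
  if (!nrow(in_slice)) in_slice <- idx
  center <- c(colMeans(in_slice[, 1:2, drop = FALSE]), k0)

  kmax <- max(idx[, 3])
  cand <- idx[idx[, 3] == kmax, , drop = FALSE]
  d2 <- (cand[, 1] - center[1])^2 + (cand[, 2] - center[2])^2
  apex <- as.numeric(cand[which.min(d2), ])

  if (sqrt(sum((apex - center)^2)) <= 2)
    stop("degenerate long axis")

  X <- sweep(idx_w, 2L, centroid)
  X <- sweep(X, 2L, lv_mask$spacing, `*`)
  C <- crossprod(X * wts, X) / sum(wts)
  eg <- eigen(C, symmetric = TRUE)
  ext <- sqrt(pmax(eg$values, 0))
  if (ext[2] <= 0 || ext[1] / ext[2] < 1.1)
    stop("degenerate long axis")
  v <- eg$vectors[, 1]
  apex_dir <- (apex - centroid) * lv_mask$spacing
  if (sum(v * apex_dir) < 0) v <- -v

  dev_ax <- atan2(v[2], v[3]) * 180 / pi
  dev_co <- atan2(v[1], v[3]) * 180 / pi
  wrap90 <- function(a) ifelse(a > 90, a - 180, ifelse(a < -90, a + 180, a))
  structure(list(center = center, apex = apex,
                 dev_axial_deg = wrap90(dev_ax),
                 dev_coronal_deg = wrap90(dev_co),
                 direction = v, extent_ratio = ext[1] / ext[2]),
            class = "cf_axis")
}

#' @export
print.cf_axis <- function(x, ...) {
  cat(sprintf("<cf_axis> dev axial %.2f deg, dev coronal %.2f deg, apex (%g, %g, %g)\n",
              x$dev_axial_deg, x$dev_coronal_deg, x$apex[1], x$apex[2],
              x$apex[3]))
  invisible(x)
}

#' Align the LV long axis to the RL direction
#'
#' Applies corrective in-plane rotations - first in the axial plane (about
#' the axial axis), then in the coronal plane (about the coronal axis),
#' re-estimating the axis between and within steps - until both deviation
#' angles fall below `tol_deg`. The corrections are composed into a single
#' rotation matrix and the volume is resampled once from the original data,
#' so repeated alignment does not accumulate interpolation blur.
#'
#' @param volume CTCA [cf_volume()].
#' @param lv_mask LV mask [cf_volume()] on the same grid.
#' @param tol_deg stop once both residual deviations are below this (deg).
#' @param max_iter maximum corrections per plane.
#' @param order correction order, `c("axial", "coronal")` by default.
#' @return list with `volume` (aligned, trilinear), `mask` (aligned,
#'   nearest-neighbour), `applied_deg` (named: axial, coronal - total
#'   corrective rotations), `rotation` (composed 3x3 matrix), `axis_before`,
#'   `axis_after`.
#' @export
align_long_axis <- function(volume, lv_mask, tol_deg = 0.1, max_iter = 4L,
                            order = c("axial", "coronal")) {
  volume <- as_volume(volume)
  lv_mask <- as_volume(lv_mask)
  axis_before <- estimate_axis(lv_mask)
  A <- diag(3)
  applied <- c(axial = 0, coronal = 0)
  cur_mask <- lv_mask
  for (plane in order) {
    for (it in seq_len(max_iter)) {
      est <- estimate_axis(cur_mask)
      dev <- if (plane == "axial") est$dev_axial_deg else est$dev_coronal_deg
      if (abs(dev) <= tol_deg) break
      # rotation about axis 1 by +dev cancels an axial deviation of dev;
      # about axis 2 the sign flips (see rot_about_axis orientation)
      if (plane == "axial") {
        A <- rot_about_axis(1L, dev) %*% A
        applied["axial"] <- applied["axial"] + dev
      } else {
        A <- rot_about_axis(2L, -dev) %*% A
        applied["coronal"] <- applied["coronal"] - dev
      }
      # trilinear (soft) resampling for the re-estimates: the weighted
      # moment estimator then avoids nearest-neighbour quantization
      cur_mask <- rotate_volume_matrix(lv_mask, A, mode = "trilinear")
    }
  }
  out_vol <- rotate_volume_matrix(volume, A, mode = "trilinear")
  out_mask <- rotate_volume_matrix(lv_mask, A, mode = "nearest")
  # residuals measured on the soft-resampled mask, matching the estimator
  # used during iteration (the binary mask adds ~0.5-1 deg quantization)
  soft_mask <- rotate_volume_matrix(lv_mask, A, mode = "trilinear")
  structure(list(volume = out_vol, mask = out_mask, applied_deg = applied,
                 rotation = A, axis_before = axis_before,
                 axis_after = estimate_axis(soft_mask)),
            class = "cf_alignment")
}

#' Generate the pseudo-label CTCA
#'
#' The fine-tuning target of the reorientation model: the model's reoriented
#' output after deterministic long-axis alignment.
#'
#' @inheritParams align_long_axis
#' @param reoriented the reorientation model's output volume.
#' @return The aligned [cf_volume()], with the alignment stored in
#'   `attr(, "alignment")`.
#' @export
make_pseudo_label_ctca <- function(reoriented, lv_mask) {
  al <- align_long_axis(reoriented, lv_mask)
  out <- al$volume
  attr(out, "alignment") <- al[c("applied_deg", "rotation", "axis_after")]
  out
}
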