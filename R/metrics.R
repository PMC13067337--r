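#' Aspect ratio of an LV cross-section
#'
#' Ratio of the minor to the major principal extent of a 2D mask, from
#' second-moment eigen-analysis (extent = 4 * sqrt(eigenvalue), the full
#' axis length of the equivalent uniform ellipse). A value of 1 indicates an
#' isotropic (circular) cross-section, i.e. a correctly reoriented
#' short-axis view; always <= 1.
#'
#' @param lv_mask_slice 2D binary matrix.
#' @return Scalar in (0, 1\].
#' @export
aspect_ratio <- function(lv_mask_slice) {
  m <- lv_mask_slice > 0.5
  if (!any(m)) stop("empty mask")
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) < 2L) stop("degenerate mask")
  X <- sweep(idx, 2L, colMeans(idx))
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[1] <= 0) stop("degenerate mask")
  sqrt(max(ev[2], 0) / ev[1])
}

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)`. Two empty masks are defined as perfectly
#' overlapping (Dice 1).
#'
#' @param mask_a,mask_b same-shaped binary arrays.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  a <- loss_data(mask_a) > 0.5
  b <- loss_data(mask_b) > 0.5
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  sab <- sum(a) + sum(b)
  if (sab == 0) return(1.0)
  2 * sum(a & b) / sab
}

# Boundary voxels/pixels of a mask: foreground with at least one face
# neighbour outside the mask (or on the array edge).
mask_boundary <- function(m) {
  d <- dim(m)
  interior <- m
  for (ax in seq_along(d)) {
    if (d[ax] < 2L) { interior[] <- FALSE; break }
    shift_lo <- shift_hi <- m
    idx <- slice.index(m, ax)
    shift_lo[idx > 1] <- m[idx < d[ax]]
    shift_lo[idx == 1] <- FALSE
    shift_hi[idx < d[ax]] <- m[idx > 1]
    shift_hi[idx == d[ax]] <- FALSE
    interior <- interior & shift_lo & shift_hi
  }
  m & !interior
}

#' Hausdorff distance between mask boundaries
#'
#' Maximum of the two directed Hausdorff distances between the boundary
#' point sets, with coordinates scaled by the voxel spacing (mm).
#'
#' @param mask_a,mask_b same-shaped non-empty binary arrays (2D or 3D).
#' @param spacing_mm per-axis spacing (recycled if scalar).
#' @return Distance in mm.
#' @export
hausdorff <- function(mask_a, mask_b, spacing_mm = 1) {
  a <- loss_data(mask_a) > 0.5
  b <- loss_data(mask_b) > 0.5
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (!any(a) || !any(b)) stop("empty mask")
  nd <- length(dim(a))
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = nd)
  pa <- sweep(which(mask_boundary(a), arr.ind = TRUE), 2L, spacing_mm, `*`)
  pb <- sweep(which(mask_boundary(b), arr.ind = TRUE), 2L, spacing_mm, `*`)
  # squared cross-distance matrix
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1L, min))), sqrt(max(apply(d2, 2L, min))))
}

#' Evaluate a reorientation against reference CMR wall masks
#'
#' Computes the standard reporting suite: aspect ratio and Dice per mapped
#' slice (then averaged), the two long-axis deviation angles from the full
#' 3D mask (reported as magnitudes), and the Hausdorff distance per slice
#' (maximum and mean over slices). CMR masks are resampled to the CTCA
#' in-plane grid before comparison.
#'
#' @param reoriented_lv_mask 3D LV (cavity or wall) mask [cf_volume()] used
#'   for AR and the long-axis deviations.
#' @param reoriented_wall_mask 3D LV wall mask [cf_volume()] compared
#'   against the CMR wall masks (defaults to `reoriented_lv_mask`).
#' @param reference_cmr_wall_masks 3D logical `(x, y, slice)` array of CMR
#'   wall masks (as from [make_phantom()]).
#' @param slice_mapping a [build_slice_mapping()] result.
#' @param cmr_pixel_spacing_mm CMR in-plane pixel size.
#' @return A `cf_metrics_report`; `tidy()` gives a one-row tibble.
#' @export
evaluate_reorientation <- function(reoriented_lv_mask,
                                   reference_cmr_wall_masks,
                                   slice_mapping,
                                   reoriented_wall_mask = reoriented_lv_mask,
                                   cmr_pixel_spacing_mm = 1) {
  stopifnot(inherits(slice_mapping, "cf_slice_mapping"))
  vol <- as_volume(reoriented_lv_mask)
  wall <- as_volume(reoriented_wall_mask)
  ns <- slice_mapping$n_slices
  if (ns < 1L || dim(reference_cmr_wall_masks)[3] < ns)
    stop("mapping and reference slices disagree")
  d <- dim(vol$data)
  ar <- dsc <- hd <- numeric(ns)
  for (s in seq_len(ns)) {
    k <- slice_mapping$indices[s]
    ct_slice <- vol$data[, , k] > 0.5
    ct_wall <- wall$data[, , k] > 0.5
    cmr <- resample_2d_to(reference_cmr_wall_masks[, , s] * 1,
                          rep(cmr_pixel_spacing_mm, 2), d[1:2],
                          vol$spacing[1:2]) > 0.5
    ar[s] <- aspect_ratio(ct_slice)
    dsc[s] <- dice(ct_wall, cmr)
    hd[s] <- if (any(ct_wall) && any(cmr))
      hausdorff(ct_wall, cmr, vol$spacing[1:2]) else NA_real_
  }
  axis <- estimate_axis(vol)
  structure(list(ar = mean(ar), ar_per_slice = ar,
                 dsc = mean(dsc), dsc_per_slice = dsc,
                 la_dev_axial_deg = abs(axis$dev_axial_deg),
                 la_dev_coronal_deg = abs(axis$dev_coronal_deg),
                 hd_mm = if (all(is.na(hd))) NA_real_ else max(hd,
                                                               na.rm = TRUE),
                 hd_mean_mm = if (all(is.na(hd))) NA_real_ else mean(hd,
                                                                    na.rm = TRUE),
                 hd_per_slice = hd,
                 n_slices_used = ns), class = "cf_metrics_report")
}

#' @export
print.cf_metrics_report <- function(x, ...) {
  cat(sprintf("<cf_metrics_report> AR %.3f | DSC %.3f | LA dev (axial %.2f, coronal %.2f) deg | HD %.2f mm | %d slices\n",
              x$ar, x$dsc, x$la_dev_axial_deg, x$la_dev_coronal_deg,
              x$hd_mm, x$n_slices_used))
  invisible(x)
}

#' Tidy a metrics report into a one-row tibble
#'
#' Columns follow the usual reporting order: AR, DSC, the two long-axis
#' deviation angles, Hausdorff distance.
#'
#' @param x a `cf_metrics_report`.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
tidy.cf_metrics_report <- function(x, ...) {
  tibble::tibble(ar = x$ar, dsc = x$dsc,
                 la_dev_ang1_deg = x$la_dev_axial_deg,
                 la_dev_ang2_deg = x$la_dev_coronal_deg,
                 hd_mm = x$hd_mm, n_slices = x$n_slices_used)
}

#' @importFrom generics tidy
#' @export
generics::tidy
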