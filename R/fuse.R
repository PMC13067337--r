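#' Fuse coronary anatomy with a wall perfusion map
#'
#' Builds an integer labelmap on co-registered grids: LV wall voxels with
#' perfusion below `deficit_threshold` times the median wall perfusion are
#' labelled hypoperfused (3), other wall voxels normal (2), and coronary
#' voxels 1 (coronary wins overlaps); background is 0.
#'
#' @param coronary_mask,wall_mask binary [cf_volume()]s on one grid.
#' @param perfusion_map [cf_volume()] of per-voxel perfusion values on the
#'   same grid.
#' @param deficit_threshold fraction of the wall's median perfusion below
#'   which a wall voxel counts as hypoperfused (default 0.6).
#' @return A `cf_fusion` with `fused_labelmap` ([cf_volume()]),
#'   `label_counts` (named integer vector) and `provenance`.
#' @export
fuse <- function(coronary_mask, wall_mask, perfusion_map,
                 deficit_threshold = 0.6) {
  cm <- as_volume(coronary_mask); wm <- as_volume(wall_mask)
  pm <- as_volume(perfusion_map)
  if (!identical(dim(cm$data), dim(wm$data)) ||
      !identical(dim(cm$data), dim(pm$data)))
    stop("fusion inputs must share one grid")
  co <- cm$data > 0.5
  wa <- wm$data > 0.5
  lab <- array(0L, dim(co))
  wall_perf <- pm$data[wa]
  thr <- deficit_threshold * stats::median(wall_perf)
  lab[wa] <- ifelse(pm$data[wa] < thr, 3L, 2L)
  lab[co] <- 1L
  counts <- c(background = sum(lab == 0L), coronary = sum(lab == 1L),
              wall_normal = sum(lab == 2L), wall_deficit = sum(lab == 3L))
  structure(list(fused_labelmap = cf_volume(lab, cm$spacing),
                 label_counts = counts,
                 deficit_threshold = deficit_threshold,
                 provenance = list(created = "cardiofuse::fuse",
                                   version =
                                     as.character(packageVersion("cardiofuse")))),
            class = "cf_fusion")
}

#' @export
print.cf_fusion <- function(x, ...) {
  cat("<cf_fusion> labels:",
      paste(names(x$label_counts), x$label_counts, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full fusion pipeline on a phantom sample
#'
#' Inference path: predict reorientation angles with the trained model,
#' reorient the CTCA and its masks, refine the long axis with the anatomical
#' prior, select the highest-contrast CMR frames and motion-correct them,
#' map CMR slices into the reoriented volume, crop both modalities about
#' their LV centres, register each CMR slice with the deformation network,
#' then fuse coronary anatomy with the registered perfusion map and report
#' the metric suite. Deterministic for fixed checkpoints.
#'
#' @param sample a `cf_phantom` (or a list with the same fields, e.g. loaded
#'   from files).
#' @param reorient_model trained `cf_reorient_model` or checkpoint path.
#' @param sdn_model trained `cf_sdn_model` or checkpoint path.
#' @param fov in-plane field of view for the per-slice registration; both
#'   sides must be divisible by 4 (network constraint).
#' @param k_frames CMR frames kept by [select_contrast_frames()].
#' @param deficit_threshold passed to [fuse()].
#' @param motion_correct run [rigid_motion_correct()] on the selected frames.
#' @return list with `fusion` (`cf_fusion`), `metrics`
#'   (`cf_metrics_report`), `aligned` (refinement output), `angles`
#'   (predicted), `registered_slices` (per-slice registration results).
#' @export
run_pipeline <- function(sample, reorient_model, sdn_model,
                         fov = c(64, 64), k_frames = 10,
                         deficit_threshold = 0.6, motion_correct = TRUE) {
  if (is.character(reorient_model)) {
    if (!file.exists(reorient_model))
      stop("reorientation stage: checkpoint not found: ", reorient_model)
    reorient_model <- load_checkpoint(reorient_model)
  }
  if (is.character(sdn_model)) {
    if (!file.exists(sdn_model))
      stop("registration stage: checkpoint not found: ", sdn_model)
    sdn_model <- load_checkpoint(sdn_model)
  }
  if (!inherits(reorient_model, "cf_reorient_model"))
    stop("reorientation stage: uninitialized model")
  if (!inherits(sdn_model, "cf_sdn_model"))
    stop("registration stage: uninitialized model")

  conv <- reorient_model$config$euler_convention
  angles <- predict_angles(reorient_model, sample$ctca)
  reor <- rotate_volume(sample$ctca, angles, convention = conv)
  reor_cav <- rotate_volume(sample$lv_cavity_mask, angles, mode = "nearest",
                            convention = conv)
  reor_wall <- rotate_volume(sample$lv_wall_mask, angles, mode = "nearest",
                             convention = conv)
  reor_cor <- rotate_volume(sample$coronary_mask, angles, mode = "nearest",
                            convention = conv)

  al <- align_long_axis(reor, reor_cav)
  A <- al$rotation
  ct <- al$volume
  cav <- al$mask
  wallv <- rotate_volume_matrix(reor_wall, A, mode = "nearest")
  corv <- rotate_volume_matrix(reor_cor, A, mode = "nearest")

  st <- select_contrast_frames(sample$cmr_stack, k_frames)
  if (motion_correct) st <- rigid_motion_correct(st)$stack

  mapping <- build_slice_mapping(ct, cav, st$slice_spacing_mm, st$n_slices)
  d <- dim(ct$data)
  csp <- st$pixel_spacing_mm

  n_bins <- 72L
  profiles <- matrix(NA_real_, st$n_slices, n_bins)
  reg_slices <- vector("list", st$n_slices)
  hough_radius <- c(3, floor(min(dim(st$frames)[1:2]) / 2) - 1)
  for (s in seq_len(st$n_slices)) {
    k <- mapping$indices[s]
    cmr_ref <- st$frames[, , s, st$n_frames]
    cmr_ct <- resample_2d_to(cmr_ref, rep(csp, 2), d[1:2], ct$spacing[1:2])
    perf_ct <- resample_2d_to(sample$perfusion_map[, , s], rep(csp, 2),
                              d[1:2], ct$spacing[1:2])
    cmr_wall_ct <- resample_2d_to(sample$cmr_wall_masks[, , s] * 1,
                                  rep(csp, 2), d[1:2],
                                  ct$spacing[1:2]) > 0.5
    ct_slice <- ct$data[, , k]
    # CTCA LV centre from the cavity mask (a mask is always an input here);
    # the CMR centre comes from the Hough transform on the intensity image
    cav_px <- which(cav$data[, , k] > 0.5, arr.ind = TRUE)
    ct_center <- if (nrow(cav_px)) colMeans(cav_px) else (d[1:2] + 1) / 2
    cmr_center <- tryCatch(detect_lv_center(cmr_ct)$center,
                           error = function(e) (d[1:2] + 1) / 2)
    ct_crop <- crop_to_fov(ct_slice, ct_center, fov)
    cmr_crop <- crop_to_fov(cmr_ct, cmr_center, fov)
    perf_crop <- crop_to_fov(perf_ct, cmr_center, fov)
    wall_crop <- crop_to_fov(cmr_wall_ct * 1, cmr_center, fov)
    reg <- register_cmr(sdn_model, ct_crop, cmr_crop)
    perf_reg <- warp_2d(perf_crop, reg$field)
    wall_reg <- warp_2d(wall_crop, reg$field) > 0.5
    # angular perfusion profile of the registered wall about the LV centre
    # (the crop centre): perfusion deficits are territorial, so the profile
    # is what extends to off-slice wall voxels
    ci <- fov[1] %/% 2L + 1L; cj <- fov[2] %/% 2L + 1L
    wpx <- which(wall_reg, arr.ind = TRUE)
    if (nrow(wpx)) {
      theta <- atan2(wpx[, 1] - ci, wpx[, 2] - cj)
      bin <- pmin(floor((theta + pi) / (2 * pi) * n_bins) + 1L, n_bins)
      vals <- perf_reg[wpx]
      profiles[s, ] <- vapply(seq_len(n_bins), function(b_) {
        v <- vals[bin == b_]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    }
    reg_slices[[s]] <- list(slice = s, ctca_index = k, image = reg$image,
                            field = reg$field, ctca_crop = ct_crop,
                            cmr_crop = cmr_crop,
                            cmr_wall_crop = wall_crop > 0.5,
                            cmr_wall_registered = wall_reg,
                            ctca_wall_crop =
                              crop_to_fov(wallv$data[, , k] * 1, ct_center,
                                          fov) > 0.5)
  }

  # assign every wall voxel the profile value of its angle about the LV
  # axis, from the nearest mapped slice; angles without coverage take the
  # median of the covered profile
  wall_idx <- which(wallv$data > 0.5, arr.ind = TRUE)
  nearest_s <- max.col(-abs(outer(wall_idx[, 3], mapping$indices, "-")),
                       ties.method = "first")
  # LV axis position per sagittal slice = in-slice cavity centroid (global
  # centroid where the cavity is absent)
  cav_all <- which(cav$data > 0.5, arr.ind = TRUE)
  gctr <- colMeans(cav_all[, 1:2, drop = FALSE])
  ax_ctr <- matrix(rep(gctr, each = d[3]), d[3], 2)
  for (k in unique(wall_idx[, 3])) {
    px <- cav_all[cav_all[, 3] == k, , drop = FALSE]
    if (nrow(px) > 3) ax_ctr[k, ] <- colMeans(px[, 1:2, drop = FALSE])
  }
  theta_v <- atan2(wall_idx[, 1] - ax_ctr[wall_idx[, 3], 1],
                   wall_idx[, 2] - ax_ctr[wall_idx[, 3], 2])
  bin_v <- pmin(floor((theta_v + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  pv <- profiles[cbind(nearest_s, bin_v)]
  pv[is.na(pv)] <- stats::median(profiles, na.rm = TRUE)
  perf_vol <- array(0, d)
  perf_vol[wall_idx] <- pv

  fus <- fuse(corv, wallv, cf_volume(perf_vol, ct$spacing),
              deficit_threshold)
  fus$provenance$reorient_version <- reorient_model$version
  fus$provenance$sdn_version <- sdn_model$version

  metrics <- evaluate_reorientation(cav, sample$cmr_wall_masks, mapping,
                                    reoriented_wall_mask = wallv,
                                    cmr_pixel_spacing_mm = csp)
  list(fusion = fus, metrics = metrics, aligned = al, angles = angles,
       mapping = mapping, registered_slices = reg_slices,
       wall_dice_pre = vapply(reg_slices, function(r)
         dice(r$cmr_wall_crop, r$ctca_wall_crop), numeric(1)),
       wall_dice_post = vapply(reg_slices, function(r)
         dice(r$cmr_wall_registered, r$ctca_wall_crop), numeric(1)))
}
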