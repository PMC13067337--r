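# Seeded dataset builders: the phantom cohorts used to train and evaluate
# the two networks at desk scale. All randomness (geometry jitter,
# orientations, per-phantom noise seeds) is drawn up front from the base
# seed, because make_phantom() re-seeds the RNG with its own config seed.

#' Phantom configuration scaled to a reduced grid
#'
#' Scales the default anatomy (defined for a 96-voxel grid) to a smaller
#' cube so training volumes stay cheap while keeping proportions.
#'
#' @param grid_size cube edge in voxels.
#' @param ... overrides passed to [phantom_config()].
#' @return A `cf_phantom_config`.
#' @export
scaled_phantom_config <- function(grid_size = 48L, ...) {
  f <- grid_size / 96
  args <- list(grid_size = as.integer(grid_size),
               lv_long_semiaxis_mm = 30 * f,
               lv_short_semiaxis_mm = 15 * f,
               wall_thickness_mm = 6 * f,
               coronary_radius_mm = max(1, 2.5 * f),
               cmr_slice_spacing_mm = 8 * f,
               cmr_inplane_shift_mm = c(2, 1) * f)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}

#' Build a reorientation training cohort
#'
#' Each sample is one synthetic subject: a CTCA volume generated at a random
#' long-axis orientation (uniform per axis within `rotation_range`), its
#' aligned short-axis twin as the template, the LV cavity mask, and the
#' subject's CMR slices (highest-contrast frame, on the CTCA in-plane
#' grid). Geometry is jittered a few percent per subject to emulate
#' anatomical variation.
#'
#' @param n number of subjects.
#' @param grid_size cube edge in voxels.
#' @param rotation_range per-axis orientation range in degrees.
#' @param seed base seed.
#' @param jitter relative geometry jitter (uniform, +/-).
#' @return list of samples (see [train_reorientation()]), each also carrying
#'   `aligned_cavity`, `aligned_wall` and `true_orientation` for evaluation.
#' @export
build_reorient_dataset <- function(n, grid_size = 48L,
                                   rotation_range = c(-30, 30), seed = 0L,
                                   jitter = 0.08) {
  set.seed(seed)
  angles <- matrix(runif(3 * n, rotation_range[1], rotation_range[2]), n, 3)
  jit <- matrix(runif(2 * n, -jitter, jitter), n, 2)
  lapply(seq_len(n), function(i) {
    cfg_al <- scaled_phantom_config(
      grid_size,
      lv_long_semiaxis_mm = 30 * grid_size / 96 * (1 + jit[i, 1]),
      lv_short_semiaxis_mm = 15 * grid_size / 96 * (1 + jit[i, 2]),
      seed = seed + 1000L + i)
    cfg_rot <- cfg_al
    cfg_rot$long_axis_orientation <- euler_angles(angles[i, 1], angles[i, 2],
                                                  angles[i, 3])
    aligned <- make_phantom(cfg_al)
    rotated <- make_phantom(cfg_rot)
    nf <- aligned$cmr_stack$n_frames
    d <- dim(aligned$ctca$data)
    cmr_slices <- lapply(seq_len(aligned$cmr_stack$n_slices), function(s)
      resample_2d_to(aligned$cmr_stack$frames[, , s, nf],
                     rep(aligned$cmr_stack$pixel_spacing_mm, 2), d[1:2],
                     aligned$ctca$spacing[1:2]))
    list(ct = rotated$ctca,
         lv_mask = rotated$lv_cavity_mask,
         template = aligned$ctca,
         cmr_slices = cmr_slices,
         cmr_slice_spacing_mm = cfg_al$cmr_slice_spacing_mm,
         aligned_cavity = aligned$lv_cavity_mask,
         aligned_wall = aligned$lv_wall_mask,
         cmr_wall_masks = aligned$cmr_wall_masks,
         true_orientation = cfg_rot$long_axis_orientation,
         config = cfg_rot)
  })
}

#' Evaluate a reorientation model on held-out phantoms
#'
#' For each sample: predict angles, reorient volume and cavity mask, refine
#' with [align_long_axis()], and measure the residual long-axis deviation
#' (largest of the two plane magnitudes) plus the LV cavity Dice against the
#' sample's aligned ground truth.
#'
#' @param model a `cf_reorient_model`.
#' @param samples output of [build_reorient_dataset()].
#' @param refine apply the anatomical-prior refinement (default TRUE).
#' @return tibble: sample, la_dev_deg, lv_dice, plus the predicted angles.
#' @export
evaluate_reorientation_on_phantoms <- function(model, samples,
                                               refine = TRUE) {
  conv <- model$config$euler_convention
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    ang <- predict_angles(model, s$ct)
    vol <- rotate_volume(s$ct, ang, convention = conv)
    msk <- rotate_volume(s$lv_mask, ang, mode = "nearest", convention = conv)
    if (refine) {
      al <- align_long_axis(vol, msk)
      msk <- al$mask
      ax <- al$axis_after
    } else {
      ax <- estimate_axis(msk)
    }
    tibble::tibble(sample = i,
                   la_dev_deg = max(abs(ax$dev_axial_deg),
                                    abs(ax$dev_coronal_deg)),
                   lv_dice = dice(msk, s$aligned_cavity),
                   alpha_deg = ang[1], beta_deg = ang[2], gamma_deg = ang[3])
  })
  do.call(rbind, rows)
}

#' Build pseudo-label CTCA volumes for fine-tuning
#'
#' Runs the current model on each sample and refines the reoriented output
#' into its pseudo-label (Step A of the pipeline).
#'
#' @param model a trained `cf_reorient_model`.
#' @param samples output of [build_reorient_dataset()].
#' @return list of `(ct, pseudo_label)` pairs for [fine_tune()].
#' @export
build_pseudo_label_dataset <- function(model, samples) {
  conv <- model$config$euler_convention
  lapply(samples, function(s) {
    ang <- predict_angles(model, s$ct)
    vol <- rotate_volume(s$ct, ang, convention = conv)
    msk <- rotate_volume(s$lv_mask, ang, mode = "nearest", convention = conv)
    pl <- make_pseudo_label_ctca(vol, msk)
    # the pseudo-label supervises the *input* volume: compose the predicted
    # rotation and the refinement into the target for s$ct
    al <- attr(pl, "alignment")
    target <- rotate_volume_matrix(
      s$ct, al$rotation %*% euler_to_matrix(ang, conv))
    list(ct = s$ct, pseudo_label = target)
  })
}

#' Build a deformation-network training set
#'
#' Generates phantom subjects, takes each mapped short-axis slice pair
#' (reoriented CTCA, cropped CMR) about the Hough-detected LV centres, and
#' builds the pseudo-label CMR by classical nonrigid wall-mask registration.
#'
#' @param n_triplets number of slice triplets (3 per subject).
#' @param grid_size phantom cube edge.
#' @param fov crop field of view (sides divisible by 4).
#' @param seed base seed.
#' @return list with `dataset` (triplets for [train_sdn()]) and `masks`
#'   (per-triplet cropped CMR/CTCA wall masks, for evaluation).
#' @export
build_sdn_dataset <- function(n_triplets, grid_size = 48L, fov = c(64, 64),
                              seed = 0L) {
  n_subj <- ceiling(n_triplets / 3)
  set.seed(seed)
  jit <- matrix(runif(2 * n_subj, -0.08, 0.08), n_subj, 2)
  dataset <- list(); masks <- list()
  for (i in seq_len(n_subj)) {
    cfg <- scaled_phantom_config(
      grid_size,
      lv_long_semiaxis_mm = 30 * grid_size / 96 * (1 + jit[i, 1]),
      lv_short_semiaxis_mm = 15 * grid_size / 96 * (1 + jit[i, 2]),
      seed = seed + 2000L + i)
    ph <- make_phantom(cfg)
    st <- ph$cmr_stack
    d <- dim(ph$ctca$data)
    mapping <- build_slice_mapping(ph$ctca, ph$lv_cavity_mask,
                                   st$slice_spacing_mm, st$n_slices)
    for (s in seq_len(st$n_slices)) {
      if (length(dataset) >= n_triplets) break
      k <- mapping$indices[s]
      ct_slice <- ph$ctca$data[, , k]
      cmr_ref <- resample_2d_to(st$frames[, , s, st$n_frames],
                                rep(st$pixel_spacing_mm, 2), d[1:2],
                                ph$ctca$spacing[1:2])
      cmr_wall <- resample_2d_to(ph$cmr_wall_masks[, , s] * 1,
                                 rep(st$pixel_spacing_mm, 2), d[1:2],
                                 ph$ctca$spacing[1:2]) > 0.5
      cav_px <- which(ph$lv_cavity_mask$data[, , k], arr.ind = TRUE)
      ct_center <- if (nrow(cav_px)) colMeans(cav_px) else (d[1:2] + 1) / 2
      cmr_center <- tryCatch(detect_lv_center(cmr_ref)$center,
                             error = function(e) (d[1:2] + 1) / 2)
      ct_crop <- crop_to_fov(ct_slice, ct_center, fov)
      ct_wall_crop <- crop_to_fov(ph$lv_wall_mask$data[, , k] * 1,
                                  ct_center, fov) > 0.5
      cmr_crop <- crop_to_fov(cmr_ref, cmr_center, fov)
      cmr_wall_crop <- crop_to_fov(cmr_wall * 1, cmr_center, fov) > 0.5
      pl <- make_pseudo_label_cmr(cmr_crop, cmr_wall_crop, ct_wall_crop)
      dataset[[length(dataset) + 1L]] <-
        list(ctca = ct_crop, cmr = cmr_crop, pseudo = pl$image)
      masks[[length(masks) + 1L]] <-
        list(cmr_wall = cmr_wall_crop, ctca_wall = ct_wall_crop,
             pseudo_field = pl$field)
    }
  }
  list(dataset = dataset, masks = masks)
}
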