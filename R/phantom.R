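#' Configuration for the synthetic cardiac phantom
#'
#' The phantom emulates the acquisition geometry the pipeline assumes: a
#' contrast-CT-like volume holding a truncated prolate-ellipsoid LV (bright
#' cavity, intermediate wall, dark background), an RV crescent, a coronary
#' tube on the epicardial surface, and a short-axis CMR-like stack (first
#' slice most basal) with a smooth contrast-enhancement time course and an
#' optional hypoperfused sector. The CMR-phase wall is thicker than the CT
#' wall by `wall_thickness_cmr_scale` and carries a small fixed in-plane
#' offset and elliptical distortion, emulating breath-hold/phase differences
#' between the modalities; these are the discrepancies the registration
#' stages must close.
#'
#' @param grid_size voxels per axis (scalar cube, default 96).
#' @param voxel_spacing_mm isotropic CT voxel size in mm.
#' @param lv_long_semiaxis_mm,lv_short_semiaxis_mm cavity ellipsoid semi-axes.
#' @param wall_thickness_mm myocardial shell thickness on CT.
#' @param wall_thickness_cmr_scale multiplicative CMR wall thickness factor.
#' @param long_axis_orientation `cf_euler` orientation of the LV long axis
#'   (identity = long axis along the sagittal/RL direction, apex toward
#'   increasing sagittal index).
#' @param coronary_radius_mm tube radius of the synthetic coronary artery.
#' @param deficit_sector numeric length-3: sector centre angle (deg), angular
#'   width (deg), hypoperfusion fraction in \[0, 1\].
#' @param noise_sigma additive Gaussian noise level (post-normalization units).
#' @param n_frames CMR time frames (default 90).
#' @param n_slices CMR short-axis slices (default 3).
#' @param cmr_slice_spacing_mm distance between CMR slices.
#' @param cmr_pixel_spacing_mm CMR in-plane pixel size.
#' @param cmr_inplane_shift_mm fixed in-plane LV offset of the CMR geometry.
#' @param cmr_wall_ellipticity in-plane anisotropic scaling of the CMR LV
#'   (1 = none).
#' @param base_trunc_frac basal truncation of the ellipsoid, as a fraction of
#'   the long semi-axis.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `cf_phantom_config` list.
#' @export
phantom_config <- function(grid_size = 96L,
                           voxel_spacing_mm = 1.0,
                           lv_long_semiaxis_mm = 30,
                           lv_short_semiaxis_mm = 15,
                           wall_thickness_mm = 6,
                           wall_thickness_cmr_scale = 1.25,
                           long_axis_orientation = euler_angles(0, 0, 0),
                           coronary_radius_mm = 2.5,
                           deficit_sector = c(center_deg = 0, width_deg = 90,
                                              hypoperfusion = 0.5),
                           noise_sigma = 0.02,
                           n_frames = 90L,
                           n_slices = 3L,
                           cmr_slice_spacing_mm = 8,
                           cmr_pixel_spacing_mm = 1.0,
                           cmr_inplane_shift_mm = c(2, 1),
                           cmr_wall_ellipticity = 1.10,
                           base_trunc_frac = 0.3,
                           seed = 1L) {
  cfg <- list(grid_size = as.integer(grid_size),
              voxel_spacing_mm = voxel_spacing_mm,
              lv_long_semiaxis_mm = lv_long_semiaxis_mm,
              lv_short_semiaxis_mm = lv_short_semiaxis_mm,
              wall_thickness_mm = wall_thickness_mm,
              wall_thickness_cmr_scale = wall_thickness_cmr_scale,
              long_axis_orientation = as_euler(long_axis_orientation),
              coronary_radius_mm = coronary_radius_mm,
              deficit_sector = deficit_sector,
              noise_sigma = noise_sigma,
              n_frames = as.integer(n_frames),
              n_slices = as.integer(n_slices),
              cmr_slice_spacing_mm = cmr_slice_spacing_mm,
              cmr_pixel_spacing_mm = cmr_pixel_spacing_mm,
              cmr_inplane_shift_mm = cmr_inplane_shift_mm,
              cmr_wall_ellipticity = cmr_wall_ellipticity,
              base_trunc_frac = base_trunc_frac,
              seed = as.integer(seed))
  lens <- c(cfg$grid_size, cfg$voxel_spacing_mm, cfg$lv_long_semiaxis_mm,
            cfg$lv_short_semiaxis_mm, cfg$wall_thickness_mm,
            cfg$coronary_radius_mm, cfg$cmr_slice_spacing_mm,
            cfg$cmr_pixel_spacing_mm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom lengths must be positive")
  if (cfg$wall_thickness_cmr_scale <= 0)
    stop("wall_thickness_cmr_scale must be positive")
  if (cfg$deficit_sector[3] < 0 || cfg$deficit_sector[3] > 1)
    stop("hypoperfusion fraction must lie in [0, 1]")
  if (cfg$n_slices < 1L) stop("n_slices must be >= 1")
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0")
  half_extent <- (cfg$grid_size - 1) / 2 * cfg$voxel_spacing_mm
  if (cfg$lv_long_semiaxis_mm + cfg$wall_thickness_mm >= half_extent)
    stop("phantom exceeds field of view")
  structure(cfg, class = "cf_phantom_config")
}

# angular distance in degrees, wrapped to [0, 180]
ang_dist <- function(a, b) {
  d <- abs(((a - b + 180) %% 360) - 180)
  d
}

#' Generate a synthetic cardiac phantom
#'
#' Produces a CTCA-like volume (min-max normalized to \[0, 1\]) with LV
#' cavity/wall and coronary masks, a CMR-like short-axis stack with its wall
#' masks and ground-truth perfusion map, and the true long-axis orientation.
#' The CMR stack is always generated in the aligned short-axis frame; the CT
#' geometry is rotated analytically by the configured orientation, so the
#' masks stay sharp at any angle.
#'
#' @param config a [phantom_config()].
#' @return A `cf_phantom` list with elements `ctca`, `lv_cavity_mask`,
#'   `lv_wall_mask`, `coronary_mask` (all [cf_volume()]), `cmr_stack`
#'   ([cf_cmr_stack()]), `cmr_wall_masks` (3D logical `(x, y, slice)`),
#'   `perfusion_map` (same shape, ground-truth wall perfusion),
#'   `true_orientation` (`cf_euler`), and `config`.
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "cf_phantom_config"))
  set.seed(config$seed)
  n <- config$grid_size
  sp <- config$voxel_spacing_mm
  a <- config$lv_long_semiaxis_mm
  b <- config$lv_short_semiaxis_mm
  w <- config$wall_thickness_mm
  trunc_z <- -config$base_trunc_frac * a

  ax <- (seq_len(n) - (n + 1) / 2) * sp
  P <- cbind(rep(ax, times = n * n),
             rep(rep(ax, each = n), times = n),
             rep(ax, each = n * n))
  R <- euler_to_matrix(config$long_axis_orientation)
  U <- P %*% R  # body coordinates (long axis = column 3)

  ell <- function(u, bs, as_) {
    (u[, 1] / bs)^2 + (u[, 2] / bs)^2 + (u[, 3] / as_)^2 <= 1
  }
  keep <- U[, 3] >= trunc_z
  cavity <- ell(U, b, a) & keep
  outer <- ell(U, b + w, a + w) & U[, 3] >= trunc_z - w
  wall <- outer & !cavity

  # RV crescent abutting the LV wall on the anterior side
  Urv <- cbind(U[, 1], U[, 2] + (b + w) * 0.95, U[, 3] + 0.1 * a)
  rv <- ell(Urv, 0.8 * b, 0.7 * a) & keep & !outer

  # Coronary tube along the epicardial surface toward the apex
  psi <- seq(0.65 * pi, 0.06 * pi, length.out = 120)
  theta <- seq(0.3, 1.8, length.out = 120)
  r_surf <- 1.02
  cz <- (a + w) * r_surf * cos(psi)
  crho <- (b + w) * r_surf * sin(psi)
  curve_body <- cbind(crho * sin(theta), crho * cos(theta), cz)
  curve_world <- curve_body %*% t(R)
  coronary <- logical(n^3)
  rad_vox <- config$coronary_radius_mm / sp
  ctr <- (n + 1) / 2
  for (s in seq_len(nrow(curve_world))) {
    cvox <- curve_world[s, ] / sp + ctr
    lo <- pmax(1L, floor(cvox - rad_vox - 1))
    hi <- pmin(n, ceiling(cvox + rad_vox + 1))
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dx2 <- (ii - cvox[1])^2; dy2 <- (jj - cvox[2])^2; dz2 <- (kk - cvox[3])^2
    ball <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rad_vox^2
    lin <- as.vector(outer(outer(ii, (jj - 1) * n, "+"),
                           (kk - 1) * n * n, "+"))
    coronary[lin[as.vector(ball)]] <- TRUE
  }
  coronary <- coronary & !cavity

  intens <- rep(0.10, n^3)
  intens[rv] <- 0.70
  intens[wall] <- 0.45
  intens[cavity] <- 0.95
  intens[coronary] <- 0.90
  if (config$noise_sigma > 0)
    intens <- pmin(1, pmax(0, intens + rnorm(n^3, 0, config$noise_sigma)))
  ct <- cf_volume(array(minmax_norm(intens), dim = c(n, n, n)), rep(sp, 3))

  # ---- CMR stack, aligned short-axis frame --------------------------------
  w_cmr <- w * config$wall_thickness_cmr_scale
  e <- config$cmr_wall_ellipticity
  sh <- config$cmr_inplane_shift_mm
  csp <- config$cmr_pixel_spacing_mm
  nc <- max(8L, round(n * sp / csp))
  cax <- (seq_len(nc) - (nc + 1) / 2) * csp
  v1 <- (rep(cax, times = nc) - sh[1]) / e
  v2 <- (rep(cax, each = nc) - sh[2]) * e
  rho2 <- v1^2 + v2^2
  theta_px <- atan2(v1, v2) * 180 / pi

  zs <- trunc_z + (seq_len(config$n_slices) - 1) * config$cmr_slice_spacing_mm
  if (any(zs > a))
    stop("CMR slices fall outside the LV: reduce slice spacing or n_slices")

  sector <- config$deficit_sector
  in_sector <- ang_dist(theta_px, sector[1]) <= sector[2] / 2

  nf <- config$n_frames
  tt <- seq_len(nf) / nf
  cav_curve <- 1 - exp(-4 * tt)
  wall_curve <- 1 - exp(-4 * pmax(0, tt - 0.15))

  frames <- array(0, dim = c(nc, nc, config$n_slices, nf))
  wall_masks <- array(FALSE, dim = c(nc, nc, config$n_slices))
  perf_map <- array(0, dim = c(nc, nc, config$n_slices))
  for (s in seq_len(config$n_slices)) {
    z <- zs[s]
    cav2 <- rho2 <= b^2 * max(0, 1 - (z / a)^2)
    out2 <- rho2 <= (b + w_cmr)^2 * max(0, 1 - (z / (a + w_cmr))^2)
    ring <- out2 & !cav2
    perf <- ifelse(in_sector, 1 - sector[3], 1)
    wall_masks[, , s] <- matrix(ring, nc, nc)
    perf_map[, , s] <- matrix(ring * perf, nc, nc)
    for (f in seq_len(nf)) {
      img <- rep(0.05, nc * nc)
      img[ring] <- 0.10 + 0.55 * wall_curve[f] * perf[ring]
      img[cav2] <- 0.10 + 0.85 * cav_curve[f]
      frames[, , s, f] <- matrix(img, nc, nc)
    }
  }
  if (config$noise_sigma > 0)
    frames <- pmax(pmin(frames + rnorm(length(frames), 0,
                                       config$noise_sigma), 1), 0)
  frames <- minmax_norm(frames)

  mk_mask <- function(v) cf_volume(array(v, dim = c(n, n, n)), rep(sp, 3))
  structure(list(
    ctca = ct,
    lv_cavity_mask = mk_mask(cavity),
    lv_wall_mask = mk_mask(wall),
    coronary_mask = mk_mask(coronary),
    cmr_stack = cf_cmr_stack(frames, config$cmr_slice_spacing_mm, csp),
    cmr_wall_masks = wall_masks,
    perfusion_map = perf_map,
    cmr_slice_positions_mm = zs,
    true_orientation = config$long_axis_orientation,
    config = config), class = "cf_phantom")
}

#' @export
print.cf_phantom <- function(x, ...) {
  cat("<cf_phantom>\n")
  print(x$ctca)
  print(x$cmr_stack)
  cat(sprintf("  true orientation: (%.1f, %.1f, %.1f) deg\n",
              x$true_orientation[1], x$true_orientation[2],
              x$true_orientation[3]))
  invisible(x)
}

#' Apply a random rotation with known ground truth
#'
#' Rotates a volume by Euler angles drawn uniformly and independently per axis
#' from `range_deg`, returning both the rotated volume and the sampled angles.
#' This is the augmentation used to build training inputs whose inverse
#' orientation is known.
#'
#' @param volume a [cf_volume()].
#' @param range_deg length-2 interval within \[-180, 180\].
#' @param seed integer seed.
#' @param mode interpolation mode passed to [rotate_volume()].
#' @return list with `volume` (rotated) and `angles` (`cf_euler`).
#' @export
apply_random_rotation <- function(volume, range_deg = c(-180, 180), seed = 1L,
                                  mode = "trilinear") {
  if (length(range_deg) != 2L || range_deg[1] > range_deg[2] ||
      range_deg[1] < -180 || range_deg[2] > 180)
    stop("range_deg must be an interval within [-180, 180]")
  set.seed(seed)
  ang <- runif(3, range_deg[1], range_deg[2])
  angles <- euler_angles(ang[1], ang[2], ang[3])
  list(volume = rotate_volume(volume, angles, mode = mode), angles = angles)
}

#' Write a phantom sample to disk
#'
#' Writes the CT volume and masks as gzipped NIfTI, the CMR stack as 4D
#' NIfTI, and the ground-truth orientation plus config as a JSON sidecar.
#'
#' @param sample a `cf_phantom`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_phantom <- function(sample, dir) {
  stopifnot(inherits(sample, "cf_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(ctca = file.path(dir, "ctca.nii.gz"),
             lv_cavity = file.path(dir, "lv_cavity_mask.nii.gz"),
             lv_wall = file.path(dir, "lv_wall_mask.nii.gz"),
             coronary = file.path(dir, "coronary_mask.nii.gz"),
             cmr = file.path(dir, "cmr_stack.nii.gz"),
             cmr_walls = file.path(dir, "cmr_wall_masks.nii.gz"),
             perfusion = file.path(dir, "perfusion_map.nii.gz"),
             meta = file.path(dir, "phantom.json"))
  write_volume(sample$ctca, paths["ctca"])
  write_volume(sample$lv_cavity_mask, paths["lv_cavity"])
  write_volume(sample$lv_wall_mask, paths["lv_wall"])
  write_volume(sample$coronary_mask, paths["coronary"])
  st <- sample$cmr_stack
  img4 <- RNifti::asNifti(st$frames)
  RNifti::pixdim(img4) <- c(st$pixel_spacing_mm, st$pixel_spacing_mm,
                            st$slice_spacing_mm, 1)
  RNifti::writeNifti(img4, paths["cmr"])
  wr3 <- function(arr, path) {
    img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
    RNifti::pixdim(img) <- c(st$pixel_spacing_mm, st$pixel_spacing_mm,
                             st$slice_spacing_mm)
    RNifti::writeNifti(img, path)
  }
  wr3(sample$cmr_wall_masks, paths["cmr_walls"])
  wr3(sample$perfusion_map, paths["perfusion"])
  cfg <- unclass(sample$config)
  cfg$long_axis_orientation <- as.numeric(cfg$long_axis_orientation)
  jsonlite::write_json(
    list(true_orientation_deg = as.numeric(sample$true_orientation),
         cmr_slice_positions_mm = sample$cmr_slice_positions_mm,
         config = cfg),
    paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
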