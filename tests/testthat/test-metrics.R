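test_that("aspect ratio reads isotropy and ellipticity from moments", {
  expect_equal(aspect_ratio(disk_mask(41, 41, 21, 21, 15)), 1.0,
               tolerance = 0.02)
  # rasterized ellipse with semi-axes 20 and 10
  ell <- outer(((1:61 - 31) / 20)^2, ((1:61 - 31) / 10)^2, "+") <= 1
  expect_equal(aspect_ratio(ell), 0.5, tolerance = 0.03)
  expect_error(aspect_ratio(matrix(FALSE, 5, 5)), "empty")
  one_px <- matrix(FALSE, 5, 5); one_px[3, 3] <- TRUE
  expect_error(aspect_ratio(one_px), "degenerate")
})

test_that("AR of a tilted prolate ellipsoid decreases with tilt", {
  prev <- Inf
  for (th in c(0, 15, 30, 45, 60)) {
    m <- cf_volume(ellipsoid_mask(49, c(8, 8, 20)))
    tilted <- cardiofuse:::rotate_volume_matrix(
      m, cardiofuse:::rot_about_axis(1L, th), mode = "nearest")
    ar <- aspect_ratio(tilted$data[, , 25])
    expect_lt(ar, prev + 1e-6)
    prev <- ar
  }
})

test_that("dice follows its closed form and conventions", {
  a <- disk_mask(20, 20, 10, 10, 5)
  expect_equal(dice(a, a), 1.0)
  b <- disk_mask(20, 20, 3, 3, 2)
  expect_equal(dice(a, b), 0.0)
  x <- matrix(FALSE, 20, 20); x[1:10, 1:10] <- TRUE   # |A| = 100
  y <- matrix(FALSE, 20, 20); y[6:15, 1:10] <- TRUE   # |B| = 100, overlap 50
  expect_equal(dice(x, y), 0.5)
  expect_equal(dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1.0)
  expect_equal(dice(x, y), dice(y, x))
  expect_error(dice(x, y[1:10, ]), "shape")
  # nested masks: dice decreases as the overlap shrinks
  d_prev <- 1
  for (r in c(9, 7, 5, 3)) {
    d <- dice(disk_mask(31, 31, 16, 16, 10), disk_mask(31, 31, 16, 16, r))
    expect_lt(d, d_prev)
    d_prev <- d
  }
})

test_that("hausdorff matches the brute-force boundary oracle", {
  expect_equal(hausdorff(disk_mask(20, 20, 10, 10, 5),
                         disk_mask(20, 20, 10, 10, 5)), 0.0)
  p1 <- matrix(FALSE, 12, 12); p1[4, 6] <- TRUE
  p2 <- matrix(FALSE, 12, 12); p2[9, 6] <- TRUE
  expect_equal(hausdorff(p1, p2, 2), 10.0)
  set.seed(14)
  for (i in 1:3) {
    a <- matrix(runif(100) < 0.2, 10, 10)
    b <- matrix(runif(100) < 0.2, 10, 10)
    if (!any(a) || !any(b)) next
    # brute force over boundary sets (here: every set pixel of a sparse mask
    # whose 4-neighbourhood is not fully set is boundary)
    bnd <- function(m) {
      keep <- matrix(FALSE, 10, 10)
      for (x in 1:10) for (y in 1:10) if (m[x, y]) {
        nb <- c(if (x > 1) m[x - 1, y] else FALSE,
                if (x < 10) m[x + 1, y] else FALSE,
                if (y > 1) m[x, y - 1] else FALSE,
                if (y < 10) m[x, y + 1] else FALSE)
        if (!all(nb)) keep[x, y] <- TRUE
      }
      which(keep, arr.ind = TRUE)
    }
    pa <- bnd(a); pb <- bnd(b)
    dmax <- 0
    for (s in seq_len(nrow(pa))) {
      dmin <- Inf
      for (t in seq_len(nrow(pb)))
        dmin <- min(dmin, sqrt(sum((pa[s, ] - pb[t, ])^2)))
      dmax <- max(dmax, dmin)
    }
    for (t in seq_len(nrow(pb))) {
      dmin <- Inf
      for (s in seq_len(nrow(pa)))
        dmin <- min(dmin, sqrt(sum((pa[s, ] - pb[t, ])^2)))
      dmax <- max(dmax, dmin)
    }
    expect_lt(abs(hausdorff(a, b) - dmax), 1e-9)
    expect_equal(hausdorff(a, b), hausdorff(b, a))
    expect_equal(hausdorff(a, b, 3), 3 * hausdorff(a, b))
  }
  expect_error(hausdorff(p1, matrix(FALSE, 12, 12)), "empty")
})

test_that("evaluate_reorientation aggregates the per-slice suite", {
  ph <- small_phantom()
  mapping <- build_slice_mapping(ph$ctca, ph$lv_cavity_mask,
                                 ph$cmr_stack$slice_spacing_mm,
                                 ph$cmr_stack$n_slices)
  rep_ <- evaluate_reorientation(ph$lv_cavity_mask, ph$cmr_wall_masks,
                                 mapping,
                                 reoriented_wall_mask = ph$lv_wall_mask,
                                 cmr_pixel_spacing_mm =
                                   ph$cmr_stack$pixel_spacing_mm)
  expect_gte(rep_$ar, 0.95)
  expect_lte(rep_$la_dev_axial_deg, 0.5)
  expect_lte(rep_$la_dev_coronal_deg, 0.5)
  expect_equal(rep_$n_slices_used, 3L)
  expect_true(all(rep_$dsc_per_slice >= 0 & rep_$dsc_per_slice <= 1))
  expect_gte(rep_$hd_mm, 0)
  # a mis-rotated phantom scores a strictly lower aspect ratio
  R20 <- cardiofuse:::rot_about_axis(1L, 20)
  cav20 <- cardiofuse:::rotate_volume_matrix(ph$lv_cavity_mask, R20,
                                             mode = "nearest")
  wall20 <- cardiofuse:::rotate_volume_matrix(ph$lv_wall_mask, R20,
                                              mode = "nearest")
  mapping20 <- build_slice_mapping(ph$ctca, cav20,
                                   ph$cmr_stack$slice_spacing_mm, 3)
  rep20 <- evaluate_reorientation(cav20, ph$cmr_wall_masks, mapping20,
                                  reoriented_wall_mask = wall20)
  expect_lt(rep20$ar, rep_$ar)
  expect_gt(rep20$la_dev_axial_deg, 15)
  # tidy() gives the reporting row
  td <- tidy(rep_)
  expect_equal(names(td)[1:4], c("ar", "dsc", "la_dev_ang1_deg",
                                 "la_dev_ang2_deg"))
})

test_that("result objects have plotting surfaces", {
  ph <- small_phantom()
  mapping <- build_slice_mapping(ph$ctca, ph$lv_cavity_mask,
                                 ph$cmr_stack$slice_spacing_mm, 3)
  rep_ <- evaluate_reorientation(ph$lv_cavity_mask, ph$cmr_wall_masks,
                                 mapping,
                                 reoriented_wall_mask = ph$lv_wall_mask)
  expect_s3_class(autoplot(rep_), "ggplot")
  hist <- tibble::tibble(epoch = 1:3, l_sing = c(3, 2, 1),
                         l_cross = c(2, 2, 1), l_total = c(2.6, 2, 1))
  expect_s3_class(plot_training_history(hist), "ggplot")
})
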