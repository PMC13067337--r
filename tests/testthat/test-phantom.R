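test_that("identical config and seed give bit-identical phantoms", {
  cfg <- scaled_phantom_config(32, seed = 7L)
  a <- make_phantom(cfg)
  b <- make_phantom(cfg)
  expect_identical(a$ctca$data, b$ctca$data)
  expect_identical(a$cmr_stack$frames, b$cmr_stack$frames)
  expect_identical(a$lv_wall_mask$data, b$lv_wall_mask$data)
})

test_that("aligned phantom's cavity principal axis lies along RL", {
  ph <- small_phantom()
  idx <- which(ph$lv_cavity_mask$data, arr.ind = TRUE)
  X <- sweep(idx, 2, colMeans(idx))
  v <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)$vectors[, 1]
  ang <- acos(abs(v[3]) / sqrt(sum(v^2))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("phantom masks satisfy their geometric invariants", {
  ph <- small_phantom()
  expect_false(any(ph$lv_cavity_mask$data & ph$lv_wall_mask$data))
  expect_false(any(ph$lv_cavity_mask$data & ph$coronary_mask$data))
  expect_identical(as.numeric(ph$true_orientation),
                   as.numeric(ph$config$long_axis_orientation))
  # short-axis cavity cross-sections are circular by construction
  for (k in seq(18, 34, by = 4)) {
    sl <- ph$lv_cavity_mask$data[, , k]
    if (sum(sl) > 20) expect_gte(aspect_ratio(sl), 0.95)
  }
  # wall surrounds the cavity in cross-section: the one-pixel ring just
  # outside the cavity is wall everywhere
  for (k in c(20, 24, 28)) {
    sl_cav <- ph$lv_cavity_mask$data[, , k]
    if (sum(sl_cav) < 20) next
    sl_wall <- ph$lv_wall_mask$data[, , k]
    dil <- rbind(sl_cav[-1, ], FALSE) | rbind(FALSE, sl_cav[-nrow(sl_cav), ]) |
      cbind(sl_cav[, -1], FALSE) | cbind(FALSE, sl_cav[, -ncol(sl_cav)]) |
      sl_cav
    ring <- dil & !sl_cav
    expect_true(all(sl_wall[ring]))
  }
})

test_that("CMR wall area exceeds the CTCA wall area by the thickness scale", {
  ph <- small_phantom()
  mapping <- build_slice_mapping(ph$ctca, ph$lv_cavity_mask,
                                 ph$cmr_stack$slice_spacing_mm,
                                 ph$cmr_stack$n_slices)
  ratio <- vapply(seq_len(mapping$n_slices), function(s) {
    sum(ph$cmr_wall_masks[, , s]) /
      sum(ph$lv_wall_mask$data[, , mapping$indices[s]])
  }, numeric(1))
  scale <- ph$config$wall_thickness_cmr_scale
  expect_lt(abs(mean(ratio) - scale) / scale, 0.10)
})

test_that("cavity enhancement is monotone to the final frame", {
  ph <- make_phantom(scaled_phantom_config(32, seed = 3L, noise_sigma = 0))
  nf <- ph$cmr_stack$n_frames
  cav <- ph$cmr_stack$frames[, , 1, nf] > 0.7
  means <- vapply(seq_len(nf),
                  function(f) mean(ph$cmr_stack$frames[, , 1, f][cav]),
                  numeric(1))
  expect_true(all(diff(means) >= -1e-12))
  expect_equal(which.max(means), nf)
})

test_that("zero deficit gives a rotationally uniform perfusion map", {
  ph <- make_phantom(scaled_phantom_config(
    32, seed = 3L, deficit_sector = c(0, 90, 0)))
  wall <- ph$cmr_wall_masks[, , 2]
  expect_equal(sd(ph$perfusion_map[, , 2][wall]), 0)
  expect_true(all(ph$perfusion_map[, , 2][wall] == 1))
})

test_that("oversized anatomy is rejected", {
  expect_error(phantom_config(grid_size = 32, lv_long_semiaxis_mm = 30),
               "exceeds field of view")
  expect_error(phantom_config(deficit_sector = c(0, 90, 1.5)),
               "hypoperfusion")
})

test_that("apply_random_rotation is seeded, bounded and uniform", {
  v <- small_phantom()$ctca
  r0 <- apply_random_rotation(v, c(0, 0), seed = 5L)
  expect_equal(as.numeric(r0$angles), c(0, 0, 0))
  interior <- 10:39
  expect_lt(max(abs(r0$volume$data[interior, interior, interior] -
                      v$data[interior, interior, interior])), 1e-6)
  a <- apply_random_rotation(v, c(-30, 30), seed = 9L)$angles
  b <- apply_random_rotation(v, c(-30, 30), seed = 9L)$angles
  expect_identical(as.numeric(a), as.numeric(b))
  expect_error(apply_random_rotation(v, c(-200, 10)), "interval")
  # 1000 draws on a tiny volume: per-axis mean within 3 SE of 0
  tiny <- cf_volume(array(runif(8^3), c(8, 8, 8)))
  draws <- t(vapply(1:1000, function(s)
    as.numeric(apply_random_rotation(tiny, c(-180, 180), seed = s)$angles),
    numeric(3)))
  se <- 360 / sqrt(12) / sqrt(1000)
  expect_true(all(abs(colMeans(draws)) < 3 * se))
})

test_that("phantom writes NIfTI volumes plus a JSON sidecar", {
  ph <- make_phantom(scaled_phantom_config(24, seed = 2L))
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir)
  expect_true(all(file.exists(paths)))
  back <- read_volume(paths[["ctca"]])
  expect_equal(back$data, ph$ctca$data, tolerance = 1e-6)
  expect_equal(back$spacing, ph$ctca$spacing)
  meta <- jsonlite::read_json(paths[["meta"]], simplifyVector = TRUE)
  expect_equal(meta$true_orientation_deg,
               as.numeric(ph$true_orientation))
})
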