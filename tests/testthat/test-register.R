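test_that("contrast-frame selection keeps the last k frames", {
  ph <- make_phantom(scaled_phantom_config(24, seed = 2L))
  st <- ph$cmr_stack
  expect_equal(st$n_frames, 90L)
  k10 <- select_contrast_frames(st, 10)
  expect_equal(k10$n_frames, 10L)
  expect_identical(k10$frames[, , , 1], st$frames[, , , 81])
  expect_identical(k10$frames[, , , 10], st$frames[, , , 90])
  all_ <- select_contrast_frames(st, st$n_frames)
  expect_identical(all_$frames, st$frames)
  expect_error(select_contrast_frames(st, 0), "between 1 and")
  expect_error(select_contrast_frames(st, 91), "between 1 and")
})

test_that("rigid motion correction recovers known integer shifts", {
  set.seed(12)
  base <- matrix(0, 48, 48)
  base[disk_mask(48, 48, 24, 25, 10)] <- 1
  base <- base + matrix(rnorm(48 * 48, 0, 0.02), 48, 48)
  shifts <- rbind(c(3, -2), c(-3, 1), c(2, 3), c(0, 0))
  frames <- array(0, c(48, 48, 1, 4))
  for (f in 1:4)
    frames[, , 1, f] <- warp_2d(base, cardiofuse:::rigid_field_2d(
      c(48, 48), 0, -shifts[f, ]))
  mc <- rigid_motion_correct(cf_cmr_stack(frames, 8, 1))
  expect_equal(mc$transforms$du, shifts[, 1], tolerance = 0.5)
  expect_equal(mc$transforms$dv, shifts[, 2], tolerance = 0.5)
  # reference (last) frame gets the identity
  expect_equal(unlist(mc$transforms[4, 3:5]), c(rotation_deg = 0, du = 0,
                                                dv = 0))
  # an already-aligned stack stays put
  aligned <- array(rep(base, 3), c(48, 48, 1, 3))
  mca <- rigid_motion_correct(cf_cmr_stack(aligned, 8, 1))
  expect_true(all(abs(mca$transforms$du) <= 0.2))
  expect_true(all(abs(mca$transforms$dv) <= 0.2))
  expect_true(all(abs(mca$transforms$rotation_deg) <= 0.2))
  # constant frames: identity with a warning per degenerate frame
  ws <- capture_warnings(
    mcc <- rigid_motion_correct(cf_cmr_stack(array(1, c(16, 16, 1, 3)),
                                             8, 1)))
  expect_match(ws, "constant", all = TRUE)
  expect_gte(length(ws), 1L)
  expect_true(all(mcc$transforms$du == 0))
})

test_that("Hough transform finds the dominant circle", {
  img <- matrix(0, 80, 60)
  img[disk_mask(80, 60, 40, 30, 12)] <- 1
  r <- detect_lv_center(img, c(6, 20))
  expect_lte(max(abs(r$center - c(40, 30))), 1)
  expect_lte(abs(r$radius - 12), 1)
  # stronger circle wins over a smaller one
  img2 <- img
  img2[disk_mask(80, 60, 15, 45, 6)] <- 0.4
  r2 <- detect_lv_center(img2, c(4, 20))
  expect_lte(max(abs(r2$center - c(40, 30))), 1)
  expect_error(detect_lv_center(matrix(0.5, 50, 50), c(5, 15)),
               "no circular structure")
  expect_error(detect_lv_center(img, c(1, 100)), "radius range")
})

test_that("crop_to_fov pads, centres and inverts losslessly", {
  img <- matrix(runif(50 * 40), 50, 40)
  cr <- crop_to_fov(img, c(25, 20), c(105, 75))
  expect_equal(dim(cr), c(105L, 75L))
  same <- crop_to_fov(img, c(25.4, 20.2), dim(img))
  expect_equal(same[, ], img, ignore_attr = TRUE)
  tl <- crop_to_fov(img, c(1, 1), c(20, 20))
  expect_true(all(tl[1:9, ] == 0) && all(tl[, 1:9] == 0))
  expect_equal(tl[10:20, 10:20], img[1:11, 1:11])
  # paste-back is lossless inside the window
  cr2 <- crop_to_fov(img, c(10, 35), c(16, 16))
  back <- cardiofuse:::uncrop(cr2, dim(img))
  inside <- back > 0
  expect_equal(back[inside], img[inside])
  expect_error(crop_to_fov(img, c(5, 5), c(0, 10)), "positive")
})

test_that("classical nonrigid registration harmonizes ring thickness", {
  mov <- ring_mask(64, 32.5, 32.5, 17, 25)  # thickness 8
  fix <- ring_mask(64, 32.5, 32.5, 15, 21)  # thickness 6
  expect_lte(dice(mov, fix), 0.8)
  f <- classical_nonrigid_register(mov, fix, levels = 6)
  expect_gte(dice(warp_2d(mov * 1, f) > 0.5, fix), 0.90)
  expect_gte(mean(field_jacobian(f) >= 0), 0.99)
  # six levels do at least as well as one
  f1 <- classical_nonrigid_register(mov, fix, levels = 1)
  expect_gte(dice(warp_2d(mov * 1, f) > 0.5, fix) + 1e-9,
             dice(warp_2d(mov * 1, f1) > 0.5, fix))
  # moving == fixed: identity field
  fid <- classical_nonrigid_register(fix, fix)
  expect_lte(max(abs(fid)), 0.5)
  expect_equal(dice(warp_2d(fix * 1, fid) > 0.5, fix), 1)
  expect_error(classical_nonrigid_register(mov, matrix(FALSE, 64, 64)),
               "empty mask")
  expect_error(classical_nonrigid_register(mov, fix[1:32, ]), "shape")
})

test_that("registration never decreases wall-mask Dice", {
  set.seed(33)
  for (i in 1:3) {
    c1 <- 32.5 + runif(2, -3, 3)
    mov <- ring_mask(64, c1[1], c1[2], 13 + i, 20 + i)
    fix <- ring_mask(64, 32.5, 32.5, 15, 21)
    f <- classical_nonrigid_register(mov, fix)
    expect_gte(dice(warp_2d(mov * 1, f) > 0.5, fix), dice(mov, fix))
  }
})

test_that("pseudo-label CMR warps the intensity slice by the mask field", {
  ph <- small_phantom()
  mov <- ring_mask(64, 33.5, 31.5, 14, 21)
  fix <- ring_mask(64, 32.5, 32.5, 15, 21)
  slice <- matrix(runif(64 * 64), 64, 64)
  pl <- make_pseudo_label_cmr(slice, mov, fix)
  expect_equal(pl$image, warp_2d(slice, pl$field))
  expect_gte(dice(warp_2d(mov * 1, pl$field) > 0.5, fix), 0.9)
  # identical wall masks: pseudo-label equals the input
  pl2 <- make_pseudo_label_cmr(slice, fix, fix)
  expect_lt(max(abs(pl2$image - slice)), 0.05)
  expect_error(make_pseudo_label_cmr(slice, mov, matrix(FALSE, 64, 64)),
               "empty mask")
})

test_that("deformation network gradients match numerical differentiation", {
  set.seed(1)
  cfg <- sdn_config(base_width = 4L, seed = 5L)
  m <- init_sdn(cfg)
  m$params$out_w <- array(rnorm(length(m$params$out_w), 0, 0.05),
                          dim(m$params$out_w))
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  cmr <- matrix(runif(256), 16, 16)
  pseudo <- matrix(runif(256), 16, 16)
  loss_of <- function(model) {
    fw <- cardiofuse:::sdn_forward(model, x)
    mean((warp_2d(cmr, fw$field) - pseudo)^2) +
      cfg$smoothness_weight * cardiofuse:::field_smoothness(fw$field)
  }
  fw <- cardiofuse:::sdn_forward(m, x)
  resid <- warp_2d(cmr, fw$field) - pseudo
  gfield <- array(cardiofuse:::.cpp_warp2d_bwd(
    as.numeric(cmr), dim(cmr), as.numeric(fw$field),
    as.numeric(2 * resid / length(resid))), c(16, 16, 2)) +
    cfg$smoothness_weight * cardiofuse:::field_smoothness_grad(fw$field)
  gr <- cardiofuse:::sdn_backward(m, fw$cache, gfield)
  for (pn in c("enc1_w", "enc2_w", "bott_w", "dec2_w", "dec1_w", "out_w")) {
    i <- 2L; eps <- 1e-6
    m2 <- m; m2$params[[pn]][i] <- m2$params[[pn]][i] + eps
    lp <- loss_of(m2)
    m2$params[[pn]][i] <- m2$params[[pn]][i] - 2 * eps
    lm <- loss_of(m2)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(gr[[pn]][i] - num), 1e-6 * max(1, abs(num)))
  }
})

test_that("SDN training is seeded and inference deterministic", {
  set.seed(77)
  mk <- function() {
    ct <- matrix(runif(32 * 32), 32, 32)
    list(ctca = ct, cmr = ct * 0.8, pseudo = ct * 0.9)
  }
  ds <- lapply(1:4, function(i) mk())
  cfg <- sdn_config(base_width = 4L, epochs = 2L, seed = 9L)
  a <- train_sdn(ds, cfg)
  b <- train_sdn(ds, cfg)
  expect_identical(a$history, b$history)
  cfg0 <- sdn_config(base_width = 4L, epochs = 0L, seed = 9L)
  tr0 <- train_sdn(ds, cfg0)
  expect_identical(tr0$model$params, init_sdn(cfg0)$params)
  r1 <- register_cmr(a$model, ds[[1]]$ctca, ds[[1]]$cmr)
  r2 <- register_cmr(a$model, ds[[1]]$ctca, ds[[1]]$cmr)
  expect_identical(r1$image, r2$image)
  expect_error(register_cmr(a$model, ds[[1]]$ctca, matrix(0, 16, 16)),
               "shape mismatch")
  expect_error(register_cmr(list(), ds[[1]]$ctca, ds[[1]]$cmr),
               "uninitialized")
  expect_error(train_sdn(list(), cfg), "empty")
})
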