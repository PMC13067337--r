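test_that("single- and cross-modal losses match scalar-loop oracles", {
  set.seed(8)
  p <- array(runif(8^3), c(8, 8, 8))
  t_ <- array(runif(8^3), c(8, 8, 8))
  expect_equal(single_modal_loss(p, p), 0)
  expect_equal(single_modal_loss(p, p + 1), 1)
  loop <- 0
  for (i in seq_along(p)) loop <- loop + (p[i] - t_[i])^2
  expect_lt(abs(single_modal_loss(p, t_) - loop / length(p)), 1e-12)
  expect_error(single_modal_loss(p, t_[1:4, , ]), "shape")

  a <- lapply(1:3, function(i) matrix(runif(64), 8, 8))
  b <- lapply(1:3, function(i) matrix(runif(64), 8, 8))
  expect_equal(cross_modal_loss(a, a), 0)
  one <- list(matrix(0.5, 8, 8))
  expect_equal(cross_modal_loss(one, list(matrix(0, 8, 8))), 0.25)
  loop <- 0; np <- 0
  for (i in 1:3) for (j in seq_along(a[[i]])) {
    loop <- loop + (a[[i]][j] - b[[i]][j])^2; np <- np + 1
  }
  expect_lt(abs(cross_modal_loss(a, b) - loop / np), 1e-12)
  expect_error(cross_modal_loss(a, b[1:2]), "equal length")
})

test_that("negated mutual information behaves like an information measure", {
  set.seed(9)
  x <- matrix(runif(64 * 64), 64, 64)
  # self-pairing: MI(X;X) = H(X) of the binned image
  nb <- 16L
  bins <- pmin(floor(x * nb) + 1L, nb)
  pr <- tabulate(bins, nb) / length(bins)
  h <- -sum(pr[pr > 0] * log(pr[pr > 0]))
  expect_lt(abs(cross_modal_loss_mi(list(x), list(x), nb) - (-h)), 1e-9)
  # independent noise: MI near zero
  y <- matrix(runif(64 * 64), 64, 64)
  expect_gte(cross_modal_loss_mi(list(x), list(y), nb), -0.1)
  # a bin-permuting monotone remap leaves MI unchanged
  z <- matrix(runif(64 * 64), 64, 64)
  mi1 <- cross_modal_loss_mi(list(x), list(z), nb)
  mi2 <- cross_modal_loss_mi(list(x), list(1 - z), nb)
  expect_lt(abs(mi1 - mi2) / max(abs(mi1), 1e-9), 0.05)
  expect_error(cross_modal_loss_mi(list(x), list(x), 1L), "n_bins")
})

test_that("total loss is the exact weighted sum", {
  expect_equal(total_loss(1, 1, loss_weights(0.6, 0.4)), 1.0)
  expect_equal(total_loss(3.3, 99, loss_weights(1, 0)), 3.3)
  expect_equal(total_loss(2.0, 0.5, loss_weights(0.6, 0.4)), 1.4)
  expect_error(loss_weights(-0.1, 0.4), "non-negative")
  # exact linearity
  set.seed(10)
  for (i in 1:20) {
    ls <- runif(1, 0, 5); lc <- runif(1, 0, 5); k <- runif(1, 0, 3)
    w <- loss_weights(0.6, 0.4)
    expect_equal(total_loss(k * ls, k * lc, w), k * total_loss(ls, lc, w))
  }
})

test_that("slice mapping follows the anchor and step rules", {
  ph <- small_phantom()
  mp <- build_slice_mapping(ph$ctca, ph$lv_cavity_mask, 8, 2)
  expect_equal(mp$step_voxels, 8L)
  expect_equal(mp$indices, mp$anchor_index + c(0L, 8L))
  # anchor: basal-most slice at >= 50% of the max cross-section area
  areas <- apply(ph$lv_cavity_mask$data, 3, sum)
  expect_equal(mp$anchor_index, which(areas >= 0.5 * max(areas))[1])
  mp1 <- build_slice_mapping(ph$ctca, ph$lv_cavity_mask, 8, 1)
  expect_equal(length(mp1$indices), 1L)
  expect_error(build_slice_mapping(ph$ctca, ph$lv_cavity_mask, 8, 50),
               "exceeds volume")
  expect_error(build_slice_mapping(ph$ctca,
                                   cf_volume(array(FALSE, dim(ph$ctca))),
                                   8, 3), "LV not found")
})

test_that("angle prediction is deterministic and bounded", {
  cfg <- reorient_model_config(width = 4L, input_size = 24L, seed = 1L)
  m <- init_reorient_model(cfg)
  v <- cf_volume(array(runif(24^3), c(24, 24, 24)))
  a1 <- predict_angles(m, v)
  a2 <- predict_angles(m, v)
  expect_identical(as.numeric(a1), as.numeric(a2))
  expect_true(all(is.finite(a1)) && all(abs(a1) <= 180))
  expect_error(predict_angles(list(), v), "uninitialized")
  expect_error(predict_angles(m, cf_volume(array(0, c(16, 16, 16)))),
               "input size")
})

test_that("encoder backward pass matches numerical gradients", {
  set.seed(42)
  cfg <- reorient_model_config(width = 4L, input_size = 16L, seed = 3L)
  m <- init_reorient_model(cfg)
  vol <- array(runif(16^3), c(16, 16, 16))
  fw <- cardiofuse:::reorient_forward(m, vol)
  gang <- c(0.3, -0.2, 0.5)
  gr <- cardiofuse:::reorient_backward(m, fw$cache, gang)
  for (pn in c("conv1_w", "res1a_w", "res1b_w", "conv2_w", "res2a_w",
               "res2b_w", "fc_w", "fc_b")) {
    i <- min(2L, length(m$params[[pn]]))
    eps <- 1e-6
    m2 <- m; m2$params[[pn]][i] <- m2$params[[pn]][i] + eps
    fp <- cardiofuse:::reorient_forward(m2, vol)$angles
    m2$params[[pn]][i] <- m2$params[[pn]][i] - 2 * eps
    fm <- cardiofuse:::reorient_forward(m2, vol)$angles
    num <- sum(gang * (fp - fm)) / (2 * eps)
    expect_lt(abs(gr[[pn]][i] - num), 1e-6 * max(1, abs(num)))
  }
})

test_that("training is seeded-reproducible and epoch 0 returns the init", {
  ds <- build_reorient_dataset(3, grid_size = 24L, seed = 21L)
  cfg0 <- reorient_model_config(width = 4L, input_size = 24L, epochs = 0L,
                                seed = 5L)
  tr0 <- train_reorientation(ds, cfg0)
  expect_equal(nrow(tr0$history), 0L)
  expect_identical(tr0$model$params, init_reorient_model(cfg0)$params)
  cfg1 <- reorient_model_config(width = 4L, input_size = 24L, epochs = 1L,
                                seed = 5L)
  a <- train_reorientation(ds, cfg1)
  b <- train_reorientation(ds, cfg1)
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
  expect_error(train_reorientation(list(), cfg1), "empty dataset")
})

test_that("fine-tuning at a fixed point leaves parameters almost unchanged", {
  ds <- build_reorient_dataset(2, grid_size = 24L, seed = 31L)
  cfg <- reorient_model_config(width = 4L, input_size = 24L, epochs = 1L,
                               seed = 2L, learning_rate = 1e-6)
  m <- init_reorient_model(cfg)
  # pseudo-label = the model's own current output
  pl <- lapply(ds, function(s) {
    ang <- predict_angles(m, s$ct)
    list(ct = s$ct, pseudo_label = rotate_volume(s$ct, ang))
  })
  mft <- fine_tune(m, pl, cfg)
  delta <- max(vapply(names(m$params), function(nm)
    max(abs(mft$params[[nm]] - m$params[[nm]])), numeric(1)))
  expect_lt(delta, 1e-4)
  expect_lt(attr(mft, "history")$l_sing[1], 1e-8)
  expect_error(fine_tune(m, list(), cfg), "empty")
})
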