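#' Loss weights for self-supervised reorientation training
#'
#' The total training loss is `mu1 * L_sing + mu2 * L_cross`, balancing
#' alignment against the fixed short-axis template (single-modal) and against
#' the subject's own CMR slices (cross-modal). Defaults 0.6 / 0.4.
#'
#' @param mu1 single-modal weight (>= 0).
#' @param mu2 cross-modal weight (>= 0).
#' @return A `cf_loss_weights` list.
#' @export
loss_weights <- function(mu1 = 0.6, mu2 = 0.4) {
  if (mu1 < 0 || mu2 < 0) stop("loss weights must be non-negative")
  structure(list(mu1 = mu1, mu2 = mu2), class = "cf_loss_weights")
}

loss_data <- function(x) {
  if (is_volume(x)) x$data else x
}

#' Single-modal loss: MSE to the short-axis template
#'
#' Mean over all voxels of squared differences between the reoriented volume
#' and the fixed manually reoriented template.
#'
#' @param reoriented,template same-shaped volumes or arrays.
#' @return Non-negative scalar.
#' @export
single_modal_loss <- function(reoriented, template) {
  p <- loss_data(reoriented); t_ <- loss_data(template)
  if (!identical(dim(p), dim(t_))) stop("shape mismatch in single_modal_loss")
  mean((p - t_)^2)
}

#' Cross-modal loss: MSE between mapped CTCA slices and CMR slices
#'
#' Mean over all pixels of all slice pairs of squared differences. The CMR
#' slices must already be resampled onto the CTCA in-plane grid so the
#' comparison is pixelwise.
#'
#' @param ctca_slices,cmr_slices equal-length lists of equal-shaped matrices.
#' @return Non-negative scalar.
#' @export
cross_modal_loss <- function(ctca_slices, cmr_slices) {
  if (length(ctca_slices) != length(cmr_slices) || !length(ctca_slices))
    stop("slice lists must be non-empty and of equal length")
  num <- 0; den <- 0
  for (i in seq_along(ctca_slices)) {
    p <- ctca_slices[[i]]; r <- cmr_slices[[i]]
    if (!identical(dim(p), dim(r))) stop("slice shape mismatch")
    num <- num + sum((p - r)^2)
    den <- den + length(p)
  }
  num / den
}

#' Negated mutual information cross-modal loss
#'
#' An optional similarity variant: mutual information of the joint intensity
#' histogram of the paired slices (values clipped to \[0, 1\], equal-width
#' bins, natural log), negated so that lower is better like the MSE loss.
#'
#' @inheritParams cross_modal_loss
#' @param n_bins number of histogram bins (>= 2).
#' @return `-MI` in nats.
#' @export
cross_modal_loss_mi <- function(ctca_slices, cmr_slices, n_bins = 16L) {
  if (length(ctca_slices) != length(cmr_slices) || !length(ctca_slices))
    stop("slice lists must be non-empty and of equal length")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  xs <- ys <- numeric(0)
  for (i in seq_along(ctca_slices)) {
    p <- ctca_slices[[i]]; r <- cmr_slices[[i]]
    if (!identical(dim(p), dim(r))) stop("slice shape mismatch")
    xs <- c(xs, as.numeric(p)); ys <- c(ys, as.numeric(r))
  }
  bx <- pmin(pmax(floor(pmin(pmax(xs, 0), 1) * n_bins) + 1L, 1L), n_bins)
  by <- pmin(pmax(floor(pmin(pmax(ys, 0), 1) * n_bins) + 1L, 1L), n_bins)
  joint <- table(factor(bx, levels = seq_len(n_bins)),
                 factor(by, levels = seq_len(n_bins)))
  pxy <- joint / sum(joint)
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / (outer(px, py)[nz])))
  -mi
}

#' Weighted total loss
#'
#' `mu1 * l_sing + mu2 * l_cross`, exactly linear in its two loss arguments.
#'
#' @param l_sing,l_cross non-negative scalars.
#' @param weights a [loss_weights()].
#' @return Scalar.
#' @export
total_loss <- function(l_sing, l_cross, weights = loss_weights()) {
  stopifnot(inherits(weights, "cf_loss_weights"))
  weights$mu1 * l_sing + weights$mu2 * l_cross
}

#' Map CMR slices onto sagittal slices of a reoriented CTCA volume
#'
#' The anchor is the basal-most sagittal slice (lowest sagittal index) whose
#' LV cross-section area reaches at least half of the maximal cross-section
#' area; subsequent slices advance apically by
#' `round(cmr_slice_spacing_mm / sagittal voxel size)` voxels.
#'
#' @param volume reoriented CTCA [cf_volume()] (used for spacing/bounds).
#' @param lv_mask LV mask [cf_volume()] in the same grid.
#' @param cmr_slice_spacing_mm CMR inter-slice distance.
#' @param n_slices number of CMR slices to map (>= 1).
#' @return A `cf_slice_mapping` with `anchor_index`, `step_voxels`, `indices`.
#' @export
build_slice_mapping <- function(volume, lv_mask, cmr_slice_spacing_mm,
                                n_slices) {
  volume <- as_volume(volume)
  m <- loss_data(lv_mask) > 0.5
  if (!any(m)) stop("LV not found")
  if (n_slices < 1L) stop("n_slices must be >= 1")
  areas <- apply(m, 3L, sum)
  anchor <- which(areas >= 0.5 * max(areas))[1]
  step <- max(1L, as.integer(round(cmr_slice_spacing_mm / volume$spacing[3])))
  idx <- anchor + (seq_len(n_slices) - 1L) * step
  if (any(idx > dim(volume$data)[3])) stop("mapping exceeds volume")
  structure(list(anchor_index = as.integer(anchor), step_voxels = step,
                 indices = as.integer(idx), n_slices = as.integer(n_slices)),
            class = "cf_slice_mapping")
}

#' Reorientation model configuration
#'
#' A compact residual 3D convolutional encoder (a reduced-width 3D adaptation
#' of a ResNet-style backbone, sized for phantom volumes) regresses the three
#' Euler angles; a scaled tanh head bounds them to \[-180, 180\] degrees.
#' The gradient of the image loss with respect to the three angles is taken
#' by one-sided finite differences through the resampler (three extra loss
#' evaluations per step); all other gradients are analytic.
#'
#' @param width base channel width of the encoder.
#' @param input_size cube edge of the input volume in voxels (>= 16,
#'   divisible by 8).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs training epochs.
#' @param batch_size samples per optimizer step.
#' @param seed RNG seed covering initialization, data order and augmentation.
#' @param fd_step_deg finite-difference step for the angle gradient, degrees.
#' @param augment re-sample an extra random rotation of each input every
#'   epoch (self-supervised augmentation).
#' @param augment_deg per-axis range of the augmentation rotation.
#' @param euler_convention passed to [euler_to_matrix()].
#' @return A `cf_reorient_config` list.
#' @export
reorient_model_config <- function(width = 8L, input_size = 48L,
                                  learning_rate = 1e-4, epochs = 20L,
                                  batch_size = 1L, seed = 0L,
                                  fd_step_deg = 1.0, augment = FALSE,
                                  augment_deg = 10,
                                  euler_convention = "as_printed_yxz") {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (input_size < 16L) stop("input cube size must be >= 16")
  if (input_size %% 8L != 0L) stop("input_size must be divisible by 8")
  structure(list(width = as.integer(width), input_size = as.integer(input_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 fd_step_deg = fd_step_deg, augment = augment,
                 augment_deg = augment_deg,
                 euler_convention = euler_convention),
            class = "cf_reorient_config")
}

#' Initialize a reorientation model
#'
#' @param config a [reorient_model_config()].
#' @return A `cf_reorient_model` with randomly initialized weights.
#' @export
init_reorient_model <- function(config = reorient_model_config()) {
  stopifnot(inherits(config, "cf_reorient_config"))
  set.seed(config$seed)
  W <- config$width
  params <- list(
    conv1_w = he_init(c(3, 3, 3, 1, W), 27),
    conv1_b = numeric(W),
    res1a_w = he_init(c(3, 3, 3, W, W), 27 * W),
    res1a_b = numeric(W),
    res1b_w = he_init(c(3, 3, 3, W, W), 27 * W),
    res1b_b = numeric(W),
    conv2_w = he_init(c(3, 3, 3, W, 2 * W), 27 * W),
    conv2_b = numeric(2 * W),
    res2a_w = he_init(c(3, 3, 3, 2 * W, 2 * W), 27 * 2 * W),
    res2a_b = numeric(2 * W),
    res2b_w = he_init(c(3, 3, 3, 2 * W, 2 * W), 27 * 2 * W),
    res2b_b = numeric(2 * W),
    fc_w = matrix(rnorm(3 * 2 * W, 0, 0.01), 3, 2 * W),
    fc_b = numeric(3))
  structure(list(params = params, config = config,
                 version = as.character(packageVersion("cardiofuse"))),
            class = "cf_reorient_model")
}

# Forward pass of the encoder; returns predicted angles (degrees, bounded by
# the scaled tanh head) and the cache needed for the backward pass.
reorient_forward <- function(model, vol_arr) {
  p <- model$params
  x0 <- array(vol_arr, c(dim(vol_arr), 1L))
  z1 <- conv3d(x0, p$conv1_w, p$conv1_b, stride = 2L)
  a1 <- relu(z1)
  p1 <- avgpool2_3d(a1)
  z2 <- conv3d(p1, p$res1a_w, p$res1a_b)
  a2 <- relu(z2)
  z3 <- conv3d(a2, p$res1b_w, p$res1b_b)
  r1 <- relu(z3 + p1)
  z4 <- conv3d(r1, p$conv2_w, p$conv2_b, stride = 2L)
  a4 <- relu(z4)
  z5 <- conv3d(a4, p$res2a_w, p$res2a_b)
  a5 <- relu(z5)
  z6 <- conv3d(a5, p$res2b_w, p$res2b_b)
  r2 <- relu(z6 + a4)
  g <- colMeans(matrix(r2, prod(dim(r2)[1:3]), dim(r2)[4]))
  z <- as.numeric(p$fc_w %*% g + p$fc_b)
  angles <- 180 * tanh(z)
  list(angles = angles,
       cache = list(x0 = x0, a1 = a1, p1 = p1, a2 = a2, r1 = r1, a4 = a4,
                    a5 = a5, r2 = r2, g = g, z = z))
}

# Backward pass: gradient of the scalar loss w.r.t. all encoder parameters,
# given dL/d(angles).
reorient_backward <- function(model, cache, gangles) {
  p <- model$params
  gz <- gangles * 180 * (1 - tanh(cache$z)^2)
  gfc_w <- outer(gz, cache$g)
  gfc_b <- gz
  gg <- as.numeric(t(p$fc_w) %*% gz)
  d2 <- dim(cache$r2)
  nvox <- prod(d2[1:3])
  gr2 <- array(rep(gg / nvox, each = nvox), d2)
  gpre2 <- gr2 * (cache$r2 > 0)
  b6 <- conv3d_bwd(cache$a5, p$res2b_w, gpre2)
  ga5 <- b6$gx * (cache$a5 > 0)
  b5 <- conv3d_bwd(cache$a4, p$res2a_w, ga5)
  ga4 <- (b5$gx + gpre2) * (cache$a4 > 0)
  b4 <- conv3d_bwd(cache$r1, p$conv2_w, ga4, stride = 2L)
  gpre1 <- b4$gx * (cache$r1 > 0)
  b3 <- conv3d_bwd(cache$a2, p$res1b_w, gpre1)
  ga2 <- b3$gx * (cache$a2 > 0)
  b2 <- conv3d_bwd(cache$p1, p$res1a_w, ga2)
  gp1 <- b2$gx + gpre1
  ga1 <- avgpool2_3d_bwd(gp1, dim(cache$a1)) * (cache$a1 > 0)
  b1 <- conv3d_bwd(cache$x0, p$conv1_w, ga1, stride = 2L)
  list(conv1_w = b1$gw, conv1_b = b1$gb,
       res1a_w = b2$gw, res1a_b = b2$gb,
       res1b_w = b3$gw, res1b_b = b3$gb,
       conv2_w = b4$gw, conv2_b = b4$gb,
       res2a_w = b5$gw, res2a_b = b5$gb,
       res2b_w = b6$gw, res2b_b = b6$gb,
       fc_w = gfc_w, fc_b = gfc_b)
}

#' Predict reorientation angles for a volume
#'
#' Deterministic forward pass of a (trained) reorientation model in
#' evaluation mode.
#'
#' @param model a `cf_reorient_model`.
#' @param volume a [cf_volume()] matching the model input size.
#' @return A `cf_euler` of predicted angles, bounded to \[-180, 180\].
#' @export
predict_angles <- function(model, volume) {
  if (!inherits(model, "cf_reorient_model")) stop("uninitialized model")
  volume <- as_volume(volume)
  d <- dim(volume$data)
  if (!all(d == model$config$input_size))
    stop("volume shape (", paste(d, collapse = "x"),
         ") does not match model input size ", model$config$input_size)
  fw <- reorient_forward(model, volume$data)
  euler_angles(fw$angles[1], fw$angles[2], fw$angles[3])
}

# Per-sample training loss at the given angles, holding the slice mapping
# fixed. sample: list(ct, template, cmr_slices, cmr_slice_spacing_mm).
reorient_sample_loss <- function(sample, angles, mapping, weights,
                                 convention) {
  vol_r <- rotate_volume(sample$ct, angles, convention = convention)
  ls <- single_modal_loss(vol_r, sample$template)
  lc <- 0
  if (!is.null(mapping) && length(sample$cmr_slices)) {
    ctca_slices <- lapply(mapping$indices,
                          function(k) vol_r$data[, , k])
    lc <- cross_modal_loss(ctca_slices, sample$cmr_slices)
  }
  list(l_sing = ls, l_cross = lc, l_total = total_loss(ls, lc, weights))
}

# Slice mapping for the current prediction: the input's LV mask reoriented by
# the predicted angles (nearest-neighbour); NULL if the LV cannot be mapped.
reorient_sample_mapping <- function(sample, angles, convention) {
  if (is.null(sample$lv_mask) || !length(sample$cmr_slices)) return(NULL)
  mask_r <- rotate_volume(sample$lv_mask, angles, mode = "nearest",
                          convention = convention)
  tryCatch(build_slice_mapping(mask_r, mask_r, sample$cmr_slice_spacing_mm,
                               length(sample$cmr_slices)),
           error = function(e) NULL)
}

# One training step on one sample; returns gradients and the central losses.
reorient_sample_grad <- function(model, sample, weights, config) {
  fw <- reorient_forward(model, sample$ct$data)
  ang <- fw$angles
  mapping <- reorient_sample_mapping(sample, ang, config$euler_convention)
  central <- reorient_sample_loss(sample, ang, mapping, weights,
                                  config$euler_convention)
  h <- config$fd_step_deg
  gang <- numeric(3)
  for (i in 1:3) {
    ap <- ang; ap[i] <- ap[i] + h
    lp <- reorient_sample_loss(sample, ap, mapping, weights,
                               config$euler_convention)$l_total
    gang[i] <- (lp - central$l_total) / h
  }
  grads <- reorient_backward(model, fw$cache, gang)
  list(grads = grads, losses = central)
}

#' Train the reorientation model (self-supervised)
#'
#' Each dataset sample pairs a rotated CTCA volume with the fixed short-axis
#' template and the subject's CMR slices (already on the CTCA in-plane grid).
#' The loss is `mu1 * L_sing + mu2 * L_cross`; optimization uses Adam. All
#' stochasticity (initialization, data order, augmentation) derives from the
#' config seed, so identical seeds and data give identical results.
#'
#' @param dataset list of samples; each a list with `ct` ([cf_volume()]),
#'   `template` ([cf_volume()]), optionally `lv_mask` ([cf_volume()]),
#'   `cmr_slices` (list of matrices) and `cmr_slice_spacing_mm`.
#' @param config a [reorient_model_config()].
#' @param weights a [loss_weights()].
#' @return list with `model` and `history` (tibble: epoch, l_sing, l_cross,
#'   l_total).
#' @export
train_reorientation <- function(dataset, config = reorient_model_config(),
                                weights = loss_weights()) {
  if (!length(dataset)) stop("empty dataset")
  shp <- dim(dataset[[1]]$ct$data)
  for (s in dataset)
    if (!all(dim(s$ct$data) == shp)) stop("all volumes must share one shape")
  model <- init_reorient_model(config)
  opt <- adam_state(model$params)
  hist <- vector("list", config$epochs)
  if (config$epochs > 0L) {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(dataset))
      ls_ep <- lc_ep <- lt_ep <- numeric(length(dataset))
      acc <- NULL; acc_n <- 0L
      for (t in seq_along(ord)) {
        s <- dataset[[ord[t]]]
        if (isTRUE(config$augment)) {
          aug <- runif(3, -config$augment_deg, config$augment_deg)
          s$ct <- rotate_volume(s$ct, aug,
                                convention = config$euler_convention)
          if (!is.null(s$lv_mask))
            s$lv_mask <- rotate_volume(s$lv_mask, aug, mode = "nearest",
                                       convention = config$euler_convention)
        }
        r <- reorient_sample_grad(model, s, weights, config)
        if (!is.finite(r$losses$l_total))
          stop("NaN loss at epoch ", ep, ", sample ", ord[t],
               "; aborting training")
        ls_ep[t] <- r$losses$l_sing
        lc_ep[t] <- r$losses$l_cross
        lt_ep[t] <- r$losses$l_total
        acc <- if (is.null(acc)) r$grads
               else mapply(`+`, acc, r$grads, SIMPLIFY = FALSE)
        acc_n <- acc_n + 1L
        if (acc_n == config$batch_size || t == length(ord)) {
          acc <- lapply(acc, function(g) g / acc_n)
          upd <- adam_step(model$params, acc, opt, config$learning_rate)
          model$params <- upd$params
          opt <- upd$state
          acc <- NULL; acc_n <- 0L
        }
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, l_sing = mean(ls_ep),
                                   l_cross = mean(lc_ep),
                                   l_total = mean(lt_ep))
    }
  }
  history <- if (config$epochs > 0L) do.call(rbind, hist)
             else tibble::tibble(epoch = integer(), l_sing = numeric(),
                                 l_cross = numeric(), l_total = numeric())
  list(model = model, history = history)
}

#' Fine-tune a reorientation model on pseudo-labels
#'
#' Continues training with the single-modal loss only, computed against each
#' sample's own pseudo-label CTCA (the anatomically refined reorientation)
#' instead of the global template.
#'
#' @param model a trained `cf_reorient_model`.
#' @param dataset list of samples, each a list with `ct` and `pseudo_label`
#'   ([cf_volume()], same shape).
#' @param config a [reorient_model_config()] (epochs/learning rate for the
#'   fine-tuning phase).
#' @return The fine-tuned model, with the per-epoch history in
#'   `attr(, "history")`.
#' @export
fine_tune <- function(model, dataset, config = model$config) {
  if (!inherits(model, "cf_reorient_model")) stop("uninitialized model")
  if (!length(dataset)) stop("empty dataset")
  for (s in dataset) {
    if (!identical(dim(s$ct$data), dim(s$pseudo_label$data)))
      stop("pseudo-labels must match volume shapes")
  }
  set.seed(config$seed + 1L)
  opt <- adam_state(model$params)
  hist <- vector("list", max(config$epochs, 0L))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(dataset))
    lt_ep <- numeric(length(ord))
    for (t in seq_along(ord)) {
      s <- dataset[[ord[t]]]
      fw <- reorient_forward(model, s$ct$data)
      ang <- fw$angles
      lfun <- function(a)
        single_modal_loss(rotate_volume(s$ct, a,
                                        convention = config$euler_convention),
                          s$pseudo_label)
      l0 <- lfun(ang)
      if (!is.finite(l0)) stop("NaN loss during fine-tuning; aborting")
      h <- config$fd_step_deg
      gang <- numeric(3)
      for (i in 1:3) {
        ap <- ang; ap[i] <- ap[i] + h
        gang[i] <- (lfun(ap) - l0) / h
      }
      grads <- reorient_backward(model, fw$cache, gang)
      upd <- adam_step(model$params, grads, opt, config$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      lt_ep[t] <- l0
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, l_sing = mean(lt_ep))
  }
  attr(model, "history") <- if (length(hist)) do.call(rbind, hist)
                            else tibble::tibble(epoch = integer(),
                                                l_sing = numeric())
  model
}
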