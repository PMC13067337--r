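# Memoized training runs shared by the acceptance tests: the reorientation
# network and the deformation network are each trained once per test session
# under the study conditions, then reused by every block that needs them.

.acc_cache <- new.env(parent = emptyenv())

acc_reorient_run <- function() {
  if (is.null(.acc_cache$reorient)) {
    ds <- build_reorient_dataset(200, grid_size = 48L,
                                 rotation_range = c(-30, 30), seed = 11L)
    cfg <- reorient_model_config(width = 8L, input_size = 48L,
                                 epochs = 20L, seed = 0L)
    tr <- train_reorientation(ds, cfg)
    holdout <- build_reorient_dataset(20, grid_size = 48L,
                                      rotation_range = c(-30, 30),
                                      seed = 777L)
    ev <- evaluate_reorientation_on_phantoms(tr$model, holdout)
    pl <- build_pseudo_label_dataset(tr$model, ds[1:50])
    ft_cfg <- reorient_model_config(width = 8L, input_size = 48L,
                                    epochs = 2L, seed = 0L)
    ft_model <- fine_tune(tr$model, pl, ft_cfg)
    ev_ft <- evaluate_reorientation_on_phantoms(ft_model, holdout)
    .acc_cache$reorient <- list(model = tr$model, history = tr$history,
                                holdout = holdout, eval = ev,
                                ft_model = ft_model, eval_ft = ev_ft)
  }
  .acc_cache$reorient
}

acc_sdn_run <- function() {
  if (is.null(.acc_cache$sdn)) {
    sd <- build_sdn_dataset(100, grid_size = 48L, fov = c(64, 64),
                            seed = 3L)
    tr <- train_sdn(sd$dataset, sdn_config(epochs = 30L, seed = 1L))
    held <- build_sdn_dataset(9, grid_size = 48L, fov = c(64, 64),
                              seed = 99L)
    pre <- vapply(held$masks, function(m) dice(m$cmr_wall, m$ctca_wall),
                  numeric(1))
    post <- vapply(seq_along(held$dataset), function(i) {
      r <- register_cmr(tr$model, held$dataset[[i]]$ctca,
                        held$dataset[[i]]$cmr)
      dice(warp_2d(held$masks[[i]]$cmr_wall * 1, r$field) > 0.5,
           held$masks[[i]]$ctca_wall)
    }, numeric(1))
    .acc_cache$sdn <- list(model = tr$model, history = tr$history,
                           pre = pre, post = post)
  }
  .acc_cache$sdn
}
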