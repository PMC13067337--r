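# Plotting surfaces for the tabular results (training histories, metric
# reports). Volumes are best viewed in a NIfTI viewer; plot_slice() gives a
# quick base-graphics look at one slice.

#' Plot a training history
#'
#' @param history tibble from [train_reorientation()] or [train_sdn()].
#' @return A ggplot object (loss per epoch, one line per loss component).
#' @export
plot_training_history <- function(history) {
  stopifnot(is.data.frame(history), "epoch" %in% names(history))
  long <- do.call(rbind, lapply(setdiff(names(history), "epoch"),
                                function(nm)
                                  tibble::tibble(epoch = history$epoch,
                                                 loss = history[[nm]],
                                                 component = nm)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a metrics report
#'
#' @param object a `cf_metrics_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cf_metrics_report <- function(object, ...) {
  df <- tibble::tibble(
    metric = factor(c("AR", "DSC", "LA dev axial (deg)",
                      "LA dev coronal (deg)"),
                    levels = c("AR", "DSC", "LA dev axial (deg)",
                               "LA dev coronal (deg)")),
    value = c(object$ar, object$dsc, object$la_dev_axial_deg,
              object$la_dev_coronal_deg))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Display one slice of a volume
#'
#' @param volume a [cf_volume()].
#' @param k sagittal slice index (default: middle).
#' @param ... passed to [graphics::image()].
#' @export
plot_slice <- function(volume, k = NULL, ...) {
  volume <- as_volume(volume)
  d <- dim(volume$data)
  if (is.null(k)) k <- (d[3] + 1L) %/% 2L
  graphics::image(volume$data[, , k], asp = d[2] / d[1],
                  col = grey.colors(128, 0, 1), axes = FALSE, ...)
  invisible(volume)
}
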