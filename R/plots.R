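# ggplot2 visualisations for evaluation objects.

#' Plot a calibration curve
#'
#' Mean predicted probability versus observed positive fraction per bin,
#' with the identity line of a perfectly calibrated model.
#'
#' @param object a `ds_calibration` from [calibration_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ds_calibration
#' @export
autoplot.ds_calibration <- function(object, ...) {
  df <- dplyr::filter(object, .data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_pred, y = .data$obs_frac)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$count), alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed positive fraction", size = "Bin count") +
    ggplot2::theme_minimal()
}

#' Plot a deployment report
#'
#' AUC (with bootstrap CI) of each strategy on each per-domain and pooled
#' test set.
#'
#' @param object a `ds_deployment` from [deployment_report()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ds_deployment
#' @export
autoplot.ds_deployment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$eval_domain, y = .data$auc,
                               colour = .data$strategy,
                               group = interaction(.data$strategy,
                                                   .data$variant))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Evaluation domain", y = "AUC (%)",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot adaptation loss histories
#'
#' Component losses over training iterations, faceted by update phase.
#'
#' @param adaptation a `ds_adaptation`.
#' @param smooth_window rolling-mean window in logged points (1 = raw).
#' @return a ggplot.
#' @export
plot_loss_history <- function(adaptation, smooth_window = 1) {
  df <- tidy(adaptation)
  if (smooth_window > 1) {
    df <- df |>
      dplyr::group_by(.data$phase, .data$component) |>
      dplyr::arrange(.data$iteration, .by_group = TRUE) |>
      dplyr::mutate(value = stats::filter(.data$value,
                                          rep(1 / smooth_window,
                                              smooth_window),
                                          sides = 1)) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$value))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line(alpha = 0.9) +
    ggplot2::facet_wrap(~phase, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = "Loss") +
    ggplot2::theme_minimal()
}

#' Plot domain spread against training-data fraction
#'
#' @param spread tibble with `data_fraction` and `spread` (the attribute
#'   attached by [deployment_report()]).
#' @return a ggplot.
#' @export
plot_domain_spread <- function(spread) {
  ggplot2::ggplot(spread, ggplot2::aes(x = .data$data_fraction,
                                       y = .data$spread)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Training data fraction",
                  y = "Domain spread (AUC variance)") +
    ggplot2::theme_minimal()
}

#' Show a grid of images from an image set
#'
#' Renders a few images (optionally alongside their translations) as a
#' raster plot; handy for eyeballing what the generator does.
#'
#' @param set an [image_set()].
#' @param idx item indices to show.
#' @param ncol grid columns.
#' @return a ggplot.
#' @export
plot_images <- function(set, idx = 1:8, ncol = 4) {
  dfs <- lapply(idx, function(i) {
    img <- denormalize_image(set$images[, , , i])
    H <- dim(img)[1]; W <- dim(img)[2]
    tibble::tibble(
      item = i,
      x = rep(seq_len(W), each = H),
      y = rep(rev(seq_len(H)), W),
      fill = grDevices::rgb(pmin(pmax(img[, , 1], 0), 1),
                            pmin(pmax(img[, , min(2, dim(img)[3])], 0), 1),
                            pmin(pmax(img[, , min(3, dim(img)[3])], 0), 1)))
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = I(.data$fill))) +
    ggplot2::facet_wrap(~item, ncol = ncol) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
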