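# broom-style tidiers for fitted objects.

#' Tidy a trained classifier's history
#'
#' @param x a `ds_classifier`.
#' @param ... unused.
#' @return tibble with one row per epoch: `epoch`, `train_loss`, `val_auc`.
#' @method tidy ds_classifier
#' @export
tidy.ds_classifier <- function(x, ...) x$history

#' One-row summary of a trained classifier
#'
#' @param x a `ds_classifier`.
#' @param ... unused.
#' @return tibble with `best_val_auc`, `best_epoch`, `epochs_run`,
#'   `n_parameters`.
#' @method glance ds_classifier
#' @export
glance.ds_classifier <- function(x, ...) {
  tibble::tibble(best_val_auc = x$best_val_auc, best_epoch = x$best_epoch,
                 epochs_run = nrow(x$history),
                 n_parameters = n_parameters(x$model))
}

#' Tidy an adaptation run's loss history
#'
#' @param x a `ds_adaptation`.
#' @param ... unused.
#' @return long tibble: `iteration`, `phase`, `component`, `value`.
#' @method tidy ds_adaptation
#' @export
tidy.ds_adaptation <- function(x, ...) {
  tidyr::pivot_longer(x$history, -c("iteration", "phase"),
                      names_to = "component", values_to = "value",
                      values_drop_na = TRUE)
}

#' One-row summary of an adaptation run
#'
#' @param x a `ds_adaptation`.
#' @param ... unused.
#' @return tibble with iteration count, parameter counts, and the mean of
#'   each component loss over the last tenth of training.
#' @method glance ds_adaptation
#' @export
glance.ds_adaptation <- function(x, ...) {
  h <- tidy(x)
  tail_from <- max(1, ceiling(0.9 * x$cfg$iterations))
  tail_means <- h |>
    dplyr::filter(.data$iteration >= tail_from) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "component", values_from = "value",
                       names_prefix = "final_")
  dplyr::bind_cols(
    tibble::tibble(iterations = x$cfg$iterations,
                   g_parameters = n_parameters(x$G),
                   d_parameters = n_parameters(x$D)),
    tail_means)
}

#' Tidy an experiment's pair-level report
#'
#' @param x a `ds_experiment`.
#' @param ... unused.
#' @return the pair-level report tibble (AUCs in percent, salvage, changes).
#' @method tidy ds_experiment
#' @export
tidy.ds_experiment <- function(x, ...) x$report
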