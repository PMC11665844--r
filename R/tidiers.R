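#' Tidy methods for result objects
#'
#' `tidy()` returns per-unit rows (per slice, per epoch); `glance()` returns
#' a one-row summary, broom-style.
#'
#' @param x a `metrics_report` or `train_result`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.metrics_report <- function(x, ...) x$per_slice

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(n_slices = nrow(x$per_slice))
  for (i in seq_len(nrow(s))) {
    out[[paste0(s$metric[i], "_mean")]] <- s$mean[i]
    out[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
  }
  out
}

#' @rdname tidy.metrics_report
#' @export
tidy.train_result <- function(x, ...) x$log

#' @rdname tidy.metrics_report
#' @export
glance.train_result <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_dice = x$best_dice,
    final_train_loss = x$log$train_loss[nrow(x$log)],
    parameters = count_parameters(x$model)
  )
}

#' Plot training curves
#'
#' Train/test loss per epoch alongside the mean test Dice trajectory.
#'
#' @param object a `train_result` from [train_fold()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.train_result <- function(object, ...) {
  long <- object$log |>
    tidyr::pivot_longer(c("train_loss", "test_loss", "test_dice"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training trajectory") +
    ggplot2::theme_minimal()
}

#' Plot per-slice metric distributions
#'
#' @param object a `metrics_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- object$per_slice |>
    tidyr::pivot_longer(dplyr::all_of(metric_names),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "per-slice value",
                  title = "Segmentation metrics") +
    ggplot2::theme_minimal()
}

#' Plot a slice with its mask (and optionally a prediction)
#'
#' @param pair a `slice_pair`.
#' @param prob optional probability map to overlay as contours at 0.5.
#' @return a ggplot object.
#' @export
plot_slice_pair <- function(pair, prob = NULL) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(pair$image)), ncol(pair$image)),
    col = rep(seq_len(ncol(pair$image)), each = nrow(pair$image)),
    intensity = as.numeric(pair$image),
    mask = as.numeric(pair$mask)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = pair$slice_id, fill = "CT")
  if (any(df$mask > 0)) {
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = .data$mask),
                                   breaks = 0.5, colour = "red", linewidth = 0.4)
  }
  if (!is.null(prob)) {
    df$prob <- as.numeric(prob)
    p <- p + ggplot2::geom_contour(data = df, ggplot2::aes(z = .data$prob),
                                   breaks = 0.5, colour = "cyan", linewidth = 0.4)
  }
  p
}
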