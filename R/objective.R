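#' Hybrid loss configuration
#'
#' The training objective is `alpha * L_BCE + beta * L_Dice`: pixelwise
#' binary cross-entropy for stable optimisation plus soft Dice for overlap
#' under heavy class imbalance. The adopted setting is `alpha = beta = 1`.
#'
#' @param alpha nonnegative weight of the binary cross-entropy term.
#' @param beta nonnegative weight of the Dice term (`alpha + beta > 0`).
#' @param smooth positive Dice smoothing constant (default 1, the common
#'   practice; resolves the empty-mask 0/0 case).
#' @param clamp_eps probability floor in (0, 0.5) applied before logarithms.
#' @return a `loss_config` list.
#' @export
loss_config <- function(alpha = 1, beta = 1, smooth = 1, clamp_eps = 1e-7) {
  bad <- function(x) length(x) != 1L || !is.numeric(x) || is.na(x)
  if (bad(alpha) || alpha < 0) abort_value("`alpha` must be a nonnegative number")
  if (bad(beta) || beta < 0) abort_value("`beta` must be a nonnegative number")
  if (alpha + beta <= 0) abort_value("`alpha` + `beta` must be positive")
  if (bad(smooth) || smooth <= 0) abort_value("`smooth` must be positive")
  if (bad(clamp_eps) || clamp_eps <= 0 || clamp_eps >= 0.5) {
    abort_value("`clamp_eps` must lie in (0, 0.5)")
  }
  structure(list(alpha = alpha, beta = beta, smooth = smooth, clamp_eps = clamp_eps),
            class = "loss_config")
}

check_pixel_vectors <- function(y, p) {
  if (length(y) != length(p)) {
    abort_value("`y` and `p` must have equal length (", length(y), " vs ", length(p), ")")
  }
  if (length(y) == 0L) abort_value("empty pixel vectors")
  if (!all(y %in% c(0, 1))) abort_value("`y` must be binary (0/1)")
  if (any(p < 0 | p > 1)) abort_value("`p` must lie in [0, 1]")
  invisible(NULL)
}

#' Binary cross-entropy over pixel vectors
#'
#' `-(1/N) * sum(y * log p + (1 - y) * log(1 - p))`, with `p` clamped to
#' `[clamp_eps, 1 - clamp_eps]` before the logarithms.
#'
#' @param y binary ground-truth vector.
#' @param p predicted probabilities in \[0, 1\], same length.
#' @param clamp_eps log-argument floor.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(y, p, clamp_eps = 1e-7) {
  check_pixel_vectors(y, p)
  p <- pmin(pmax(p, clamp_eps), 1 - clamp_eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Soft Dice loss over pixel vectors
#'
#' `1 - (2 * sum(y * p) + smooth) / (sum(y) + sum(p) + smooth)`.
#'
#' @inheritParams bce_loss
#' @param smooth positive smoothing constant.
#' @return scalar in \[0, 1\].
#' @export
dice_loss <- function(y, p, smooth = 1) {
  check_pixel_vectors(y, p)
  1 - (2 * sum(y * p) + smooth) / (sum(y) + sum(p) + smooth)
}

#' Hybrid BCE + Dice loss
#'
#' @inheritParams bce_loss
#' @param cfg a [loss_config()].
#' @return nonnegative scalar `alpha * bce + beta * dice`.
#' @export
total_loss <- function(y, p, cfg = loss_config()) {
  cfg$alpha * bce_loss(y, p, cfg$clamp_eps) + cfg$beta * dice_loss(y, p, cfg$smooth)
}

# differentiable hybrid loss node for training; y is a plain 0/1 array with
# the shape of the prediction tensor
ag_hybrid_loss <- function(p, y, cfg = loss_config()) {
  pv <- ag_val(p)
  yv <- as.numeric(y)
  n <- length(pv)
  eps <- cfg$clamp_eps
  pc <- pmin(pmax(as.numeric(pv), eps), 1 - eps)
  S <- sum(yv * pc)
  U <- sum(yv) + sum(pc)
  sm <- cfg$smooth
  val <- cfg$alpha * (-mean(yv * log(pc) + (1 - yv) * log(1 - pc))) +
    cfg$beta * (1 - (2 * S + sm) / (U + sm))
  ag_record(val, list(p), function(node) {
    inside <- as.numeric(pv) > eps & as.numeric(pv) < 1 - eps
    dbce <- -(yv / pc - (1 - yv) / (1 - pc)) / n
    ddice <- -(2 * yv * (U + sm) - (2 * S + sm)) / (U + sm)^2
    g <- (cfg$alpha * dbce + cfg$beta * ddice) * inside * node$grad
    list(array(g, dim = dim(pv)))
  })
}

# ---- confusion counts and metrics ------------------------------------------

#' Pixelwise confusion counts between two binary masks
#'
#' @param pred_mask,truth_mask binary arrays of identical shape.
#' @return a `confusion_counts` list with fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(pred_mask, truth_mask) {
  dp <- dim(pred_mask) %||% length(pred_mask)
  dt <- dim(truth_mask) %||% length(truth_mask)
  if (!identical(as.integer(dp), as.integer(dt))) {
    abort_dim("mask shapes differ: ", paste(dp, collapse = "x"), " vs ",
              paste(dt, collapse = "x"))
  }
  p <- as.numeric(pred_mask) != 0
  t <- as.numeric(truth_mask) != 0
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den, empty_num_ok) {
  if (den == 0) return(if (empty_num_ok) 1 else 0)
  num / den
}

#' Segmentation metrics from confusion counts
#'
#' Dice `2TP/(2TP+FP+FN)`, Jaccard `TP/(TP+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(FP+TN)` and pixel accuracy `(TP+TN)/(TP+TN+FP+FN)`.
#' Degenerate denominators follow the usual benchmark conventions: an empty
#' truth mask scores sensitivity (and Dice/Jaccard) 1 when the prediction is
#' also empty and 0 otherwise, and symmetrically for specificity.
#'
#' @param counts a [confusion()] result (or list with `TP`, `FP`, `TN`, `FN`).
#' @param slice_id optional identifier carried into the report row.
#' @return one-row tibble: `slice_id`, `dice`, `jaccard`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
metrics_from_counts <- function(counts, slice_id = NA_character_) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (min(TP, FP, TN, FN) < 0) abort_value("confusion counts must be nonnegative")
  tibble::tibble(
    slice_id = as.character(slice_id),
    dice = safe_ratio(2 * TP, 2 * TP + FP + FN, empty_num_ok = TRUE),
    jaccard = safe_ratio(TP, TP + FP + FN, empty_num_ok = TRUE),
    sensitivity = if (TP + FN == 0) (if (FP == 0) 1 else 0) else TP / (TP + FN),
    specificity = if (FP + TN == 0) (if (FN == 0) 1 else 0) else TN / (FP + TN),
    accuracy = safe_ratio(TP + TN, TP + TN + FP + FN, empty_num_ok = TRUE)
  )
}

metric_names <- c("dice", "jaccard", "sensitivity", "specificity", "accuracy")

#' Aggregate per-slice metrics into mean and spread
#'
#' @param per_slice tibble of per-slice rows from [metrics_from_counts()]
#'   (or a `metrics_report`).
#' @return a `metrics_report`: list with `per_slice` (tibble) and `summary`
#'   (tibble of metric, mean, sd; sd is the population standard deviation).
#' @export
aggregate_metrics <- function(per_slice) {
  if (inherits(per_slice, "metrics_report")) per_slice <- per_slice$per_slice
  if (!is.data.frame(per_slice) || nrow(per_slice) == 0L) {
    abort_value("`per_slice` must be a non-empty data frame of slice metrics")
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summary <- per_slice |>
    tidyr::pivot_longer(dplyr::all_of(metric_names),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = pop_sd(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$metric, metric_names))
  structure(list(per_slice = tibble::as_tibble(per_slice), summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics over", nrow(x$per_slice), "slice(s)\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' One row per slice plus `mean` and `sd` footer rows.
#'
#' @param report a `metrics_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  per <- report$per_slice
  footer <- tibble::tibble(
    slice_id = c("mean", "sd"),
    !!!setNames(lapply(metric_names, function(m) {
      s <- report$summary
      c(s$mean[s$metric == m], s$sd[s$metric == m])
    }), metric_names)
  )
  write.csv(dplyr::bind_rows(per, footer), path, row.names = FALSE)
  invisible(path)
}
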