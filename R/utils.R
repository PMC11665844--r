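abort_config <- function(...) {
  rlang::abort(paste0(...), class = "hemoseg_config_error")
}

abort_dim <- function(...) {
  rlang::abort(paste0(...), class = "hemoseg_dim_error")
}

abort_value <- function(...) {
  rlang::abort(paste0(...), class = "hemoseg_value_error")
}

check_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != round(x)) {
    abort_config("`", name, "` must be a single positive integer")
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0 || x >= 1) {
    abort_value("`", name, "` must lie strictly in (0, 1)")
  }
  invisible(x)
}

check_range2 <- function(x, name, lo = -Inf) {
  if (length(x) != 2L || any(is.na(x)) || x[1] > x[2] || x[1] < lo) {
    abort_config("`", name, "` must be a [min, max] pair with min >= ", lo)
  }
  invisible(x)
}
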