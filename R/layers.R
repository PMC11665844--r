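#' @keywords internal
#' @name layers
#' @title Network layer modules
#'
#' @description
#' Layers are environments (`hs_module`) holding parameter tensors
#' (`$params`), child modules (`$modules`) and normalisation buffers. The
#' [forward()] generic runs a layer; gradients land on the parameter tensors
#' when called inside [with_tape()].
NULL

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$params <- list()
  m$modules <- list()
  class(m) <- c(paste0("hs_", type), "hs_module")
  m
}

#' Run a module forward
#' @param mod an `hs_module`.
#' @param x input tensor (`ag_tensor` or plain array, layout `c(C,H,W,N)`).
#' @param training logical; training mode (batch statistics, tape-friendly).
#' @param ... passed along.
#' @export
forward <- function(mod, x, training = FALSE, ...) UseMethod("forward")

# He-normal initialisation; draws come from the R RNG so set.seed() controls
# every weight in the model.
he_init <- function(shape, fan_in) {
  array(stats::rnorm(prod(shape), sd = sqrt(2 / fan_in)), dim = shape)
}

new_conv2d <- function(in_channels, out_channels, kernel = 3L, stride = 1L,
                       pad = 0L, dilation = 1L, bias = TRUE) {
  m <- new_module("conv2d")
  m$stride <- as.integer(stride)
  m$pad <- as.integer(pad)
  m$dilation <- as.integer(dilation)
  m$params$w <- ag_tensor(
    he_init(c(in_channels, kernel, kernel, out_channels), in_channels * kernel^2),
    requires_grad = TRUE
  )
  if (bias) m$params$b <- ag_tensor(numeric(out_channels), requires_grad = TRUE)
  m
}

#' @export
forward.hs_conv2d <- function(mod, x, training = FALSE, ...) {
  ag_conv2d(x, mod$params$w, mod$params$b,
            stride = mod$stride, pad = mod$pad, dilation = mod$dilation)
}

new_batchnorm <- function(channels, momentum = 0.1, eps = 1e-5) {
  m <- new_module("batchnorm")
  m$params$gamma <- ag_tensor(rep(1, channels), requires_grad = TRUE)
  m$params$beta <- ag_tensor(numeric(channels), requires_grad = TRUE)
  m$buf <- new.env(parent = emptyenv())
  m$buf$running_mean <- numeric(channels)
  m$buf$running_var <- rep(1, channels)
  m$momentum <- momentum
  m$eps <- eps
  m
}

#' @export
forward.hs_batchnorm <- function(mod, x, training = FALSE, ...) {
  ag_batchnorm(x, mod$params$gamma, mod$params$beta, mod$buf,
               training = training, momentum = mod$momentum, eps = mod$eps)
}

new_dense <- function(in_features, out_features, bias = TRUE) {
  m <- new_module("dense")
  m$params$w <- ag_tensor(
    matrix(stats::rnorm(out_features * in_features, sd = sqrt(2 / in_features)),
           out_features, in_features),
    requires_grad = TRUE
  )
  if (bias) m$params$b <- ag_tensor(numeric(out_features), requires_grad = TRUE)
  m
}

#' @export
forward.hs_dense <- function(mod, x, training = FALSE, ...) {
  ag_dense(x, mod$params$w, mod$params$b)
}

# ---- parameter handling ----------------------------------------------------

#' Collect all parameter tensors of a module tree
#' @param mod an `hs_module`.
#' @return named list of `ag_tensor` leaves (names are dotted paths).
#' @export
parameters <- function(mod) {
  out <- list()
  collect <- function(m, prefix) {
    for (nm in names(m$params)) out[[paste0(prefix, nm)]] <<- m$params[[nm]]
    for (nm in names(m$modules)) collect(m$modules[[nm]], paste0(prefix, nm, "."))
  }
  collect(mod, "")
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' Total number of learnable scalars in a module tree
#' @param model an `hs_module`.
#' @return integer count of learnable scalar parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(parameters(model), function(p) length(p$value), numeric(1)))
}

#' Overwrite every parameter of a module tree with a constant (test utility)
#' @param mod module; `value` the fill constant.
#' @param value numeric scalar.
#' @export
set_all_params <- function(mod, value = 0) {
  for (p in parameters(mod)) p$value[] <- value
  invisible(mod)
}

#' Put all batch-norm layers in analytic pass-through state
#'
#' Sets unit scale, zero shift and evaluation statistics that make the layer
#' an exact identity in evaluation mode; used by closed-form layer tests.
#' @param mod module tree.
#' @export
set_bn_passthrough <- function(mod) {
  walk_mod <- function(m) {
    if (inherits(m, "hs_batchnorm")) {
      m$params$gamma$value[] <- 1
      m$params$beta$value[] <- 0
      m$buf$running_mean[] <- 0
      m$buf$running_var[] <- 1 - m$eps
    }
    for (child in m$modules) walk_mod(child)
  }
  walk_mod(mod)
  invisible(mod)
}

# deep-copy the parameter/buffer state of a module tree (for checkpoints)
module_state <- function(mod) {
  st <- list(params = lapply(parameters(mod), function(p) p$value), buffers = list())
  collect_buf <- function(m, prefix) {
    if (!is.null(m$buf)) {
      st$buffers[[paste0(prefix, "running_mean")]] <<- m$buf$running_mean
      st$buffers[[paste0(prefix, "running_var")]] <<- m$buf$running_var
    }
    for (nm in names(m$modules)) collect_buf(m$modules[[nm]], paste0(prefix, nm, "."))
  }
  collect_buf(mod, "")
  st
}

load_module_state <- function(mod, st) {
  ps <- parameters(mod)
  stopifnot(setequal(names(ps), names(st$params)))
  for (nm in names(ps)) {
    stopifnot(length(ps[[nm]]$value) == length(st$params[[nm]]))
    ps[[nm]]$value <- array(as.numeric(st$params[[nm]]), dim = dim(ps[[nm]]$value) %||% length(ps[[nm]]$value))
  }
  apply_buf <- function(m, prefix) {
    if (!is.null(m$buf)) {
      m$buf$running_mean <- as.numeric(st$buffers[[paste0(prefix, "running_mean")]])
      m$buf$running_var <- as.numeric(st$buffers[[paste0(prefix, "running_var")]])
    }
    for (nm in names(m$modules)) apply_buf(m$modules[[nm]], paste0(prefix, nm, "."))
  }
  apply_buf(mod, "")
  invisible(mod)
}

# ---- Adam ------------------------------------------------------------------

#' Adaptive-moment (Adam) optimiser
#' @param params named list from [parameters()].
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical floor.
#' @return optimiser state environment with an `$step()` closure.
#' @export
new_adam <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$t <- 0L
  opt$m <- lapply(params, function(p) p$value * 0)
  opt$v <- lapply(params, function(p) p$value * 0)
  opt$step <- function() {
    opt$t <- opt$t + 1L
    bc1 <- 1 - beta1^opt$t
    bc2 <- 1 - beta2^opt$t
    for (nm in names(opt$params)) {
      p <- opt$params[[nm]]
      if (is.null(p$grad)) next
      g <- p$grad
      opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
      opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
      p$value <- p$value - opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    }
    invisible(NULL)
  }
  class(opt) <- "hs_adam"
  opt
}
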