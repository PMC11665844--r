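#' Configuration for the architecture building blocks
#'
#' Collects the hyperparameters of the dilated-convolution-pooling (DCP)
#' block, the self-attention bridge, the residual block and the
#' channel/spatial attention gates.
#'
#' @param in_channels,out_channels positive integers.
#' @param dilation_rates strictly increasing positive integers; one parallel
#'   3x3 branch per rate. Default `c(1, 2, 4)`: geometric growth keeps the
#'   effective kernel extents (3, 5, 9 pixels) inside the smallest mid-level
#'   feature maps while still widening the receptive field.
#' @param channel_reduction squeeze-excitation bottleneck ratio; must divide
#'   the channel count where the gate is applied. Default 16.
#' @param attention_key_reduction divisor for the query/key channels of the
#'   self-attention bridge (non-local-block convention). Default 8. The value
#'   path keeps the full channel count.
#' @param spatial_kernel odd kernel size of the spatial-attention convolution.
#'   Default 7.
#' @return a `block_config` list.
#' @export
block_config <- function(in_channels, out_channels = in_channels,
                         dilation_rates = c(1L, 2L, 4L),
                         channel_reduction = 16L,
                         attention_key_reduction = 8L,
                         spatial_kernel = 7L) {
  check_count(in_channels, "in_channels")
  check_count(out_channels, "out_channels")
  if (length(dilation_rates) == 0 || any(dilation_rates < 1) ||
      any(diff(dilation_rates) <= 0)) {
    abort_config("`dilation_rates` must be a non-empty strictly increasing vector of positive integers")
  }
  check_count(channel_reduction, "channel_reduction")
  check_count(attention_key_reduction, "attention_key_reduction")
  check_count(spatial_kernel, "spatial_kernel")
  if (spatial_kernel %% 2L == 0L) {
    abort_config("`spatial_kernel` must be odd, got ", spatial_kernel)
  }
  structure(
    list(in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels),
         dilation_rates = as.integer(dilation_rates),
         channel_reduction = as.integer(channel_reduction),
         attention_key_reduction = as.integer(attention_key_reduction),
         spatial_kernel = as.integer(spatial_kernel)),
    class = "block_config"
  )
}

# ---- dilated convolution pooling -------------------------------------------

#' Dilated-convolution-pooling block constructor
#'
#' Parallel 3x3 convolutions, one per dilation rate (each padded by its rate
#' so all branches keep the input size, then batch-normalised and rectified),
#' merged by channel concatenation, compressed by a 1x1 convolution
#' (batch-norm + ReLU), and finally 2x2 stride-2 max-pooled, so the block
#' halves the spatial size while widening the receptive field.
#'
#' @param cfg a [block_config()].
#' @return an `hs_module`.
#' @export
new_dcp_block <- function(cfg) {
  m <- new_module("dcp")
  m$cfg <- cfg
  for (i in seq_along(cfg$dilation_rates)) {
    d <- cfg$dilation_rates[i]
    m$modules[[paste0("branch", i, "_conv")]] <-
      new_conv2d(cfg$in_channels, cfg$out_channels, 3L, pad = d, dilation = d, bias = FALSE)
    m$modules[[paste0("branch", i, "_bn")]] <- new_batchnorm(cfg$out_channels)
  }
  merged <- cfg$out_channels * length(cfg$dilation_rates)
  m$modules$compress_conv <- new_conv2d(merged, cfg$out_channels, 1L, bias = FALSE)
  m$modules$compress_bn <- new_batchnorm(cfg$out_channels)
  m
}

#' @export
forward.hs_dcp <- function(mod, x, training = FALSE, ...) {
  d <- dim(ag_val(x))
  if (d[1] != mod$cfg$in_channels) {
    abort_config("DCP block expects ", mod$cfg$in_channels, " input channels, got ", d[1])
  }
  if (d[2] %% 2L != 0L) abort_dim("DCP block needs an even height, got ", d[2])
  if (d[3] %% 2L != 0L) abort_dim("DCP block needs an even width, got ", d[3])
  branches <- lapply(seq_along(mod$cfg$dilation_rates), function(i) {
    h <- forward(mod$modules[[paste0("branch", i, "_conv")]], x, training)
    ag_relu(forward(mod$modules[[paste0("branch", i, "_bn")]], h, training))
  })
  merged <- Reduce(ag_concat, branches)
  h <- forward(mod$modules$compress_conv, merged, training)
  h <- ag_relu(forward(mod$modules$compress_bn, h, training))
  ag_maxpool2(h)
}

# ---- self-attention bridge -------------------------------------------------

#' Self-attention (non-local) block constructor
#'
#' Query, key and value tensors come from three 1x1 convolutions (query and
#' key reduced to `channels / attention_key_reduction` channels, value kept
#' full width). Every spatial position attends to every other through a
#' row-softmax of the query-key inner products; the value mixture is passed
#' through an output 1x1 convolution and added back to the input.
#'
#' @param cfg a [block_config()]; `in_channels` must be divisible by
#'   `attention_key_reduction`.
#' @return an `hs_module`.
#' @export
new_self_attention <- function(cfg) {
  C <- cfg$in_channels
  if (C %% cfg$attention_key_reduction != 0L) {
    abort_config("in_channels (", C, ") must be divisible by attention_key_reduction (",
                 cfg$attention_key_reduction, ")")
  }
  Cr <- C %/% cfg$attention_key_reduction
  m <- new_module("sam")
  m$cfg <- cfg
  m$modules$q_conv <- new_conv2d(C, Cr, 1L)
  m$modules$k_conv <- new_conv2d(C, Cr, 1L)
  m$modules$v_conv <- new_conv2d(C, C, 1L)
  m$modules$out_conv <- new_conv2d(C, C, 1L)
  m
}

#' @export
forward.hs_sam <- function(mod, x, training = FALSE, ...) {
  d <- dim(ag_val(x))
  if (d[1] != mod$cfg$in_channels) {
    abort_config("self-attention expects ", mod$cfg$in_channels, " channels, got ", d[1])
  }
  q <- forward(mod$modules$q_conv, x, training)
  k <- forward(mod$modules$k_conv, x, training)
  v <- forward(mod$modules$v_conv, x, training)
  att <- ag_attend(q, k, v)
  mod$last_weights <- att$weights
  ag_add(x, forward(mod$modules$out_conv, att, training))
}

# ---- residual block --------------------------------------------------------

#' Residual block constructor
#'
#' Main path: 3x3 conv, batch-norm, ReLU, 3x3 conv, batch-norm. Shortcut:
#' identity when shapes already match, otherwise a 1x1 conv + batch-norm
#' projection. Output is the rectified sum. `stride` > 1 (used inside the
#' encoder stages) downsamples both paths.
#'
#' @param cfg a [block_config()].
#' @param stride stride of the first convolution (and of the projection).
#' @return an `hs_module`.
#' @export
new_residual_block <- function(cfg, stride = 1L) {
  m <- new_module("residual")
  m$cfg <- cfg
  m$stride <- as.integer(stride)
  m$modules$conv1 <- new_conv2d(cfg$in_channels, cfg$out_channels, 3L,
                                stride = stride, pad = 1L, bias = FALSE)
  m$modules$bn1 <- new_batchnorm(cfg$out_channels)
  m$modules$conv2 <- new_conv2d(cfg$out_channels, cfg$out_channels, 3L, pad = 1L, bias = FALSE)
  m$modules$bn2 <- new_batchnorm(cfg$out_channels)
  m$project <- cfg$in_channels != cfg$out_channels || stride != 1L
  if (m$project) {
    m$modules$short_conv <- new_conv2d(cfg$in_channels, cfg$out_channels, 1L,
                                       stride = stride, bias = FALSE)
    m$modules$short_bn <- new_batchnorm(cfg$out_channels)
  }
  m
}

#' @export
forward.hs_residual <- function(mod, x, training = FALSE, ...) {
  h <- forward(mod$modules$conv1, x, training)
  h <- ag_relu(forward(mod$modules$bn1, h, training))
  h <- forward(mod$modules$conv2, h, training)
  h <- forward(mod$modules$bn2, h, training)
  s <- if (mod$project) {
    forward(mod$modules$short_bn, forward(mod$modules$short_conv, x, training), training)
  } else {
    x
  }
  ag_relu(ag_add(h, s))
}

# ---- channel and spatial attention -----------------------------------------

#' Channel-attention (squeeze-excitation) gate constructor
#'
#' Global average pooling gives one statistic per channel; a two-layer
#' bottleneck (width `channels / channel_reduction`, ReLU between, logistic
#' squash after) turns it into a per-channel gate in (0, 1) that rescales the
#' input channelwise.
#'
#' @param cfg a [block_config()]; `channel_reduction` must divide
#'   `in_channels`.
#' @return an `hs_module`.
#' @export
new_channel_attention <- function(cfg) {
  C <- cfg$in_channels
  if (C %% cfg$channel_reduction != 0L) {
    abort_config("in_channels (", C, ") must be divisible by channel_reduction (",
                 cfg$channel_reduction, ")")
  }
  m <- new_module("channel_att")
  m$cfg <- cfg
  m$modules$fc1 <- new_dense(C, C %/% cfg$channel_reduction)
  m$modules$fc2 <- new_dense(C %/% cfg$channel_reduction, C)
  m
}

#' @export
forward.hs_channel_att <- function(mod, x, training = FALSE, ...) {
  d <- dim(ag_val(x))
  if (d[1] != mod$cfg$in_channels) {
    abort_config("channel attention expects ", mod$cfg$in_channels, " channels, got ", d[1])
  }
  z <- ag_gap(x)
  g <- ag_sigmoid(forward(mod$modules$fc2, ag_relu(forward(mod$modules$fc1, z, training)), training))
  mod$last_gate <- ag_val(g)
  ag_scale_channels(x, g)
}

#' Spatial-attention gate constructor
#'
#' The channelwise mean map and channelwise max map are stacked into a
#' two-channel descriptor, convolved with a `spatial_kernel` x
#' `spatial_kernel` kernel and logistic-squashed into a per-position gate in
#' (0, 1) that rescales the input positionwise.
#'
#' @param cfg a [block_config()]; `spatial_kernel` must be odd.
#' @return an `hs_module`.
#' @export
new_spatial_attention <- function(cfg) {
  m <- new_module("spatial_att")
  m$cfg <- cfg
  m$modules$conv <- new_conv2d(2L, 1L, cfg$spatial_kernel,
                               pad = (cfg$spatial_kernel - 1L) %/% 2L, bias = TRUE)
  m
}

#' @export
forward.hs_spatial_att <- function(mod, x, training = FALSE, ...) {
  s <- ag_channel_stats(x)
  g <- ag_sigmoid(forward(mod$modules$conv, s, training))
  mod$last_gate <- ag_val(g)
  ag_scale_spatial(x, g)
}

#' Channel-then-spatial attention block constructor
#'
#' Sequential composition used in every decoder step: the channel gate first,
#' then the spatial gate on its output.
#'
#' @param cfg a [block_config()].
#' @return an `hs_module`.
#' @export
new_csa_block <- function(cfg) {
  m <- new_module("csa")
  m$cfg <- cfg
  m$modules$channel <- new_channel_attention(cfg)
  m$modules$spatial <- new_spatial_attention(cfg)
  m
}

#' @export
forward.hs_csa <- function(mod, x, training = FALSE, ...) {
  forward(mod$modules$spatial, forward(mod$modules$channel, x, training), training)
}

# ---- functional wrappers ---------------------------------------------------

block_apply <- function(ctor, x, cfg, block) {
  x3 <- length(dim(x)) == 3L
  if (x3) dim(x) <- c(dim(x), 1L)
  if (!all(is.finite(x))) abort_value("feature map contains non-finite values")
  if (is.null(block)) block <- ctor(cfg)
  y <- ag_val(forward(block, x, training = FALSE))
  if (x3) dim(y) <- dim(y)[1:3]
  y
}

#' Apply an architecture block to a feature map
#'
#' Functional forms of the block constructors: each builds (or reuses via
#' `block`) a module and runs it in evaluation mode on a feature map of
#' layout `(channels, height, width)` (a trailing sample axis is also
#' accepted). `dcp_block()` halves the spatial size; the others preserve it.
#'
#' @param x numeric array `(C, H, W)` or `(C, H, W, N)`, all entries finite.
#' @param cfg a [block_config()].
#' @param block optional pre-built module (from the matching `new_*`
#'   constructor) so weights can be fixed beforehand; a fresh randomly
#'   initialised module is created otherwise.
#' @return numeric array of the same layout as `x`.
#' @export
dcp_block <- function(x, cfg, block = NULL) block_apply(new_dcp_block, x, cfg, block)

#' @rdname dcp_block
#' @export
self_attention <- function(x, cfg, block = NULL) block_apply(new_self_attention, x, cfg, block)

#' @rdname dcp_block
#' @export
residual_block <- function(x, cfg, block = NULL) block_apply(new_residual_block, x, cfg, block)

#' @rdname dcp_block
#' @export
channel_attention <- function(x, cfg, block = NULL) block_apply(new_channel_attention, x, cfg, block)

#' @rdname dcp_block
#' @export
spatial_attention <- function(x, cfg, block = NULL) block_apply(new_spatial_attention, x, cfg, block)

#' @rdname dcp_block
#' @export
csa_block <- function(x, cfg, block = NULL) block_apply(new_csa_block, x, cfg, block)
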