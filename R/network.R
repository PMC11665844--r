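#' Model configuration
#'
#' Describes the full encoder-decoder: a ResNet-style backbone encoder,
#' dilated-convolution-pooling (DCP) side branches on the chosen encoder
#' levels, an optional self-attention bridge on the deepest feature, and a
#' decoder of residual blocks gated by channel-then-spatial attention.
#'
#' @param in_channels input image channels (1 for CT).
#' @param encoder_depth 34 (basic blocks) or 50 (bottlenecks).
#' @param stage_channels five stage widths; defaults to the reference recipe
#'   for the chosen depth (`c(64, 64, 128, 256, 512)` for depth 34,
#'   `c(64, 256, 512, 1024, 2048)` for depth 50).
#' @param use_pretrained_encoder load ImageNet-pretrained encoder weights.
#'   No weights are bundled with the package, so enabling this errors with
#'   instructions unless a weights file is supplied by other means.
#' @param dcp_levels encoder levels (subset of 2:5) that receive an additive
#'   DCP side branch; every level except the first, by default.
#' @param sam_at_bridge apply the self-attention block to the deepest
#'   (level-5) feature before decoding.
#' @param decoder_channels five decoder stage widths (default
#'   `c(256, 128, 64, 64, 32)`, mirroring the encoder widths halved).
#' @param output_threshold probability threshold used when binarising
#'   predictions; strictly in (0, 1).
#' @param dilation_rates,channel_reduction,attention_key_reduction,spatial_kernel
#'   block hyperparameters, see [block_config()].
#' @return a `model_config` list.
#' @export
model_config <- function(in_channels = 1L,
                         encoder_depth = 34L,
                         stage_channels = NULL,
                         use_pretrained_encoder = FALSE,
                         dcp_levels = 2:5,
                         sam_at_bridge = TRUE,
                         decoder_channels = c(256L, 128L, 64L, 64L, 32L),
                         output_threshold = 0.5,
                         dilation_rates = c(1L, 2L, 4L),
                         channel_reduction = 16L,
                         attention_key_reduction = 8L,
                         spatial_kernel = 7L) {
  if (!encoder_depth %in% c(34L, 50L)) {
    abort_config("`encoder_depth` must be 34 or 50, got ", encoder_depth)
  }
  if (is.null(stage_channels)) {
    stage_channels <- if (encoder_depth == 34L) c(64L, 64L, 128L, 256L, 512L)
                      else c(64L, 256L, 512L, 1024L, 2048L)
  }
  if (length(stage_channels) != 5L) abort_config("`stage_channels` must have length 5")
  if (length(decoder_channels) != 5L) abort_config("`decoder_channels` must have length 5")
  if (length(dcp_levels) && !all(dcp_levels %in% 2:5)) {
    abort_config("`dcp_levels` must be a subset of 2:5 (the first encoder level never carries a DCP branch)")
  }
  check_count(in_channels, "in_channels")
  check_fraction(output_threshold, "output_threshold")
  structure(
    list(in_channels = as.integer(in_channels),
         encoder_depth = as.integer(encoder_depth),
         stage_channels = as.integer(stage_channels),
         use_pretrained_encoder = isTRUE(use_pretrained_encoder),
         dcp_levels = as.integer(sort(unique(dcp_levels))),
         sam_at_bridge = isTRUE(sam_at_bridge),
         decoder_channels = as.integer(decoder_channels),
         output_threshold = output_threshold,
         dilation_rates = as.integer(dilation_rates),
         channel_reduction = as.integer(channel_reduction),
         attention_key_reduction = as.integer(attention_key_reduction),
         spatial_kernel = as.integer(spatial_kernel)),
    class = "model_config"
  )
}

# reference block counts per stage (stages 2..5)
encoder_block_counts <- function(depth) c(3L, 4L, 6L, 3L)

new_bottleneck <- function(in_channels, out_channels, stride = 1L) {
  mid <- out_channels %/% 4L
  m <- new_module("bottleneck")
  m$modules$conv1 <- new_conv2d(in_channels, mid, 1L, bias = FALSE)
  m$modules$bn1 <- new_batchnorm(mid)
  m$modules$conv2 <- new_conv2d(mid, mid, 3L, stride = stride, pad = 1L, bias = FALSE)
  m$modules$bn2 <- new_batchnorm(mid)
  m$modules$conv3 <- new_conv2d(mid, out_channels, 1L, bias = FALSE)
  m$modules$bn3 <- new_batchnorm(out_channels)
  m$project <- in_channels != out_channels || stride != 1L
  if (m$project) {
    m$modules$short_conv <- new_conv2d(in_channels, out_channels, 1L, stride = stride, bias = FALSE)
    m$modules$short_bn <- new_batchnorm(out_channels)
  }
  m
}

#' @export
forward.hs_bottleneck <- function(mod, x, training = FALSE, ...) {
  h <- ag_relu(forward(mod$modules$bn1, forward(mod$modules$conv1, x, training), training))
  h <- ag_relu(forward(mod$modules$bn2, forward(mod$modules$conv2, h, training), training))
  h <- forward(mod$modules$bn3, forward(mod$modules$conv3, h, training), training)
  s <- if (mod$project) {
    forward(mod$modules$short_bn, forward(mod$modules$short_conv, x, training), training)
  } else {
    x
  }
  ag_relu(ag_add(h, s))
}

new_stage <- function(in_channels, out_channels, n_blocks, depth, stride1, pool_first = FALSE) {
  m <- new_module("stage")
  m$pool_first <- pool_first
  mk <- function(ci, co, s) {
    if (depth == 34L) new_residual_block(block_config(ci, co), stride = s)
    else new_bottleneck(ci, co, stride = s)
  }
  m$modules$block1 <- mk(in_channels, out_channels, stride1)
  if (n_blocks > 1L) {
    for (i in 2:n_blocks) m$modules[[paste0("block", i)]] <- mk(out_channels, out_channels, 1L)
  }
  m
}

#' @export
forward.hs_stage <- function(mod, x, training = FALSE, ...) {
  h <- if (mod$pool_first) ag_maxpool2(x) else x
  for (blk in mod$modules) h <- forward(blk, h, training)
  h
}

#' Build the backbone encoder
#'
#' Five stages in the reference ResNet layout: a 7x7 stride-2 stem
#' (batch-norm + ReLU), then four residual stages, the first preceded by a
#' 2x2 stride-2 max-pool and the rest opening with a stride-2 block, so
#' stage `l` runs at 1/2^l of the input resolution.
#'
#' @param cfg a [model_config()].
#' @return an `hs_module` whose forward pass returns the list of five stage
#'   outputs.
#' @export
build_encoder <- function(cfg) {
  if (cfg$use_pretrained_encoder) {
    abort_config(
      "pretrained encoder weights are not bundled with the package; ",
      "set use_pretrained_encoder = FALSE (random initialisation) to proceed"
    )
  }
  s <- cfg$stage_channels
  nb <- encoder_block_counts(cfg$encoder_depth)
  m <- new_module("encoder")
  m$cfg <- cfg
  m$modules$stem_conv <- new_conv2d(cfg$in_channels, s[1], 7L, stride = 2L, pad = 3L, bias = FALSE)
  m$modules$stem_bn <- new_batchnorm(s[1])
  m$modules$stage2 <- new_stage(s[1], s[2], nb[1], cfg$encoder_depth, 1L, pool_first = TRUE)
  m$modules$stage3 <- new_stage(s[2], s[3], nb[2], cfg$encoder_depth, 2L)
  m$modules$stage4 <- new_stage(s[3], s[4], nb[3], cfg$encoder_depth, 2L)
  m$modules$stage5 <- new_stage(s[4], s[5], nb[4], cfg$encoder_depth, 2L)
  m
}

#' @export
forward.hs_encoder <- function(mod, x, training = FALSE, ...) {
  s1 <- ag_relu(forward(mod$modules$stem_bn, forward(mod$modules$stem_conv, x, training), training))
  s2 <- forward(mod$modules$stage2, s1, training)
  s3 <- forward(mod$modules$stage3, s2, training)
  s4 <- forward(mod$modules$stage4, s3, training)
  s5 <- forward(mod$modules$stage5, s4, training)
  list(s1, s2, s3, s4, s5)
}

# shared encoder-enrichment pass: stage outputs with additive DCP branches;
# returns the list of five (enriched) stage features
enriched_forward <- function(encoder, dcp_mods, x, training = FALSE) {
  s1 <- ag_relu(forward(encoder$modules$stem_bn,
                        forward(encoder$modules$stem_conv, x, training), training))
  feats <- list(s1)
  for (l in 2:5) {
    h <- forward(encoder$modules[[paste0("stage", l)]], feats[[l - 1L]], training)
    dcp <- dcp_mods[[paste0("dcp", l)]]
    if (!is.null(dcp)) h <- ag_add(h, forward(dcp, feats[[l - 1L]], training))
    feats[[l]] <- h
  }
  feats
}

#' Attach DCP side branches to an encoder
#'
#' For each level in `cfg$dcp_levels`, a dilated-convolution-pooling branch
#' consumes the previous level's output (the branch's internal pooling
#' supplies the x2 downsampling) and is element-wise summed with the stage
#' output; the enriched sum is both the decoder skip and the next stage's
#' input. With `dcp_levels = integer()` the result is exactly the plain
#' backbone.
#'
#' @param encoder a [build_encoder()] module.
#' @param cfg the [model_config()] used to build the encoder.
#' @return an `hs_enriched_encoder` module whose forward pass returns the
#'   list of five (enriched) stage features.
#' @export
attach_dcp <- function(encoder, cfg) {
  if (length(cfg$dcp_levels) && !all(cfg$dcp_levels %in% 2:5)) {
    abort_config("`dcp_levels` must be a subset of 2:5")
  }
  m <- new_module("enriched_encoder")
  m$cfg <- cfg
  m$modules$encoder <- encoder
  s <- cfg$stage_channels
  for (l in cfg$dcp_levels) {
    m$modules[[paste0("dcp", l)]] <- new_dcp_block(
      block_config(s[l - 1L], s[l], dilation_rates = cfg$dilation_rates)
    )
  }
  m
}

#' @export
forward.hs_enriched_encoder <- function(mod, x, training = FALSE, ...) {
  enriched_forward(mod$modules$encoder, mod$modules, x, training)
}

new_decoder_step <- function(in_channels, out_channels, cfg) {
  m <- new_module("decoder_step")
  bc <- block_config(in_channels, out_channels,
                     channel_reduction = cfg$channel_reduction,
                     spatial_kernel = cfg$spatial_kernel)
  m$modules$res <- new_residual_block(bc)
  m$modules$csa <- new_csa_block(block_config(out_channels, out_channels,
                                              channel_reduction = cfg$channel_reduction,
                                              spatial_kernel = cfg$spatial_kernel))
  m
}

#' @export
forward.hs_decoder_step <- function(mod, x, training = FALSE, ...) {
  forward(mod$modules$csa, forward(mod$modules$res, x, training), training)
}

#' Build the full segmentation network
#'
#' Assembles the encoder, the additive DCP side branches (each consumes the
#' previous level's output, its built-in pooling supplies the x2
#' downsampling, and its output is element-wise summed with the stage
#' output), the self-attention bridge on the deepest enriched feature, and a
#' five-step decoder (bilinear x2 upsample, concatenate the matching skip
#' where one exists, residual block, channel-spatial attention), closed by a
#' 1x1 convolution and logistic squash into a probability map.
#'
#' @param cfg a [model_config()].
#' @return an `hs_hemo_net` module.
#' @export
hemo_net <- function(cfg = model_config()) {
  s <- cfg$stage_channels
  m <- new_module("hemo_net")
  m$cfg <- cfg
  m$modules$encoder <- build_encoder(cfg)
  for (l in cfg$dcp_levels) {
    m$modules[[paste0("dcp", l)]] <- new_dcp_block(
      block_config(s[l - 1L], s[l], dilation_rates = cfg$dilation_rates)
    )
  }
  if (cfg$sam_at_bridge) {
    m$modules$sam <- new_self_attention(
      block_config(s[5], s[5], attention_key_reduction = cfg$attention_key_reduction)
    )
  }
  dc <- cfg$decoder_channels
  skip_ch <- c(s[4], s[3], s[2], s[1], 0L) # skips for steps 1..4; step 5 has none
  in_ch <- c(s[5] + skip_ch[1],
             dc[1] + skip_ch[2],
             dc[2] + skip_ch[3],
             dc[3] + skip_ch[4],
             dc[4])
  for (i in 1:5) {
    m$modules[[paste0("dec", i)]] <- new_decoder_step(in_ch[i], dc[i], cfg)
  }
  m$modules$head <- new_conv2d(dc[5], 1L, 1L)
  m
}

#' @export
forward.hs_hemo_net <- function(mod, x, training = FALSE, ...) {
  cfg <- mod$cfg
  xv <- ag_val(x)
  d <- dim(xv)
  if (length(d) != 4L) abort_dim("expected a (C,H,W,N) input tensor")
  if (d[2] %% 32L != 0L || d[3] %% 32L != 0L) {
    abort_dim("input height and width must be a multiple of 32, got ",
              d[2], " x ", d[3])
  }
  if (d[1] != cfg$in_channels) {
    abort_config("model expects ", cfg$in_channels, " input channels, got ", d[1])
  }
  feats <- enriched_forward(mod$modules$encoder, mod$modules, x, training)
  bridge <- if (cfg$sam_at_bridge) forward(mod$modules$sam, feats[[5]], training) else feats[[5]]
  h <- bridge
  skips <- list(feats[[4]], feats[[3]], feats[[2]], feats[[1]], NULL)
  for (i in 1:5) {
    h <- ag_upsample2(h)
    if (!is.null(skips[[i]])) h <- ag_concat(h, skips[[i]])
    h <- forward(mod$modules[[paste0("dec", i)]], h, training)
  }
  ag_sigmoid(forward(mod$modules$head, h, training))
}

#' Predict the lesion probability map for one slice
#'
#' Runs the network in evaluation mode on a single grayscale slice.
#'
#' @param model an [hemo_net()] module.
#' @param image numeric matrix (H x W) in \[0, 1\], or a `(C,H,W)` array.
#' @return numeric H x W matrix of probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, image) {
  x <- image
  if (is.matrix(x)) x <- array(x, dim = c(1L, nrow(x), ncol(x)))
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  y <- ag_val(forward(model, x, training = FALSE))
  matrix(y[1L, , , 1L], dim(y)[2], dim(y)[3])
}

#' Threshold a probability map into a binary mask
#'
#' @param p numeric array of probabilities in \[0, 1\].
#' @param threshold scalar strictly in (0, 1); pixels with `p >= threshold`
#'   become 1.
#' @return integer array of 0/1 with the shape of `p`.
#' @export
binarize <- function(p, threshold = 0.5) {
  check_fraction(threshold, "threshold")
  if (any(p < 0 | p > 1)) abort_value("probability map values must lie in [0, 1]")
  array(as.integer(p >= threshold), dim = dim(p) %||% length(p))
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The weights container is an RDS file of all parameter arrays and
#' normalisation buffers; a JSON sidecar (`<path>.json`) holds the full
#' [model_config()] so the checkpoint is self-describing.
#'
#' @param model an `hs_hemo_net` module.
#' @param path file path for the weights container.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(module_state(model), path)
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort_value("checkpoint not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) abort_value("checkpoint sidecar config not found: ", sidecar)
  cj <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  cfg <- model_config(
    in_channels = cj$in_channels, encoder_depth = cj$encoder_depth,
    stage_channels = cj$stage_channels,
    use_pretrained_encoder = FALSE,
    dcp_levels = cj$dcp_levels %||% integer(),
    sam_at_bridge = cj$sam_at_bridge,
    decoder_channels = cj$decoder_channels,
    output_threshold = cj$output_threshold,
    dilation_rates = cj$dilation_rates,
    channel_reduction = cj$channel_reduction,
    attention_key_reduction = cj$attention_key_reduction,
    spatial_kernel = cj$spatial_kernel
  )
  model <- hemo_net(cfg)
  load_module_state(model, readRDS(path))
  model
}

#' Per-component parameter summary of a model
#'
#' @param model an `hs_hemo_net` module.
#' @return a tibble with one row per top-level component plus a total row.
#' @export
model_summary <- function(model) {
  rows <- purrr::map_dfr(names(model$modules), function(nm) {
    tibble::tibble(component = nm, parameters = count_parameters(model$modules[[nm]]))
  })
  dplyr::bind_rows(rows, tibble::tibble(component = "total",
                                        parameters = sum(rows$parameters)))
}
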