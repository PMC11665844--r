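test_that("block_config validates its hyperparameters", {
  expect_s3_class(block_config(16, 32), "block_config")
  expect_error(block_config(16, dilation_rates = c(2, 2)), class = "hemoseg_config_error")
  expect_error(block_config(16, dilation_rates = integer()), class = "hemoseg_config_error")
  expect_error(block_config(16, spatial_kernel = 4), class = "hemoseg_config_error")
  expect_error(block_config(0), class = "hemoseg_config_error")
})

test_that("DCP block halves the spatial size and widens channels", {
  set.seed(11)
  x <- rand_fmap3(8, 16, 16)
  y <- dcp_block(x, block_config(8, 12))
  expect_identical(dim(y), c(12L, 8L, 8L))
  # odd sizes are rejected with the offending axis named
  expect_error(dcp_block(rand_fmap3(8, 15, 16), block_config(8, 12)),
               regexp = "height", class = "hemoseg_dim_error")
  expect_error(dcp_block(rand_fmap3(8, 16, 15), block_config(8, 12)),
               regexp = "width", class = "hemoseg_dim_error")
  expect_error(dcp_block(rand_fmap3(4, 16, 16), block_config(8, 12)),
               class = "hemoseg_config_error")
})

test_that("DCP block with all weights zeroed maps any input to zero", {
  set.seed(12)
  blk <- new_dcp_block(block_config(4, 6))
  set_all_params(blk, 0)
  y <- dcp_block(rand_fmap3(4, 8, 8), block_config(4, 6), block = blk)
  expect_true(all(y == 0))
})

test_that("a rate-4 dilated 3x3 branch sees exactly a 9x9 neighbourhood", {
  # unit impulse through a single dilated convolution: the non-zero response
  # must be confined to the 9x9 window centred on the impulse (extent 2*4+1)
  x <- array(0, c(1, 32, 32, 1))
  x[1, 16, 16, 1] <- 1
  w <- ag_tensor(array(1, c(1, 3, 3, 1)))
  y <- ag_val(ag_conv2d(x, w, NULL, pad = 4, dilation = 4))
  nz <- which(y[1, , , 1] != 0, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1] - 16) <= 4))
  expect_true(all(abs(nz[, 2] - 16) <= 4))
  expect_identical(nrow(nz), 9L) # 3x3 taps at spacing 4
})

test_that("self-attention preserves shape and its rows form a distribution", {
  set.seed(13)
  cfg <- block_config(16, attention_key_reduction = 8)
  blk <- new_self_attention(cfg)
  x <- rand_fmap3(16, 4, 4)
  y <- self_attention(x, cfg, block = blk)
  expect_identical(dim(y), dim(x))
  for (A in blk$last_weights) {
    expect_true(all(A >= 0 & A <= 1))
    expect_true(all(abs(rowSums(A) - 1) < 1e-5))
  }
  expect_error(self_attention(rand_fmap3(12, 4, 4), block_config(12, attention_key_reduction = 8)),
               class = "hemoseg_config_error")
})

test_that("zeroed output projection makes self-attention the identity", {
  set.seed(14)
  cfg <- block_config(8, attention_key_reduction = 8)
  blk <- new_self_attention(cfg)
  blk$modules$out_conv$params$w$value[] <- 0
  blk$modules$out_conv$params$b$value[] <- 0
  x <- rand_fmap3(8, 3, 3)
  expect_identical(self_attention(x, cfg, block = blk), x)
})

test_that("self-attention matches the brute-force position-pair oracle", {
  set.seed(15)
  for (case in list(c(C = 1L, H = 2L, W = 2L), c(C = 8L, H = 3L, W = 2L),
                    c(C = 8L, H = 4L, W = 4L))) {
    C <- case[["C"]]; H <- case[["H"]]; W <- case[["W"]]
    red <- if (C == 1L) 1L else 8L
    cfg <- block_config(C, attention_key_reduction = red)
    blk <- new_self_attention(cfg)
    Cr <- C %/% red
    wq <- matrix(rnorm(C * Cr), C, Cr); bq <- rnorm(Cr)
    wk <- matrix(rnorm(C * Cr), C, Cr); bk <- rnorm(Cr)
    wv <- matrix(rnorm(C * C), C, C); bv <- rnorm(C)
    wo <- matrix(rnorm(C * C), C, C); bo <- rnorm(C)
    set_conv1x1(blk$modules$q_conv, wq, bq)
    set_conv1x1(blk$modules$k_conv, wk, bk)
    set_conv1x1(blk$modules$v_conv, wv, bv)
    set_conv1x1(blk$modules$out_conv, wo, bo)
    x <- rand_fmap3(C, H, W)
    got <- self_attention(x, cfg, block = blk)
    ref <- sam_bruteforce(x, wq, bq, wk, bk, wv, bv, wo, bo)
    expect_lt(max(abs(got - ref$y)), 1e-5)
    expect_lt(max(abs(blk$last_weights[[1]] - ref$weights)), 1e-5)
  }
})

test_that("residual block shape contract and identity shortcut", {
  set.seed(16)
  x <- rand_fmap3(8, 16, 16)
  y_same <- residual_block(x, block_config(8, 8))
  expect_identical(dim(y_same), dim(x))
  y_proj <- residual_block(x, block_config(8, 12))
  expect_identical(dim(y_proj), c(12L, 16L, 16L))
  blk <- new_residual_block(block_config(8, 8))
  expect_false(blk$project)
  expect_true(new_residual_block(block_config(8, 12))$project)
})

test_that("zeroed main path reduces the residual block to rectification", {
  set.seed(17)
  blk <- new_residual_block(block_config(4, 4))
  blk$modules$conv1$params$w$value[] <- 0
  blk$modules$conv2$params$w$value[] <- 0
  set_bn_passthrough(blk)
  x <- rand_fmap3(4, 6, 6)
  y <- residual_block(x, block_config(4, 4), block = blk)
  expect_equal(y, pmax(x, 0), tolerance = 1e-12)
})

test_that("channel attention gates lie in (0,1) and zero weights give 0.5 x", {
  set.seed(18)
  cfg <- block_config(8, channel_reduction = 4)
  x <- rand_fmap3(8, 5, 5)
  blk <- new_channel_attention(cfg)
  y <- channel_attention(x, cfg, block = blk)
  expect_identical(dim(y), dim(x))
  expect_true(all(blk$last_gate > 0 & blk$last_gate < 1))
  set_all_params(blk, 0)
  expect_equal(channel_attention(x, cfg, block = blk), 0.5 * x, tolerance = 1e-15)
  expect_error(channel_attention(rand_fmap3(6, 5, 5), block_config(6, channel_reduction = 4)),
               class = "hemoseg_config_error")
})

test_that("channel attention reproduces hand-computed logistic gates", {
  # two channels (one all-zero, one constant c), reduction 2, hand-set
  # bottleneck weights -> gates computable in closed form
  cfg <- block_config(2, channel_reduction = 2)
  blk <- new_channel_attention(cfg)
  c0 <- 0.8
  x <- array(0, c(2, 3, 3, 1))
  x[2, , , 1] <- c0
  w1 <- matrix(c(1, 2), 1, 2)  # 1x2: bottleneck z = relu(0*1 + c0*2)
  w2 <- matrix(c(0.5, -1), 2, 1)
  blk$modules$fc1$params$w$value <- w1
  blk$modules$fc1$params$b$value[] <- 0
  blk$modules$fc2$params$w$value <- w2
  blk$modules$fc2$params$b$value[] <- 0
  z <- max(0, 2 * c0)
  gates <- plogis(c(0.5 * z, -1 * z))
  y <- ag_val(forward(blk, x))
  expect_equal(y[1, 1, 1, 1], 0, tolerance = 1e-12)
  expect_equal(y[2, 1, 1, 1], c0 * gates[2], tolerance = 1e-12)
  expect_equal(blk$last_gate[, 1], gates, tolerance = 1e-12)
})

test_that("spatial attention gates lie in (0,1) and zero kernel gives 0.5 x", {
  set.seed(19)
  cfg <- block_config(4, spatial_kernel = 7)
  x <- rand_fmap3(4, 8, 8)
  blk <- new_spatial_attention(cfg)
  y <- spatial_attention(x, cfg, block = blk)
  expect_identical(dim(y), dim(x))
  expect_true(all(blk$last_gate > 0 & blk$last_gate < 1))
  set_all_params(blk, 0)
  expect_equal(spatial_attention(x, cfg, block = blk), 0.5 * x, tolerance = 1e-15)
})

test_that("single-channel spatial attention with a 1x1 kernel equals logistic of scaled input", {
  # one channel: mean map == max map == input; 1x1 kernel (a, b) with bias c
  # gives gate = plogis(a*x + b*x + c) at every position
  cfg <- block_config(1, spatial_kernel = 1)
  blk <- new_spatial_attention(cfg)
  a <- 0.7; b <- -0.2; cc <- 0.1
  blk$modules$conv$params$w$value <- array(c(a, b), c(2, 1, 1, 1))
  blk$modules$conv$params$b$value[] <- cc
  x <- array(seq(-1, 1, length.out = 9), c(1, 3, 3, 1))
  y <- ag_val(forward(blk, x))
  expect_equal(as.numeric(y), as.numeric(x * plogis((a + b) * x + cc)), tolerance = 1e-12)
})

test_that("channel-spatial attention is the sequential composition of its gates", {
  set.seed(20)
  cfg <- block_config(8, channel_reduction = 4, spatial_kernel = 3)
  blk <- new_csa_block(cfg)
  x <- rand_fmap3(8, 6, 6)
  y <- csa_block(x, cfg, block = blk)
  expect_identical(dim(y), dim(x))
  manual <- ag_val(forward(blk$modules$spatial, forward(blk$modules$channel, array(x, c(dim(x), 1)))))
  expect_equal(as.numeric(y), as.numeric(manual), tolerance = 1e-12)
  set_all_params(blk, 0)
  expect_equal(csa_block(x, cfg, block = blk), 0.25 * x, tolerance = 1e-15)
})

test_that("every block parameter receives gradient on a random input", {
  set.seed(21)
  builders <- list(
    dcp = function() new_dcp_block(block_config(4, 6)),
    sam = function() new_self_attention(block_config(8, attention_key_reduction = 4)),
    residual = function() new_residual_block(block_config(4, 6)),
    csa = function() new_csa_block(block_config(8, channel_reduction = 4, spatial_kernel = 3))
  )
  chans <- c(dcp = 4, sam = 8, residual = 4, csa = 8)
  for (nm in names(builders)) {
    blk <- builders[[nm]]()
    x <- rand_fmap(chans[[nm]], 8, 8, 2)
    ps <- parameters(blk)
    with_tape({
      out <- ag_sigmoid(forward(blk, ag_tensor(x, requires_grad = TRUE), training = TRUE))
      tgt <- array(rbinom(length(ag_val(out)), 1, 0.3), dim = dim(ag_val(out)))
      ag_backward(hemoseg:::ag_hybrid_loss(out, tgt, loss_config()))
    })
    norms <- vapply(ps, function(p) if (is.null(p$grad)) 0 else sqrt(sum(p$grad^2)), 0)
    expect_true(all(norms > 0),
                info = paste(nm, "zero-grad params:",
                             paste(names(norms)[norms == 0], collapse = ", ")))
  }
})
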