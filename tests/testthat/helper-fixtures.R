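# Shared fixtures: small model configurations, numeric-gradient oracle and a
# brute-force self-attention oracle. Everything is generated in code.

# local aliases for the internal autograd primitives exercised by the tests
ag_tensor <- hemoseg:::ag_tensor
with_tape <- hemoseg:::with_tape
ag_backward <- hemoseg:::ag_backward
ag_val <- hemoseg:::ag_val
ag_conv2d <- hemoseg:::ag_conv2d
ag_batchnorm <- hemoseg:::ag_batchnorm
ag_relu <- hemoseg:::ag_relu
ag_sigmoid <- hemoseg:::ag_sigmoid
ag_maxpool2 <- hemoseg:::ag_maxpool2
ag_upsample2 <- hemoseg:::ag_upsample2
ag_attend <- hemoseg:::ag_attend
ag_mean_all <- hemoseg:::ag_mean_all

slim_model_config <- function(...) {
  model_config(stage_channels = c(8L, 8L, 16L, 32L, 64L),
               decoder_channels = c(32L, 16L, 16L, 8L, 8L),
               channel_reduction = 4L, ...)
}

rand_fmap <- function(C, H, W, N = 1L) {
  array(stats::rnorm(C * H * W * N), dim = c(C, H, W, N))
}

# single-sample FeatureMap layout (C, H, W)
rand_fmap3 <- function(C, H, W) {
  array(stats::rnorm(C * H * W), dim = c(C, H, W))
}

# central-difference gradient of f (scalar-valued) at x
numeric_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force non-local attention oracle: explicit double loop over all
# position pairs of a (C,H,W) feature map, given the four 1x1 conv weights.
# wq/wk: (C x Cr), wv/wo: (C x C); b* are bias vectors.
sam_bruteforce <- function(x, wq, bq, wk, bk, wv, bv, wo, bo) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  P <- H * W
  xm <- matrix(x, nrow = C) # C x P (column p = (h, w) with h fastest)
  Cr <- ncol(wq)
  q <- matrix(0, P, Cr); k <- matrix(0, P, Cr); v <- matrix(0, P, C)
  for (p in seq_len(P)) {
    q[p, ] <- drop(t(wq) %*% xm[, p]) + bq
    k[p, ] <- drop(t(wk) %*% xm[, p]) + bk
    v[p, ] <- drop(t(wv) %*% xm[, p]) + bv
  }
  att <- matrix(0, P, P)
  out <- matrix(0, C, P)
  for (i in seq_len(P)) {
    s <- numeric(P)
    for (j in seq_len(P)) s[j] <- sum(q[i, ] * k[j, ])
    e <- exp(s - max(s))
    att[i, ] <- e / sum(e)
    acc <- numeric(C)
    for (j in seq_len(P)) acc <- acc + att[i, j] * v[j, ]
    out[, i] <- acc
  }
  y <- matrix(0, C, P)
  for (p in seq_len(P)) y[, p] <- xm[, p] + drop(t(wo) %*% out[, p]) + bo
  list(y = array(y, dim = c(C, H, W)), weights = att)
}

# install 1x1 conv weights (stored (C_in,1,1,C_out)) from a C_in x C_out matrix
set_conv1x1 <- function(conv, w, b = NULL) {
  conv$params$w$value <- array(w, dim = c(nrow(w), 1L, 1L, ncol(w)))
  if (!is.null(b)) conv$params$b$value[] <- b
  invisible(conv)
}
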