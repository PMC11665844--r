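#' @keywords internal
#' @name autograd
#' @title Reverse-mode automatic differentiation tape
#'
#' @description
#' A minimal dynamic autograd engine sufficient for the segmentation network:
#' tensors are environments holding a `value` array (layout `c(C, H, W, N)`,
#' channel fastest) and, for differentiable nodes, an accumulated `grad`.
#' While a tape is active (see [with_tape()]), every primitive operation
#' records a node with a hand-derived backward closure; [ag_backward()]
#' replays the tape in reverse. Outside a tape the same primitives run as
#' plain numeric code, which is what evaluation-mode inference uses.
NULL

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$nodes <- list()
.ag$n <- 0L
.ag$cache <- new.env(parent = emptyenv()) # memoised interpolation matrices

#' Create a tensor leaf
#'
#' @param value numeric array.
#' @param requires_grad should gradients accumulate here (parameters)?
#' @return an `ag_tensor` environment.
#' @keywords internal
ag_tensor <- function(value, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$requires <- requires_grad
  class(t) <- "ag_tensor"
  t
}

is_ag <- function(x) inherits(x, "ag_tensor")
ag_val <- function(x) if (is_ag(x)) x$value else x

ag_requires <- function(x) is_ag(x) && isTRUE(x$requires)

#' Run an expression under a fresh gradient tape
#' @param expr expression building the computation graph.
#' @keywords internal
with_tape <- function(expr) {
  old_rec <- .ag$recording
  old_nodes <- .ag$nodes
  old_n <- .ag$n
  .ag$recording <- TRUE
  .ag$nodes <- vector("list", 256L)
  .ag$n <- 0L
  on.exit({
    .ag$recording <- old_rec
    .ag$nodes <- old_nodes
    .ag$n <- old_n
  })
  expr
}

ag_push <- function(node) {
  n <- .ag$n + 1L
  if (n > length(.ag$nodes)) .ag$nodes <- c(.ag$nodes, vector("list", length(.ag$nodes)))
  .ag$nodes[[n]] <- node
  .ag$n <- n
  invisible(node)
}

# Record an op result. `backward` is function(node) returning a list of
# gradients, one per parent (NULL allowed for non-differentiable parents).
ag_record <- function(value, parents, backward) {
  req <- any(vapply(parents, ag_requires, logical(1)))
  out <- ag_tensor(value, requires_grad = FALSE)
  if (.ag$recording && req) {
    out$requires <- TRUE
    out$parents <- parents
    out$backward <- backward
    ag_push(out)
  }
  out
}

acc_grad <- function(t, g) {
  if (is.null(g) || !ag_requires(t)) return(invisible(NULL))
  t$grad <- if (is.null(t$grad)) g else t$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node through the active tape
#' @param loss an `ag_tensor` produced under [with_tape()] (call inside the
#'   same `with_tape()` block).
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  loss$grad <- 1
  if (.ag$n == 0L) return(invisible(NULL))
  for (i in rev(seq_len(.ag$n))) {
    node <- .ag$nodes[[i]]
    if (is.null(node$grad)) next
    gs <- node$backward(node)
    for (j in seq_along(node$parents)) acc_grad(node$parents[[j]], gs[[j]])
    if (!identical(node, loss)) node$grad <- NULL # free as we go
  }
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

#' 2-d convolution (C,H,W,N tensors; weight (C_in, kh, kw, C_out))
#' @keywords internal
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  xv <- ag_val(x)
  wv <- ag_val(w)
  bv <- if (is.null(b)) NULL else ag_val(b)
  y <- conv2d_fwd_cpp(xv, wv, bv, as.integer(stride), as.integer(pad), as.integer(dilation))
  parents <- list(x, w)
  if (!is.null(b)) parents <- c(parents, list(b))
  ag_record(y, parents, function(node) {
    need_dx <- ag_requires(x)
    g <- conv2d_bwd_cpp(xv, wv, node$grad,
                        as.integer(stride), as.integer(pad), as.integer(dilation), need_dx)
    out <- list(if (need_dx) g$dx else NULL, g$dw)
    if (!is.null(b)) out <- c(out, list(g$db))
    out
  })
}

#' Batch normalisation over (H, W, N) per channel
#'
#' `buf` is an environment with `running_mean`, `running_var` (length C);
#' in training mode batch statistics normalise and the buffers are updated
#' in place with momentum; in evaluation mode the buffers normalise.
#' @keywords internal
ag_batchnorm <- function(x, gamma, beta, buf, training = FALSE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- ag_val(x)
  d <- dim(xv)
  C <- d[1]
  m <- length(xv) / C
  xm <- matrix(xv, nrow = C)
  gv <- as.numeric(ag_val(gamma))
  bv <- as.numeric(ag_val(beta))
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)
    inv <- 1 / sqrt(va + eps)
    xhat <- xc * inv
    buf$running_mean <- (1 - momentum) * buf$running_mean + momentum * mu
    unb <- if (m > 1) va * m / (m - 1) else va
    buf$running_var <- (1 - momentum) * buf$running_var + momentum * unb
  } else {
    mu <- buf$running_mean
    inv <- 1 / sqrt(buf$running_var + eps)
    xhat <- (xm - mu) * inv
  }
  y <- array(xhat * gv + bv, dim = d)
  ag_record(y, list(x, gamma, beta), function(node) {
    dy <- matrix(node$grad, nrow = C)
    dgamma <- rowSums(dy * xhat)
    dbeta <- rowSums(dy)
    dx <- NULL
    if (ag_requires(x)) {
      dxhat <- dy * gv
      if (training) {
        dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
      } else {
        dx <- dxhat * inv
      }
      dx <- array(dx, dim = d)
    }
    list(dx, dgamma, dbeta)
  })
}

#' @keywords internal
ag_relu <- function(x) {
  xv <- ag_val(x)
  mask <- xv > 0
  y <- xv * mask
  ag_record(y, list(x), function(node) list(node$grad * mask))
}

#' @keywords internal
ag_sigmoid <- function(x) {
  xv <- ag_val(x)
  y <- 1 / (1 + exp(-xv))
  ag_record(y, list(x), function(node) list(node$grad * y * (1 - y)))
}

#' @keywords internal
ag_add <- function(a, b) {
  y <- ag_val(a) + ag_val(b)
  ag_record(y, list(a, b), function(node) list(node$grad, node$grad))
}

#' Concatenate two tensors along the channel axis
#' @keywords internal
ag_concat <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(all(da[-1] == db[-1]))
  Ca <- da[1]; Cb <- db[1]
  d <- da; d[1] <- Ca + Cb
  am <- matrix(av, nrow = Ca); bm <- matrix(bv, nrow = Cb)
  y <- array(rbind(am, bm), dim = d)
  ag_record(y, list(a, b), function(node) {
    g <- matrix(node$grad, nrow = Ca + Cb)
    list(array(g[seq_len(Ca), , drop = FALSE], dim = da),
         array(g[Ca + seq_len(Cb), , drop = FALSE], dim = db))
  })
}

#' @keywords internal
ag_maxpool2 <- function(x) {
  xv <- ag_val(x)
  f <- maxpool2_fwd_cpp(xv)
  ag_record(f$y, list(x), function(node) {
    list(maxpool2_bwd_cpp(node$grad, f$idx, dim(xv)))
  })
}

# memoised bilinear x2 interpolation matrix (2H x H, half-pixel centres)
bilin_mat2x <- function(H) {
  key <- paste0("A", H)
  A <- .ag$cache[[key]]
  if (!is.null(A)) return(A)
  A <- matrix(0, 2L * H, H)
  for (i in seq_len(2L * H)) {
    src <- (i - 0.5) / 2 - 0.5 # 0-based source coordinate
    h0 <- floor(src)
    fr <- src - h0
    h0c <- min(max(h0, 0), H - 1)
    h1c <- min(max(h0 + 1, 0), H - 1)
    A[i, h0c + 1] <- A[i, h0c + 1] + (1 - fr)
    A[i, h1c + 1] <- A[i, h1c + 1] + fr
  }
  .ag$cache[[key]] <- A
  A
}

# apply M (R x H) along axis 2 (height) of a (C,H,W,N) tensor
contract_h <- function(x, M) {
  d <- dim(x)
  xp <- aperm(x, c(2L, 1L, 3L, 4L))
  y <- M %*% matrix(xp, nrow = d[2])
  aperm(array(y, dim = c(nrow(M), d[1], d[3], d[4])), c(2L, 1L, 3L, 4L))
}

contract_w <- function(x, M) {
  d <- dim(x)
  xp <- aperm(x, c(3L, 1L, 2L, 4L))
  y <- M %*% matrix(xp, nrow = d[3])
  aperm(array(y, dim = c(nrow(M), d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
}

#' Bilinear x2 upsampling (half-pixel centre convention)
#' @keywords internal
ag_upsample2 <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  A <- bilin_mat2x(d[2]); B <- bilin_mat2x(d[3])
  y <- contract_w(contract_h(xv, A), B)
  ag_record(y, list(x), function(node) {
    list(contract_h(contract_w(node$grad, t(B)), t(A)))
  })
}

#' Global average pool to a C x N matrix
#' @keywords internal
ag_gap <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  P <- d[2] * d[3]
  y <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4])) y[, n] <- rowMeans(matrix(xv[, , , n], nrow = d[1]))
  ag_record(y, list(x), function(node) {
    g <- array(0, dim = d)
    for (n in seq_len(d[4])) g[, , , n] <- array(node$grad[, n] / P, dim = d[1:3])
    list(g)
  })
}

#' Dense layer on a C_in x N matrix: W (C_out x C_in) %*% z + b
#' @keywords internal
ag_dense <- function(z, w, b = NULL) {
  zv <- ag_val(z); wv <- ag_val(w)
  y <- wv %*% zv
  if (!is.null(b)) y <- y + as.numeric(ag_val(b))
  parents <- list(z, w)
  if (!is.null(b)) parents <- c(parents, list(b))
  ag_record(y, parents, function(node) {
    out <- list(t(wv) %*% node$grad, node$grad %*% t(zv))
    if (!is.null(b)) out <- c(out, list(rowSums(node$grad)))
    out
  })
}

#' Scale a (C,H,W,N) tensor channelwise by a C x N gate matrix
#' @keywords internal
ag_scale_channels <- function(x, g) {
  xv <- ag_val(x); gv <- ag_val(g)
  d <- dim(xv)
  y <- array(0, dim = d)
  for (n in seq_len(d[4])) y[, , , n] <- xv[, , , n] * gv[, n]
  ag_record(y, list(x, g), function(node) {
    dy <- node$grad
    dx <- array(0, dim = d)
    dg <- matrix(0, d[1], d[4])
    for (n in seq_len(d[4])) {
      dx[, , , n] <- dy[, , , n] * gv[, n]
      dg[, n] <- rowSums(matrix(dy[, , , n] * xv[, , , n], nrow = d[1]))
    }
    list(dx, dg)
  })
}

#' Scale a (C,H,W,N) tensor positionwise by a (1,H,W,N) gate
#' @keywords internal
ag_scale_spatial <- function(x, g) {
  xv <- ag_val(x); gv <- ag_val(g)
  d <- dim(xv)
  C <- d[1]
  gm <- rep(as.numeric(gv), each = C)
  y <- array(as.numeric(xv) * gm, dim = d)
  ag_record(y, list(x, g), function(node) {
    dy <- node$grad
    dx <- array(as.numeric(dy) * gm, dim = d)
    dg <- array(colSums(matrix(as.numeric(dy) * as.numeric(xv), nrow = C)),
                dim = dim(gv))
    list(dx, dg)
  })
}

#' Channelwise mean and max maps stacked to a (2,H,W,N) tensor
#' @keywords internal
ag_channel_stats <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  C <- d[1]
  mx <- channel_max_fwd_cpp(xv)
  mean_map <- colMeans(matrix(xv, nrow = C))
  y <- array(rbind(mean_map, as.numeric(mx$y)), dim = c(2L, d[2], d[3], d[4]))
  ag_record(y, list(x), function(node) {
    g <- matrix(node$grad, nrow = 2L)
    d_mean <- array(rep(g[1, ] / C, each = C), dim = d)
    gmax <- array(g[2, ], dim = c(1L, d[2], d[3], d[4]))
    d_max <- channel_max_bwd_cpp(gmax, mx$arg, dim(xv))
    list(d_mean + d_max)
  })
}

#' Non-local attention: softmax(Q K) mixing of value vectors, per sample
#'
#' `q` is (Cr,H,W,N), `k` is (Cr,H,W,N), `v` is (C,H,W,N). For each sample the
#' P = H*W positions attend to one another: `A = softmax_rows(Q'K)` with
#' `Q' (P x Cr)`, `K (Cr x P)`; output position i is the A\[i,\]-weighted sum of
#' value columns. Softmax rows sum to one; no temperature scaling is applied.
#' @keywords internal
ag_attend <- function(q, k, v) {
  qv <- ag_val(q); kv <- ag_val(k); vv <- ag_val(v)
  d <- dim(vv)
  P <- d[2] * d[3]
  N <- d[4]
  Cr <- dim(qv)[1]
  y <- array(0, dim = d)
  Qs <- Ks <- Vs <- As <- vector("list", N)
  for (n in seq_len(N)) {
    Q <- t(matrix(qv[, , , n], nrow = Cr)) # P x Cr
    K <- matrix(kv[, , , n], nrow = Cr)    # Cr x P
    V <- matrix(vv[, , , n], nrow = d[1])  # C x P
    S <- Q %*% K
    S <- S - apply(S, 1, max)
    E <- exp(S)
    A <- E / rowSums(E)                    # P x P, rows sum to 1
    y[, , , n] <- array(V %*% t(A), dim = d[1:3])
    Qs[[n]] <- Q; Ks[[n]] <- K; Vs[[n]] <- V; As[[n]] <- A
  }
  res <- ag_record(y, list(q, k, v), function(node) {
    dq <- array(0, dim = dim(qv))
    dk <- array(0, dim = dim(kv))
    dv <- array(0, dim = dim(vv))
    for (n in seq_len(N)) {
      dO <- matrix(node$grad[, , , n], nrow = d[1]) # C x P
      A <- As[[n]]
      dV <- dO %*% A
      # O[c,i] = sum_j V[c,j] A[i,j]  =>  dL/dA[i,j] = sum_c dO[c,i] V[c,j]
      dA <- crossprod(dO, Vs[[n]])                   # P x P
      dS <- A * (dA - rowSums(dA * A))               # softmax rows backward
      dQ <- dS %*% t(Ks[[n]])                        # P x Cr
      dK <- t(Qs[[n]]) %*% dS                        # Cr x P
      dq[, , , n] <- array(t(dQ), dim = dim(qv)[1:3])
      dk[, , , n] <- array(dK, dim = dim(kv)[1:3])
      dv[, , , n] <- array(dV, dim = d[1:3])
    }
    list(dq, dk, dv)
  })
  res$weights <- As # per-sample attention matrices, for inspection/tests
  res
}

#' Mean over all elements (scalar node)
#' @keywords internal
ag_mean_all <- function(x) {
  xv <- ag_val(x)
  n <- length(xv)
  ag_record(mean(xv), list(x), function(node) {
    list(array(node$grad / n, dim = dim(xv) %||% n))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
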