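# Minimal reverse-mode autodiff engine for batched image tensors.
#
# Internally tensors are R arrays laid out channels-first, [C, H, W, N]
# (column-major, C fastest), wrapped in mutable environments so gradients
# accumulate in place. Channels-first makes every channel-wise operation a
# plain vector recycle over the first dimension and turns a 3x3 stride-1
# convolution into nine shifted channel matmuls (BLAS), with no transposes
# anywhere in the hot path. A forward pass optionally records backward
# closures on a tape; run_backward() replays the tape in reverse.

new_tensor <- function(value) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$leaf <- FALSE
  t
}

acc_grad <- function(t, g) {
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(t)
}

new_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$ops <- list()
  e
}

tape_push <- function(tape, bwd) {
  if (!is.null(tape)) tape$ops[[length(tape$ops) + 1L]] <- bwd
  invisible(NULL)
}

run_backward <- function(tape, out, grad) {
  out$grad <- grad
  for (i in rev(seq_along(tape$ops))) tape$ops[[i]]()
  invisible(NULL)
}

# ---- layers ------------------------------------------------------------

# He-normal init. The weight matrix has one row per output channel; columns
# follow the (kernel row a, kernel col b, in channel) ordering with a
# fastest, so the 3x3 sub-block for a fixed (a, b) is a strided column
# selection.
new_conv <- function(cin, cout, k) {
  l <- new.env(parent = emptyenv())
  l$kind <- "conv"; l$k <- as.integer(k); l$cin <- cin; l$cout <- cout
  l$W <- new_tensor(matrix(rnorm(cout * k * k * cin, sd = sqrt(2 / (k * k * cin))),
                           nrow = cout))
  l$b <- new_tensor(numeric(cout))
  l
}

conv_block_cols <- function(k, C, a, b) {
  seq.int(a + (b - 1L) * k, by = k * k, length.out = C)
}

new_bn <- function(c, momentum = 0.9) {
  l <- new.env(parent = emptyenv())
  l$kind <- "bn"; l$c <- c; l$momentum <- momentum
  l$gamma <- new_tensor(rep(1, c))
  l$beta <- new_tensor(rep(0, c))
  l$rmean <- rep(0, c)
  l$rvar <- rep(1, c)
  l
}

layer_params <- function(l) {
  switch(l$kind,
    conv = list(l$W, l$b),
    bn = list(l$gamma, l$beta)
  )
}

op_conv <- function(tape, x, l) {
  d <- dim(x$value); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  stopifnot(C == l$cin)
  M <- H * W * N
  cout <- l$cout
  if (l$k == 1L) {
    xm <- x$value; dim(xm) <- c(C, M)
    ym <- l$W$value %*% xm + l$b$value
    out <- new_tensor(array(ym, c(cout, H, W, N)))
    if (!is.null(tape)) {
      tape_push(tape, function() {
        dy <- out$grad; dim(dy) <- c(cout, M)
        acc_grad(l$W, tcrossprod(dy, xm))
        acc_grad(l$b, rowSums(dy))
        if (!x$leaf) {
          dx <- crossprod(l$W$value, dy)
          dim(dx) <- c(C, H, W, N)
          acc_grad(x, dx)
        }
      })
    }
    return(out)
  }
  # 3x3, stride 1, pad 1
  Xp <- array(0, c(C, H + 2L, W + 2L, N))
  Xp[, 2L:(H + 1L), 2L:(W + 1L), ] <- x$value
  ym <- matrix(0, cout, M)
  for (b in 1:3) {
    for (a in 1:3) {
      xs <- Xp[, a:(a + H - 1L), b:(b + W - 1L), , drop = FALSE]
      dim(xs) <- c(C, M)
      ym <- ym + l$W$value[, conv_block_cols(3L, C, a, b), drop = FALSE] %*% xs
    }
  }
  ym <- ym + l$b$value
  out <- new_tensor(array(ym, c(cout, H, W, N)))
  if (!is.null(tape)) {
    tape_push(tape, function() {
      dy <- out$grad; dim(dy) <- c(cout, M)
      acc_grad(l$b, rowSums(dy))
      dW <- matrix(0, cout, 9L * C)
      dXp <- if (x$leaf) NULL else array(0, c(C, H + 2L, W + 2L, N))
      for (b in 1:3) {
        for (a in 1:3) {
          cols <- conv_block_cols(3L, C, a, b)
          xs <- Xp[, a:(a + H - 1L), b:(b + W - 1L), , drop = FALSE]
          dim(xs) <- c(C, M)
          dW[, cols] <- tcrossprod(dy, xs)
          if (!is.null(dXp)) {
            dxs <- crossprod(l$W$value[, cols, drop = FALSE], dy)
            dim(dxs) <- c(C, H, W, N)
            dXp[, a:(a + H - 1L), b:(b + W - 1L), ] <-
              dXp[, a:(a + H - 1L), b:(b + W - 1L), , drop = FALSE] + dxs
          }
        }
      }
      acc_grad(l$W, dW)
      if (!is.null(dXp)) {
        acc_grad(x, dXp[, 2L:(H + 1L), 2L:(W + 1L), , drop = FALSE])
      }
    })
  }
  out
}

channel_stats <- function(v, C) {
  m <- v; dim(m) <- c(C, length(v) %/% C)
  rowMeans(m)
}

op_bn <- function(tape, x, l, train) {
  d <- dim(x$value); C <- d[1]
  eps <- 1e-5
  if (train) {
    mu <- channel_stats(x$value, C)
    v <- pmax(channel_stats(x$value^2, C) - mu^2, 0)
    l$rmean <- l$momentum * l$rmean + (1 - l$momentum) * mu
    l$rvar <- l$momentum * l$rvar + (1 - l$momentum) * v
  } else {
    mu <- l$rmean; v <- l$rvar
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (x$value - mu) * istd # length-C vectors recycle over dim 1
  out <- new_tensor(l$gamma$value * xhat + l$beta$value)
  dim(out$value) <- d
  if (!is.null(tape)) {
    tape_push(tape, function() {
      dy <- out$grad
      n <- length(dy) %/% C
      dbeta <- channel_stats(dy, C) * n
      dgamma <- channel_stats(dy * xhat, C) * n
      acc_grad(l$beta, dbeta)
      acc_grad(l$gamma, dgamma)
      gi <- l$gamma$value * istd
      dx <- if (train) {
        gi * (dy - dbeta / n - xhat * (dgamma / n))
      } else {
        gi * dy
      }
      dim(dx) <- d
      acc_grad(x, dx)
    })
  }
  out
}

op_relu <- function(tape, x) {
  pos <- x$value > 0
  out <- new_tensor(x$value * pos)
  if (!is.null(tape)) {
    tape_push(tape, function() acc_grad(x, out$grad * pos))
  }
  out
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  out <- new_tensor(s)
  if (!is.null(tape)) {
    tape_push(tape, function() acc_grad(x, out$grad * s * (1 - s)))
  }
  out
}

op_add <- function(tape, x1, x2) {
  out <- new_tensor(x1$value + x2$value)
  if (!is.null(tape)) {
    tape_push(tape, function() {
      acc_grad(x1, out$grad)
      acc_grad(x2, out$grad)
    })
  }
  out
}

op_concat <- function(tape, x1, x2) {
  d1 <- dim(x1$value); d2 <- dim(x2$value)
  stopifnot(all(d1[2:4] == d2[2:4]))
  C1 <- d1[1]; C2 <- d2[1]
  yv <- array(0, c(C1 + C2, d1[2], d1[3], d1[4]))
  yv[seq_len(C1), , , ] <- x1$value
  yv[C1 + seq_len(C2), , , ] <- x2$value
  out <- new_tensor(yv)
  if (!is.null(tape)) {
    tape_push(tape, function() {
      acc_grad(x1, out$grad[seq_len(C1), , , , drop = FALSE])
      acc_grad(x2, out$grad[C1 + seq_len(C2), , , , drop = FALSE])
    })
  }
  out
}

# 2x2 max pooling, stride 2. Ties resolve to the earlier entry at each of
# the two pairwise reductions, so gradients route to exactly one input.
op_maxpool <- function(tape, x) {
  d <- dim(x$value); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  A <- x$value
  dim(A) <- c(C, 2L, H2, 2L, W2, N)
  a1 <- A[, 1, , , , , drop = FALSE]
  a2 <- A[, 2, , , , , drop = FALSE]
  s1 <- a1 >= a2
  m1 <- a1 * s1 + a2 * !s1 # [C,1,H2,2,W2,N]
  b1 <- m1[, , , 1, , , drop = FALSE]
  b2 <- m1[, , , 2, , , drop = FALSE]
  s2 <- b1 >= b2
  ov <- b1 * s2 + b2 * !s2
  dim(ov) <- c(C, H2, W2, N)
  out <- new_tensor(ov)
  if (!is.null(tape)) {
    tape_push(tape, function() {
      g <- out$grad
      dim(g) <- c(C, 1L, H2, 1L, W2, N)
      dm1 <- array(0, c(C, 1L, H2, 2L, W2, N))
      dm1[, , , 1, , ] <- g * s2
      dm1[, , , 2, , ] <- g * !s2
      dA <- array(0, c(C, 2L, H2, 2L, W2, N))
      dA[, 1, , , , ] <- dm1 * s1
      dA[, 2, , , , ] <- dm1 * !s1
      dim(dA) <- c(C, H, W, N)
      acc_grad(x, dA)
    })
  }
  out
}

# Nearest-neighbour x2 upsampling.
op_upsample2 <- function(tape, x) {
  d <- dim(x$value); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  yv <- x$value[, rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), ,
                drop = FALSE]
  out <- new_tensor(yv)
  if (!is.null(tape)) {
    tape_push(tape, function() {
      A <- out$grad
      dim(A) <- c(C, 2L, H, 2L, W, N)
      s <- A[, 1, , 1, , , drop = FALSE] + A[, 2, , 1, , , drop = FALSE] +
        A[, 1, , 2, , , drop = FALSE] + A[, 2, , 2, , , drop = FALSE]
      dim(s) <- c(C, H, W, N)
      acc_grad(x, s)
    })
  }
  out
}

# Zero-insertion upsampling: input pixels land on the odd output positions.
# Followed by a 3x3 stride-1 conv this realises a stride-2 transpose
# convolution that exactly doubles the spatial dimensions.
op_zerostuff <- function(tape, x) {
  d <- dim(x$value); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  yv <- array(0, c(C, 2L * H, 2L * W, N))
  ri <- seq(1L, 2L * H, by = 2L); ci <- seq(1L, 2L * W, by = 2L)
  yv[, ri, ci, ] <- x$value
  out <- new_tensor(yv)
  if (!is.null(tape)) {
    tape_push(tape, function() {
      acc_grad(x, out$grad[, ri, ci, , drop = FALSE])
    })
  }
  out
}

op_tconv <- function(tape, x, l) {
  op_conv(tape, op_zerostuff(tape, x), l)
}

# ---- optimiser ---------------------------------------------------------

new_adam <- function(params, learning_rate, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  o <- new.env(parent = emptyenv())
  o$params <- params
  o$lr <- learning_rate; o$b1 <- beta1; o$b2 <- beta2; o$eps <- eps
  o$t <- 0L
  o$m <- lapply(params, function(p) p$value * 0)
  o$v <- lapply(params, function(p) p$value * 0)
  o
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * g
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * g^2
    p$value <- p$value -
      opt$lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    p$grad <- NULL
  }
  invisible(opt)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
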