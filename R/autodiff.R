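# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Tensors are numeric arrays laid out [channels, time, batch]; most ops
# flatten to a [channels, time*batch] matrix internally so the heavy lifting
# is plain BLAS matmul. Nodes are environments carrying value/grad plus a
# backward closure; non-leaf nodes are appended to a tape and replayed in
# reverse. Parameters live off-tape and accumulate gradients across a single
# backward sweep (zeroed explicitly each optimizer step).

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_start <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$tape_len <- 0L
  invisible(NULL)
}

ad_tape_clear <- function() {
  .ad$tape <- NULL
  .ad$tape_len <- 0L
  invisible(NULL)
}

ad_push <- function(nd) {
  i <- .ad$tape_len + 1L
  if (i > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[i]] <- nd
  .ad$tape_len <- i
  nd
}

ad_node <- function(value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  if (!is.null(backward)) {
    if (is.null(.ad$tape)) stop("no active tape; call ad_tape_start() first", call. = FALSE)
    ad_push(nd)
  }
  nd
}

ad_param <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- NULL
  nd
}

ad_const <- function(value) ad_param(value)

acc_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Run reverse sweep from a scalar loss node.
ad_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  if (.ad$tape_len > 0L) {
    for (i in seq(.ad$tape_len, 1L)) {
      nd <- .ad$tape[[i]]
      if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
    }
  }
  invisible(NULL)
}

flat <- function(x) {
  d <- dim(x)
  matrix(x, d[1L], prod(d[-1L]))
}

# ---- elementwise ----

ad_add <- function(a, b) {
  ad_node(a$value + b$value, function(g) {
    acc_grad(a, g)
    acc_grad(b, g)
  })
}

ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av * bv, function(g) {
    acc_grad(a, g * bv)
    acc_grad(b, g * av)
  })
}

ad_scale <- function(a, s) {
  ad_node(a$value * s, function(g) acc_grad(a, g * s))
}

# add a constant array (e.g. positional encoding broadcast over batch)
ad_add_bcast <- function(a, const_ct) {
  d <- dim(a$value)
  ad_node(a$value + as.vector(const_ct), function(g) acc_grad(a, g))
}

ad_relu <- function(a) {
  m <- a$value > 0
  ad_node(a$value * m, function(g) acc_grad(a, g * m))
}

# Exact Gaussian-CDF GELU: x * pnorm(x).
gelu <- function(x) x * stats::pnorm(x)

ad_gelu <- function(a) {
  x <- a$value
  ad_node(gelu(x), function(g) {
    acc_grad(a, g * (stats::pnorm(x) + x * stats::dnorm(x)))
  })
}

ad_dropout <- function(a, p, train = TRUE) {
  if (!train || p <= 0) return(a)
  keep <- (stats::runif(length(a$value)) >= p) / (1 - p)
  dim(keep) <- dim(a$value)
  ad_node(a$value * keep, function(g) acc_grad(a, g * keep))
}

ad_reshape <- function(a, newdim) {
  olddim <- dim(a$value)
  v <- a$value
  dim(v) <- newdim
  ad_node(v, function(g) {
    dim(g) <- olddim
    acc_grad(a, g)
  })
}

# ---- linear / convolutional ----

# W: [C_out, C_in], optional bias length C_out; x: [C_in, T, n]
ad_lin <- function(x, W, b = NULL) {
  d <- dim(x$value)
  Xf <- flat(x$value)
  Yf <- W$value %*% Xf
  if (!is.null(b)) Yf <- Yf + b$value
  ad_node(array(Yf, c(nrow(W$value), d[2L], d[3L])), function(g) {
    Gf <- matrix(g, nrow(W$value), ncol(Xf))
    acc_grad(W, tcrossprod(Gf, Xf))
    if (!is.null(b)) acc_grad(b, rowSums(Gf))
    acc_grad(x, array(crossprod(W$value, Gf), d))
  })
}

# zero-padded shift along the time axis: out[, t, ] = x[, t + s, ]
shift_t <- function(x, s) {
  if (s == 0L) return(x)
  d <- dim(x)
  out <- array(0, d)
  T <- d[2L]
  if (abs(s) >= T) return(out)
  if (s > 0L) {
    out[, 1L:(T - s), ] <- x[, (1L + s):T, , drop = FALSE]
  } else {
    out[, (1L - s):T, ] <- x[, 1L:(T + s), , drop = FALSE]
  }
  out
}

# 1-D convolution over time, same padding, odd kernel.
# W: [C_out, C_in, K]; x: [C_in, T, n]
ad_conv1d <- function(x, W, b = NULL) {
  d <- dim(x$value)
  K <- dim(W$value)[3L]
  if (K %% 2L == 0L) stop("conv kernel must be odd for same padding", call. = FALSE)
  half <- (K - 1L) %/% 2L
  offs <- seq.int(-half, half)
  Cout <- dim(W$value)[1L]
  shifted <- lapply(offs, function(s) shift_t(x$value, s))
  Yf <- matrix(0, Cout, d[2L] * d[3L])
  for (k in seq_len(K)) Yf <- Yf + W$value[, , k] %*% flat(shifted[[k]])
  if (!is.null(b)) Yf <- Yf + b$value
  ad_node(array(Yf, c(Cout, d[2L], d[3L])), function(g) {
    Gf <- matrix(g, Cout, d[2L] * d[3L])
    dW <- array(0, dim(W$value))
    dX <- array(0, d)
    Ga <- array(g, c(Cout, d[2L], d[3L]))
    for (k in seq_len(K)) {
      dW[, , k] <- tcrossprod(Gf, flat(shifted[[k]]))
      dX <- dX + array(crossprod(W$value[, , k], flat(shift_t(Ga, -offs[k]))), d)
    }
    acc_grad(W, dW)
    if (!is.null(b)) acc_grad(b, rowSums(Gf))
    acc_grad(x, dX)
  })
}

# depthwise 1-D convolution: w [C, K], per-channel kernels, same padding
ad_dwconv1d <- function(x, w, b = NULL) {
  d <- dim(x$value)
  K <- dim(w$value)[2L]
  if (K %% 2L == 0L) stop("conv kernel must be odd for same padding", call. = FALSE)
  half <- (K - 1L) %/% 2L
  offs <- seq.int(-half, half)
  shifted <- lapply(offs, function(s) shift_t(x$value, s))
  Y <- array(0, d)
  for (k in seq_len(K)) Y <- Y + w$value[, k] * shifted[[k]]  # recycles down channels
  if (!is.null(b)) Y <- Y + b$value
  ad_node(Y, function(g) {
    dw <- matrix(0, d[1L], K)
    for (k in seq_len(K)) dw[, k] <- rowSums(flat(g * shifted[[k]]))
    acc_grad(w, dw)
    if (!is.null(b)) acc_grad(b, rowSums(flat(g)))
    dX <- array(0, d)
    for (k in seq_len(K)) dX <- dX + w$value[, k] * shift_t(g, -offs[k])
    acc_grad(x, dX)
  })
}

# apply a fixed T x T mixing matrix along the time axis (multi-scale pooling)
ad_timemix <- function(x, M) {
  d <- dim(x$value)
  xp <- aperm(x$value, c(2L, 1L, 3L))          # [T, C, n]
  yp <- M %*% matrix(xp, d[2L], d[1L] * d[3L])
  y <- aperm(array(yp, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
  ad_node(y, function(g) {
    gp <- aperm(g, c(2L, 1L, 3L))
    dxp <- crossprod(M, matrix(gp, d[2L], d[1L] * d[3L]))
    acc_grad(x, aperm(array(dxp, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L)))
  })
}

# ---- normalization ----

# layer norm across channels, per (time, sample) column
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  Xf <- flat(x$value)
  C <- d[1L]
  mu <- colMeans(Xf)
  xc <- sweep(Xf, 2L, mu)
  v <- colMeans(xc * xc)
  s <- sqrt(v + eps)
  xhat <- sweep(xc, 2L, s, "/")
  Yf <- xhat * gamma$value + beta$value
  ad_node(array(Yf, d), function(g) {
    Gf <- matrix(g, C, ncol(Xf))
    acc_grad(gamma, rowSums(Gf * xhat))
    acc_grad(beta, rowSums(Gf))
    dxhat <- Gf * gamma$value
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dX <- sweep(sweep(dxhat, 2L, m1) - sweep(xhat, 2L, m2, "*"), 2L, s, "/")
    acc_grad(x, array(dX, d))
  })
}

# ---- attention ----

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# multi-head self-attention over the time axis.
# x: [C, T, n]; Wq..Wo: [C, C]; biases length C.
# T == 1 collapses to out = Wo (Wv x + bv) + bo (softmax over one key is 1).
ad_mhsa <- function(x, Wq, Wk, Wv, Wo, bq, bk, bv, bo, n_heads) {
  d <- dim(x$value)
  C <- d[1L]; T <- d[2L]; n <- d[3L]
  if (C %% n_heads != 0L) stop("channel count not divisible by n_heads", call. = FALSE)
  if (T == 1L) return(ad_lin(ad_lin(x, Wv, bv), Wo, bo))
  dh <- C %/% n_heads
  heads <- split(seq_len(C), rep(seq_len(n_heads), each = dh))
  Q <- array(flat_lin(Wq$value, bq$value, x$value), d)
  Kk <- array(flat_lin(Wk$value, bk$value, x$value), d)
  V <- array(flat_lin(Wv$value, bv$value, x$value), d)
  O <- array(0, d)
  A_all <- vector("list", n)
  for (i in seq_len(n)) {
    Ai <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      idx <- heads[[h]]
      Qh <- matrix(Q[idx, , i], dh, T)
      Kh <- matrix(Kk[idx, , i], dh, T)
      Vh <- matrix(V[idx, , i], dh, T)
      S <- crossprod(Qh, Kh) / sqrt(dh)  # [T, T] rows = query
      A <- softmax_rows(S)
      O[idx, , i] <- Vh %*% t(A)
      Ai[[h]] <- A
    }
    A_all[[i]] <- Ai
  }
  Yf <- Wo$value %*% flat(O) + bo$value
  ad_node(array(Yf, d), function(g) {
    Gf <- matrix(g, C, T * n)
    acc_grad(Wo, tcrossprod(Gf, flat(O)))
    acc_grad(bo, rowSums(Gf))
    dO <- array(crossprod(Wo$value, Gf), d)
    dQ <- array(0, d); dK <- array(0, d); dV <- array(0, d)
    for (i in seq_len(n)) {
      for (h in seq_len(n_heads)) {
        idx <- heads[[h]]
        A <- A_all[[i]][[h]]
        dOh <- dO[idx, , i, drop = TRUE]
        dim(dOh) <- c(dh, T)
        dV[idx, , i] <- dV[idx, , i] + dOh %*% A
        dA <- crossprod(dOh, matrix(V[idx, , i], dh, T))      # [T, T]
        dS <- A * (dA - rowSums(dA * A)) / sqrt(dh)
        dQ[idx, , i] <- dQ[idx, , i] + matrix(Kk[idx, , i], dh, T) %*% t(dS)
        dK[idx, , i] <- dK[idx, , i] + matrix(Q[idx, , i], dh, T) %*% dS
      }
    }
    Xf <- flat(x$value)
    for (pair in list(list(Wq, bq, dQ), list(Wk, bk, dK), list(Wv, bv, dV))) {
      Gp <- flat(pair[[3]])
      acc_grad(pair[[1]], tcrossprod(Gp, Xf))
      acc_grad(pair[[2]], rowSums(Gp))
    }
    dX <- crossprod(Wq$value, flat(dQ)) + crossprod(Wk$value, flat(dK)) +
      crossprod(Wv$value, flat(dV))
    acc_grad(x, array(dX, d))
  })
}

flat_lin <- function(W, b, x) {
  d <- dim(x)
  W %*% matrix(x, d[1L], prod(d[-1L])) + b
}

# ---- shape ops ----

ad_mean_time <- function(x) {
  d <- dim(x$value)
  T <- d[2L]
  y <- array(apply(x$value, c(1L, 3L), mean), c(d[1L], 1L, d[3L]))
  ad_node(y, function(g) {
    gexp <- array(0, d)
    for (t in seq_len(T)) gexp[, t, ] <- g[, 1L, ] / T
    acc_grad(x, gexp)
  })
}

ad_concat_c <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  y <- array(0, c(da[1L] + db[1L], da[2L], da[3L]))
  y[seq_len(da[1L]), , ] <- a$value
  y[da[1L] + seq_len(db[1L]), , ] <- b$value
  ad_node(y, function(g) {
    acc_grad(a, g[seq_len(da[1L]), , , drop = FALSE])
    acc_grad(b, g[da[1L] + seq_len(db[1L]), , , drop = FALSE])
  })
}

ad_slice_c <- function(x, idx) {
  d <- dim(x$value)
  ad_node(x$value[idx, , , drop = FALSE], function(g) {
    gx <- array(0, d)
    gx[idx, , ] <- g
    acc_grad(x, gx)
  })
}

# ---- losses ----

# logits: [C, n]; labels: integer in 0..C-1. Returns node whose value is the
# mean cross-entropy; attaches $probs ([C, n], softmax with max-subtraction).
ad_softmax_ce <- function(logits, labels) {
  L <- logits$value
  C <- nrow(L); n <- ncol(L)
  L <- sweep(L, 2L, apply(L, 2L, max))
  E <- exp(L)
  P <- sweep(E, 2L, colSums(E), "/")
  Y <- matrix(0, C, n)
  Y[cbind(labels + 1L, seq_len(n))] <- 1
  loss <- -sum(Y * log(pmax(P, 1e-12))) / n
  nd <- ad_node(loss, function(g) {
    acc_grad(logits, g * (P - Y) / n)
  })
  nd$probs <- P
  nd
}

# cosine-similarity DCCA loss on projected views H1, H2: [o, n] (columns are
# samples). Centers within the batch, returns -J. Backward uses the exact
# analytic gradient of J with the centering adjoint.
ad_cosdcca <- function(H1, H2, eps = 1e-12) {
  A <- H1$value; B <- H2$value
  n <- ncol(A)
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  na <- sqrt(sum(Ac * Ac)) + eps
  nb <- sqrt(sum(Bc * Bc)) + eps
  J <- sum(Ac * Bc) / (na * nb)
  nd <- ad_node(-J, function(g) {
    dA <- Bc / (na * nb) - J * Ac / (na * na)
    dB <- Ac / (na * nb) - J * Bc / (nb * nb)
    # centering adjoint: remove per-dimension mean of the gradient
    dA <- dA - rowMeans(dA)
    dB <- dB - rowMeans(dB)
    acc_grad(H1, -g * dA)
    acc_grad(H2, -g * dB)
  })
  nd$J <- J
  nd
}

# ---- optimizer ----

adam_state <- function(params) {
  lapply(params, function(p) list(m = array(0, dim(p$value) %||% length(p$value)),
                                  v = array(0, dim(p$value) %||% length(p$value)),
                                  t = 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, state, lr, betas = c(0.9, 0.999), eps = 1e-8,
                      weight_decay = 0) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value  # decoupled (AdamW)
    st <- state[[i]]
    st$t <- st$t + 1L
    st$m <- betas[1L] * st$m + (1 - betas[1L]) * g
    st$v <- betas[2L] * st$v + (1 - betas[2L]) * g * g
    mhat <- st$m / (1 - betas[1L]^st$t)
    vhat <- st$v / (1 - betas[2L]^st$t)
    newv <- p$value - lr * mhat / (sqrt(vhat) + eps)
    if (is.null(dim(p$value))) newv <- as.vector(newv)  # keep vectors plain
    p$value <- newv
    state[[i]] <- st
  }
  state
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
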