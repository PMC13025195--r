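# Building blocks of the ICTD network. Public wrappers take batch-first
# arrays [n, channels, timesteps]; internally everything runs on the
# [channels, timesteps, batch] layout of the autodiff engine.

to_ctn <- function(x) {
  d <- dim(x)
  if (length(d) != 3L) stop("expected an [n, channels, timesteps] array",
                            call. = FALSE)
  aperm(x, c(2L, 3L, 1L))
}

to_nct <- function(x) aperm(x, c(3L, 1L, 2L))

#' Sinusoidal positional encoding
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i/d))` and entry `(pos, 2i+1)` is
#' `cos(pos / 10000^(2i/d))`, for positions `0..max_pos-1` and an even
#' encoding dimension `d`. Each sin/cos pair lies on the unit circle.
#'
#' @param max_pos number of positions (>= 1).
#' @param d encoding dimension (even, >= 2).
#' @return `max_pos x d` matrix; row 1 is position 0.
#' @export
positional_encoding <- function(max_pos, d) {
  if (d %% 2L != 0L) stop("encoding dimension d must be even", call. = FALSE)
  stopifnot(max_pos >= 1L, d >= 2L)
  pos <- seq_len(max_pos) - 1
  i <- seq_len(d %/% 2L) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / d))
  PE <- matrix(0, max_pos, d)
  PE[, 2 * i + 1L] <- sin(ang)
  PE[, 2 * i + 2L] <- cos(ang)
  PE
}

#' Model architecture configuration
#'
#' Holds every architecture hyperparameter in one validated place: the conv
#' stack (kernel 3, `in_channels -> 64 -> 128` with ReLU and same padding),
#' the multi-scale average-pooling kernels, the transformer encoder
#' (8 heads, 2 layers, dropout 0.3) and the IFFN (partial-convolution ratio
#' 0.25, 128 x 128 projections).
#'
#' @param in_channels input channels per view (the view feature dimension;
#'   5 is the SEED-style raw default).
#' @param conv1_out,conv2_out conv stack output channels (64, 128).
#' @param conv_kernel convolution kernel size (odd).
#' @param pool_kernels multi-scale average-pooling kernel lengths; kernels
#'   longer than the sequence clamp to the sequence length.
#' @param n_heads,n_layers transformer encoder heads and layers.
#' @param hidden1,hidden2 projection-net hidden widths (64, 128).
#' @param dropout dropout fraction in attention and IFFN sublayers.
#' @param pconv_ratio fraction of leading channels the partial convolution
#'   touches, in (0, 1].
#' @param iffn_autoencoder if TRUE, a linear encode-decode bottleneck
#'   `d -> d/2 -> d` precedes the IFFN.
#' @param use_iffn if FALSE the feedforward sublayer is a plain two-layer
#'   FFN of matched width (the ablation baseline).
#' @param multiscale_merge `"average"` (upsample and average with the
#'   unpooled map) or `"none"`.
#' @return object of class `model_config`.
#' @export
model_config <- function(in_channels = 5L, conv1_out = 64L, conv2_out = 128L,
                         conv_kernel = 3L,
                         pool_kernels = c(8L, 16L, 32L, 64L, 128L, 256L, 512L),
                         n_heads = 8L, n_layers = 2L, hidden1 = 64L,
                         hidden2 = 128L, dropout = 0.3, pconv_ratio = 0.25,
                         iffn_autoencoder = FALSE, use_iffn = TRUE,
                         multiscale_merge = c("average", "none")) {
  multiscale_merge <- match.arg(multiscale_merge)
  if (conv2_out %% n_heads != 0L)
    stop("conv2_out must be divisible by n_heads", call. = FALSE)
  if (pconv_ratio <= 0 || pconv_ratio > 1)
    stop("pconv_ratio must be in (0, 1]", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must be in [0, 1)", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 conv1_out = as.integer(conv1_out),
                 conv2_out = as.integer(conv2_out),
                 conv_kernel = as.integer(conv_kernel),
                 pool_kernels = as.integer(pool_kernels),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 hidden1 = as.integer(hidden1),
                 hidden2 = as.integer(hidden2),
                 dropout = dropout, pconv_ratio = pconv_ratio,
                 iffn_autoencoder = iffn_autoencoder,
                 use_iffn = use_iffn,
                 multiscale_merge = multiscale_merge),
            class = "model_config")
}

# combined multi-scale operator: T x T matrix averaging the identity map
# with one block-average map per pool kernel (kernels clamp to T; blocks are
# non-overlapping, stride = kernel, trailing partial block allowed), each
# upsampled by nearest-neighbor repetition back to T
multiscale_matrix <- function(T, kernels, merge = "average") {
  if (merge == "none") return(diag(T))
  M <- diag(T)
  for (k in kernels) {
    kc <- min(k, T)
    P <- matrix(0, T, T)
    starts <- seq(1L, T, by = kc)
    for (s in starts) {
      blk <- s:min(s + kc - 1L, T)
      P[blk, blk] <- 1 / length(blk)
    }
    M <- M + P
  }
  M / (length(kernels) + 1)
}

glorot <- function(nout, nin, k = 1L) {
  s <- sqrt(2 / (nin * k + nout * k))
  array(stats::rnorm(nout * nin * k, sd = s), c(nout, nin, k))
}

init_branch_params <- function(cfg, d_in) {
  C <- cfg$conv2_out
  half <- C %/% 2L
  cp <- ceiling(cfg$pconv_ratio * C)
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    lay <- list(
      Wq = ad_param(glorot(C, C)[, , 1L]), bq = ad_param(numeric(C)),
      Wk = ad_param(glorot(C, C)[, , 1L]), bk = ad_param(numeric(C)),
      Wv = ad_param(glorot(C, C)[, , 1L]), bv = ad_param(numeric(C)),
      Wo = ad_param(glorot(C, C)[, , 1L]), bo = ad_param(numeric(C)),
      ln1_g = ad_param(rep(1, C)), ln1_b = ad_param(numeric(C)),
      ln2_g = ad_param(rep(1, C)), ln2_b = ad_param(numeric(C)))
    if (cfg$use_iffn) {
      lay$ffn <- list(
        pcW = ad_param(glorot(cp, cp, cfg$conv_kernel)),
        pcb = ad_param(numeric(cp)),
        W1 = ad_param(glorot(C, C)[, , 1L]), b1 = ad_param(numeric(C)),
        gw = ad_param(matrix(stats::rnorm(half * cfg$conv_kernel,
                                          sd = 1 / sqrt(cfg$conv_kernel)),
                             half, cfg$conv_kernel)),
        gb = ad_param(numeric(half)),
        W2 = ad_param(glorot(C, C)[, , 1L]), b2 = ad_param(numeric(C)))
      if (cfg$iffn_autoencoder) {
        lay$ffn$aeW1 <- ad_param(glorot(half, C)[, , 1L])
        lay$ffn$aeb1 <- ad_param(numeric(half))
        lay$ffn$aeW2 <- ad_param(glorot(C, half)[, , 1L])
        lay$ffn$aeb2 <- ad_param(numeric(C))
      }
    } else {
      lay$ffn <- list(
        F1 = ad_param(glorot(C, C)[, , 1L]), f1b = ad_param(numeric(C)),
        F2 = ad_param(glorot(C, C)[, , 1L]), f2b = ad_param(numeric(C)))
    }
    lay
  })
  list(conv1W = ad_param(glorot(cfg$conv1_out, d_in, cfg$conv_kernel)),
       conv1b = ad_param(numeric(cfg$conv1_out)),
       conv2W = ad_param(glorot(cfg$conv2_out, cfg$conv1_out, cfg$conv_kernel)),
       conv2b = ad_param(numeric(cfg$conv2_out)),
       layers = layers)
}

branch_param_list <- function(bp) {
  out <- list(bp$conv1W, bp$conv1b, bp$conv2W, bp$conv2b)
  for (lay in bp$layers) {
    out <- c(out, lay[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                        "ln1_g", "ln1_b", "ln2_g", "ln2_b")], lay$ffn)
  }
  out
}

# ---- ad-graph forwards (shared by training and public wrappers) ------------

iffn_node <- function(x, fw, cfg) {
  C <- dim(x$value)[1L]
  if (C %% 2L != 0L) stop("IFFN needs an even channel count", call. = FALSE)
  half <- C %/% 2L
  cp <- ceiling(cfg$pconv_ratio * C)
  h <- x
  if (isTRUE(cfg$iffn_autoencoder)) {
    # linear encode-decode bottleneck d -> d/2 -> d
    h <- ad_lin(ad_lin(x, fw$aeW1, fw$aeb1), fw$aeW2, fw$aeb2)
  }
  # partial convolution on the leading cp channels, identity elsewhere
  head <- ad_slice_c(h, seq_len(cp))
  head <- ad_conv1d(head, fw$pcW, fw$pcb)
  pc <- if (cp < C) ad_concat_c(head, ad_slice_c(h, (cp + 1L):C)) else head
  u <- ad_gelu(ad_lin(pc, fw$W1, fw$b1))
  u1 <- ad_slice_c(u, seq_len(half))
  u2 <- ad_slice_c(u, (half + 1L):C)
  r <- ad_mul(u1, ad_dwconv1d(u2, fw$gw, fw$gb))
  rf <- ad_concat_c(r, u2)
  ad_gelu(ad_lin(rf, fw$W2, fw$b2))
}

ffn_node <- function(x, fw) {
  ad_lin(ad_gelu(ad_lin(x, fw$F1, fw$f1b)), fw$F2, fw$f2b)
}

encoder_layer_node <- function(x, lay, cfg, train = FALSE) {
  a <- ad_mhsa(x, lay$Wq, lay$Wk, lay$Wv, lay$Wo,
               lay$bq, lay$bk, lay$bv, lay$bo, cfg$n_heads)
  a <- ad_dropout(a, cfg$dropout, train)
  h <- ad_layernorm(ad_add(x, a), lay$ln1_g, lay$ln1_b)
  f <- if (cfg$use_iffn) iffn_node(h, lay$ffn, cfg) else ffn_node(h, lay$ffn)
  f <- ad_dropout(f, cfg$dropout, train)
  ad_layernorm(ad_add(h, f), lay$ln2_g, lay$ln2_b)
}

branch_forward_node <- function(bp, x, cfg, train = FALSE) {
  d <- dim(x$value)
  h <- ad_relu(ad_conv1d(x, bp$conv1W, bp$conv1b))
  h <- ad_relu(ad_conv1d(h, bp$conv2W, bp$conv2b))
  M <- multiscale_matrix(d[2L], cfg$pool_kernels, cfg$multiscale_merge)
  h <- ad_timemix(h, M)
  PE <- t(positional_encoding(d[2L], cfg$conv2_out))    # [C, T]
  h <- ad_add_bcast(h, array(PE, c(cfg$conv2_out, d[2L], 1L))[, , rep(1L, d[3L]), drop = FALSE])
  for (lay in bp$layers) h <- encoder_layer_node(h, lay, cfg, train)
  h
}

# ---- public forward wrappers -----------------------------------------------

with_tape <- function(expr) {
  had <- !is.null(.ad$tape)
  if (!had) ad_tape_start()
  on.exit(if (!had) ad_tape_clear())
  expr
}

#' Multi-scale CNN branch (forward pass)
#'
#' Two same-padded kernel-3 convolutions with ReLU raise the channel count
#' to 128 while preserving the timestep count; average-pooled copies at the
#' configured kernel lengths (clamped to the sequence length) are upsampled
#' by nearest-neighbor repetition and averaged with the unpooled map.
#'
#' @param x input array `[n, in_channels, T]`.
#' @param params branch parameters from [ictd_model()] (one view's
#'   `$params$view1` / `$view2`), or NULL to initialize fresh seeded ones.
#' @param cfg a [model_config()].
#' @param seed seed used when `params` is NULL.
#' @return array `[n, conv2_out, T]`.
#' @export
multiscale_cnn_branch <- function(x, params = NULL, cfg = model_config(),
                                  seed = 1L) {
  d <- dim(x)
  if (d[2L] != cfg$in_channels)
    stop(sprintf("input has %d channels but cfg$in_channels = %d", d[2L],
                 cfg$in_channels), call. = FALSE)
  if (is.null(params))
    params <- withr::with_seed(seed, init_branch_params(cfg, d[2L]))
  with_tape({
    h <- ad_relu(ad_conv1d(ad_const(to_ctn(x)), params$conv1W, params$conv1b))
    h <- ad_relu(ad_conv1d(h, params$conv2W, params$conv2b))
    M <- multiscale_matrix(d[3L], cfg$pool_kernels, cfg$multiscale_merge)
    to_nct(ad_timemix(h, M)$value)
  })
}

#' Partial convolution over leading channels
#'
#' Applies a same-padded 1-D convolution to the first `ceil(ratio * C)`
#' channels and passes the remaining channels through untouched. With a
#' validity `mask` (length-T logical, or `n x T` matrix), convolution inputs
#' are restricted to the valid region: outputs are renormalized by the
#' fraction of valid entries under the kernel and positions with no valid
#' input are zeroed.
#'
#' @param x input array `[n, C, T]`.
#' @param weights list with `W` (`cp x cp x K` kernel, odd K) and optional
#'   `b`; NULL initializes seeded random weights.
#' @param ratio fraction of leading channels convolved, in (0, 1].
#' @param mask optional validity mask over time.
#' @param seed seed used when `weights` is NULL.
#' @return array `[n, C, T]`.
#' @export
partial_conv <- function(x, weights = NULL, ratio = 0.25, mask = NULL,
                         seed = 1L) {
  d <- dim(x)
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]", call. = FALSE)
  cp <- ceiling(ratio * d[2L])
  if (is.null(weights)) {
    weights <- withr::with_seed(seed, list(W = glorot(cp, cp, 3L),
                                           b = numeric(cp)))
  }
  K <- dim(weights$W)[3L]
  if (K > 2L * d[3L]) stop("kernel larger than twice the sequence length",
                           call. = FALSE)
  if (is.null(mask)) {
    m <- matrix(1, d[1L], d[3L])
  } else {
    m <- if (is.matrix(mask)) mask * 1 else
      matrix(as.numeric(mask), d[1L], d[3L], byrow = TRUE)
  }
  xm <- x
  for (c in seq_len(cp)) xm[, c, ] <- x[, c, ] * m
  out <- x
  num <- with_tape(ad_conv1d(ad_const(to_ctn(xm[, seq_len(cp), , drop = FALSE])),
                             ad_const(weights$W), NULL)$value)
  num <- to_nct(num)
  # count of valid inputs under the kernel per (sample, time); out-of-range
  # taps behave like ordinary zero padding (counted valid), so an all-valid
  # mask reproduces plain same-padded convolution exactly
  cnt <- matrix(cp * K, d[1L], d[3L])
  half <- (K - 1L) %/% 2L
  for (off in -half:half) {
    tt <- seq_len(d[3L]) + off
    okt <- tt >= 1L & tt <= d[3L]
    cnt[, okt] <- cnt[, okt] - cp * (1 - m[, tt[okt], drop = FALSE])
  }
  all_invalid <- matrix(rowSums(matrix(m, d[1L], d[3L])) == 0, d[1L], d[3L])
  scalef <- ifelse(all_invalid | cnt <= 0, 0, (cp * K) / cnt)
  for (c in seq_len(cp)) {
    out[, c, ] <- num[, c, ] * scalef
    if (!is.null(weights$b)) out[, c, ] <- out[, c, ] +
        ifelse(cnt > 0, weights$b[c], 0)
  }
  out
}

#' Initialize IFFN weights
#'
#' @param d channel width (even; 128 in the reference configuration).
#' @param cfg a [model_config()] providing `pconv_ratio` and `conv_kernel`.
#' @param seed seed for the random draws.
#' @return list of weight arrays (`pcW`, `pcb`, `W1`, `b1`, `gw`, `gb`,
#'   `W2`, `b2`).
#' @export
iffn_weights <- function(d = 128L, cfg = model_config(), seed = 1L) {
  cp <- ceiling(cfg$pconv_ratio * d)
  half <- d %/% 2L
  withr::with_seed(seed, list(
    pcW = glorot(cp, cp, cfg$conv_kernel), pcb = numeric(cp),
    W1 = glorot(d, d)[, , 1L], b1 = numeric(d),
    gw = matrix(stats::rnorm(half * cfg$conv_kernel,
                             sd = 1 / sqrt(cfg$conv_kernel)),
                half, cfg$conv_kernel),
    gb = numeric(half),
    W2 = glorot(d, d)[, , 1L], b2 = numeric(d)))
}

#' Incremental feature feedforward network (forward pass)
#'
#' `u = GELU(W1 PConv(x))`; `u` splits into channel halves `(u1, u2)`;
#' `r = u1 * DepthwiseConv(u2)` (elementwise gate); the gated product is
#' concatenated with the gate branch to restore the full width, then
#' `out = GELU(W2 [r; u2])`. Shape-preserving.
#'
#' @param x_hat input array `[n, d, T]`, even `d`.
#' @param w IFFN weights as plain arrays (see [iffn_weights()]).
#' @param cfg a [model_config()].
#' @return array `[n, d, T]`.
#' @export
iffn <- function(x_hat, w, cfg = model_config()) {
  d <- dim(x_hat)
  if (d[2L] %% 2L != 0L) stop("IFFN needs an even channel count", call. = FALSE)
  fw <- lapply(w, ad_const)
  with_tape(to_nct(iffn_node(ad_const(to_ctn(x_hat)), fw, cfg)$value))
}

#' Transformer encoder block stack (forward pass)
#'
#' Adds the sinusoidal positional encoding, then applies `n_layers` blocks
#' of multi-head self-attention and IFFN, each with residual connection and
#' layer normalization. In evaluation mode (`train = FALSE`) dropout is
#' disabled and the map is deterministic.
#'
#' @param x input array `[n, conv2_out, T]`.
#' @param params branch parameters (from [ictd_model()]), or NULL for fresh
#'   seeded ones.
#' @param cfg a [model_config()].
#' @param train enable dropout.
#' @param add_positions add the positional encoding before the blocks.
#' @param seed seed used when `params` is NULL.
#' @return array `[n, conv2_out, T]`.
#' @export
encoder_block <- function(x, params = NULL, cfg = model_config(),
                          train = FALSE, add_positions = TRUE, seed = 1L) {
  d <- dim(x)
  if (d[2L] %% cfg$n_heads != 0L)
    stop("channel count not divisible by n_heads", call. = FALSE)
  if (is.null(params))
    params <- withr::with_seed(seed, init_branch_params(cfg, cfg$in_channels))
  with_tape({
    h <- ad_const(to_ctn(x))
    if (add_positions) {
      PE <- t(positional_encoding(d[3L], d[2L]))
      h <- ad_add_bcast(h, array(PE, c(d[2L], d[3L], 1L))[, , rep(1L, d[1L]),
                                                          drop = FALSE])
    }
    for (lay in params$layers) h <- encoder_layer_node(h, lay, cfg, train)
    to_nct(h$value)
  })
}

#' Softmax classifier head
#'
#' Computes `softmax(ml %*% Wy + b)` row-wise with max-subtraction for
#' numerical stability; rows sum to one and survive logits of large
#' magnitude.
#'
#' @param ml fused representation, `n x d_fused` matrix.
#' @param Wy weight matrix `d_fused x C`, `C >= 2`.
#' @param b optional bias (length C).
#' @return `n x C` probability matrix.
#' @export
classify <- function(ml, Wy, b = NULL) {
  ml <- as.matrix(ml); Wy <- as.matrix(Wy)
  if (ncol(Wy) < 2L) stop("classifier needs C >= 2 classes", call. = FALSE)
  L <- ml %*% Wy
  if (!is.null(b)) L <- sweep(L, 2L, b, "+")
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}
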