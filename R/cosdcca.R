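# Cosine-similarity deep canonical correlation analysis: centering, the
# matrix (Frobenius) cosine objective, its exact and as-printed gradients,
# the training loss, projection networks, and a closed-form linear CCA
# oracle used for testing and calibration.
#
# Convention: samples are rows (n x o) throughout the public API.

#' Center two projected views
#'
#' Subtracts the per-dimension sample mean from each view so centered
#' columns have mean zero.
#'
#' @param H1p,H2p numeric matrices, samples as rows (n x o), same shape.
#' @return list `H1c`, `H2c` of centered matrices.
#' @export
center_views <- function(H1p, H2p) {
  H1p <- as.matrix(H1p); H2p <- as.matrix(H2p)
  if (nrow(H1p) < 2L) stop("centering needs n >= 2 samples", call. = FALSE)
  if (!all(dim(H1p) == dim(H2p)))
    stop("views must have identical shape", call. = FALSE)
  list(H1c = sweep(H1p, 2L, colMeans(H1p)),
       H2c = sweep(H2p, 2L, colMeans(H2p)))
}

#' Cosine similarity of one projected sample pair
#'
#' @param h1,h2 nonzero numeric vectors of equal length.
#' @param eps optional nonnegative guard added to each norm (training mode);
#'   the default 0 errors on zero vectors (strict library mode).
#' @return cosine in `[-1, 1]`.
#' @export
pairwise_cosine <- function(h1, h2, eps = 0) {
  n1 <- sqrt(sum(h1^2)); n2 <- sqrt(sum(h2^2))
  if (eps == 0 && (n1 == 0 || n2 == 0))
    stop("cosine of a zero vector is undefined", call. = FALSE)
  sum(h1 * h2) / ((n1 + eps) * (n2 + eps))
}

#' Matrix cosine objective between centered views
#'
#' `J = trace(H1c' H2c) / (||H1c||_F ||H2c||_F)`: the cosine between the two
#' matrices flattened to vectors. Scale-invariant in each view and bounded
#' in `[-1, 1]`. With `form = "mean_pairwise"` the per-sample mean cosine
#' `1/n sum_i cos(h1_i, h2_i)` is returned instead (the two quantities are
#' distinct in general).
#'
#' @param H1c,H2c centered views, samples as rows.
#' @param form `"frobenius"` (canonical) or `"mean_pairwise"`.
#' @param eps nonnegative norm guard; 0 = strict (error on zero view).
#' @return scalar objective J.
#' @export
matrix_cosine_objective <- function(H1c, H2c, form = c("frobenius", "mean_pairwise"),
                                    eps = 0) {
  form <- match.arg(form)
  H1c <- as.matrix(H1c); H2c <- as.matrix(H2c)
  if (form == "mean_pairwise") {
    return(mean(vapply(seq_len(nrow(H1c)), function(i)
      pairwise_cosine(H1c[i, ], H2c[i, ], eps = eps), numeric(1))))
  }
  n1 <- sqrt(sum(H1c^2)); n2 <- sqrt(sum(H2c^2))
  if (eps == 0 && (n1 == 0 || n2 == 0))
    stop("objective undefined for an all-zero view", call. = FALSE)
  sum(H1c * H2c) / ((n1 + eps) * (n2 + eps))
}

#' Gradient of the matrix cosine objective
#'
#' The exact gradient of `J` with respect to each centered view is
#' `dJ/dH1c = H2c / (||H1c||_F ||H2c||_F) - J * H1c / ||H1c||_F^2`
#' (symmetrically for `H2c`). The `as_printed` form keeps only the first
#' term; the two coincide exactly when `J = 0` and diverge as `|J|` grows
#' (at `J = 1` the exact gradient vanishes by stationarity while the
#' printed form does not).
#'
#' @param H1c,H2c centered views, samples as rows.
#' @param form `"exact"` (default, used in training) or `"as_printed"`.
#' @return list `dH1`, `dH2` of gradient matrices.
#' @export
objective_gradient <- function(H1c, H2c, form = c("exact", "as_printed")) {
  form <- match.arg(form)
  H1c <- as.matrix(H1c); H2c <- as.matrix(H2c)
  n1 <- sqrt(sum(H1c^2)); n2 <- sqrt(sum(H2c^2))
  if (n1 == 0 || n2 == 0)
    stop("gradient undefined for an all-zero view", call. = FALSE)
  if (form == "as_printed") {
    return(list(dH1 = H2c / (n1 * n2), dH2 = H1c / (n1 * n2)))
  }
  J <- sum(H1c * H2c) / (n1 * n2)
  list(dH1 = H2c / (n1 * n2) - J * H1c / n1^2,
       dH2 = H1c / (n1 * n2) - J * H2c / n2^2)
}

#' Cosine-similarity DCCA loss
#'
#' Centers the projected views and returns `-J`, so that minimizing the
#' joint training loss maximizes the cross-view cosine similarity.
#'
#' @param H1p,H2p projected views, samples as rows (n x o), n >= 2.
#' @param eps nonnegative norm guard (0 = strict).
#' @return scalar loss in `[-1, 1]`.
#' @export
cos_dcca_loss <- function(H1p, H2p, eps = 0) {
  cv <- center_views(H1p, H2p)
  -matrix_cosine_objective(cv$H1c, cv$H2c, eps = eps)
}

# ---- closed-form linear CCA oracle -----------------------------------------

#' Closed-form linear canonical correlation analysis
#'
#' Classical CCA via the whitened cross-covariance SVD:
#' `T = S11^{-1/2} S12 S22^{-1/2}`, whose singular values are the canonical
#' correlations. Covariance diagonals are regularized with a small ridge.
#' This is the linear specialization that the deep projections should
#' approach; it serves as the package's independent oracle.
#'
#' @param X1,X2 data matrices, samples as rows (`n > max(d1, d2)`).
#' @param k number of canonical pairs to return.
#' @param ridge ridge added to the covariance diagonals (default 1e-8).
#' @return list with `correlations` (length k, descending, clipped to
#'   `[0, 1]`), `A`, `B` (projection bases, columns are directions).
#' @export
linear_cca_oracle <- function(X1, X2, k = 1L, ridge = 1e-8) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n <- nrow(X1)
  if (n <= max(ncol(X1), ncol(X2)))
    stop("need more samples than the larger view dimension", call. = FALSE)
  X1c <- sweep(X1, 2L, colMeans(X1))
  X2c <- sweep(X2, 2L, colMeans(X2))
  S11 <- crossprod(X1c) / (n - 1) + diag(ridge, ncol(X1))
  S22 <- crossprod(X2c) / (n - 1) + diag(ridge, ncol(X2))
  S12 <- crossprod(X1c, X2c) / (n - 1)
  isq <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    if (any(e$values <= 0))
      stop("rank-deficient view; increase ridge", call. = FALSE)
    e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
  }
  W1 <- isq(S11); W2 <- isq(S22)
  sv <- svd(W1 %*% S12 %*% W2)
  k <- min(k, length(sv$d))
  list(correlations = pmin(pmax(sv$d[seq_len(k)], 0), 1),
       A = W1 %*% sv$u[, seq_len(k), drop = FALSE],
       B = W2 %*% sv$v[, seq_len(k), drop = FALSE])
}

# ---- projection networks ---------------------------------------------------

#' Build a pair of projection networks
#'
#' Two multilayer perceptrons `d_in -> hidden1 -> hidden2 -> o` (defaults
#' 64 and 128) mapping each view into a shared `o`-dimensional space. With
#' `nonlinearity = "identity"` the composition is linear and the trained
#' projections should approach the linear CCA oracle.
#'
#' @param d_in1,d_in2 input dimensions of the two views.
#' @param o shared output dimension.
#' @param hidden1,hidden2 hidden widths.
#' @param nonlinearity `"identity"`, `"relu"` or `"tanh"`.
#' @param seed seed for the Glorot-style initialization.
#' @return object of class `projection_nets`.
#' @export
projection_nets <- function(d_in1, d_in2, o = 1L, hidden1 = 64L,
                            hidden2 = 128L, nonlinearity = "identity",
                            seed = 1L) {
  stopifnot(o >= 1L)
  make_net <- function(d_in) {
    dims <- c(d_in, hidden1, hidden2, o)
    lapply(seq_len(length(dims) - 1L), function(i) {
      s <- sqrt(2 / (dims[i] + dims[i + 1L]))
      list(W = ad_param(matrix(stats::rnorm(dims[i + 1L] * dims[i], sd = s),
                               dims[i + 1L], dims[i])),
           b = ad_param(numeric(dims[i + 1L])))
    })
  }
  withr::with_seed(seed, {
    structure(list(net1 = make_net(d_in1), net2 = make_net(d_in2),
                   nonlinearity = nonlinearity, o = as.integer(o)),
              class = "projection_nets")
  })
}

proj_forward <- function(net, X, nonlinearity) {
  # X: n x d -> node [o, 1, n]
  h <- ad_const(array(t(X), c(ncol(X), 1L, nrow(X))))
  act <- switch(nonlinearity,
                identity = function(z) z,
                relu = ad_relu,
                tanh = function(z) ad_node(tanh(z$value), function(g)
                  acc_grad(z, g * (1 - tanh(z$value)^2))))
  for (i in seq_along(net)) {
    h <- ad_lin(h, net[[i]]$W, net[[i]]$b)
    if (i < length(net)) h <- act(h)
  }
  h
}

#' Train projection networks on the cos-DCCA objective
#'
#' Full-batch Adam ascent on the matrix cosine objective J between the two
#' projected views (implemented as descent on `-J`).
#'
#' @param nets a [projection_nets()] pair.
#' @param X1,X2 view matrices, samples as rows.
#' @param steps number of Adam steps.
#' @param lr learning rate.
#' @return the trained nets, with `$history` (J per step) attached.
#' @export
fit_projection_nets <- function(nets, X1, X2, steps = 500L, lr = 0.01) {
  params <- c(unlist(nets$net1, recursive = FALSE),
              unlist(nets$net2, recursive = FALSE))
  names(params) <- NULL
  st <- adam_state(params)
  hist <- numeric(steps)
  for (s in seq_len(steps)) {
    ad_tape_start()
    zero_grads(params)
    H1 <- proj_forward(nets$net1, X1, nets$nonlinearity)
    H2 <- proj_forward(nets$net2, X2, nets$nonlinearity)
    H1m <- ad_reshape(H1, c(nets$o, nrow(X1)))
    H2m <- ad_reshape(H2, c(nets$o, nrow(X2)))
    loss <- ad_cosdcca(H1m, H2m, eps = 1e-12)
    ad_backward(loss)
    st <- adam_step(params, st, lr)
    hist[s] <- loss$J
    ad_tape_clear()
  }
  nets$history <- hist
  nets
}

#' Project both views through trained projection nets
#'
#' @param nets trained [projection_nets()].
#' @param X1,X2 view matrices, samples as rows.
#' @return list `H1p`, `H2p` of n x o projections.
#' @export
project_views <- function(nets, X1, X2) {
  ad_tape_start()
  H1 <- proj_forward(nets$net1, X1, nets$nonlinearity)
  H2 <- proj_forward(nets$net2, X2, nets$nonlinearity)
  out <- list(H1p = t(matrix(H1$value, nets$o, nrow(X1))),
              H2p = t(matrix(H2$value, nets$o, nrow(X2))))
  ad_tape_clear()
  out
}
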