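# Positional encoding, CNN branch, partial convolution, IFFN, encoder
# blocks, classifier head, and backward-pass correctness of the autodiff
# layers they are built from.

test_that("positional encoding matches its definition", {
  PE <- positional_encoding(5L, 4L)
  expect_equal(PE[1L, ], c(0, 1, 0, 1))                   # position 0
  expect_equal(PE[2L, 1:2], c(sin(1), cos(1)))            # pos 1, i = 0
  expect_equal(PE[2L, 3:4], c(sin(1 / 100), cos(1 / 100)))
  pairs <- PE[, c(1, 3)]^2 + PE[, c(2, 4)]^2
  expect_equal(pairs, matrix(1, 5, 2))
  expect_error(positional_encoding(3L, 5L), "even")
})

test_that("multi-scale CNN branch preserves timesteps and lifts channels", {
  cfg <- model_config(in_channels = 5L)
  x <- array(stats::rnorm(2 * 5 * 600), c(2, 5, 600))
  out <- multiscale_cnn_branch(x, cfg = cfg, seed = 4L)
  expect_equal(dim(out), c(2L, 128L, 600L))
  expect_error(multiscale_cnn_branch(array(0, c(2, 4, 10)), cfg = cfg),
               "channels")
})

test_that("multi-scale merge is the identity on constant maps and at T = 1", {
  M <- ictd:::multiscale_matrix(20L, c(4L, 8L, 64L))
  expect_equal(rowSums(M), rep(1, 20))          # constant input unchanged
  expect_equal(M %*% rep(3.5, 20), matrix(3.5, 20, 1))
  expect_equal(ictd:::multiscale_matrix(1L, c(8L, 16L)), diag(1L))
})

test_that("partial convolution touches only the leading channel block", {
  x <- array(stats::rnorm(3 * 8 * 10), c(3, 8, 10))
  out <- partial_conv(x, ratio = 0.25, seed = 2L)      # cp = 2
  expect_identical(out[, 3:8, ], x[, 3:8, ])
  expect_false(isTRUE(all.equal(out[, 1:2, ], x[, 1:2, ])))
  # identity kernel on a single channel reproduces the input
  x1 <- array(stats::rnorm(1 * 1 * 12), c(1, 1, 12))
  w <- list(W = array(c(0, 1, 0), c(1, 1, 3)), b = 0)
  expect_equal(partial_conv(x1, w, ratio = 1), x1)
  # ratio 1 with all-valid mask equals ordinary convolution
  xc <- array(stats::rnorm(2 * 4 * 6), c(2, 4, 6))
  wf <- list(W = array(stats::rnorm(4 * 4 * 3), c(4, 4, 3)), b = rep(0, 4))
  full <- partial_conv(xc, wf, ratio = 1, mask = rep(TRUE, 6))
  plain <- partial_conv(xc, wf, ratio = 1)
  expect_equal(full, plain, tolerance = 1e-12)
  expect_error(partial_conv(array(0, c(1, 2, 2)),
                            list(W = array(1, c(1, 1, 5))), ratio = 0.5),
               "kernel")
})

test_that("masked partial convolution renormalizes and zeroes dead regions", {
  x <- array(1, c(1, 1, 10))
  w <- list(W = array(1 / 3, c(1, 1, 3)), b = 0)
  mask <- rep(TRUE, 10); mask[5] <- FALSE
  out <- partial_conv(x, w, ratio = 1, mask = mask)
  # interior positions away from the hole: plain average of ones = 1; edges
  # see ordinary zero padding (2/3), matching plain same-padded convolution
  expect_equal(as.vector(out)[c(2, 3, 8, 9)], rep(1, 4))
  expect_equal(as.vector(out)[c(1, 10)], c(2 / 3, 2 / 3))
  # neighbors of the hole: 2 valid of 3 under the kernel, renormalized to 1
  expect_equal(as.vector(out)[c(4, 6)], c(1, 1))
  none <- partial_conv(x, w, ratio = 1, mask = rep(FALSE, 10))
  expect_equal(as.vector(none), rep(0, 10))
})

test_that("IFFN: zero fixed point, shape preservation, hand-checked example", {
  cfg <- model_config(in_channels = 4L, conv2_out = 4L, n_heads = 2L,
                      pconv_ratio = 0.25)
  w0 <- iffn_weights(4L, cfg, seed = 1L)
  w0$pcb <- 0 * w0$pcb; w0$b1 <- 0 * w0$b1
  w0$gb <- 0 * w0$gb; w0$b2 <- 0 * w0$b2
  z <- array(0, c(2, 4, 3))
  expect_equal(iffn(z, w0, cfg), z)
  x <- array(stats::rnorm(2 * 4 * 3), c(2, 4, 3))
  expect_equal(dim(iffn(x, iffn_weights(4L, cfg, seed = 2L), cfg)),
               c(2L, 4L, 3L))
  # identity weights: u = GELU(1); r = u^2 on the gated half
  wid <- list(pcW = array(c(0, 1, 0), c(1, 1, 3)), pcb = 0,
              W1 = diag(4), b1 = rep(0, 4),
              gw = matrix(c(0, 1, 0), 2, 3, byrow = TRUE), gb = rep(0, 2),
              W2 = diag(4), b2 = rep(0, 4))
  out <- iffn(array(1, c(1, 4, 1)), wid, cfg)
  g <- 1 * stats::pnorm(1)
  gl <- function(v) v * stats::pnorm(v)
  expect_equal(as.vector(out), c(gl(g^2), gl(g^2), gl(g), gl(g)),
               tolerance = 1e-12)
  expect_error(iffn(array(0, c(1, 5, 2)), wid, cfg), "even")
})

test_that("encoder blocks are deterministic in eval mode and preserve shape", {
  cfg <- model_config(in_channels = 8L, conv1_out = 8L, conv2_out = 8L,
                      n_heads = 2L, pool_kernels = c(2L, 4L))
  params <- withr::with_seed(5L, ictd:::init_branch_params(cfg, 8L))
  x <- array(stats::rnorm(2 * 8 * 3), c(2, 8, 3))
  y1 <- encoder_block(x, params, cfg, train = FALSE)
  y2 <- encoder_block(x, params, cfg, train = FALSE)
  expect_identical(y1, y2)
  expect_equal(dim(y1), dim(x))
  expect_error(encoder_block(array(0, c(1, 9, 2)), params,
                             model_config(n_heads = 8L, conv2_out = 128L)),
               "divisible")
})

test_that("self-attention without positions is permutation-equivariant", {
  C <- 8L; T <- 3L; n <- 2L
  withr::with_seed(6L, {
    Ws <- replicate(4, ad_param(matrix(stats::rnorm(C * C, sd = 0.3), C, C)),
                    simplify = FALSE)
    bs <- replicate(4, ad_param(stats::rnorm(C, sd = 0.1)), simplify = FALSE)
    x <- array(stats::rnorm(C * T * n), c(C, T, n))
  })
  run <- function(xv) {
    ad_tape_start()
    on.exit(ad_tape_clear())
    ad_mhsa(ad_const(xv), Ws[[1]], Ws[[2]], Ws[[3]], Ws[[4]],
            bs[[1]], bs[[2]], bs[[3]], bs[[4]], n_heads = 2L)$value
  }
  y <- run(x)
  perm <- c(3L, 1L, 2L)
  y_perm <- run(x[, perm, , drop = FALSE])
  expect_equal(y_perm, y[, perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("attention backward matches finite differences at T > 1", {
  C <- 4L; T <- 3L; n <- 2L
  withr::with_seed(7L, {
    Ws <- replicate(4, ad_param(matrix(stats::rnorm(C * C, sd = 0.5), C, C)),
                    simplify = FALSE)
    bs <- replicate(4, ad_param(stats::rnorm(C, sd = 0.1)), simplify = FALSE)
    xv <- array(stats::rnorm(C * T * n), c(C, T, n))
    wts <- array(stats::rnorm(C * T * n), c(C, T, n))
  })
  fwd <- function(xval) {
    ad_tape_start()
    on.exit(ad_tape_clear())
    out <- ad_mhsa(ad_const(xval), Ws[[1]], Ws[[2]], Ws[[3]], Ws[[4]],
                   bs[[1]], bs[[2]], bs[[3]], bs[[4]], n_heads = 2L)
    sum(out$value * wts)
  }
  ad_tape_start()
  xn <- ad_param(xv)
  out <- ad_mhsa(xn, Ws[[1]], Ws[[2]], Ws[[3]], Ws[[4]],
                 bs[[1]], bs[[2]], bs[[3]], bs[[4]], n_heads = 2L)
  loss <- ictd:::ad_node(sum(out$value * wts),
                         function(g) ictd:::acc_grad(out, g * wts))
  ad_backward(loss)
  ad_tape_clear()
  h <- 1e-6
  for (idx in c(1L, 5L, 13L, 24L)) {
    E <- array(0, c(C, T, n)); E[idx] <- h
    fd <- (fwd(xv + E) - fwd(xv - E)) / (2 * h)
    expect_lt(abs(xn$grad[idx] - fd), 1e-6)
  }
})

test_that("conv, depthwise conv and layer norm backward pass finite differences", {
  withr::with_seed(9L, {
    x <- array(stats::rnorm(3 * 5 * 2), c(3, 5, 2))
    W <- array(stats::rnorm(4 * 3 * 3, sd = 0.5), c(4, 3, 3))
    b <- stats::rnorm(4, sd = 0.1)
    wts <- array(stats::rnorm(4 * 5 * 2), c(4, 5, 2))
  })
  fwd <- function(xval) {
    ad_tape_start(); on.exit(ad_tape_clear())
    sum(ad_conv1d(ad_const(xval), ad_const(W), ad_const(b))$value * wts)
  }
  ad_tape_start()
  xn <- ad_param(x)
  out <- ad_conv1d(xn, ad_const(W), ad_const(b))
  loss <- ictd:::ad_node(sum(out$value * wts),
                         function(g) ictd:::acc_grad(out, g * wts))
  ad_backward(loss); ad_tape_clear()
  h <- 1e-6
  for (idx in c(2L, 11L, 28L)) {
    E <- array(0, dim(x)); E[idx] <- h
    expect_lt(abs(xn$grad[idx] - (fwd(x + E) - fwd(x - E)) / (2 * h)), 1e-6)
  }
  # layer norm
  withr::with_seed(10L, {
    g_par <- stats::rnorm(3, sd = 0.2) + 1
    b_par <- stats::rnorm(3, sd = 0.2)
    wl <- array(stats::rnorm(3 * 5 * 2), c(3, 5, 2))
  })
  fwd_ln <- function(xval) {
    ad_tape_start(); on.exit(ad_tape_clear())
    sum(ad_layernorm(ad_const(xval), ad_const(g_par), ad_const(b_par))$value * wl)
  }
  ad_tape_start()
  xn2 <- ad_param(x)
  out2 <- ad_layernorm(xn2, ad_const(g_par), ad_const(b_par))
  loss2 <- ictd:::ad_node(sum(out2$value * wl),
                          function(g) ictd:::acc_grad(out2, g * wl))
  ad_backward(loss2); ad_tape_clear()
  for (idx in c(3L, 17L, 25L)) {
    E <- array(0, dim(x)); E[idx] <- h
    expect_lt(abs(xn2$grad[idx] - (fwd_ln(x + E) - fwd_ln(x - E)) / (2 * h)),
              1e-5)
  }
})

test_that("classifier head is a stable softmax", {
  P <- classify(matrix(0, 3, 2), diag(2))
  expect_equal(P, matrix(0.5, 3, 2))
  big <- classify(matrix(c(1000, 0), 1, 2), diag(2))
  expect_true(all(is.finite(big)))
  expect_equal(big[1, 1], 1, tolerance = 1e-12)
  P3 <- classify(matrix(c(1, 2, 3), 1, 3), diag(3))
  expect_equal(as.vector(P3), exp(1:3) / sum(exp(1:3)), tolerance = 1e-12)
  withr::with_seed(11L, {
    L <- matrix(stats::rnorm(40, sd = 5), 10, 4)
    P4 <- classify(L, diag(4))
    expect_equal(rowSums(P4), rep(1, 10), tolerance = 1e-6)
    expect_true(all(P4 > 0 & P4 < 1))
  })
  expect_error(classify(matrix(1, 2, 1), matrix(1, 1, 1)), "classes")
})

test_that("parameter count is finite and architecture-deterministic", {
  m1 <- ictd_model(16L, 8L, 4L, tiny_model_cfg(), seed = 1L)
  m2 <- ictd_model(16L, 8L, 4L, tiny_model_cfg(), seed = 99L)
  expect_identical(n_parameters(m1), n_parameters(m2))
  expect_true(is.finite(n_parameters(m1)) && n_parameters(m1) > 0)
})
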