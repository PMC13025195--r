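# Centering, cosine objective, gradients, loss sign, and the linear CCA
# oracle.

test_that("centering subtracts per-dimension means and is idempotent", {
  M <- matrix(c(1, 2, 3, 6, 2, 2, 2, 2), 4, 2)
  cv <- center_views(M, M)
  expect_equal(cv$H1c[, 1L], c(-2, -1, 0, 3))
  expect_equal(cv$H1c[, 2L], rep(0, 4))
  expect_equal(center_views(cv$H1c, cv$H2c)$H1c, cv$H1c)
  const <- matrix(rep(c(1, 2), each = 4), 4, 2)
  expect_equal(center_views(const, const)$H1c, matrix(0, 4, 2))
  expect_error(center_views(matrix(1, 1, 2), matrix(1, 1, 2)), "n >= 2")
})

test_that("pairwise cosine: identical, orthogonal, worked example, zero", {
  expect_equal(pairwise_cosine(c(1, 2), c(1, 2)), 1)
  expect_equal(pairwise_cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(pairwise_cosine(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(pairwise_cosine(c(0, 0), c(1, 1)), "zero vector")
})

test_that("matrix objective equals the flattened-vector cosine", {
  expect_equal(matrix_cosine_objective(diag(2), rbind(c(1, 0), c(0, 0))),
               1 / sqrt(2))
  withr::with_seed(1L, {
    for (i in 1:20) {
      A <- matrix(stats::rnorm(15), 5, 3)
      B <- matrix(stats::rnorm(15), 5, 3)
      J <- matrix_cosine_objective(A, B)
      expect_equal(J, sum(A * B) / sqrt(sum(A^2) * sum(B^2)),
                   tolerance = 1e-14)
      expect_true(J >= -1 && J <= 1)
      # scale invariance under positive rescaling of either view
      expect_equal(matrix_cosine_objective(37 * A, 0.004 * B), J,
                   tolerance = 1e-12)
    }
  })
  A <- matrix(stats::rnorm(8), 4, 2)
  expect_equal(matrix_cosine_objective(A, A), 1)
  expect_equal(matrix_cosine_objective(A, -A), -1)
  expect_error(matrix_cosine_objective(matrix(0, 3, 2), A[1:3, ]),
               "all-zero")
})

test_that("mean-pairwise form differs from the Frobenius form in general", {
  A <- rbind(c(1, 0), c(0, 1))
  B <- rbind(c(1, 0), c(1, 0))
  expect_equal(matrix_cosine_objective(A, B, form = "mean_pairwise"), 0.5)
  expect_equal(matrix_cosine_objective(A, B), 1 / 2)
  A2 <- rbind(c(2, 0), c(0, 1))
  expect_false(isTRUE(all.equal(
    matrix_cosine_objective(A2, B, form = "mean_pairwise"),
    matrix_cosine_objective(A2, B))))
})

test_that("exact gradient passes finite differences; printed form diverges at J = 1", {
  withr::with_seed(2L, {
    for (i in 1:10) {
      A <- matrix(stats::rnorm(12), 4, 3)
      B <- matrix(stats::rnorm(12), 4, 3)
      g <- objective_gradient(A, B)
      h <- 1e-6
      for (idx in sample(12, 4)) {
        E <- matrix(0, 4, 3); E[idx] <- h
        fd <- (matrix_cosine_objective(A + E, B) -
                 matrix_cosine_objective(A - E, B)) / (2 * h)
        expect_lt(abs(g$dH1[idx] - fd), 1e-5 * max(abs(fd), 1e-3))
      }
    }
  })
  # orthogonal views (J = 0): printed form equals the exact gradient
  A <- rbind(c(1, 0), c(-1, 0)); B <- rbind(c(0, 1), c(0, -1))
  expect_equal(matrix_cosine_objective(A, B), 0)
  expect_equal(objective_gradient(A, B, "exact"),
               objective_gradient(A, B, "as_printed"))
  # identical views (J = 1): exact gradient vanishes, printed form does not
  g1 <- objective_gradient(A, A, "exact")
  expect_lt(max(abs(g1$dH1)), 1e-12)
  g2 <- objective_gradient(A, A, "as_printed")
  expect_gt(max(abs(g2$dH1)), 0.1)
  expect_error(objective_gradient(matrix(0, 2, 2), A), "all-zero")
})

test_that("loss is the negated objective with centering built in", {
  A <- matrix(stats::rnorm(10), 5, 2)
  expect_equal(cos_dcca_loss(A, A), -1)
  Ac <- sweep(A, 2, colMeans(A))
  expect_equal(cos_dcca_loss(Ac, -Ac), 1)
  H1 <- diag(2); H2 <- rbind(c(1, 0), c(0, 0))
  # inputs treated as pre-centered up to the loss's own centering
  expect_equal(cos_dcca_loss(rbind(H1, -H1), rbind(H2, -H2)), -1 / sqrt(2))
})

test_that("linear CCA oracle: identity, null and shared-latent cases", {
  withr::with_seed(3L, {
    X <- matrix(stats::rnorm(300), 100, 3)
    r <- linear_cca_oracle(X, X, k = 3L)
    expect_true(all(abs(r$correlations - 1) < 1e-6))
    X1 <- matrix(stats::rnorm(15000), 5000, 3)
    X2 <- matrix(stats::rnorm(15000), 5000, 3)
    expect_lt(linear_cca_oracle(X1, X2, k = 1L)$correlations, 0.1)
    z <- stats::rnorm(10000)
    Y1 <- matrix(z + stats::rnorm(10000), ncol = 1L)
    Y2 <- matrix(z + stats::rnorm(10000), ncol = 1L)
    expect_lt(abs(linear_cca_oracle(Y1, Y2)$correlations - 0.5), 0.02)
  })
  expect_error(linear_cca_oracle(matrix(1, 2, 3), matrix(1, 2, 3)),
               "more samples")
})

test_that("per-sample cosine objective resists magnitude outliers better than Pearson", {
  pearson_obj <- function(A, B)
    mean(vapply(seq_len(ncol(A)), function(j) stats::cor(A[, j], B[, j]),
                numeric(1)))
  for (s in c(9L, 21L, 33L)) {
    withr::with_seed(s, {
      n <- 200L; o <- 5L
      H1 <- matrix(stats::rnorm(n * o), n, o)
      H2 <- 0.5 * H1 + sqrt(0.75) * matrix(stats::rnorm(n * o), n, o)
      # magnitude outlier: an existing paired sample rescaled 100x
      H1o <- rbind(H1, 100 * H1[1L, ])
      H2o <- rbind(H2, 100 * H2[1L, ])
      dJ <- abs(matrix_cosine_objective(H1o, H2o, form = "mean_pairwise") -
                  matrix_cosine_objective(H1, H2, form = "mean_pairwise"))
      dR <- abs(pearson_obj(H1o, H2o) - pearson_obj(H1, H2))
      expect_lt(dJ, dR)
    })
  }
})
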