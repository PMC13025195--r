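# The assembled ICTD network: one CNN + transformer-encoder branch per view
# (gaze, pupil), cosine-DCCA alignment between the pooled branch outputs,
# concatenation fusion, and a softmax classifier head.

#' Construct an ICTD model
#'
#' Initializes all parameters (seeded) for the dual-branch network. Trials
#' arriving as feature vectors are treated as single-timestep sequences of
#' `D` channels per view; the multi-scale path degenerates gracefully there
#' (all pool kernels clamp to length 1).
#'
#' @param d_in1,d_in2 feature dimensions of the gaze and pupil views.
#' @param n_classes number of emotion classes (>= 2).
#' @param cfg a [model_config()]; `in_channels` is overridden per view.
#' @param seed initialization seed.
#' @return object of class `ictd_model`.
#' @export
ictd_model <- function(d_in1, d_in2, n_classes, cfg = model_config(),
                       seed = 1L) {
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  withr::with_seed(seed, {
    view1 <- init_branch_params(cfg, d_in1)
    view2 <- init_branch_params(cfg, d_in2)
    fused <- 2L * cfg$conv2_out
    Wy <- ad_param(matrix(stats::rnorm(n_classes * fused,
                                       sd = sqrt(2 / (fused + n_classes))),
                          n_classes, fused))
    by <- ad_param(numeric(n_classes))
    structure(list(cfg = cfg, d_in1 = d_in1, d_in2 = d_in2,
                   n_classes = as.integer(n_classes),
                   params = list(view1 = view1, view2 = view2,
                                 Wy = Wy, by = by),
                   seed = as.integer(seed)),
              class = "ictd_model")
  })
}

model_param_list <- function(model) {
  c(branch_param_list(model$params$view1),
    branch_param_list(model$params$view2),
    list(model$params$Wy, model$params$by))
}

#' Number of trainable parameters
#' @param model an [ictd_model()].
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model_param_list(model), function(p) length(p$value), numeric(1)))
}

# forward through both branches; X1, X2 are n x d matrices (T = 1) or
# [n, d, T] arrays. Returns nodes: pooled h1, h2 ([C, n]) and probs/loss
# helpers are assembled by callers.
ictd_forward_nodes <- function(model, X1, X2, train = FALSE) {
  as_ctn <- function(X) {
    if (is.matrix(X)) array(t(X), c(ncol(X), 1L, nrow(X))) else to_ctn(X)
  }
  x1 <- ad_const(as_ctn(X1))
  x2 <- ad_const(as_ctn(X2))
  h1 <- branch_forward_node(model$params$view1, x1, model$cfg, train)
  h2 <- branch_forward_node(model$params$view2, x2, model$cfg, train)
  n <- dim(x1$value)[3L]
  p1 <- ad_reshape(ad_mean_time(h1), c(model$cfg$conv2_out, n))
  p2 <- ad_reshape(ad_mean_time(h2), c(model$cfg$conv2_out, n))
  list(h1 = p1, h2 = p2, n = n)
}

#' Forward pass of the ICTD network
#'
#' @param model an [ictd_model()].
#' @param X1,X2 gaze/pupil view matrices (`n x d`) or `[n, d, T]` arrays.
#' @param train enable dropout (training mode).
#' @return list with `probs` (`n x C`), `H1p`, `H2p` (`n x 128` pooled
#'   branch representations).
#' @export
ictd_forward <- function(model, X1, X2, train = FALSE) {
  ad_tape_start()
  on.exit(ad_tape_clear())
  fw <- ictd_forward_nodes(model, X1, X2, train)
  fused <- ad_concat2d(fw$h1, fw$h2)
  L <- model$params$Wy$value %*% fused$value + model$params$by$value
  L <- sweep(L, 2L, apply(L, 2L, max))
  E <- exp(L)
  P <- sweep(E, 2L, colSums(E), "/")
  list(probs = t(P), H1p = t(fw$h1$value), H2p = t(fw$h2$value))
}

# concat two [C, n] nodes along channels
ad_concat2d <- function(a, b) {
  Ca <- nrow(a$value); Cb <- nrow(b$value)
  ad_node(rbind(a$value, b$value), function(g) {
    acc_grad(a, g[seq_len(Ca), , drop = FALSE])
    acc_grad(b, g[Ca + seq_len(Cb), , drop = FALSE])
  })
}

#' Predict class labels
#' @param object an `ictd_model`.
#' @param X1,X2 view matrices.
#' @param ... unused.
#' @return integer labels in `0..C-1`.
#' @export
predict.ictd_model <- function(object, X1, X2, ...) {
  P <- ictd_forward(object, X1, X2, train = FALSE)$probs
  max.col(P, ties.method = "first") - 1L
}
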