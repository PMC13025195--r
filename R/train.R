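# Joint-loss training, subject-independent cross-validation, evaluation
# metrics, and the ablation harness.

#' Training configuration
#'
#' Defaults follow the reference setup: Adam with learning rate 5e-4 and
#' momentum pair (0.9, 0.999), batch size 128, weight decay 0.01, loss
#' weights `w1 = 0.1` (cross-entropy) and `w2 = 0.9` (cosine-DCCA,
#' `w1 + w2 = 1`), 5 folds, and a single x0.1 learning-rate step at half the
#' epoch budget.
#'
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param momentum Adam beta pair.
#' @param batch_size minibatch size.
#' @param decay_rate learning-rate multiplier applied once at
#'   `ceil(epochs/2)`.
#' @param weight_decay decoupled weight decay.
#' @param w1,w2 loss weights; must sum to 1.
#' @param folds cross-validation folds (over subjects).
#' @param seed training seed (shuffling, dropout, init fan-out).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, learning_rate = 5e-4,
                         momentum = c(0.9, 0.999), batch_size = 128L,
                         decay_rate = 0.1, weight_decay = 0.01,
                         w1 = 0.1, w2 = 0.9, folds = 5L, seed = 1L) {
  if (abs(w1 + w2 - 1) > 1e-12)
    stop("loss weights must satisfy w1 + w2 = 1", call. = FALSE)
  if (learning_rate <= 0 || batch_size < 1L || epochs < 1L)
    stop("rates and sizes must be positive", call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 decay_rate = decay_rate, weight_decay = weight_decay,
                 w1 = w1, w2 = w2, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Joint cross-entropy + cosine-DCCA loss
#'
#' `L = w1 * L_CE + w2 * L_DCCA`, where `L_CE` is the mean categorical
#' cross-entropy of the predicted probabilities against one-hot labels and
#' `L_DCCA` is [cos_dcca_loss()] of the projected views (the negated matrix
#' cosine, so minimizing L maximizes alignment).
#'
#' @param probs `n x C` probability matrix.
#' @param labels integer labels in `0..C-1`.
#' @param H1p,H2p projected views (`n x o`).
#' @param w1,w2 loss weights summing to 1.
#' @return list with `loss`, `ce`, `dcca`.
#' @export
joint_loss <- function(probs, labels, H1p, H2p, w1 = 0.1, w2 = 0.9) {
  if (abs(w1 + w2 - 1) > 1e-12)
    stop("loss weights must satisfy w1 + w2 = 1", call. = FALSE)
  probs <- as.matrix(probs)
  n <- nrow(probs)
  p_true <- probs[cbind(seq_len(n), labels + 1L)]
  ce <- -mean(log(pmax(p_true, 1e-12)))
  dcca <- cos_dcca_loss(H1p, H2p, eps = 1e-12)
  list(loss = w1 * ce + w2 * dcca, ce = ce, dcca = dcca)
}

#' Subject-independent k-fold assignment
#'
#' Subjects (not trials) are shuffled by seed and partitioned into `folds`
#' groups; each fold tests one group and trains on the rest, so no subject
#' contributes trials to both sides of any fold.
#'
#' @param dataset a `dual_modality_dataset` (or any list with
#'   `subject_ids`).
#' @param folds number of folds (<= number of subjects).
#' @param seed shuffling seed.
#' @return object of class `fold_assignment`: list of folds, each with
#'   `train_subjects`, `test_subjects`, `train_idx`, `test_idx`.
#' @export
subject_kfold_split <- function(dataset, folds = 5L, seed = 1L) {
  subjects <- sort(unique(dataset$subject_ids))
  if (length(subjects) < folds)
    stop("fewer subjects than folds", call. = FALSE)
  withr::with_seed(seed, {
    perm <- sample(subjects)
    grp <- rep(seq_len(folds), length.out = length(perm))
    assign <- lapply(seq_len(folds), function(f) {
      test_s <- sort(perm[grp == f])
      train_s <- sort(setdiff(subjects, test_s))
      list(train_subjects = train_s, test_subjects = test_s,
           train_idx = which(dataset$subject_ids %in% train_s),
           test_idx = which(dataset$subject_ids %in% test_s))
    })
    structure(assign, class = "fold_assignment", seed = seed)
  })
}

#' Train the ICTD network on one fold
#'
#' Minibatch Adam on the joint loss; the cosine-DCCA term is computed per
#' minibatch on that batch's pooled branch representations (centering within
#' the batch). The learning rate is multiplied by `decay_rate` once at epoch
#' `ceil(epochs/2)`. Per-epoch training loss, its CE and DCCA components,
#' and held-out accuracy are logged.
#'
#' @param dataset a `dual_modality_dataset`.
#' @param model_cfg a [model_config()] (its `in_channels` is taken from the
#'   data).
#' @param train_cfg a [train_config()].
#' @param fold one element of a [subject_kfold_split()] assignment, or NULL
#'   to train on everything (no validation accuracy logged).
#' @return list with `model` (trained `ictd_model`) and `log` (data frame
#'   of per-epoch metrics).
#' @export
train_ictd <- function(dataset, model_cfg = model_config(),
                       train_cfg = train_config(), fold = NULL) {
  tr_idx <- if (is.null(fold)) seq_along(dataset$labels) else fold$train_idx
  te_idx <- if (is.null(fold)) integer(0) else fold$test_idx
  X1 <- dataset$gaze_view[tr_idx, , drop = FALSE]
  X2 <- dataset$pupil_view[tr_idx, , drop = FALSE]
  y <- dataset$labels[tr_idx]
  C <- length(unique(dataset$labels))
  model <- ictd_model(ncol(X1), ncol(X2), C, model_cfg,
                      seed = train_cfg$seed)
  params <- model_param_list(model)
  st <- adam_state(params)
  nb <- max(1L, ceiling(length(y) / train_cfg$batch_size))
  log <- vector("list", train_cfg$epochs)
  withr::with_seed(train_cfg$seed + 1L, {
    for (ep in seq_len(train_cfg$epochs)) {
      lr <- train_cfg$learning_rate *
        if (ep > ceiling(train_cfg$epochs / 2)) train_cfg$decay_rate else 1
      ord <- sample(length(y))
      ep_loss <- ep_ce <- ep_dcca <- 0
      for (b in seq_len(nb)) {
        idx <- ord[seq.int((b - 1L) * train_cfg$batch_size + 1L,
                           min(b * train_cfg$batch_size, length(y)))]
        step <- ictd_train_step(model, params, st,
                                X1[idx, , drop = FALSE],
                                X2[idx, , drop = FALSE], y[idx],
                                train_cfg, lr)
        st <- step$state
        ep_loss <- ep_loss + step$loss * length(idx)
        ep_ce <- ep_ce + step$ce * length(idx)
        ep_dcca <- ep_dcca + step$dcca * length(idx)
      }
      val_acc <- NA_real_
      if (length(te_idx)) {
        pred <- predict(model, dataset$gaze_view[te_idx, , drop = FALSE],
                        dataset$pupil_view[te_idx, , drop = FALSE])
        val_acc <- mean(pred == dataset$labels[te_idx])
      }
      log[[ep]] <- data.frame(epoch = ep, lr = lr,
                              loss = ep_loss / length(y),
                              ce = ep_ce / length(y),
                              dcca = ep_dcca / length(y),
                              val_accuracy = val_acc)
    }
  })
  list(model = model, log = do.call(rbind, log))
}

ictd_train_step <- function(model, params, st, X1b, X2b, yb, train_cfg, lr) {
  ad_tape_start()
  on.exit(ad_tape_clear())
  zero_grads(params)
  fw <- ictd_forward_nodes(model, X1b, X2b, train = TRUE)
  fused <- ad_concat2d(fw$h1, fw$h2)
  logits <- ad_lin(ad_reshape(fused, c(nrow(fused$value), 1L, fw$n)),
                   model$params$Wy, model$params$by)
  logits2 <- ad_reshape(logits, c(model$n_classes, fw$n))
  ce <- ad_softmax_ce(logits2, yb)
  dcca <- ad_cosdcca(fw$h1, fw$h2, eps = 1e-12)
  loss <- ad_add(ad_scale(ce, train_cfg$w1), ad_scale(dcca, train_cfg$w2))
  if (!is.finite(loss$value))
    stop(sprintf("NaN/Inf loss (ce=%g, dcca=%g); check norm guards",
                 ce$value, dcca$value), call. = FALSE)
  ad_backward(loss)
  state <- adam_step(params, st, lr, betas = train_cfg$momentum,
                     weight_decay = train_cfg$weight_decay)
  list(state = state, loss = loss$value, ce = ce$value, dcca = dcca$value)
}

#' Evaluate a trained model on a test split
#'
#' Multiclass accuracy is the trace of the confusion matrix over the test
#' size (the multiclass generalization of the TP/TN rate); macro-F1 is the
#' unweighted mean of per-class F1 (classes absent from both truth and
#' prediction contribute F1 = 0 only if present in the label set).
#'
#' @param model a trained `ictd_model`.
#' @param dataset the dataset.
#' @param test_idx indices of the test trials (nonempty).
#' @return object of class `eval_report`: accuracy, macro_f1, confusion
#'   (C x C counts, rows = truth), confusion_norm (row-normalized),
#'   per-class F1.
#' @export
evaluate <- function(model, dataset, test_idx) {
  if (!length(test_idx)) stop("empty test split", call. = FALSE)
  truth <- dataset$labels[test_idx]
  pred <- predict(model, dataset$gaze_view[test_idx, , drop = FALSE],
                  dataset$pupil_view[test_idx, , drop = FALSE])
  C <- model$n_classes
  metrics_from_predictions(truth, pred, C)
}

metrics_from_predictions <- function(truth, pred, C) {
  conf <- matrix(0L, C, C,
                 dimnames = list(truth = 0:(C - 1), pred = 0:(C - 1)))
  for (i in seq_along(truth)) {
    conf[truth[i] + 1L, pred[i] + 1L] <- conf[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  acc <- sum(diag(conf)) / sum(conf)
  f1 <- vapply(seq_len(C), function(c) {
    tp <- conf[c, c]; fp <- sum(conf[-c, c]); fn <- sum(conf[c, -c])
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  rs <- rowSums(conf)
  structure(list(accuracy = acc, macro_f1 = mean(f1), confusion = conf,
                 confusion_norm = conf / ifelse(rs > 0, rs, 1),
                 per_class_f1 = f1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f, macro-F1 %.4f (n = %d)\n", x$accuracy,
              x$macro_f1, sum(x$confusion)))
  invisible(x)
}

#' Subject-independent cross-validation of the ICTD network
#'
#' Trains one model per fold of a [subject_kfold_split()] and aggregates:
#' mean accuracy and macro-F1 with a normal-approximation 95% CI across
#' folds (`mean +/- 1.96 sd/sqrt(k)`).
#'
#' @param dataset a `dual_modality_dataset`.
#' @param model_cfg,train_cfg configurations.
#' @param folds either a fold count or a prebuilt `fold_assignment`.
#' @param ablation_tag optional label carried into the report.
#' @return list with `per_fold` (data frame), `accuracy`, `macro_f1`,
#'   `ci95` (accuracy CI), `assignment`, `ablation_tag`.
#' @export
cross_validate <- function(dataset, model_cfg = model_config(),
                           train_cfg = train_config(), folds = NULL,
                           ablation_tag = NULL) {
  assign <- if (inherits(folds, "fold_assignment")) folds else
    subject_kfold_split(dataset, folds %||% train_cfg$folds,
                        seed = train_cfg$seed)
  per <- lapply(seq_along(assign), function(f) {
    fit <- train_ictd(dataset, model_cfg, train_cfg, assign[[f]])
    rep <- evaluate(fit$model, dataset, assign[[f]]$test_idx)
    data.frame(fold = f, accuracy = rep$accuracy, macro_f1 = rep$macro_f1)
  })
  per <- do.call(rbind, per)
  k <- nrow(per)
  ci <- mean(per$accuracy) + c(-1, 1) * 1.96 * stats::sd(per$accuracy) / sqrt(k)
  list(per_fold = per, accuracy = mean(per$accuracy),
       macro_f1 = mean(per$macro_f1), ci95 = ci, assignment = assign,
       ablation_tag = ablation_tag)
}

#' Ablation harness
#'
#' Trains and evaluates four variants under identical fold assignments and
#' seeds: the full model; the IFFN replaced by a plain FFN of matched
#' width; the alignment loss disabled (`w2 = 0`, CE only); and both
#' removals.
#'
#' @param dataset a `dual_modality_dataset`.
#' @param model_cfg,train_cfg base configurations.
#' @param variants subset of `c("full", "no_iffn", "no_dcca", "neither")`.
#' @param folds fold count or prebuilt assignment.
#' @return data frame: variant, accuracy, macro_f1, plus the shared fold
#'   assignment as an attribute.
#' @export
run_ablation <- function(dataset, model_cfg = model_config(),
                         train_cfg = train_config(),
                         variants = c("full", "no_iffn", "no_dcca", "neither"),
                         folds = NULL) {
  assign <- if (inherits(folds, "fold_assignment")) folds else
    subject_kfold_split(dataset, folds %||% train_cfg$folds,
                        seed = train_cfg$seed)
  variant_cfg <- function(v) {
    mc <- model_cfg; tc <- train_cfg
    if (v %in% c("no_iffn", "neither")) mc$use_iffn <- FALSE
    if (v %in% c("no_dcca", "neither")) { tc$w1 <- 1; tc$w2 <- 0 }
    list(mc = mc, tc = tc)
  }
  rows <- lapply(variants, function(v) {
    vc <- variant_cfg(v)
    cv <- cross_validate(dataset, vc$mc, vc$tc, folds = assign,
                         ablation_tag = v)
    data.frame(variant = v, accuracy = cv$accuracy, macro_f1 = cv$macro_f1)
  })
  out <- do.call(rbind, rows)
  attr(out, "assignment") <- assign
  out
}
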