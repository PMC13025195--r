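# Synthetic dual-view datasets and synthetic raw gaze streams.
#
# The generator exists so that every downstream stage (alignment objective,
# classifier, event detector, feature formulas) can be exercised against
# known ground truth without any external recordings.

#' Specification of a synthetic dual-view dataset
#'
#' Samples are drawn from a shared latent class structure: each trial has a
#' latent point `mu_class + z` (`z` standard normal in `latent_dim`
#' dimensions), which is mapped into each view by a fixed random loading
#' matrix, then shifted by a per-subject offset and corrupted by additive
#' Gaussian noise. Class means sit on a scaled simplex so every pair of
#' classes is exactly `class_separation` apart in latent space.
#'
#' @param n_classes number of emotion classes (>= 2).
#' @param n_subjects number of subjects; trials are assigned to subjects in
#'   contiguous blocks, which makes subject-independent splitting meaningful.
#' @param trials_per_subject trials recorded per subject.
#' @param latent_dim dimension of the shared latent space; must be at least
#'   `n_classes - 1` so the class-mean simplex fits.
#' @param view_dims integer pair `(d1, d2)`: output dimensions of the gaze
#'   view and the pupil view.
#' @param class_separation pairwise Euclidean distance between latent class
#'   means (0 = classes indistinguishable).
#' @param loading_seed_scale standard deviation of the seeded Gaussian
#'   entries of the latent-to-view loading matrices.
#' @param noise_sd nonnegative pair: additive noise sd per view.
#' @param subject_shift_sd sd of the per-subject additive offset in view
#'   space (models individual variability).
#' @param seed integer seed; identical spec + seed gives identical data.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 4L, n_subjects = 10L,
                           trials_per_subject = 50L, latent_dim = 4L,
                           view_dims = c(16L, 8L), class_separation = 4,
                           loading_seed_scale = 1, noise_sd = c(1, 1),
                           subject_shift_sd = 0.5, seed = 1L) {
  spec <- list(n_classes = as.integer(n_classes),
               n_subjects = as.integer(n_subjects),
               trials_per_subject = as.integer(trials_per_subject),
               latent_dim = as.integer(latent_dim),
               view_dims = as.integer(view_dims),
               class_separation = class_separation,
               loading_seed_scale = loading_seed_scale,
               noise_sd = as.numeric(noise_sd),
               subject_shift_sd = subject_shift_sd,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  chk <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid synthetic_spec field '%s': %s", field, why),
                  call. = FALSE)
  }
  chk(spec$n_classes >= 2L, "n_classes", "must be >= 2")
  chk(spec$n_subjects >= 1L, "n_subjects", "must be >= 1")
  chk(spec$trials_per_subject >= 1L, "trials_per_subject", "must be >= 1")
  chk(spec$latent_dim >= 1L, "latent_dim", "must be >= 1")
  chk(spec$latent_dim >= spec$n_classes - 1L, "latent_dim",
      "must be >= n_classes - 1 so class means fit on a simplex")
  chk(length(spec$view_dims) == 2L && all(spec$view_dims >= 1L), "view_dims",
      "must be two counts >= 1")
  chk(spec$class_separation >= 0, "class_separation", "must be >= 0")
  chk(spec$loading_seed_scale > 0, "loading_seed_scale", "must be > 0")
  chk(length(spec$noise_sd) == 2L && all(spec$noise_sd >= 0), "noise_sd",
      "must be two nonnegative reals")
  chk(spec$subject_shift_sd >= 0, "subject_shift_sd", "must be >= 0")
  invisible(spec)
}

# coordinates of a regular unit-edge simplex in C-1 dims, centered at the
# origin: the Gram matrix of such vertices is (I - 11'/C)/2, so any matrix
# square root of it gives valid coordinates
simplex_coords <- function(C) {
  G <- (diag(C) - matrix(1 / C, C, C)) / 2
  e <- eigen(G, symmetric = TRUE)
  keep <- seq_len(C - 1L)
  e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[keep], 0)), C - 1L)
}

#' Generate a synthetic dual-view dataset
#'
#' @param spec a [synthetic_spec()].
#' @param loadings optional list of two loading matrices (`d1 x latent_dim`,
#'   `d2 x latent_dim`) overriding the seeded random draws; used when a
#'   closed-form oracle needs fixed loadings.
#' @return a `dual_modality_dataset`: list with `gaze_view` (n x d1 matrix),
#'   `pupil_view` (n x d2), `labels` (integer in `0..C-1`), `subject_ids`
#'   (integer), `class_names`, and the generating `spec`.
#' @export
generate_dual_modality <- function(spec, loadings = NULL) {
  validate_synthetic_spec(spec)
  n <- spec$n_subjects * spec$trials_per_subject
  C <- spec$n_classes
  withr::with_seed(spec$seed, {
    mu <- simplex_coords(C) * spec$class_separation      # C x (C-1), unit edge
    M <- matrix(0, C, spec$latent_dim)
    M[, seq_len(C - 1L)] <- mu
    if (is.null(loadings)) {
      A1 <- matrix(stats::rnorm(spec$view_dims[1L] * spec$latent_dim,
                                sd = spec$loading_seed_scale),
                   spec$view_dims[1L], spec$latent_dim)
      A2 <- matrix(stats::rnorm(spec$view_dims[2L] * spec$latent_dim,
                                sd = spec$loading_seed_scale),
                   spec$view_dims[2L], spec$latent_dim)
    } else {
      A1 <- as.matrix(loadings[[1L]]); A2 <- as.matrix(loadings[[2L]])
      stopifnot(ncol(A1) == spec$latent_dim, ncol(A2) == spec$latent_dim)
    }
    subj_off1 <- matrix(stats::rnorm(spec$n_subjects * spec$view_dims[1L],
                                     sd = spec$subject_shift_sd),
                        spec$n_subjects, spec$view_dims[1L])
    subj_off2 <- matrix(stats::rnorm(spec$n_subjects * spec$view_dims[2L],
                                     sd = spec$subject_shift_sd),
                        spec$n_subjects, spec$view_dims[2L])
    subject_ids <- rep(seq_len(spec$n_subjects) - 1L,
                       each = spec$trials_per_subject)
    # balanced labels: cycle classes within each subject block
    labels <- (seq_len(n) - 1L) %% C
    Z <- matrix(stats::rnorm(n * spec$latent_dim), n, spec$latent_dim)
    lat <- M[labels + 1L, , drop = FALSE] + Z
    X1 <- lat %*% t(A1) + subj_off1[subject_ids + 1L, , drop = FALSE]
    X2 <- lat %*% t(A2) + subj_off2[subject_ids + 1L, , drop = FALSE]
    if (spec$noise_sd[1L] > 0)
      X1 <- X1 + matrix(stats::rnorm(length(X1), sd = spec$noise_sd[1L]),
                        nrow(X1), ncol(X1))
    if (spec$noise_sd[2L] > 0)
      X2 <- X2 + matrix(stats::rnorm(length(X2), sd = spec$noise_sd[2L]),
                        nrow(X2), ncol(X2))
    colnames(X1) <- paste0("gaze_f", seq_len(ncol(X1)))
    colnames(X2) <- paste0("pupil_f", seq_len(ncol(X2)))
    structure(list(gaze_view = X1, pupil_view = X2,
                   labels = as.integer(labels),
                   subject_ids = as.integer(subject_ids),
                   class_names = paste0("class", seq_len(C) - 1L),
                   spec = spec),
              class = "dual_modality_dataset")
  })
}

#' @export
print.dual_modality_dataset <- function(x, ...) {
  cat(sprintf("dual_modality_dataset: %d trials, %d classes, %d subjects\n",
              nrow(x$gaze_view), length(unique(x$labels)),
              length(unique(x$subject_ids))))
  cat(sprintf("  gaze view: %d features; pupil view: %d features\n",
              ncol(x$gaze_view), ncol(x$pupil_view)))
  invisible(x)
}

# ---- raw gaze streams -------------------------------------------------------

#' Specification of a synthetic raw gaze stream
#'
#' The plan alternates fixations and saccades (`k` fixations imply `k - 1`
#' saccades between them); blinks flag validity off over their interval.
#' All intervals are half-open `[onset, offset)` in milliseconds; a sample at
#' time `t` belongs to the interval containing `t`.
#'
#' @param fixation_plan data frame with columns `duration_ms`, `x`, `y`,
#'   `dispersion` (sd of isotropic scatter around the center, position units).
#' @param saccade_plan data frame with column `duration_ms` (one fewer row
#'   than `fixation_plan`); the saccade ramps linearly between the flanking
#'   fixation centers.
#' @param blink_plan data frame with columns `onset_ms`, `duration_ms` (may
#'   be empty).
#' @param pupil_baseline baseline pupil diameter, mm.
#' @param pupil_noise_sd sd of additive pupil noise, mm.
#' @param sample_rate sampling rate, Hz.
#' @param seed integer seed for the scatter/noise draws.
#' @return object of class `gaze_stream_spec`.
#' @export
gaze_stream_spec <- function(fixation_plan, saccade_plan = NULL,
                             blink_plan = NULL, pupil_baseline = 3,
                             pupil_noise_sd = 0, sample_rate = 100,
                             seed = 1L) {
  fixation_plan <- as.data.frame(fixation_plan)
  saccade_plan <- if (is.null(saccade_plan))
    data.frame(duration_ms = numeric(0)) else as.data.frame(saccade_plan)
  blink_plan <- if (is.null(blink_plan))
    data.frame(onset_ms = numeric(0), duration_ms = numeric(0))
  else as.data.frame(blink_plan)
  if (nrow(fixation_plan) < 1L)
    stop("fixation_plan must contain at least one fixation", call. = FALSE)
  if (nrow(saccade_plan) != nrow(fixation_plan) - 1L)
    stop("plans must alternate: k fixations require k-1 saccades",
         call. = FALSE)
  if (any(fixation_plan$duration_ms <= 0) ||
      (nrow(saccade_plan) > 0 && any(saccade_plan$duration_ms <= 0)) ||
      (nrow(blink_plan) > 0 && any(blink_plan$duration_ms <= 0)))
    stop("all durations must be > 0", call. = FALSE)
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  structure(list(fixation_plan = fixation_plan, saccade_plan = saccade_plan,
                 blink_plan = blink_plan, pupil_baseline = pupil_baseline,
                 pupil_noise_sd = pupil_noise_sd, sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "gaze_stream_spec")
}

#' Generate a synthetic gaze recording with event ground truth
#'
#' Fixations scatter samples around their center with the planned
#' dispersion; saccades ramp linearly (constant velocity) between the
#' flanking fixation centers; blinks flag validity off. Sample count over a
#' segment of duration `D` ms at rate `r` Hz is `D * r / 1000` under the
#' half-open interval convention.
#'
#' @param spec a [gaze_stream_spec()].
#' @return list with `recording` (a [gaze_recording()]) and `ground_truth`
#'   (data frame `kind`, `onset_ms`, `offset_ms`).
#' @export
generate_gaze_stream <- function(spec) {
  stopifnot(inherits(spec, "gaze_stream_spec"))
  fp <- spec$fixation_plan; sp <- spec$saccade_plan
  durs <- numeric(0); kinds <- character(0)
  for (i in seq_len(nrow(fp))) {
    durs <- c(durs, fp$duration_ms[i]); kinds <- c(kinds, "fixation")
    if (i <= nrow(sp)) {
      durs <- c(durs, sp$duration_ms[i]); kinds <- c(kinds, "saccade")
    }
  }
  total <- sum(durs)
  if (total <= 0) stop("total plan duration is zero", call. = FALSE)
  offs <- cumsum(c(0, durs))
  gt <- data.frame(kind = kinds, onset_ms = offs[-length(offs)],
                   offset_ms = offs[-1L])
  dt <- 1000 / spec$sample_rate
  t_ms <- seq(0, total - dt / 2, by = dt)   # half-open [0, total)
  n <- length(t_ms)
  x <- numeric(n); y <- numeric(n)
  withr::with_seed(spec$seed, {
    seg <- findInterval(t_ms, offs, rightmost.closed = FALSE)
    fix_idx <- cumsum(gt$kind == "fixation")
    for (s in seq_len(nrow(gt))) {
      in_s <- which(seg == s)
      if (!length(in_s)) next
      if (gt$kind[s] == "fixation") {
        f <- fix_idx[s]
        x[in_s] <- fp$x[f]
        y[in_s] <- fp$y[f]
        if (fp$dispersion[f] > 0) {
          x[in_s] <- x[in_s] + stats::rnorm(length(in_s), sd = fp$dispersion[f])
          y[in_s] <- y[in_s] + stats::rnorm(length(in_s), sd = fp$dispersion[f])
        }
      } else {
        f <- fix_idx[s]                      # fixation before this saccade
        frac <- (t_ms[in_s] - gt$onset_ms[s]) /
          (gt$offset_ms[s] - gt$onset_ms[s])
        x[in_s] <- fp$x[f] + frac * (fp$x[f + 1L] - fp$x[f])
        y[in_s] <- fp$y[f] + frac * (fp$y[f + 1L] - fp$y[f])
      }
    }
    pupil <- rep(spec$pupil_baseline, n)
    if (spec$pupil_noise_sd > 0)
      pupil <- pupil + stats::rnorm(n, sd = spec$pupil_noise_sd)
    valid <- rep(TRUE, n)
    bp <- spec$blink_plan
    if (nrow(bp) > 0) {
      for (b in seq_len(nrow(bp))) {
        on <- bp$onset_ms[b]; off <- on + bp$duration_ms[b]
        valid[t_ms >= on & t_ms < off] <- FALSE
        gt <- rbind(gt, data.frame(kind = "blink", onset_ms = on,
                                   offset_ms = off))
      }
    }
    rec <- gaze_recording(t_ms = t_ms, x = x, y = y, pupil_l = pupil,
                          pupil_r = pupil, valid = valid,
                          sample_rate = spec$sample_rate)
    list(recording = rec, ground_truth = gt[order(gt$onset_ms, gt$kind), ])
  })
}
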