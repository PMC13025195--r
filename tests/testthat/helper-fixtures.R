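# Shared fixtures and independent brute-force oracles.

# small, quickly trainable architecture for smoke tests
tiny_model_cfg <- function() {
  model_config(conv1_out = 16L, conv2_out = 32L, n_heads = 4L, n_layers = 2L,
               pool_kernels = c(2L, 4L), dropout = 0.1)
}

tiny_dataset <- function(seed = 42L, n_subjects = 6L, trials = 20L,
                         separation = 6, noise = 0.8) {
  generate_dual_modality(synthetic_spec(
    n_classes = 3L, n_subjects = n_subjects, trials_per_subject = trials,
    latent_dim = 3L, view_dims = c(6L, 4L), class_separation = separation,
    noise_sd = c(noise, noise), subject_shift_sd = 0.3, seed = seed))
}

# random alternating fixation/saccade plan (noise-free)
random_plan_spec <- function(seed, max_fix = 5L, blinks = 0L) {
  withr::with_seed(seed, {
    k <- sample(2:max_fix, 1L)
    fp <- data.frame(duration_ms = sample(seq(200, 600, by = 50), k, TRUE),
                     x = cumsum(stats::runif(k, 5, 15)),
                     y = cumsum(stats::runif(k, 5, 15)),
                     dispersion = 0)
    sp <- data.frame(duration_ms = sample(seq(30, 60, by = 10), k - 1L, TRUE))
    bp <- NULL
    if (blinks > 0L) {
      total <- sum(fp$duration_ms) + sum(sp$duration_ms)
      # put blinks strictly inside fixations so counts stay unambiguous
      onsets <- fp$duration_ms[1L] / 2
      bp <- data.frame(onset_ms = onsets, duration_ms = 100)
    }
    gaze_stream_spec(fp, sp, bp, sample_rate = 500, seed = seed)
  })
}

# events data frame built directly (bypassing detection) for formula tests
fake_events <- function(seed = 1L, n_fix = 4L, n_sac = 3L, n_blink = 1L) {
  withr::with_seed(seed, {
    rows <- list()
    t <- 0
    mk <- function(kind, dur) {
      r <- data.frame(kind = kind, onset_ms = t, offset_ms = t + dur,
                      duration_ms = dur, dispersion_x = NA_real_,
                      dispersion_y = NA_real_, dispersion = NA_real_,
                      amplitude = NA_real_, distance = NA_real_,
                      mean_velocity = NA_real_, peak_velocity = NA_real_)
      t <<- t + dur
      r
    }
    for (i in seq_len(n_fix)) {
      r <- mk("fixation", stats::runif(1, 100, 500))
      r$dispersion_x <- stats::runif(1, 0, 2)
      r$dispersion_y <- stats::runif(1, 0, 2)
      r$dispersion <- r$dispersion_x + r$dispersion_y
      rows <- c(rows, list(r))
      if (i <= n_sac) {
        r <- mk("saccade", stats::runif(1, 20, 80))
        r$amplitude <- stats::runif(1, 2, 20)
        r$distance <- r$amplitude * stats::runif(1, 1, 1.3)
        r$mean_velocity <- r$distance / (r$duration_ms / 1000)
        r$peak_velocity <- r$mean_velocity * 1.5
        rows <- c(rows, list(r))
      }
    }
    for (b in seq_len(n_blink)) rows <- c(rows, list(mk("blink", 120)))
    ev <- do.call(rbind, rows)
    class(ev) <- c("ocular_events", "data.frame")
    ev
  })
}

fake_recording <- function(duration_ms = 10000, rate = 100, pupil = 3,
                           seed = 1L) {
  withr::with_seed(seed, {
    t <- seq(0, duration_ms - 1000 / rate, by = 1000 / rate)
    gaze_recording(t, x = stats::rnorm(length(t)), y = stats::rnorm(length(t)),
                   pupil_l = rep(pupil, length(t)),
                   pupil_r = rep(pupil, length(t)), sample_rate = rate)
  })
}

# ---- independent oracles (naive implementations) ---------------------------

brute_seed_features <- function(events, rec) {
  fx <- events[events$kind == "fixation", ]
  sc <- events[events$kind == "saccade", ]
  bl <- events[events$kind == "blink", ]
  dur_s <- (max(rec$t_ms) - min(rec$t_ms) + stats::median(diff(rec$t_ms))) / 1000
  pm <- function(v) if (length(v)) sum(v) / length(v) else NA_real_
  psd <- function(v) if (length(v)) sqrt(sum((v - pm(v))^2) / length(v)) else NA_real_
  c(pupil_left_mean = pm(rec$pupil_l[rec$valid]),
    pupil_left_sd = psd(rec$pupil_l[rec$valid]),
    pupil_right_mean = pm(rec$pupil_r[rec$valid]),
    pupil_right_sd = psd(rec$pupil_r[rec$valid]),
    fixation_duration_mean = pm(fx$duration_ms),
    fixation_duration_sd = psd(fx$duration_ms),
    dispersion_x_mean = pm(fx$dispersion_x),
    dispersion_x_sd = psd(fx$dispersion_x),
    dispersion_y_mean = pm(fx$dispersion_y),
    dispersion_y_sd = psd(fx$dispersion_y),
    saccade_duration_mean = pm(sc$duration_ms),
    saccade_duration_sd = psd(sc$duration_ms),
    saccade_amplitude_mean = pm(sc$amplitude),
    saccade_amplitude_sd = psd(sc$amplitude),
    blink_duration_mean = pm(bl$duration_ms),
    blink_duration_sd = psd(bl$duration_ms),
    fixation_frequency = nrow(fx) / dur_s,
    fixation_duration_max = if (nrow(fx)) max(fx$duration_ms) else NA_real_,
    fixation_dispersion_max = if (nrow(fx)) max(fx$dispersion) else NA_real_,
    fixation_dispersion_total = if (nrow(fx)) sum(fx$dispersion) else NA_real_,
    saccade_frequency = nrow(sc) / dur_s,
    saccade_duration_avg = pm(sc$duration_ms),
    saccade_amplitude_avg = pm(sc$amplitude),
    saccade_latency_avg = if (nrow(sc) >= 2)
      sum(diff(sc$onset_ms)) / (nrow(sc) - 1) else NA_real_)
}

brute_esee_features <- function(events, rec) {
  fx <- events[events$kind == "fixation", ]
  sc <- events[events$kind == "saccade", ]
  p <- ((rec$pupil_l + rec$pupil_r) / 2)[rec$valid]
  pm <- function(v) sum(v) / length(v)
  pvar <- function(v) sum((v - pm(v))^2) / length(v)
  pcv <- function(v) if (pm(v) == 0) NA_real_ else sqrt(pvar(v)) / pm(v)
  g1 <- function(v) {
    n <- length(v); m <- pm(v)
    (sum((v - m)^3) / n) / (sum((v - m)^2) / n)^1.5 *
      sqrt(n * (n - 1)) / (n - 2)
  }
  g2 <- function(v) {
    n <- length(v); m <- pm(v)
    (sum((v - m)^4) / n) / (sum((v - m)^2) / n)^2 - 3
  }
  c(pupil_diameter_mean = pm(p), pupil_diameter_var = pvar(p),
    pupil_diameter_cv = pcv(p),
    fixation_duration_mean = pm(fx$duration_ms),
    fixation_duration_var = pvar(fx$duration_ms),
    fixation_duration_cv = pcv(fx$duration_ms),
    saccade_duration_kurt = g2(sc$duration_ms),
    saccade_duration_skew = g1(sc$duration_ms),
    saccade_duration_cv = pcv(sc$duration_ms),
    saccade_speed_kurt = g2(sc$mean_velocity),
    saccade_speed_skew = g1(sc$mean_velocity),
    saccade_distance_kurt = g2(sc$distance),
    saccade_distance_skew = g1(sc$distance))
}

# from-scratch one-way ANOVA via explicit sums of squares
brute_anova <- function(v, g) {
  g <- factor(g)
  grand <- mean(v)
  ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - grand)^2))
  ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(v) - nlevels(g)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}

# write a tiny eseed-dialect feature CSV; returns path
write_esee_csv <- function(path, n = 12L, seed = 1L, constant_feature = FALSE) {
  withr::with_seed(seed, {
    nm <- esee_feature_names()
    df <- as.data.frame(matrix(stats::rnorm(n * length(nm)), n,
                               dimnames = list(NULL, nm)))
    df$label <- rep(0:1, length.out = n)
    df$subject <- rep(0:3, length.out = n)
    # make one feature clearly class-separated so screening keeps something
    df$pupil_diameter_mean <- df$label * 5 + stats::rnorm(n, sd = 0.1)
    if (constant_feature) df$saccade_speed_kurt <- 1.5
    utils::write.csv(df, path, row.names = FALSE)
    path
  })
}
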