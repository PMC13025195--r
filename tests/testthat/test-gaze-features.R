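# Preprocessing, event detection, feature formulas, ANOVA screening,
# Russell mapping.

test_that("preprocessing is the identity on clean recordings", {
  rec <- fake_recording(duration_ms = 1000, rate = 100)
  expect_identical(preprocess(rec, smooth_window = 1L), rec)
})

test_that("a single invalid sample between 2.0 and 4.0 interpolates to 3.0", {
  t <- seq(0, 90, by = 10)
  x <- rep(2, 10); x[5] <- 999
  x[6:10] <- 4
  valid <- rep(TRUE, 10); valid[5] <- FALSE
  rec <- gaze_recording(t, x, x, pupil_l = rep(3, 10), pupil_r = rep(3, 10),
                        valid = valid)
  out <- preprocess(rec, max_gap_ms = 50, smooth_window = 1L)
  expect_equal(out$x[5], 3.0)
  expect_true(out$valid[5])
})

test_that("moving-average smoothing preserves a linear ramp away from edges", {
  t <- seq(0, 990, by = 10)
  ramp <- seq_along(t) * 0.5
  rec <- gaze_recording(t, ramp, ramp, pupil_l = rep(3, 100),
                        pupil_r = rep(3, 100))
  out <- preprocess(rec, smooth_window = 5L)
  expect_equal(out$x[3:98], ramp[3:98], tolerance = 1e-12)
})

test_that("gaps longer than max_gap_ms stay invalid; all-invalid errors", {
  t <- seq(0, 990, by = 10)
  valid <- rep(TRUE, 100); valid[40:60] <- FALSE
  rec <- gaze_recording(t, rnorm(100), rnorm(100), pupil_l = rep(3, 100),
                        pupil_r = rep(3, 100), valid = valid)
  out <- preprocess(rec, max_gap_ms = 50, smooth_window = 1L)
  expect_true(all(!out$valid[40:60]))
  rec_bad <- gaze_recording(t, rnorm(100), rnorm(100),
                            pupil_l = rep(3, 100), pupil_r = rep(3, 100),
                            valid = rep(FALSE, 100))
  expect_error(preprocess(rec_bad), "no valid samples")
})

test_that("I-VT recovers planned events within one sample period", {
  gs <- generate_gaze_stream(random_plan_spec(11L))
  ev <- detect_events(gs$recording)
  gt <- gs$ground_truth
  for (kind in c("fixation", "saccade")) {
    expect_equal(sum(ev$kind == kind), sum(gt$kind == kind), info = kind)
  }
  dt <- 1000 / 500
  got <- ev[ev$kind != "blink", ]
  want <- gt[gt$kind != "blink", ]
  expect_true(all(abs(got$onset_ms - want$onset_ms) <= dt + 1e-9))
})

test_that("detector handles stationary, blink-bearing and empty input", {
  rec <- gaze_recording(seq(0, 990, by = 10), rep(1, 100), rep(2, 100),
                        pupil_l = rep(3, 100), pupil_r = rep(3, 100))
  ev <- detect_events(rec)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "fixation")
  expect_equal(ev$duration_ms, 1000)

  gs <- generate_gaze_stream(random_plan_spec(13L, blinks = 1L))
  ev2 <- detect_events(gs$recording)
  expect_equal(sum(ev2$kind == "blink"), 1L)

  empty <- gaze_recording(numeric(0), numeric(0), numeric(0), numeric(0),
                          numeric(0), logical(0), sample_rate = 100)
  expect_error(detect_events(empty), "empty")
})

test_that("SEED feature formulas match hand computations", {
  ev <- fake_events(seed = 2L)
  ev$duration_ms[ev$kind == "fixation"] <- c(200, 300, 400, 300)
  rec <- fake_recording(duration_ms = 10000, rate = 100)
  f <- extract_seed_features(ev, rec)
  expect_equal(unname(f["fixation_duration_mean"]), 300)
  expect_equal(unname(f["fixation_duration_max"]), 400)
  expect_equal(unname(f["fixation_frequency"]), 4 / 10)
  expect_equal(unname(f["pupil_left_mean"]), 3)
  expect_equal(unname(f["pupil_left_sd"]), 0)
})

test_that("feature formulas agree with a brute-force oracle on random events", {
  for (s in 1:5) {
    ev <- fake_events(seed = s, n_fix = 5L, n_sac = 4L, n_blink = 2L)
    rec <- fake_recording(seed = s)
    expect_equal(extract_seed_features(ev, rec), brute_seed_features(ev, rec),
                 tolerance = 1e-10)
    expect_equal(extract_esee_features(ev, rec), brute_esee_features(ev, rec),
                 tolerance = 1e-10)
  }
})

test_that("eSEE-d moment formulas: worked saccade-duration example", {
  ev <- fake_events(seed = 4L, n_fix = 4L, n_sac = 3L)
  ev$duration_ms[ev$kind == "saccade"] <- c(100, 200, 300)
  rec <- fake_recording()
  f <- extract_esee_features(ev, rec)
  # population variance of {100, 200, 300} and its CV
  expect_equal(unname(f["saccade_duration_cv"]),
               sqrt(20000 / 3) / 200, tolerance = 1e-12)
  ev$duration_ms[ev$kind == "fixation"] <- 250
  f2 <- extract_esee_features(ev, rec)
  expect_equal(unname(f2["fixation_duration_var"]), 0)
  expect_equal(unname(f2["fixation_duration_cv"]), 0)
})

test_that("moment conventions match e1071 and converge for gaussian samples", {
  skip_if_not_installed("e1071")
  withr::with_seed(8L, v <- stats::rnorm(10000))
  expect_equal(skewness_conv(v, "moment"), e1071::skewness(v, type = 1),
               tolerance = 1e-12)
  expect_equal(skewness_conv(v, "adjusted"), e1071::skewness(v, type = 2),
               tolerance = 1e-12)
  expect_equal(kurtosis_conv(v, "excess"), e1071::kurtosis(v, type = 1),
               tolerance = 1e-12)
  # convergence to 0 skew / 0 excess kurtosis; n large enough that the
  # estimator sd (sqrt(24/n) for kurtosis) sits well inside the band
  withr::with_seed(8L, vbig <- stats::rnorm(1e5))
  expect_lt(abs(skewness_conv(vbig)), 0.1)
  expect_lt(abs(kurtosis_conv(vbig)), 0.1)
})

test_that("features from absent event kinds are missing, not fabricated", {
  ev <- fake_events(seed = 3L, n_fix = 3L, n_sac = 2L, n_blink = 0L)
  ev <- ev[ev$kind != "saccade", ]
  rec <- fake_recording()
  f <- extract_seed_features(ev, rec)
  sac_feats <- setdiff(grep("^saccade", names(f), value = TRUE),
                       "saccade_frequency")
  expect_true(all(is.na(f[sac_feats])))
  expect_equal(unname(f["saccade_frequency"]), 0)
  expect_false(anyNA(f[grep("^fixation", names(f))]))
})

test_that("one-way ANOVA screen matches from-scratch sums of squares", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(0:1, each = 3L)
  tab <- list(features = data.frame(worked = v,
                                    noise = c(5, 3, 4, 4, 5, 3),
                                    const = rep(7, 6),
                                    perfect = g),
              labels = g, subject_ids = rep(0:1, 3L))
  res <- anova_screen(tab, alpha = 0.05)
  rep <- res$report
  expect_equal(rep$F[rep$feature == "worked"], 13.5, tolerance = 1e-10)
  expect_equal(rep$p[rep$feature == "worked"],
               stats::pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-10)
  expect_true(rep$retained[rep$feature == "worked"])
  expect_false(rep$retained[rep$feature == "const"])
  expect_match(rep$reason[rep$feature == "const"], "constant")
  expect_true(rep$retained[rep$feature == "perfect"])
  expect_equal(rep$p[rep$feature == "perfect"], 0)
  expect_identical(names(res$retained$features),
                   rep$feature[rep$retained])
  # random features against the brute-force computation
  withr::with_seed(10L, {
    for (i in 1:10) {
      v <- stats::rnorm(30)
      g2 <- sample(0:2, 30, TRUE)
      if (min(table(g2)) < 2) next
      b <- brute_anova(v, g2)
      r <- anova_screen(list(features = data.frame(f = v), labels = g2,
                             subject_ids = seq_len(30)), 0.05)$report
      expect_equal(r$F, b$F, tolerance = 1e-10)
      expect_equal(r$p, b$p, tolerance = 1e-10)
    }
  })
})

test_that("Russell mapping matches the published assignment and is total", {
  m <- map_to_russell(c("anger", "neutral", "tenderness", "sadness",
                        "disgust"))
  expect_equal(as.character(m$arousal), c("HA", "MA", "LA", "LA", "HA"))
  expect_equal(as.character(m$valence), c("NV", "MV", "PV", "NV", "NV"))
  all5 <- map_to_russell(c("anger", "disgust", "sadness", "tenderness",
                           "neutral"))
  expect_setequal(unique(as.character(all5$arousal)), c("HA", "LA", "MA"))
  expect_setequal(unique(as.character(all5$valence)), c("NV", "PV", "MV"))
  expect_error(map_to_russell(c("anger", "joy")), "joy")
})
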