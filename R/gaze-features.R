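# Raw gaze preprocessing, I-VT event detection, eye-movement feature
# extraction (two dialects), ANOVA feature screening, and the Russell-model
# emotion label mapping.

#' Construct a gaze recording
#'
#' @param t_ms strictly increasing timestamps in milliseconds.
#' @param x,y gaze position (degrees or pixels; keep one unit throughout).
#' @param pupil_l,pupil_r pupil diameters in mm.
#' @param valid logical validity flag per sample.
#' @param sample_rate nominal sampling rate in Hz.
#' @return object of class `gaze_recording` (a data frame with attributes).
#' @export
gaze_recording <- function(t_ms, x, y, pupil_l, pupil_r,
                           valid = rep(TRUE, length(t_ms)),
                           sample_rate = NULL) {
  n <- length(t_ms)
  if (!all(lengths(list(x, y, pupil_l, pupil_r, valid)) == n))
    stop("all channels must have equal length", call. = FALSE)
  if (n >= 2L && any(diff(t_ms) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(valid & (pupil_l <= 0 | pupil_r <= 0), na.rm = TRUE))
    stop("pupil values must be positive unless flagged invalid", call. = FALSE)
  if (is.null(sample_rate))
    sample_rate <- if (n >= 2L) 1000 / stats::median(diff(t_ms)) else NA_real_
  rec <- data.frame(t_ms = t_ms, x = x, y = y, pupil_l = pupil_l,
                    pupil_r = pupil_r, valid = valid)
  attr(rec, "sample_rate") <- sample_rate
  class(rec) <- c("gaze_recording", "data.frame")
  rec
}

interp_gaps <- function(t, v, valid, max_gap_ms) {
  out <- v
  runs <- rle(!valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  still_invalid <- !valid
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    if (i0 == 1L || i1 == length(v)) next                 # edge gap: leave
    gap <- t[i1 + 1L] - t[i0 - 1L]
    if (gap - (t[i0] - t[i0 - 1L]) > max_gap_ms) next     # too long: leave
    idx <- i0:i1
    out[idx] <- stats::approx(c(t[i0 - 1L], t[i1 + 1L]),
                              c(v[i0 - 1L], v[i1 + 1L]), xout = t[idx])$y
    still_invalid[idx] <- FALSE
  }
  list(v = out, invalid = still_invalid)
}

# moving average with partial windows at the edges (a linear ramp is
# preserved away from the edges)
moving_average <- function(v, w) {
  if (w <= 1L) return(v)
  n <- length(v)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Preprocess a gaze recording
#'
#' Linearly interpolates invalid gaps no longer than `max_gap_ms`; longer
#' gaps stay invalid (they become blink candidates for the detector). Then
#' applies moving-average smoothing of width `smooth_window` to the x, y and
#' pupil channels. Timestamps are never altered.
#'
#' @param rec a [gaze_recording()].
#' @param max_gap_ms longest invalid gap (ms) to interpolate across.
#' @param smooth_window moving-average width in samples (1 = no smoothing).
#' @return preprocessed `gaze_recording`.
#' @export
preprocess <- function(rec, max_gap_ms = 75, smooth_window = 1L) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (!any(rec$valid)) stop("recording has no valid samples", call. = FALSE)
  if (all(rec$valid) && smooth_window <= 1L) return(rec)
  inv <- !rec$valid
  for (ch in c("x", "y", "pupil_l", "pupil_r")) {
    r <- interp_gaps(rec$t_ms, rec[[ch]], rec$valid, max_gap_ms)
    rec[[ch]] <- r$v
    inv <- inv & r$invalid
  }
  rec$valid <- !inv
  if (smooth_window > 1L) {
    for (ch in c("x", "y", "pupil_l", "pupil_r"))
      rec[[ch]] <- moving_average(rec[[ch]], as.integer(smooth_window))
  }
  rec
}

#' Detect ocular events by velocity thresholding (I-VT)
#'
#' Point-to-point gaze velocity above `velocity_threshold` marks saccadic
#' samples, below marks fixational samples; contiguous invalid runs become
#' blinks and break fixation/saccade segments. Segments shorter than the
#' respective minimum duration are merged into their neighbor.
#'
#' @param rec preprocessed [gaze_recording()].
#' @param velocity_threshold saccade velocity cutoff, position units per
#'   second (default 30, the conventional I-VT setting for degrees).
#' @param min_fixation_ms,min_saccade_ms minimum event durations.
#' @return data frame of events (class `ocular_events`): `kind`, `onset_ms`,
#'   `offset_ms`, `duration_ms`, `dispersion_x`, `dispersion_y`,
#'   `dispersion`, `amplitude`, `distance`, `mean_velocity`,
#'   `peak_velocity`, in temporal order.
#' @export
detect_events <- function(rec, velocity_threshold = 30,
                          min_fixation_ms = 60, min_saccade_ms = 10) {
  stopifnot(inherits(rec, "gaze_recording"))
  n <- nrow(rec)
  if (n == 0L) stop("empty recording", call. = FALSE)
  if (n >= 2L && any(diff(rec$t_ms) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  dt_ms <- stats::median(diff(rec$t_ms))
  if (n == 1L) dt_ms <- 1000 / (attr(rec, "sample_rate") %||% 1000)
  # per-sample velocity in units/s; sample i gets velocity from i-1 -> i
  vel <- c(0, sqrt(diff(rec$x)^2 + diff(rec$y)^2) / diff(rec$t_ms) * 1000)
  lab <- ifelse(rec$valid, ifelse(vel > velocity_threshold, "saccade",
                                  "fixation"), "blink")
  lab[1L] <- if (rec$valid[1L]) "fixation" else "blink"
  segs <- segment_runs(lab)
  segs$onset_ms <- rec$t_ms[segs$start]
  segs$offset_ms <- rec$t_ms[segs$end] + dt_ms
  segs$duration_ms <- segs$offset_ms - segs$onset_ms
  # merge undersized fixation/saccade segments into a neighbor of the
  # other kind (blinks are kept as-is)
  repeat {
    min_dur <- ifelse(segs$kind == "fixation", min_fixation_ms,
                      ifelse(segs$kind == "saccade", min_saccade_ms, 0))
    short <- which(segs$kind != "blink" & segs$duration_ms < min_dur)
    if (!length(short)) break
    s <- short[1L]
    nb <- c(s - 1L, s + 1L)
    nb <- nb[nb >= 1L & nb <= nrow(segs)]
    nb <- nb[segs$kind[nb] != "blink"]
    if (!length(nb)) {                      # isolated short segment: drop
      segs <- segs[-s, , drop = FALSE]
    } else {
      tgt <- nb[which.max(segs$duration_ms[nb])]
      segs$kind[s] <- segs$kind[tgt]
      segs <- coalesce_segments(segs)
    }
  }
  events_from_segments(segs, rec, dt_ms)
}

segment_runs <- function(lab) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  data.frame(kind = r$values, start = ends - r$lengths + 1L, end = ends,
             stringsAsFactors = FALSE)
}

coalesce_segments <- function(segs) {
  out <- segs[1L, , drop = FALSE]
  for (i in seq_len(nrow(segs))[-1L]) {
    j <- nrow(out)
    if (segs$kind[i] == out$kind[j]) {
      out$end[j] <- segs$end[i]
      out$offset_ms[j] <- segs$offset_ms[i]
      out$duration_ms[j] <- out$offset_ms[j] - out$onset_ms[j]
    } else {
      out <- rbind(out, segs[i, , drop = FALSE])
    }
  }
  out
}

events_from_segments <- function(segs, rec, dt_ms) {
  ev <- data.frame(kind = segs$kind, onset_ms = segs$onset_ms,
                   offset_ms = segs$offset_ms,
                   duration_ms = segs$duration_ms,
                   dispersion_x = NA_real_, dispersion_y = NA_real_,
                   dispersion = NA_real_, amplitude = NA_real_,
                   distance = NA_real_, mean_velocity = NA_real_,
                   peak_velocity = NA_real_)
  for (i in seq_len(nrow(segs))) {
    idx <- segs$start[i]:segs$end[i]
    if (segs$kind[i] == "fixation") {
      ev$dispersion_x[i] <- diff(range(rec$x[idx]))
      ev$dispersion_y[i] <- diff(range(rec$y[idx]))
      ev$dispersion[i] <- ev$dispersion_x[i] + ev$dispersion_y[i]
    } else if (segs$kind[i] == "saccade") {
      i0 <- max(segs$start[i] - 1L, 1L)     # include launch point
      dx <- rec$x[segs$end[i]] - rec$x[i0]
      dy <- rec$y[segs$end[i]] - rec$y[i0]
      ev$amplitude[i] <- sqrt(dx^2 + dy^2)
      path <- sum(sqrt(diff(rec$x[i0:segs$end[i]])^2 +
                         diff(rec$y[i0:segs$end[i]])^2))
      ev$distance[i] <- path
      ev$mean_velocity[i] <- path / (ev$duration_ms[i] / 1000)
      vs <- sqrt(diff(rec$x[i0:segs$end[i]])^2 +
                   diff(rec$y[i0:segs$end[i]])^2) /
        diff(rec$t_ms[i0:segs$end[i]]) * 1000
      ev$peak_velocity[i] <- max(vs)
    }
  }
  class(ev) <- c("ocular_events", "data.frame")
  ev
}

# ---- moments with documented conventions -----------------------------------

# population (ddof = 0) or sample (ddof = 1) variance
var_conv <- function(v, ddof = 0L) {
  n <- length(v)
  if (n == 0L) return(NA_real_)
  m <- mean(v)
  sum((v - m)^2) / (n - ddof)
}

sd_conv <- function(v, ddof = 0L) sqrt(var_conv(v, ddof))

# coefficient of variation; undefined (NA) when the mean is 0
cv_conv <- function(v, ddof = 0L) {
  m <- mean(v)
  if (length(v) == 0L || m == 0) return(NA_real_)
  sd_conv(v, ddof) / m
}

#' Skewness and excess kurtosis
#'
#' `skewness_conv` defaults to the adjusted Fisher-Pearson coefficient
#' `G1 = g1 * sqrt(n(n-1))/(n-2)`; `type = "moment"` gives the raw `g1`.
#' `kurtosis_conv` defaults to Fisher excess kurtosis `g2 = m4/m2^2 - 3`;
#' `type = "raw"` gives `m4/m2^2` without the `-3`.
#'
#' @param v numeric vector.
#' @param type convention switch, see details.
#' @return a single numeric value (NA for degenerate input).
#' @export
skewness_conv <- function(v, type = c("adjusted", "moment")) {
  type <- match.arg(type)
  n <- length(v)
  if (n < 3L) return(NA_real_)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((v - m)^3) / m2^1.5
  if (type == "moment") g1 else g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' @rdname skewness_conv
#' @export
kurtosis_conv <- function(v, type = c("excess", "raw")) {
  type <- match.arg(type)
  n <- length(v)
  if (n < 2L) return(NA_real_)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) return(NA_real_)
  k <- mean((v - m)^4) / m2^2
  if (type == "raw") k else k - 3
}

# mean pupil series: average of the two eyes where both valid, single
# channel otherwise
pupil_series <- function(rec) {
  p <- (rec$pupil_l + rec$pupil_r) / 2
  p[rec$valid]
}

# ---- feature dialects ------------------------------------------------------

#' Extract the SEED-style eye-movement feature set
#'
#' Means and standard deviations of pupil diameter (left/right), fixation
#' duration, fixation dispersion (X and Y), saccade duration, saccade
#' amplitude and blink duration, plus the event statistics: fixation
#' frequency (events/s), maximum fixation duration, maximum and total
#' fixation dispersion, saccade frequency, average saccade duration,
#' average saccade amplitude, and average saccade latency (mean gap between
#' consecutive saccade onsets). Features whose events are absent come back
#' `NA`, never fabricated.
#'
#' @param events an `ocular_events` data frame from [detect_events()].
#' @param rec the underlying [gaze_recording()].
#' @param ddof variance convention: 0 population (default), 1 sample.
#' @return named numeric feature vector.
#' @export
extract_seed_features <- function(events, rec, ddof = 0L) {
  fx <- events[events$kind == "fixation", , drop = FALSE]
  sc <- events[events$kind == "saccade", , drop = FALSE]
  bl <- events[events$kind == "blink", , drop = FALSE]
  dur_s <- (max(rec$t_ms) - min(rec$t_ms) +
              stats::median(diff(rec$t_ms))) / 1000
  stat_pair <- function(v) if (length(v)) c(mean(v), sd_conv(v, ddof)) else
    c(NA_real_, NA_real_)
  out <- c(
    pupil_left_mean = if (any(rec$valid)) mean(rec$pupil_l[rec$valid]) else NA_real_,
    pupil_left_sd = if (any(rec$valid)) sd_conv(rec$pupil_l[rec$valid], ddof) else NA_real_,
    pupil_right_mean = if (any(rec$valid)) mean(rec$pupil_r[rec$valid]) else NA_real_,
    pupil_right_sd = if (any(rec$valid)) sd_conv(rec$pupil_r[rec$valid], ddof) else NA_real_,
    fixation_duration_mean = stat_pair(fx$duration_ms)[1L],
    fixation_duration_sd = stat_pair(fx$duration_ms)[2L],
    dispersion_x_mean = stat_pair(fx$dispersion_x)[1L],
    dispersion_x_sd = stat_pair(fx$dispersion_x)[2L],
    dispersion_y_mean = stat_pair(fx$dispersion_y)[1L],
    dispersion_y_sd = stat_pair(fx$dispersion_y)[2L],
    saccade_duration_mean = stat_pair(sc$duration_ms)[1L],
    saccade_duration_sd = stat_pair(sc$duration_ms)[2L],
    saccade_amplitude_mean = stat_pair(sc$amplitude)[1L],
    saccade_amplitude_sd = stat_pair(sc$amplitude)[2L],
    blink_duration_mean = stat_pair(bl$duration_ms)[1L],
    blink_duration_sd = stat_pair(bl$duration_ms)[2L],
    fixation_frequency = nrow(fx) / dur_s,
    fixation_duration_max = if (nrow(fx)) max(fx$duration_ms) else NA_real_,
    fixation_dispersion_max = if (nrow(fx)) max(fx$dispersion) else NA_real_,
    fixation_dispersion_total = if (nrow(fx)) sum(fx$dispersion) else NA_real_,
    saccade_frequency = nrow(sc) / dur_s,
    saccade_duration_avg = stat_pair(sc$duration_ms)[1L],
    saccade_amplitude_avg = stat_pair(sc$amplitude)[1L],
    saccade_latency_avg = if (nrow(sc) >= 2L) mean(diff(sc$onset_ms)) else NA_real_
  )
  out
}

#' Extract the eSEE-d-style eye-movement feature set
#'
#' Thirteen features: pupil diameter mean/variance/CV, fixation duration
#' mean/variance/CV, saccade duration kurtosis/skewness/CV, saccade speed
#' kurtosis/skewness, saccade distance kurtosis/skewness. CV is the
#' (population) standard deviation over the mean and is `NA` when the mean
#' is zero.
#'
#' @inheritParams extract_seed_features
#' @param skew_type,kurt_type moment conventions, see [skewness_conv()].
#' @return named numeric vector of 13 features.
#' @export
extract_esee_features <- function(events, rec, ddof = 0L,
                                  skew_type = "adjusted",
                                  kurt_type = "excess") {
  fx <- events[events$kind == "fixation", , drop = FALSE]
  sc <- events[events$kind == "saccade", , drop = FALSE]
  p <- pupil_series(rec)
  c(pupil_diameter_mean = if (length(p)) mean(p) else NA_real_,
    pupil_diameter_var = if (length(p)) var_conv(p, ddof) else NA_real_,
    pupil_diameter_cv = if (length(p)) cv_conv(p, ddof) else NA_real_,
    fixation_duration_mean = if (nrow(fx)) mean(fx$duration_ms) else NA_real_,
    fixation_duration_var = if (nrow(fx)) var_conv(fx$duration_ms, ddof) else NA_real_,
    fixation_duration_cv = if (nrow(fx)) cv_conv(fx$duration_ms, ddof) else NA_real_,
    saccade_duration_kurt = if (nrow(sc)) kurtosis_conv(sc$duration_ms, kurt_type) else NA_real_,
    saccade_duration_skew = if (nrow(sc)) skewness_conv(sc$duration_ms, skew_type) else NA_real_,
    saccade_duration_cv = if (nrow(sc)) cv_conv(sc$duration_ms, ddof) else NA_real_,
    saccade_speed_kurt = if (nrow(sc)) kurtosis_conv(sc$mean_velocity, kurt_type) else NA_real_,
    saccade_speed_skew = if (nrow(sc)) skewness_conv(sc$mean_velocity, skew_type) else NA_real_,
    saccade_distance_kurt = if (nrow(sc)) kurtosis_conv(sc$distance, kurt_type) else NA_real_,
    saccade_distance_skew = if (nrow(sc)) skewness_conv(sc$distance, skew_type) else NA_real_)
}

#' Table 4 feature-name catalogue for the eSEE-d dialect
#' @return character vector of the 13 expected feature names.
#' @export
esee_feature_names <- function() {
  c("pupil_diameter_mean", "pupil_diameter_var", "pupil_diameter_cv",
    "fixation_duration_mean", "fixation_duration_var", "fixation_duration_cv",
    "saccade_duration_kurt", "saccade_duration_skew", "saccade_duration_cv",
    "saccade_speed_kurt", "saccade_speed_skew",
    "saccade_distance_kurt", "saccade_distance_skew")
}

# ---- ANOVA screening -------------------------------------------------------

#' Screen features by one-way ANOVA across emotion classes
#'
#' Runs a classic one-way ANOVA (equal-variance F test) per feature against
#' the label groups; features with `p < alpha` are retained. Features whose
#' F statistic is undefined (zero within- and between-group variance) are
#' dropped with a recorded reason.
#'
#' @param table a `feature_table` (see [read_feature_table()]) or a list
#'   with `features` (numeric matrix/data frame), `labels`, `subject_ids`.
#' @param alpha retention threshold on the p-value (default 0.05).
#' @return list with `retained` (the filtered feature table) and `report`
#'   (data frame: feature, F, p, retained, reason).
#' @export
anova_screen <- function(table, alpha = 0.05) {
  X <- as.data.frame(table$features)
  g <- factor(table$labels)
  if (nlevels(g) < 2L) stop("ANOVA screening needs >= 2 classes", call. = FALSE)
  if (min(table(g)) < 2L) stop("ANOVA screening needs >= 2 samples per class",
                               call. = FALSE)
  rep_rows <- lapply(names(X), function(f) {
    v <- X[[f]]
    ok <- is.finite(v)
    if (sum(ok) < 2L || length(unique(v[ok])) == 1L)
      return(data.frame(feature = f, F = NA_real_, p = NA_real_,
                        retained = FALSE, reason = "constant or empty"))
    gg <- droplevels(g[ok])
    if (nlevels(gg) < 2L)
      return(data.frame(feature = f, F = NA_real_, p = NA_real_,
                        retained = FALSE, reason = "single group after NA removal"))
    # zero within-group variance makes the F denominator 0; p -> 0
    wvar <- tapply(v[ok], gg, function(z) var_conv(z, 1L))
    if (all(wvar == 0, na.rm = TRUE)) {
      return(data.frame(feature = f, F = Inf, p = 0,
                        retained = 0 < alpha, reason = ""))
    }
    ft <- stats::oneway.test(v[ok] ~ gg, var.equal = TRUE)
    data.frame(feature = f, F = unname(ft$statistic), p = unname(ft$p.value),
               retained = unname(ft$p.value) < alpha, reason = "")
  })
  report <- do.call(rbind, rep_rows)
  keep <- report$feature[report$retained]
  retained <- table
  retained$features <- X[, keep, drop = FALSE]
  list(retained = retained, report = report)
}

# ---- Russell label mapping -------------------------------------------------

#' Map discrete emotion labels onto Russell arousal/valence classes
#'
#' anger and disgust map to high arousal / negative valence; sadness to low
#' arousal / negative valence; tenderness to low arousal / positive valence;
#' neutral to medium arousal / medium valence.
#'
#' @param emotion_labels character vector drawn from
#'   `{anger, disgust, sadness, tenderness, neutral}`.
#' @return list with factors `arousal` (levels LA, MA, HA) and `valence`
#'   (levels NV, MV, PV).
#' @export
map_to_russell <- function(emotion_labels) {
  mapping <- list(anger = c("HA", "NV"), disgust = c("HA", "NV"),
                  sadness = c("LA", "NV"), tenderness = c("LA", "PV"),
                  neutral = c("MA", "MV"))
  unknown <- setdiff(unique(emotion_labels), names(mapping))
  if (length(unknown))
    stop(sprintf("unknown emotion label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  m <- do.call(rbind, mapping[as.character(emotion_labels)])
  list(arousal = factor(m[, 1L], levels = c("LA", "MA", "HA")),
       valence = factor(m[, 2L], levels = c("NV", "MV", "PV")))
}
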