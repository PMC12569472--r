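# shared small fixtures, built in code

# a short conditioned 12-channel table of white noise (no filtering cost)
make_noise_cond <- function(n = 600, seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(time_s = seq_len(n) * 1e-3)
  for (ch in c(paste0("L", 1:6), paste0("R", 1:6))) d[[ch]] <- rnorm(n)
  attr(d, "sample_rate") <- 1000
  d
}

# joint-angle series with oscillatory content
make_angle_series <- function(n = 500, f = 2) {
  t <- seq_len(n) * 1e-3
  tibble::tibble(time_s = t,
                 theta1 = 10 * sin(2 * pi * f * t),
                 theta2 = 14 * sin(2 * pi * f * t + 0.7),
                 theta3 = 22 * cos(2 * pi * f * t),
                 theta4 = 35 * sin(2 * pi * f * t + 1.9))
}

# 6-landmark pose track from a body pose (for round trips)
pose_from_body <- function(pose) {
  track <- tibble::tibble(frame = seq_len(nrow(pose)), time_s = pose$time_s)
  for (i in 1:6) {
    track[[paste0("p", i, "_x")]] <- pose[[paste0("x", i)]]
    track[[paste0("p", i, "_y")]] <- pose[[paste0("y", i)]]
    track[[paste0("p", i, "_l")]] <- 1
  }
  attr(track, "frame_rate") <- 1000
  track
}

# brute-force peak prominence by definition (independent oracle)
oracle_peaks <- function(x, prom_min) {
  n <- length(x)
  cand <- which(vapply(2:(n - 1), function(i) {
    x[i] > x[i - 1] && x[i] > x[i + 1]
  }, logical(1))) + 1
  keep <- integer(0)
  for (i in cand) {
    left_higher <- which(x[seq_len(i - 1)] > x[i])
    lo <- if (length(left_higher)) max(left_higher) + 1 else 1
    right_higher <- which(x[(i + 1):n] > x[i])
    hi <- if (length(right_higher)) i + min(right_higher) - 1 else n
    prom <- x[i] - max(min(x[lo:i]), min(x[i:hi]))
    if (prom >= prom_min) keep <- c(keep, i)
  }
  keep
}

# matched delays for a generated trial, against the analytic landmark LD
trial_delays <- function(tr, use_truth_ld = TRUE) {
  cond <- condition_emg(tr$emg, 2500)
  env <- emg_envelope(cond)
  period <- 1 / tr$spec$f_tail_hz
  peaks <- detect_onset_peaks(env, 3, 0.4 * period)
  fracs <- tr$truth$landmark_fractions
  purrr::map_dfr(unique(peaks$channel), function(ch) {
    k <- as.integer(sub("^[LR]", "", ch))
    lm <- which.min(abs(fracs - tr$spec$channel_positions[k]))
    ld <- tibble::tibble(time_s = tr$truth$ld$time_s,
                         ld = tr$truth$ld[[paste0("ld", lm)]])
    ex <- detect_ld_extrema(ld, min_sep_s = 0.4 * period)
    match_delays(peaks[peaks$channel == ch, ], ex, horizon_s = period)
  })
}

# perturb NN parameters away from the ReLU kink before gradient checks
jitter_params <- function(p, sd = 0.05, seed = 99) {
  set.seed(seed)
  for (nm in names(p)) p[[nm]] <- p[[nm]] + rnorm(length(p[[nm]]), sd = sd)
  p
}
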