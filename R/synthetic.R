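#' Specification of a synthetic swimming trial
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' carangiform travelling-wave midline whose amplitude grows toward the tail,
#' side-alternating EMG bursts phase-locked to the local bending with a known
#' per-channel lead `tau` (positive = EMG leads), band-limited (20-450 Hz)
#' carrier noise under each burst, baseline and 50 Hz mains contamination,
#' inter-channel crosstalk, and a vortex condition in which a configurable
#' fraction of bursts carry a negative lag.
#'
#' Defaults are the study conditions: 0.274 m/s flow, a tail-beat period of
#' 0.612 s, electrodes at arclength fractions 0.5-1.0 on both sides, and a
#' +50 ms lead, which exceeds the default envelope smoothing window so sign
#' recovery is unambiguous.
#'
#' @param duration_s trial length, s.
#' @param flow_speed flow speed U, m/s.
#' @param body_length_cm body length, cm.
#' @param f_tail_hz tail-beat frequency, Hz.
#' @param amp_coef coefficients `c(c1, c2)` of the amplitude envelope
#'   `A(s) = c1*s + c2*s^2` (fraction of BL; `s` = arclength fraction).
#' @param wavelength_bl body-wave wavelength in body lengths.
#' @param channel_positions electrode arclength fractions per side.
#' @param tau_ms per-channel lead magnitude, ms (positive = EMG leads local
#'   bending); scalar or one per position.
#' @param neg_lag_fraction probability that a burst carries `-|tau|` instead
#'   of `+|tau|` (0 for laminar).
#' @param burst_gain_cv coefficient of variation of the per-burst lognormal
#'   amplitude gain (cycle-to-cycle EMG amplitude variability; mean gain 1).
#' @param noise_sd baseline white-noise SD, mV.
#' @param crosstalk_coef linear mixing coefficient from the mean of the other
#'   channels' pre-mix traces.
#' @param mains_amplitude 50 Hz contamination amplitude, mV.
#' @param dropout_fraction fraction of pose frames per landmark given a low
#'   tracking likelihood (and corrupted coordinates).
#' @param condition trial label: `laminar`, `cyl5` or `cyl7`.
#' @param seed integer seed; the trial is fully reproducible from it.
#' @return a `trial_spec` list.
#' @export
trial_spec <- function(duration_s = 20, flow_speed = 0.274,
                       body_length_cm = 30, f_tail_hz = 1 / 0.612,
                       amp_coef = c(0.02, 0.08), wavelength_bl = 1,
                       channel_positions = seq(0.5, 1, by = 0.1),
                       tau_ms = 50, neg_lag_fraction = 0,
                       burst_gain_cv = 0.25,
                       noise_sd = 0.05, crosstalk_coef = 0.05,
                       mains_amplitude = 0.02, dropout_fraction = 0,
                       condition = "laminar", seed = 1) {
  stopifnot(f_tail_hz > 0, f_tail_hz < 10,
            all(channel_positions > 0), all(channel_positions <= 1),
            neg_lag_fraction >= 0, neg_lag_fraction <= 1)
  if (condition == "laminar" && neg_lag_fraction != 0) {
    abort("laminar condition requires neg_lag_fraction = 0")
  }
  structure(list(duration_s = duration_s, flow_speed = flow_speed,
                 body_length_cm = body_length_cm, f_tail_hz = f_tail_hz,
                 amp_coef = amp_coef, wavelength_bl = wavelength_bl,
                 channel_positions = channel_positions, tau_ms = tau_ms,
                 neg_lag_fraction = neg_lag_fraction,
                 burst_gain_cv = burst_gain_cv, noise_sd = noise_sd,
                 crosstalk_coef = crosstalk_coef,
                 mains_amplitude = mains_amplitude,
                 dropout_fraction = dropout_fraction,
                 condition = condition, seed = seed),
            class = "trial_spec")
}

amp_envelope <- function(spec, s) (spec$amp_coef[1] * s + spec$amp_coef[2] * s^2)

# lateral position of arclength fraction s at time t (cm)
wave_y <- function(spec, s, t) {
  amp_envelope(spec, s) * spec$body_length_cm *
    sin(2 * pi * (spec$f_tail_hz * t - s / spec$wavelength_bl))
}

#' Generate the kinematic half of a synthetic trial
#'
#' Twelve midline landmarks at fixed arclength fractions, sampled at 100 fps,
#' follow the travelling wave `y(s, t) = A(s) * BL * sin(2*pi*(f*t - s/
#' lambda))`. Ground truth carries the analytic joint angles at 1 kHz (for
#' the default six joint landmarks), the analytic lateral displacement of
#' every landmark, and the landmark fractions.
#'
#' @param spec a [trial_spec()].
#' @return list: `pose` (pose tibble at 100 fps), `truth` (list).
#' @export
generate_kinematics <- function(spec) {
  set.seed(derive_seed(spec$seed, 1))
  fracs <- default_landmark_fractions()
  frames <- 0:(round(spec$duration_s * 100))
  t <- frames / 100
  pose <- tibble::tibble(frame = frames, time_s = t)
  for (i in seq_along(fracs)) {
    x <- rep(fracs[i] * spec$body_length_cm, length(t))
    y <- wave_y(spec, fracs[i], t)
    l <- rep(1, length(t))
    if (spec$dropout_fraction > 0) {
      nd <- round(spec$dropout_fraction * length(t))
      # keep the first/last frames valid so interpolation has anchors
      drop <- sample(seq(3, length(t) - 2), nd)
      l[drop] <- 0.3
      y[drop] <- y[drop] + rnorm(nd, sd = spec$body_length_cm * 0.2)
      x[drop] <- x[drop] + rnorm(nd, sd = spec$body_length_cm * 0.2)
    }
    pose[[paste0("p", i, "_x")]] <- x
    pose[[paste0("p", i, "_y")]] <- y
    pose[[paste0("p", i, "_l")]] <- l
  }
  attr(pose, "frame_rate") <- 100
  class(pose) <- c("pose_tbl", class(pose))

  # analytic joint angles at 1 kHz for the default joint landmarks
  jl <- c(1, 4, 6, 8, 10, 12)
  tk <- seq(0, spec$duration_s, by = 1e-3)
  X <- outer(rep(1, length(tk)), fracs[jl] * spec$body_length_cm)
  Y <- sapply(fracs[jl], function(s) wave_y(spec, s, tk))
  hd <- atan2(Y[, -1] - Y[, -6], X[, -1] - X[, -6])
  th <- wrap_rad(hd[, 2:5] - hd[, 1:4]) * 180 / pi
  lens <- sqrt((X[1, -1] - X[1, -6])^2) # nominal; actual vary with bending
  angles <- tibble::tibble(time_s = tk, theta1 = th[, 1], theta2 = th[, 2],
                           theta3 = th[, 3], theta4 = th[, 4])
  ld <- tibble::tibble(time_s = tk)
  for (i in seq_along(fracs)) ld[[paste0("ld", i)]] <- wave_y(spec, fracs[i], tk)

  list(pose = pose,
       truth = list(spec = spec, landmark_fractions = fracs,
                    joint_landmarks = jl, angles = angles, ld = ld,
                    nominal_segment_lengths = lens))
}

# 12 landmark arclength fractions, denser over the posterior half where the
# electrodes sit (0.5-1.0 BL) so every electrode station has a landmark
default_landmark_fractions <- function() {
  c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 1)
}

# map channel position to its nearest landmark index
channel_landmark <- function(position, fracs = default_landmark_fractions()) {
  which.min(abs(fracs - position))
}

#' Generate the EMG half of a synthetic trial
#'
#' Each channel at arclength fraction `s` bursts once per tail-beat cycle,
#' phase-locked to the local bending extremum of its own midline point: left
#' channels to lateral-displacement minima, right channels to maxima. The
#' burst envelope is a raised-cosine half-wave of width half a period whose
#' apex leads the extremum by `tau` (per burst, the lead flips sign with
#' probability `neg_lag_fraction`). The trace is the envelope times a
#' band-limited (20-450 Hz) unit-variance carrier, plus baseline noise, 50 Hz
#' mains and linear crosstalk from the mean of the other channels, sampled at
#' 2.5 kHz.
#'
#' @param spec a [trial_spec()].
#' @param truth the truth list from [generate_kinematics()].
#' @return list: `emg` (raw EMG tibble at 2.5 kHz), `bursts` (tibble of
#'   per-burst ground truth: channel, side, position, burst_time_s,
#'   extremum_time_s, true_lag_ms, label).
#' @export
generate_emg <- function(spec, truth) {
  fs <- 2500
  t <- seq(0, spec$duration_s, by = 1 / fs)
  n <- length(t)
  f <- spec$f_tail_hz
  Tp <- 1 / f
  bp <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  chans <- c(paste0("L", seq_along(spec$channel_positions)),
             paste0("R", seq_along(spec$channel_positions)))
  sides <- rep(c("left", "right"), each = length(spec$channel_positions))
  poss <- rep(spec$channel_positions, 2)
  taus <- rep_len(abs(spec$tau_ms), length(spec$channel_positions))
  taus <- rep(taus, 2) / 1000
  pre <- matrix(0, n, length(chans))
  bursts <- vector("list", length(chans))
  for (ci in seq_along(chans)) {
    set.seed(derive_seed(spec$seed, 100 + ci))
    s <- poss[ci]
    # extremum phase: minima (left) at f*t - s/lambda = k - 1/4,
    # maxima (right) at k + 1/4
    off <- if (sides[ci] == "left") -0.25 else 0.25
    k <- seq(floor(-s / spec$wavelength_bl - 1),
             ceiling(f * spec$duration_s + 1))
    text <- (k + off + s / spec$wavelength_bl) / f
    lag_sign <- ifelse(runif(length(text)) < spec$neg_lag_fraction, -1, 1)
    sig <- sqrt(log(1 + spec$burst_gain_cv^2))
    gain <- exp(rnorm(length(text), -sig^2 / 2, sig))
    ctr <- text - lag_sign * taus[ci]
    ok <- ctr - Tp / 4 >= 0 & ctr + Tp / 4 <= spec$duration_s
    text <- text[ok]; ctr <- ctr[ok]; lag_sign <- lag_sign[ok]; gain <- gain[ok]
    env <- numeric(n)
    for (b in seq_along(ctr)) {
      i0 <- max(1, ceiling((ctr[b] - Tp / 4) * fs) + 1)
      i1 <- min(n, floor((ctr[b] + Tp / 4) * fs) + 1)
      u <- t[i0:i1] - ctr[b]
      env[i0:i1] <- env[i0:i1] + gain[b] * cos(2 * pi * f * u)^2
    }
    carrier <- signal::filtfilt(bp, rnorm(n))
    carrier <- carrier / sd(carrier)
    pre[, ci] <- env * carrier
    bursts[[ci]] <- tibble::tibble(
      channel = chans[ci], side = sides[ci], position = s,
      burst_time_s = ctr, extremum_time_s = text,
      true_lag_ms = lag_sign * taus[ci] * 1000, gain = gain,
      label = ifelse(lag_sign > 0, "leading", "lagging"))
  }
  mixed <- pre
  if (length(chans) > 1 && spec$crosstalk_coef != 0) {
    tot <- rowSums(pre)
    for (ci in seq_along(chans)) {
      mixed[, ci] <- pre[, ci] +
        spec$crosstalk_coef * (tot - pre[, ci]) / (length(chans) - 1)
    }
  }
  set.seed(derive_seed(spec$seed, 999))
  emg <- tibble::tibble(time_s = t)
  for (ci in seq_along(chans)) {
    emg[[chans[ci]]] <- mixed[, ci] + spec$noise_sd * rnorm(n) +
      spec$mains_amplitude * sin(2 * pi * 50 * t)
  }
  attr(emg, "sample_rate") <- fs
  list(emg = emg, bursts = dplyr::bind_rows(bursts))
}

condition_presets <- function(condition) {
  switch(condition,
    laminar = list(neg_lag_fraction = 0, duration_s = 20),
    cyl5 = list(neg_lag_fraction = 0.48, duration_s = 26),
    cyl7 = list(neg_lag_fraction = 0.29, duration_s = 26),
    abort(paste0("unknown condition: ", condition)))
}

#' Generate a complete synthetic trial
#'
#' Condition presets set the negative-lag fraction: `laminar` 0, `cyl5` 0.48,
#' `cyl7` 0.29 (presets mirroring the observed fractions in the vortex
#' conditions; they are presets, not predictions). Everything is overridable
#' and the trial is byte-reproducible from `(condition, seed)`.
#'
#' @param condition `laminar`, `cyl5` or `cyl7`.
#' @param seed integer seed.
#' @param out_dir if non-NULL, write `*_emg.csv` (2.5 kHz),
#'   `*_pose.csv` (DeepLabCut dialect) and `*_truth.json` there.
#' @param overrides named list of [trial_spec()] arguments to override.
#' @return list: `spec`, `pose`, `emg`, `truth` (with `$bursts`), `paths`
#'   (NULL unless written), `manifest` (one-row tibble when written).
#' @export
generate_trial <- function(condition = "laminar", seed = 1, out_dir = NULL,
                           overrides = list()) {
  preset <- condition_presets(condition)
  args <- utils::modifyList(
    c(list(condition = condition, seed = seed), preset), overrides)
  spec <- do.call(trial_spec, args)
  kin <- generate_kinematics(spec)
  emg <- generate_emg(spec, kin$truth)
  truth <- kin$truth
  truth$bursts <- emg$bursts
  res <- list(spec = spec, pose = kin$pose, emg = emg$emg, truth = truth,
              paths = NULL, manifest = NULL)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    stem <- file.path(out_dir, sprintf("%s_seed%d", condition, seed))
    paths <- list(emg = paste0(stem, "_emg.csv"),
                  pose = paste0(stem, "_pose.csv"),
                  truth = paste0(stem, "_truth.json"))
    write_emg_csv(res$emg, paths$emg)
    write_pose_csv_dlc(res$pose, paths$pose)
    tj <- list(spec = unclass(spec), seed = seed,
               bursts = emg$bursts[c("channel", "burst_time_s",
                                     "true_lag_ms", "label")])
    jsonlite::write_json(tj, paths$truth, auto_unbox = TRUE, digits = NA)
    res$paths <- paths
    res$manifest <- tibble::tibble(
      trial_id = sprintf("%s_seed%d", condition, seed),
      emg_path = paths$emg, pose_path = paths$pose, condition = condition,
      flow_speed = spec$flow_speed, body_length_cm = spec$body_length_cm,
      pixel_scale = 1, sync_offset = 0, subject_id = seed)
  }
  res
}

#' Synthesise joint-angle targets linearly recoverable from an input matrix
#'
#' Builds targets `theta_j = sum_c w_jc * z(col_c) + noise` over the MAV and
#' RMS feature columns of every channel present, scaled to a given angle SD.
#' Because every channel's block carries independent weight, removing
#' channels removes predictive information -- the construction used to
#' exercise the mapping models and the channel-count study against a known
#' answer.
#'
#' @param V input-matrix tibble.
#' @param target_sd angle SD, degrees.
#' @param noise_frac irreducible noise SD as a fraction of `target_sd`.
#' @param seed integer seed.
#' @return tibble `theta1..theta4` with attribute `weights`.
#' @export
make_recoverable_targets <- function(V, target_sd = 20, noise_frac = 0.02,
                                     seed = 1) {
  set.seed(derive_seed(seed, 7))
  chans <- attr(V, "channel_order")
  cols <- c(paste0(chans, "_mav"), paste0(chans, "_rms"))
  Z <- scale(as.matrix(V[, cols]))
  Z[!is.finite(Z)] <- 0
  W <- matrix(rnorm(length(cols) * 4), ncol = 4)
  raw <- Z %*% W
  raw <- scale(raw)
  th <- raw * target_sd +
    matrix(rnorm(nrow(V) * 4, sd = noise_frac * target_sd), ncol = 4)
  out <- tibble::as_tibble(as.data.frame(th))
  names(out) <- paste0("theta", 1:4)
  attr(out, "weights") <- W
  attr(out, "weight_columns") <- cols
  out
}
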