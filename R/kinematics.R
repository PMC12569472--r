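#' Filter and gap-fill a pose track
#'
#' Drops per-landmark samples whose tracking likelihood is at or below
#' `likelihood_min` and fills the gaps by modified-Akima interpolation.
#' Retained samples are unchanged; the operation is idempotent.
#'
#' Pose tracks are wide tibbles: `frame`, `time_s`, then `p<i>_x`, `p<i>_y`,
#' `p<i>_l` per landmark (coordinates in cm after pixel scaling, likelihood
#' in `[0, 1]`).
#'
#' @param track pose tibble.
#' @param likelihood_min retention threshold (default 0.9; strictly-greater
#'   samples are kept).
#' @return pose tibble with filled coordinates; likelihoods are set to 1 at
#'   filled samples and left unchanged at retained ones.
#' @export
clean_pose <- function(track, likelihood_min = 0.9) {
  lm_ids <- pose_landmark_ids(track)
  out <- track
  for (i in lm_ids) {
    lcol <- paste0("p", i, "_l")
    keep <- track[[lcol]] > likelihood_min
    if (sum(keep) < 4) {
      abort(paste0("landmark ", i, " has fewer than 4 frames above the likelihood threshold"))
    }
    if (all(keep)) next
    for (cc in paste0("p", i, c("_x", "_y"))) {
      out[[cc]] <- interp_makima(track$time_s[keep], track[[cc]][keep], track$time_s)
    }
    out[[lcol]][!keep] <- 1
  }
  out
}

pose_landmark_ids <- function(track) {
  xs <- grep("^p[0-9]+_x$", names(track), value = TRUE)
  sort(as.integer(sub("^p([0-9]+)_x$", "\\1", xs)))
}

#' Reduce a pose track to four joint angles
#'
#' Six head-to-tail landmarks define five rigid segments; the joint angle
#' `theta_i` is the signed planar angle from segment `i` to segment `i + 1`
#' (counter-clockwise positive, degrees). The head frame (first landmark
#' position and first-segment heading) is carried along so body pose can be
#' re-embedded in world coordinates. Segment lengths are the per-trial median
#' inter-landmark distances. The series is resampled to the 1 kHz working
#' rate unless it is already there.
#'
#' @param track pose tibble (cleaned; see [clean_pose()]).
#' @param joint_landmarks the six landmark indices, ordered head to tail.
#'   Default `c(1, 4, 6, 8, 10, 12)`: head, mid-body, then posterior-dense to
#'   match the electrode region at 0.5-1.0 body lengths.
#' @param rate_hz output rate (default 1000). Use the input rate to skip
#'   resampling.
#' @return tibble of class `joint_angles`: `time_s`, `theta1..theta4`
#'   (degrees), `head_x`, `head_y`, `head_heading` (degrees); attribute
#'   `segment_lengths` (cm, length 5).
#' @export
pose_to_joint_angles <- function(track, joint_landmarks = c(1, 4, 6, 8, 10, 12),
                                 rate_hz = 1000) {
  if (length(joint_landmarks) != 6) abort("exactly 6 joint landmarks required")
  X <- sapply(joint_landmarks, function(i) track[[paste0("p", i, "_x")]])
  Y <- sapply(joint_landmarks, function(i) track[[paste0("p", i, "_y")]])
  dx <- X[, -1, drop = FALSE] - X[, -6, drop = FALSE]
  dy <- Y[, -1, drop = FALSE] - Y[, -6, drop = FALSE]
  seg_len_t <- sqrt(dx^2 + dy^2)
  if (any(seg_len_t == 0)) abort("degenerate zero-length segment")
  lens <- apply(seg_len_t, 2, median)
  headings <- atan2(dy, dx)                      # n x 5, radians
  th <- headings[, 2:5, drop = FALSE] - headings[, 1:4, drop = FALSE]
  th <- wrap_rad(th) * 180 / pi
  out <- tibble::tibble(
    time_s = track$time_s,
    theta1 = th[, 1], theta2 = th[, 2], theta3 = th[, 3], theta4 = th[, 4],
    head_x = X[, 1], head_y = Y[, 1],
    head_heading = headings[, 1] * 180 / pi)
  if (any(abs(th) >= 120)) {
    warn("joint angles exceed 120 degrees: anatomically implausible pose")
  }
  in_rate <- attr(track, "frame_rate") %||%
    round(1 / median(diff(track$time_s)))
  if (!isTRUE(all.equal(in_rate, rate_hz)) && nrow(out) >= 4) {
    out <- resample_to_rate(out, rate_hz)
  }
  attr(out, "segment_lengths") <- lens
  attr(out, "sample_rate") <- rate_hz
  class(out) <- c("joint_angles", class(out))
  out
}

#' Reconstruct body pose from joint angles
#'
#' Chains planar rigid transforms: anchor point 1 sits at the origin with
#' heading 0 (head frame); point `i + 1` extends point `i` by the segment
#' length along the cumulative angle `sum(theta_k, k <= i - 1)` (with
#' `theta_0 = 0`). Link lengths are preserved exactly at every sample.
#'
#' @param angles `joint_angles` tibble (needs the `segment_lengths`
#'   attribute, or pass `segment_lengths`).
#' @param segment_lengths optional override, 5 positive lengths (cm).
#' @return tibble of class `body_pose`: `time_s`, `x1..x6`, `y1..y6` (cm, head
#'   frame); attribute `segment_lengths`.
#' @export
forward_kinematics <- function(angles, segment_lengths = NULL) {
  lens <- segment_lengths %||% attr(angles, "segment_lengths")
  if (is.null(lens) || length(lens) != 5 || any(lens <= 0)) {
    abort("five positive segment lengths required")
  }
  th <- as.matrix(dplyr::select(angles, dplyr::all_of(paste0("theta", 1:4)))) * pi / 180
  n <- nrow(th)
  cum <- cbind(0, t(apply(th, 1, cumsum)))       # n x 5 cumulative headings
  if (n == 1) cum <- matrix(c(0, cumsum(th[1, ])), nrow = 1)
  X <- matrix(0, n, 6); Y <- matrix(0, n, 6)
  for (i in 1:5) {
    X[, i + 1] <- X[, i] + lens[i] * cos(cum[, i])
    Y[, i + 1] <- Y[, i] + lens[i] * sin(cum[, i])
  }
  out <- tibble::tibble(time_s = angles$time_s)
  for (i in 1:6) out[[paste0("x", i)]] <- X[, i]
  for (i in 1:6) out[[paste0("y", i)]] <- Y[, i]
  attr(out, "segment_lengths") <- lens
  class(out) <- c("body_pose", class(out))
  out
}

#' Smooth midline through the six anchor points
#'
#' Modified-Akima interpolation through the anchors of one sample of a
#' reconstructed pose, for display; anchor points are not altered.
#'
#' @param pose `body_pose` tibble.
#' @param sample row index.
#' @param n_points points on the smoothed midline.
#' @return tibble `x`, `y`.
#' @export
smooth_midline <- function(pose, sample = 1, n_points = 100) {
  xs <- as.numeric(pose[sample, paste0("x", 1:6)])
  ys <- as.numeric(pose[sample, paste0("y", 1:6)])
  s <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  sg <- seq(0, s[6], length.out = n_points)
  tibble::tibble(x = interp_makima(s, xs, sg), y = interp_makima(s, ys, sg))
}

#' Lateral displacement of a landmark
#'
#' Signed perpendicular coordinate of a landmark relative to the flow axis
#' through the trial-mean landmark position (per-landmark mean removed).
#'
#' @param track pose tibble (or any tibble with `p<i>_x`, `p<i>_y`).
#' @param landmark landmark index.
#' @param flow_axis unit vector of the tank flow direction (default `+x`).
#' @return tibble `time_s`, `ld` (cm).
#' @export
lateral_displacement <- function(track, landmark, flow_axis = c(1, 0)) {
  flow_axis <- flow_axis / sqrt(sum(flow_axis^2))
  nrm <- c(-flow_axis[2], flow_axis[1])
  x <- track[[paste0("p", landmark, "_x")]]
  y <- track[[paste0("p", landmark, "_y")]]
  ld <- (x - mean(x)) * nrm[1] + (y - mean(y)) * nrm[2]
  tibble::tibble(time_s = track$time_s, ld = ld)
}

#' Tail-beat summary and Strouhal number
#'
#' Tail-beat frequency is the dominant Welch-spectrum peak of the tail
#' lateral displacement; the period is its reciprocal; amplitude is the mean
#' peak-to-peak excursion over detected half-cycles (adjacent alternating
#' extrema); the Strouhal number is `St = f * A / U` with the amplitude
#' converted from cm to m.
#'
#' @param ld tibble `time_s`, `ld` (cm) for the tail landmark.
#' @param flow_speed flow speed `U`, m/s.
#' @param body_length_cm body length, cm (carried into the summary).
#' @return list of class `kinematic_summary`: `f_hz`, `period_s`, `amp_cm`,
#'   `strouhal`, `body_length_cm`, `flow_speed`.
#' @export
kinematic_summary <- function(ld, flow_speed, body_length_cm = NA_real_) {
  fs <- round(1 / median(diff(ld$time_s)))
  dur <- ld$time_s[nrow(ld)] - ld$time_s[1]
  pk <- dominant_frequency(ld$ld, fs)
  noise_floor <- median(pk$psd$power)
  if (max(pk$psd$power[-1]) < 10 * noise_floor) {
    abort("no spectral peak above the noise floor")
  }
  f <- pk$freq
  if (dur * f < 3) abort("need at least 3 full oscillation cycles")
  ex <- detect_ld_extrema(ld, min_sep_s = 0.25 / f)
  ev <- dplyr::arrange(ex$events, .data$time_s)
  vals <- ev$value
  amp <- mean(abs(diff(vals)))
  structure(list(f_hz = f, period_s = 1 / f, amp_cm = amp,
                 strouhal = f * (amp / 100) / flow_speed,
                 body_length_cm = body_length_cm, flow_speed = flow_speed,
                 n_cycles = dur * f),
            class = "kinematic_summary")
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat(sprintf("<kinematic_summary> f = %.3f Hz, T = %.3f s, A = %.2f cm, St = %.3f\n",
              x$f_hz, x$period_s, x$amp_cm, x$strouhal))
  invisible(x)
}

#' @rdname kinematic_summary
#' @param x a `kinematic_summary`.
#' @param ... unused.
#' @export
glance.kinematic_summary <- function(x, ...) {
  tibble::tibble(f_hz = x$f_hz, period_s = x$period_s, amp_cm = x$amp_cm,
                 strouhal = x$strouhal, flow_speed = x$flow_speed,
                 body_length_cm = x$body_length_cm)
}

#' Per-joint RMSE between predicted and measured angles
#'
#' @param pred,meas tibbles/matrices with columns `theta1..theta4`, equal
#'   shape, degrees.
#' @param cycle_times optional vector of cycle boundary times (s) with a
#'   matching `time_s` column in `pred`; if given, per-cycle RMSE mean, SD
#'   and median are added.
#' @return tibble with one row per joint: `joint`, `rmse`; attribute
#'   `per_cycle` when cycle boundaries were supplied.
#' @export
rmse_angles <- function(pred, meas, cycle_times = NULL) {
  pj <- as.matrix(dplyr::select(as.data.frame(pred), dplyr::all_of(paste0("theta", 1:4))))
  mj <- as.matrix(dplyr::select(as.data.frame(meas), dplyr::all_of(paste0("theta", 1:4))))
  if (!all(dim(pj) == dim(mj))) abort("shape mismatch between predicted and measured angles")
  out <- tibble::tibble(
    joint = paste0("theta", 1:4),
    rmse = unname(sqrt(colMeans((pj - mj)^2))))
  if (!is.null(cycle_times) && "time_s" %in% names(pred)) {
    cyc <- findInterval(pred$time_s, cycle_times)
    keep <- cyc > 0 & cyc < length(cycle_times)
    per <- tibble::tibble(cycle = cyc[keep],
                          err2 = rowMeans((pj - mj)[keep, , drop = FALSE]^2)) |>
      dplyr::summarise(rmse = sqrt(mean(.data$err2)), .by = "cycle")
    attr(out, "per_cycle") <- tibble::tibble(
      mean = mean(per$rmse), sd = sd(per$rmse), median = median(per$rmse))
  }
  out
}

#' Body-pose RMSE over the anchor-point x-coordinates
#'
#' @param pred,meas `body_pose` tibbles of equal shape.
#' @return one-row tibble `rmse_x` (cm), plus per-point breakdown.
#' @export
rmse_pose <- function(pred, meas) {
  px <- as.matrix(pred[paste0("x", 1:6)]); mx <- as.matrix(meas[paste0("x", 1:6)])
  if (!all(dim(px) == dim(mx))) abort("shape mismatch between poses")
  tibble::tibble(point = paste0("x", 1:6),
                 rmse = unname(sqrt(colMeans((px - mx)^2)))) |>
    (\(d) {attr(d, "rmse_x") <- sqrt(mean((px - mx)^2)); d})()
}

#' Instantaneous phase difference between two oscillatory series
#'
#' Instantaneous phase of each zero-meaned series via the analytic signal;
#' the difference `phi_pred - phi_meas` is wrapped to `(-180, 180]` degrees.
#' Negative values mean the prediction lags the measurement. A warning is
#' issued for broadband input (spectral flatness above 0.5), where
#' instantaneous phase is not meaningful.
#'
#' @param pred,meas numeric vectors (one joint's angle series), equal length.
#' @return list of class `phase_diff`: `dphi_deg` (vector), `mean_deg`
#'   (circular mean).
#' @export
phase_difference <- function(pred, meas) {
  stopifnot(length(pred) == length(meas))
  flatness <- function(x) {
    p <- welch_psd(x - mean(x), 1)$power
    p <- p[p > 0]
    exp(mean(log(p))) / mean(p)
  }
  if (flatness(meas) > 0.5) warn("broadband series: instantaneous phase unreliable")
  ph <- function(x) Arg(analytic_signal(x))
  d <- wrap_rad(ph(pred) - ph(meas)) * 180 / pi
  # trim analytic-signal edge transients (5% each side)
  k <- max(1, floor(length(d) * 0.05))
  core <- d[(k + 1):(length(d) - k)]
  structure(list(dphi_deg = d, mean_deg = circular_mean_deg(core)),
            class = "phase_diff")
}

#' @export
print.phase_diff <- function(x, ...) {
  cat(sprintf("<phase_diff> circular mean %.2f degrees (n = %d)\n",
              x$mean_deg, length(x$dphi_deg)))
  invisible(x)
}
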