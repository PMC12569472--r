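test_that("pose cleaning is the identity on fully confident tracks", {
  t <- seq(0, 1, by = 0.01)
  track <- tibble::tibble(frame = seq_along(t) - 1, time_s = t,
                          p1_x = t, p1_y = 2 * t, p1_l = 1)
  expect_equal(clean_pose(track), track)
})

test_that("pose cleaning fills gaps and is idempotent", {
  t <- seq(0, 2, by = 0.01)
  y <- sin(2 * pi * 2 * t)
  track <- tibble::tibble(frame = seq_along(t) - 1, time_s = t,
                          p1_x = t, p1_y = y, p1_l = 1)
  # single dropped frame inside a linear stretch of p1_x
  tr1 <- track; tr1$p1_l[50] <- 0.2; tr1$p1_x[50] <- 99
  out <- clean_pose(tr1)
  expect_equal(out$p1_x[50], t[50], tolerance = 1e-9)
  # 10% random drops of the sinusoid
  set.seed(30)
  tr2 <- track
  drop <- sample(5:(length(t) - 5), round(0.1 * length(t)))
  tr2$p1_l[drop] <- 0.1; tr2$p1_y[drop] <- 99
  out2 <- clean_pose(tr2)
  expect_lt(max(abs(out2$p1_y - y)), 0.01)
  expect_equal(clean_pose(out2), out2)
  # too few valid frames
  tr3 <- track; tr3$p1_l[-(1:3)] <- 0.1
  expect_error(clean_pose(tr3), "landmark 1")
})

test_that("collinear and right-angle poses give the expected joint angles", {
  mk <- function(xs, ys) {
    track <- tibble::tibble(frame = 1:4, time_s = (1:4) * 1e-3)
    for (i in 1:6) {
      track[[paste0("p", i, "_x")]] <- rep(xs[i], 4)
      track[[paste0("p", i, "_y")]] <- rep(ys[i], 4)
      track[[paste0("p", i, "_l")]] <- 1
    }
    attr(track, "frame_rate") <- 1000
    pose_to_joint_angles(track, 1:6, rate_hz = 1000)
  }
  straight <- mk(0:5, rep(0, 6))
  expect_equal(max(abs(as.matrix(straight[paste0("theta", 1:4)]))), 0)
  bend <- mk(c(0, 1, 1, 1, 1, 1), c(0, 0, 1, 2, 3, 4))
  expect_equal(bend$theta1[1], 90)
  expect_equal(max(abs(as.matrix(bend[paste0("theta", 2:4)]))), 0)
  expect_error(mk(rep(0, 6), rep(0, 6)), "degenerate")
})

test_that("forward kinematics places anchors as the chain dictates", {
  ang <- tibble::tibble(time_s = 1e-3, theta1 = 0, theta2 = 0, theta3 = 0,
                        theta4 = 0)
  pose <- forward_kinematics(ang, rep(5, 5))
  expect_equal(as.numeric(pose[1, paste0("x", 1:6)]), seq(0, 25, by = 5))
  expect_equal(max(abs(as.numeric(pose[1, paste0("y", 1:6)]))), 0)
  ang$theta1 <- 90
  pose <- forward_kinematics(ang, rep(1, 5))
  expect_equal(as.numeric(pose[1, c("x3", "y3")]), c(1, 1), tolerance = 1e-12)
  expect_error(forward_kinematics(ang, c(1, 2)), "five")
})

test_that("forward and inverse kinematics round-trip to numerical precision", {
  ang <- make_angle_series(400)
  lens <- c(9, 6, 6, 6, 3)
  pose <- forward_kinematics(ang, lens)
  # link lengths preserved at every sample
  for (i in 1:5) {
    d <- sqrt((pose[[paste0("x", i + 1)]] - pose[[paste0("x", i)]])^2 +
                (pose[[paste0("y", i + 1)]] - pose[[paste0("y", i)]])^2)
    expect_lt(max(abs(d - lens[i])) / lens[i], 1e-9)
  }
  rec <- pose_to_joint_angles(pose_from_body(pose), 1:6, rate_hz = 1000)
  expect_lt(max(abs(as.matrix(rec[paste0("theta", 1:4)]) -
                      as.matrix(ang[paste0("theta", 1:4)]))), 1e-9)
  pose2 <- forward_kinematics(rec)
  expect_lt(max(abs(pose2$x6 - pose$x6)), 1e-9)
})

test_that("midline smoothing keeps the anchor points", {
  ang <- make_angle_series(5)
  pose <- forward_kinematics(ang, rep(4, 5))
  sm <- smooth_midline(pose, 2, n_points = 200)
  for (i in 1:6) {
    d <- sqrt((sm$x - pose[[paste0("x", i)]][2])^2 +
                (sm$y - pose[[paste0("y", i)]][2])^2)
    expect_lt(min(d), 0.05)
  }
})

test_that("lateral displacement projects onto the flow normal", {
  t <- seq(0, 1, by = 0.01)
  track <- tibble::tibble(frame = seq_along(t), time_s = t,
                          p1_x = 3 * t, p1_y = rep(2, length(t)))
  expect_equal(max(abs(lateral_displacement(track, 1)$ld)), 0)
  track$p1_y <- 2 + 1.5 * sin(2 * pi * 3 * t)
  ld <- lateral_displacement(track, 1)
  expect_equal(max(ld$ld), 1.5, tolerance = 1e-2)
  expect_lt(abs(mean(ld$ld)), 1e-10)
  # rotated flow axis: hand-computed projection
  ax <- c(1, 1) / sqrt(2)
  track2 <- tibble::tibble(frame = 1:3, time_s = 1:3,
                           p1_x = c(0, 1, 2), p1_y = c(0, 3, 1))
  ld2 <- lateral_displacement(track2, 1, ax)
  nrm <- c(-1, 1) / sqrt(2)
  manual <- (track2$p1_x - 1) * nrm[1] + (track2$p1_y - 4 / 3) * nrm[2]
  expect_equal(ld2$ld, manual)
})

test_that("tail-beat summary recovers the closed-form Strouhal number", {
  t <- seq(0, 10, by = 1e-3)
  ld <- tibble::tibble(time_s = t, ld = 1.5 * sin(2 * pi * 2 * t))
  ks <- kinematic_summary(ld, 0.274)
  expect_equal(ks$f_hz, 2, tolerance = 0.01)
  expect_equal(ks$amp_cm, 3, tolerance = 0.01)
  expect_equal(ks$strouhal, 2 * 0.03 / 0.274, tolerance = 0.01)
  expect_equal(ks$period_s, 1 / ks$f_hz)
  # doubling A doubles St, f unchanged; St scales as 1/U
  ld2 <- tibble::tibble(time_s = t, ld = 3 * sin(2 * pi * 2 * t))
  ks2 <- kinematic_summary(ld2, 0.274)
  expect_equal(ks2$f_hz, ks$f_hz)
  expect_equal(ks2$strouhal / ks$strouhal, 2, tolerance = 1e-6)
  ks3 <- kinematic_summary(ld, 0.548)
  expect_equal(ks3$strouhal, ks$strouhal / 2, tolerance = 1e-9)
  flat <- tibble::tibble(time_s = t, ld = rnorm(length(t), sd = 1e-9))
  expect_error(kinematic_summary(flat, 0.274))
})

test_that("angle and pose RMSE follow their definitions", {
  ang <- make_angle_series(10000)
  expect_equal(max(rmse_angles(ang, ang)$rmse), 0)
  off <- ang; off$theta2 <- off$theta2 + 5
  r <- rmse_angles(off, ang)
  expect_equal(r$rmse[r$joint == "theta2"], 5)
  expect_equal(r$rmse[r$joint == "theta1"], 0)
  set.seed(31)
  noisy <- ang
  for (j in paste0("theta", 1:4)) noisy[[j]] <- noisy[[j]] + rnorm(10000, sd = 2)
  rn <- rmse_angles(noisy, ang)
  expect_true(all(abs(rn$rmse - 2) < 3 * 2 / sqrt(2 * 10000)))
  expect_error(rmse_angles(ang[1:10, ], ang), "mismatch")

  pose <- forward_kinematics(make_angle_series(500), rep(4, 5))
  expect_equal(attr(rmse_pose(pose, pose), "rmse_x"), 0)
  shifted <- pose
  for (i in 1:6) shifted[[paste0("x", i)]] <- shifted[[paste0("x", i)]] + 1.2
  expect_equal(attr(rmse_pose(shifted, pose), "rmse_x"), 1.2, tolerance = 1e-12)
})

test_that("phase differences recover imposed delays and advances", {
  t <- seq(0, 10, by = 1e-3)
  f <- 2
  meas <- sin(2 * pi * f * t)
  expect_equal(phase_difference(meas, meas)$mean_deg, 0, tolerance = 1e-6)
  lag4 <- phase_difference(sin(2 * pi * f * (t - 1 / (4 * f))), meas)
  expect_equal(lag4$mean_deg, -90, tolerance = 2)
  adv8 <- phase_difference(sin(2 * pi * f * (t + 1 / (8 * f))), meas)
  expect_equal(adv8$mean_deg, 45, tolerance = 2)
  set.seed(32)
  expect_warning(phase_difference(rnorm(2000), rnorm(2000)), "broadband")
})
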