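test_that("a zero amplitude envelope gives a straight body with zero angles", {
  tr <- generate_trial("laminar", seed = 1,
                       overrides = list(duration_s = 2, amp_coef = c(0, 0)))
  ys <- as.matrix(tr$pose[paste0("p", 1:12, "_y")])
  expect_equal(max(abs(ys)), 0)
  expect_equal(max(abs(as.matrix(tr$truth$angles[paste0("theta", 1:4)]))), 0)
})

test_that("the generated wave matches its closed-form frequency and amplitude", {
  tr <- generate_trial("laminar", seed = 2, overrides = list(duration_s = 10))
  sp <- tr$spec
  ld <- tibble::tibble(time_s = tr$truth$ld$time_s, ld = tr$truth$ld$ld12)
  ks <- kinematic_summary(ld, sp$flow_speed, sp$body_length_cm)
  expect_lt(abs(ks$f_hz - sp$f_tail_hz), 0.1)
  a_expected <- 2 * (sp$amp_coef[1] + sp$amp_coef[2]) * sp$body_length_cm
  expect_lt(abs(ks$amp_cm - a_expected) / a_expected, 0.02)
})

test_that("the body wave travels head to tail with the phase law", {
  tr <- generate_trial("laminar", seed = 3, overrides = list(duration_s = 6))
  sp <- tr$spec
  fracs <- tr$truth$landmark_fractions
  # the tail's LD lags an anterior station by 2*pi*(1 - s)/lambda
  for (s in c(0.7, 0.9)) {
    i_s <- which(fracs == s); i_tail <- which(fracs == 1)
    pd <- phase_difference(tr$truth$ld[[paste0("ld", i_tail)]],
                           tr$truth$ld[[paste0("ld", i_s)]])
    expected <- -360 * (1 - s) / sp$wavelength_bl
    expect_equal(pd$mean_deg, expected, tolerance = 0.02)
  }
})

test_that("left and right channels at one station never burst together", {
  spec <- trial_spec(duration_s = 4, noise_sd = 0, crosstalk_coef = 0,
                     mains_amplitude = 0, burst_gain_cv = 0, seed = 4)
  kin <- generate_kinematics(spec)
  emg <- generate_emg(spec, kin$truth)
  overlap <- abs(emg$emg$L6) * abs(emg$emg$R6)
  expect_equal(max(overlap), 0)
})

test_that("muscle onsets progress from anterior to posterior within a cycle", {
  tr <- generate_trial("laminar", seed = 5, overrides = list(duration_s = 6))
  b <- tr$truth$bursts
  f <- tr$spec$f_tail_hz
  phases <- b |>
    dplyr::filter(.data$side == "left") |>
    dplyr::summarise(phase = mean((.data$burst_time_s * f) %% 1),
                     .by = "position") |>
    dplyr::arrange(.data$position)
  expect_true(all(diff(phases$phase) > 0))
  # adjacent stations are 0.1 BL apart: phase step 0.1 / lambda of a cycle
  expect_equal(diff(phases$phase),
               rep(0.1 / tr$spec$wavelength_bl, 5), tolerance = 0.01)
})

test_that("a pure negative-lag trial yields all-negative matched delays", {
  tr <- generate_trial("cyl5", seed = 6,
                       overrides = list(duration_s = 6, neg_lag_fraction = 1,
                                        noise_sd = 1e-4, crosstalk_coef = 0,
                                        mains_amplitude = 0,
                                        burst_gain_cv = 0))
  expect_true(all(tr$truth$bursts$label == "lagging"))
  recs <- trial_delays(tr)
  expect_gt(nrow(recs), 50)
  expect_equal(mean(recs$delta_t_ms < 0), 1)
})

test_that("trials are byte-identical for a fixed (condition, seed)", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_trial("cyl7", seed = 7, out_dir = d1,
                 overrides = list(duration_s = 2))
  generate_trial("cyl7", seed = 7, out_dir = d2,
                 overrides = list(duration_s = 2))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("condition presets fix the negative-lag fraction", {
  expect_error(trial_spec(condition = "laminar", neg_lag_fraction = 0.2),
               "laminar")
  expect_error(generate_trial("cyl9"), "unknown condition")
  tr <- generate_trial("cyl5", seed = 8, overrides = list(duration_s = 4))
  expect_equal(tr$spec$neg_lag_fraction, 0.48)
  expect_true(all(c("leading", "lagging") %in% tr$truth$bursts$label))
})

test_that("known channel lags are recovered through the full chain", {
  tr <- generate_trial("laminar", seed = 9, overrides = list(duration_s = 10))
  recs <- trial_delays(tr)
  expect_gt(nrow(recs), 150)
  expect_gte(mean(recs$delta_t_ms > 0), 0.95)
  expect_true(abs(median(recs$delta_t_ms) - 50) < 1 + 25)
})

test_that("scaling the flow speed leaves delays fixed and rescales St", {
  tr1 <- generate_trial("laminar", seed = 10, overrides = list(duration_s = 8))
  tr2 <- generate_trial("laminar", seed = 10,
                        overrides = list(duration_s = 8, flow_speed = 0.548))
  expect_identical(tr1$emg$L6, tr2$emg$L6)
  ld <- tibble::tibble(time_s = tr1$truth$ld$time_s, ld = tr1$truth$ld$ld12)
  s1 <- kinematic_summary(ld, tr1$spec$flow_speed)
  s2 <- kinematic_summary(ld, tr2$spec$flow_speed)
  expect_equal(s1$strouhal / s2$strouhal, 2, tolerance = 1e-9)
})

test_that("recoverable targets are a linear function of their support", {
  cond <- make_noise_cond(800, seed = 11)
  V <- build_input_matrix(cond)
  Y <- make_recoverable_targets(V, target_sd = 20, noise_frac = 0, seed = 3)
  expect_equal(unname(apply(as.matrix(Y), 2, sd)), rep(20, 4), tolerance = 1e-9)
  cols <- attr(Y, "weight_columns")
  fit <- lm.fit(cbind(1, scale(as.matrix(V[, cols]))), as.matrix(Y))
  expect_lt(max(abs(fit$residuals)), 1e-6)
})
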