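mk_env <- function(x, fs = 1000) {
  d <- tibble::tibble(time_s = seq_along(x) / fs, L1 = x)
  attr(d, "sample_rate") <- fs
  class(d) <- c("emg_envelope", class(d))
  d
}

test_that("peak detection matches a brute-force prominence oracle", {
  set.seed(40)
  t <- seq(0, 6, by = 1e-3)
  x <- abs(2 * sin(2 * pi * 1.5 * t)) + 0.3 * abs(rnorm(length(t)))
  x <- emgkin:::moving_average_shrink(x, 51)
  prom <- 3 * mad(x)
  impl <- emgkin:::find_peaks_prominence(x, prom, min_sep = 1)
  oracle <- oracle_peaks(x, prom)
  expect_equal(impl, oracle)
})

test_that("a single bump yields one peak at its apex", {
  t <- seq(0, 2, by = 1e-3)
  x <- exp(-(t - 1)^2 / (2 * 0.05^2))
  p <- detect_onset_peaks(mk_env(x), prominence_k = 1, min_sep_s = 0.1)
  expect_equal(nrow(p), 1)
  expect_equal(p$time_s, 1, tolerance = 2e-3)
})

test_that("a periodic bump train gives one peak per bump", {
  dur <- 5; f <- 2
  t <- seq(0, dur, by = 1e-3)
  x <- pmax(0, sin(2 * pi * f * t))^2
  p <- detect_onset_peaks(mk_env(x), prominence_k = 1, min_sep_s = 0.2)
  expect_equal(nrow(p), floor(dur * f))
})

test_that("sub-threshold ripples are excluded", {
  t <- seq(0, 3, by = 1e-3)
  x <- pmax(0, sin(2 * pi * 1 * t))^2 + 0.02 * sin(2 * pi * 40 * t)
  p <- detect_onset_peaks(mk_env(x), prominence_k = 3, min_sep_s = 0.05)
  expect_equal(nrow(p), 3)
})

test_that("separation keeps the higher of two close candidates", {
  x <- numeric(1000)
  x[300] <- 1; x[320] <- 2
  x <- emgkin:::moving_average_shrink(x, 11)
  p <- emgkin:::find_peaks_prominence(x, 0.01, min_sep = 100)
  expect_equal(p, 320)
  expect_error(detect_onset_peaks(mk_env(numeric(0))), "empty")
})

test_that("LD extrema alternate and sit at the analytic phases", {
  t <- seq(0, 3, by = 1e-3)
  ld <- tibble::tibble(time_s = t, ld = sin(2 * pi * 2 * t))
  ex <- detect_ld_extrema(ld, min_sep_s = 0.1)
  expect_true(all(ex$events$kind[-1] != ex$events$kind[-nrow(ex$events)]))
  expect_true(all(abs((ex$maxima * 2) %% 1 - 0.25) < 0.01))
  expect_true(all(abs((ex$minima * 2) %% 1 - 0.75) < 0.01))
  set.seed(41)
  # band-limited 5% noise, as pose-derived LD noise is after upsampling;
  # the apex of a 2 Hz sine is flat, so the noise-induced argmax jitter is
  # bounded by noise slope / apex curvature -- well under a tenth period
  noise <- emgkin:::moving_average_shrink(rnorm(length(t)), 25)
  ld$ld <- ld$ld + 0.05 * noise / sd(noise)
  exn <- detect_ld_extrema(ld, min_sep_s = 0.1)
  errs <- vapply(exn$maxima, function(m) min(abs(m - ex$maxima)), numeric(1))
  expect_lt(max(errs), 0.08 * 0.5)
  expect_lt(median(errs), 0.015)
  expect_error(detect_ld_extrema(tibble::tibble(time_s = t, ld = 0 * t)),
               "flat")
})

test_that("alternation repair keeps the larger of two same-kind extrema", {
  # hand-built event sequence processed by the same repair rule used inside
  t <- seq(0, 2, by = 1e-3)
  base <- sin(2 * pi * 2 * t)
  # inject an artifact second maximum slightly lower, between max and min
  x <- base
  x[190:210] <- x[190:210] + 0.8 * exp(-((190:210) - 200)^2 / 20)
  ld <- tibble::tibble(time_s = t, ld = x)
  ex <- detect_ld_extrema(ld, prominence_k = 0.2, min_sep_s = 0.02)
  kinds <- ex$events$kind
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
})

test_that("the matching rule follows the printed epsilon inequality", {
  mkpeaks <- function(times) {
    structure(tibble::tibble(channel = "L6", time_s = times,
                             height = 1), class = c("onset_peaks", "tbl_df",
                                                    "tbl", "data.frame"))
  }
  mkex <- function(minima) {
    structure(list(events = tibble::tibble(time_s = minima, value = -1,
                                           kind = "LD_min"),
                   maxima = numeric(0), minima = minima),
              class = "ld_extrema")
  }
  # peak 100 ms before, none after within horizon
  r <- match_delays(mkpeaks(0.9), mkex(1.0), horizon_s = 0.5)
  expect_equal(r$delta_t_ms, 100)
  expect_equal(r$branch, "before")
  # peaks 30 ms before and 200 ms after: |30| - |200| < eps -> before
  r <- match_delays(mkpeaks(c(0.97, 1.2)), mkex(1.0), horizon_s = 0.5)
  expect_equal(r$delta_t_ms, 30)
  # peaks 50 ms before and 45 ms after: |50| - |45| = 5 < 10 -> before wins
  # within the epsilon band even though after is marginally closer
  r <- match_delays(mkpeaks(c(0.95, 1.045)), mkex(1.0), horizon_s = 0.5)
  expect_equal(r$delta_t_ms, 50)
  expect_equal(r$branch, "before")
  # after clearly closer: 50 vs 20 -> after
  r <- match_delays(mkpeaks(c(0.95, 1.02)), mkex(1.0), horizon_s = 0.5)
  expect_equal(r$delta_t_ms, -20)
  expect_equal(r$branch, "after")
  # no peak within horizon -> no record
  r <- match_delays(mkpeaks(3), mkex(1.0), horizon_s = 0.5)
  expect_equal(nrow(r), 0)
  # empty peaks -> empty with warning
  expect_warning(r <- match_delays(mkpeaks(numeric(0)), mkex(1.0)), "no peaks")
  expect_equal(nrow(r), 0)
})

test_that("growing epsilon can only switch choices from after to before", {
  set.seed(42)
  for (rep in 1:20) {
    t0 <- 1
    peaks <- structure(tibble::tibble(channel = "L1",
                                      time_s = sort(runif(5, 0, 2)),
                                      height = 1),
                       class = c("onset_peaks", "tbl_df", "tbl", "data.frame"))
    ex <- structure(list(events = tibble::tibble(time_s = t0, value = -1,
                                                 kind = "LD_min"),
                         maxima = numeric(0), minima = t0),
                    class = "ld_extrema")
    branches <- vapply(c(0, 5, 10, 20, 50, 200), function(eps) {
      r <- match_delays(peaks, ex, epsilon_ms = eps, horizon_s = 2)
      if (nrow(r)) r$branch else NA_character_
    }, character(1))
    b <- branches[!is.na(branches)]
    if (length(b) > 1) {
      # once "before", always "before" as epsilon grows
      expect_true(all(diff(b == "before") >= 0))
    }
  }
})

test_that("delays are equivariant under a common time shift", {
  set.seed(43)
  ptimes <- sort(runif(8, 0.5, 9.5))
  extimes <- ptimes + 0.05
  mk <- function(s) {
    peaks <- structure(tibble::tibble(channel = "R2", time_s = ptimes + s,
                                      height = 1),
                       class = c("onset_peaks", "tbl_df", "tbl", "data.frame"))
    ex <- structure(list(events = tibble::tibble(time_s = extimes + s,
                                                 value = 1, kind = "LD_max"),
                         maxima = extimes + s, minima = numeric(0)),
                    class = "ld_extrema")
    match_delays(peaks, ex, horizon_s = 0.4)$delta_t_ms
  }
  expect_equal(mk(0), mk(3.7))
})

test_that("delay summaries count signs from raw records", {
  recs <- tibble::tibble(channel = "L6", side = "left",
                         extremum_kind = "LD_min",
                         extremum_time_s = 1:4, peak_time_s = 1:4,
                         delta_t_ms = c(-10, 10, 10, 10), branch = "before")
  s <- summarize_delays(recs, fit_density = FALSE)
  expect_equal(s$percent_negative, 25)
  recs$delta_t_ms <- rep(50, 4)
  expect_equal(summarize_delays(recs, fit_density = FALSE)$percent_negative, 0)
  expect_error(summarize_delays(recs[0, ]), "no delay")
})

test_that("the location-scale F fit describes a skewed delay sample", {
  set.seed(44)
  x <- 40 + 15 * rf(400, 6, 12)
  fit <- emgkin:::fit_f_location_scale(x)
  expect_false(is.null(fit))
  expect_lt(fit$loc, min(x))
  expect_lt(fit$ks, 0.08)
})
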