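#' Channel columns of an EMG table
#'
#' EMG recordings are wide tibbles: a `time_s` column plus one numeric column
#' per channel, named `L1`..`L6`, `R1`..`R6` (subsets allowed).
#'
#' @param emg a data frame with a `time_s` column.
#' @return character vector of channel column names, in table order.
#' @export
emg_channels <- function(emg) {
  setdiff(names(emg), c("time_s", "frame"))
}

#' Filtering configuration for EMG conditioning
#'
#' Defaults follow the standard surface-EMG conditioning chain: mean
#' adjustment, a 50 Hz power-line notch, a 20-450 Hz bandpass, and
#' downsampling to a 1 kHz working rate. Both filters are applied
#' forward-backward (zero phase) so that conditioning introduces no group
#' delay -- the downstream delay statistic depends on timing being preserved.
#'
#' @param band_hz bandpass edges in Hz.
#' @param band_order Butterworth design order of the bandpass.
#' @param notch_hz notch centre frequency, Hz.
#' @param notch_q quality factor of the biquad notch.
#' @param target_rate_hz working sample rate after downsampling, Hz.
#' @return a `filter_config` list.
#' @export
filter_config <- function(band_hz = c(20, 450), band_order = 4,
                          notch_hz = 50, notch_q = 30,
                          target_rate_hz = 1000) {
  stopifnot(length(band_hz) == 2, band_hz[1] > 0, band_hz[1] < band_hz[2])
  structure(list(band_hz = band_hz, band_order = band_order,
                 notch_hz = notch_hz, notch_q = notch_q,
                 target_rate_hz = target_rate_hz),
            class = "filter_config")
}

# Zero-phase filtering with odd-reflection edge padding. Plain
# forward-backward filtering leaves long edge transients for high-Q filters
# (the notch rings for ~Q cycles); odd reflection continues the signal with
# matched value and slope so the transient falls on the pad, not the data.
filtfilt_pad <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1, 2500L)
  if (p < 3) return(signal::filtfilt(b, a, x))
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(b, a, c(left, x, right))
  y[(p + 1):(p + n)]
}

# RBJ cookbook biquad notch; returns list(b, a)
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Condition a raw EMG recording
#'
#' Applies, per channel and in order: mean subtraction, a zero-phase 50 Hz
#' notch, a zero-phase Butterworth bandpass (20-450 Hz by default), and
#' resampling onto the 1 kHz working grid by modified-Akima interpolation
#' (the 450 Hz cutoff already anti-aliases a 1 kHz target). The channel mean
#' is re-adjusted after resampling so conditioned traces are exactly
#' zero-mean.
#'
#' @param emg wide EMG tibble (`time_s` + channel columns), voltages in mV.
#' @param sample_rate input sampling rate, Hz (nominal 2500).
#' @param cfg a [filter_config()].
#' @return a tibble of the same shape at the working rate, with attributes
#'   `sample_rate` and `provenance` (the filter parameters applied).
#' @export
condition_emg <- function(emg, sample_rate = 2500, cfg = filter_config()) {
  chans <- emg_channels(emg)
  if (length(chans) < 1) abort("no EMG channels found")
  if (sample_rate < 900) {
    abort("sample rate below 900 Hz: bandpass upper edge infeasible")
  }
  if (cfg$band_hz[2] >= sample_rate / 2) {
    abort("bandpass upper edge must be below Nyquist")
  }
  bad <- chans[vapply(chans, function(ch) any(!is.finite(emg[[ch]])), logical(1))]
  if (length(bad)) {
    abort(paste0("non-finite samples in channel(s): ", paste(bad, collapse = ", ")))
  }
  nt <- design_notch(cfg$notch_hz, sample_rate, cfg$notch_q)
  bp <- signal::butter(cfg$band_order,
                       cfg$band_hz / (sample_rate / 2), type = "pass")
  n <- nrow(emg)
  m <- ceiling(n * cfg$target_rate_hz / sample_rate)
  t0 <- emg$time_s[1]
  t_new <- t0 + (seq_len(m) - 1) / cfg$target_rate_hz
  out <- tibble::tibble(time_s = t_new)
  for (ch in chans) {
    x <- emg[[ch]] - mean(emg[[ch]])
    x <- filtfilt_pad(nt$b, nt$a, x)
    x <- filtfilt_pad(bp$b, bp$a, x)
    y <- interp_makima(emg$time_s, x, t_new)
    out[[ch]] <- y - mean(y)
  }
  attr(out, "sample_rate") <- cfg$target_rate_hz
  attr(out, "provenance") <- cfg
  class(out) <- c("conditioned_emg", class(out))
  out
}

#' Extract the EMG activation envelope
#'
#' Full-wave rectification followed by a centred moving average. Edges use
#' shrinking windows so there is no zero-padding bias.
#'
#' @param cond conditioned EMG tibble at the working rate.
#' @param window_ms smoothing window, milliseconds. Default 50 ms, about a
#'   tenth of a tail-beat period at typical beat frequencies.
#' @return tibble of non-negative envelopes, same shape; attribute
#'   `smoothing_window_ms` records the window.
#' @export
emg_envelope <- function(cond, window_ms = 50) {
  stopifnot(window_ms > 0)
  fs <- attr(cond, "sample_rate") %||% 1000
  width <- max(1L, round(window_ms * fs / 1000))
  chans <- emg_channels(cond)
  out <- tibble::tibble(time_s = cond$time_s)
  for (ch in chans) out[[ch]] <- moving_average_shrink(abs(cond[[ch]]), width)
  attr(out, "sample_rate") <- fs
  attr(out, "smoothing_window_ms") <- window_ms
  class(out) <- c("emg_envelope", class(out))
  out
}

#' Resample a sampled series onto a uniform grid
#'
#' Modified-Akima piecewise-cubic interpolation of every numeric column onto
#' a uniform grid spanning the original time range. Original sample values
#' are preserved exactly at original timestamps; used to upsample 100 Hz pose
#' tracks to the 1 kHz working rate.
#'
#' @param data tibble with a monotone `time_s` column.
#' @param rate_hz target rate, Hz.
#' @return resampled tibble with attribute `sample_rate`.
#' @export
resample_to_rate <- function(data, rate_hz = 1000) {
  t <- data$time_s
  if (length(t) < 4) abort("need at least 4 samples to interpolate")
  if (any(diff(t) <= 0)) abort("timestamps must be strictly increasing")
  t_new <- seq(t[1], t[length(t)], by = 1 / rate_hz)
  cols <- setdiff(names(data), c("time_s", "frame"))
  out <- tibble::tibble(time_s = t_new)
  for (cl in cols) {
    if (is.numeric(data[[cl]])) out[[cl]] <- interp_makima(t, data[[cl]], t_new)
  }
  attr(out, "sample_rate") <- rate_hz
  out
}

#' Signal-quality metrics for a conditioned recording
#'
#' SNR per channel is the ratio of mean power inside burst epochs to mean
#' power in quiescent epochs, reported both linear and as `10*log10` dB.
#' Crosstalk is the pairwise Pearson correlation between conditioned channels
#' over burst epochs (signed), summarised by its off-diagonal mean.
#'
#' @param cond conditioned EMG tibble.
#' @param burst_mask logical tibble/matrix, same sample count, one column per
#'   channel, `TRUE` during activation epochs.
#' @return list of class `qc_report`: `snr` tibble (channel, snr_linear,
#'   snr_db), `crosstalk` matrix, `mean_crosstalk`.
#' @export
qc_metrics <- function(cond, burst_mask) {
  chans <- emg_channels(cond)
  bm <- as.data.frame(burst_mask)[chans]
  if (nrow(bm) != nrow(cond)) abort("burst mask length mismatch")
  snr_lin <- vapply(chans, function(ch) {
    m <- bm[[ch]]
    if (all(m) || !any(!m)) abort("empty quiescent epoch set")
    if (!any(m)) abort("empty burst epoch set")
    mean(cond[[ch]][m]^2) / mean(cond[[ch]][!m]^2)
  }, numeric(1))
  k <- length(chans)
  ct <- diag(1, k); dimnames(ct) <- list(chans, chans)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      m <- bm[[i]] | bm[[j]]
      r <- if (sum(m) > 2) stats::cor(cond[[chans[i]]][m], cond[[chans[j]]][m]) else NA_real_
      ct[i, j] <- r; ct[j, i] <- r
    }
  }
  structure(list(
    snr = tibble::tibble(channel = chans, snr_linear = unname(snr_lin),
                         snr_db = 10 * log10(unname(snr_lin))),
    crosstalk = ct,
    mean_crosstalk = if (k > 1) mean(ct[upper.tri(ct)]) else NA_real_
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  mean SNR: %.2f linear, %.2f dB\n",
              mean(x$snr$snr_linear), mean(x$snr$snr_db)))
  cat(sprintf("  mean crosstalk: %.3f\n", x$mean_crosstalk))
  invisible(x)
}

#' @rdname qc_metrics
#' @param x a `qc_report`.
#' @param ... unused.
#' @export
tidy.qc_report <- function(x, ...) x$snr

#' @rdname qc_metrics
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(mean_snr_linear = mean(x$snr$snr_linear),
                 mean_snr_db = mean(x$snr$snr_db),
                 mean_crosstalk = x$mean_crosstalk)
}
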