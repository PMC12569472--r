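# Daubechies-4 analysis filters (orthonormal)
db4_filters <- function() {
  h <- c(0.48296291314453414, 0.8365163037378079,
         0.2241438680420134, -0.12940952255126037)   # low-pass
  g <- c(h[4], -h[3], h[2], -h[1])                   # high-pass (QMF)
  list(lo = h, hi = g)
}

# Undecimated (stationary) 3-level Daubechies-4 cascade. Returns per-sample
# detail coefficients d1..d3 and approximation a3, each the length of x.
# Filters are upsampled by 2^(level-1) (a trous); circular extension.
swt_db4 <- function(x, levels = 3) {
  f <- db4_filters()
  n <- length(x)
  circ_filter <- function(x, h) {
    k <- length(h)
    out <- numeric(n)
    for (i in seq_len(k)) {
      out <- out + h[i] * x[((seq_len(n) - 1 + (i - 1)) %% n) + 1]
    }
    out
  }
  a <- x
  details <- list()
  for (lev in seq_len(levels)) {
    up <- 2^(lev - 1)
    lo <- numeric((4 - 1) * up + 1); lo[seq(1, length(lo), by = up)] <- f$lo
    hi <- numeric((4 - 1) * up + 1); hi[seq(1, length(hi), by = up)] <- f$hi
    details[[lev]] <- circ_filter(a, hi)
    a <- circ_filter(a, lo)
  }
  list(d = details, a = a)
}

feature_names <- function() {
  c("mav", "rms", "var", "wl", "zc", "ssc", "wamp", "iemg",
    "mnf", "mdf", "pkf", "tp", "sent", "bpr",
    "rwe_d1", "rwe_d2", "rwe_d3", "rwe_a3")
}

#' Per-channel EMG feature matrix
#'
#' Computes, per 1 kHz time index, 18 features of the conditioned signal on a
#' centred window: eight time-domain (mean absolute value, RMS, variance,
#' waveform length, zero crossings, slope-sign changes, Willison amplitude,
#' integrated EMG), six frequency-domain (mean/median/peak frequency, total
#' power, normalised spectral entropy, 20-100 Hz vs 100-450 Hz band-power
#' ratio) and four time-frequency features (relative energies of the D1, D2,
#' D3 and A3 bands of a 3-level Daubechies-4 stationary wavelet cascade).
#'
#' Time-domain features use true shrinking windows at the edges; spectral
#' windows are edge-replicated so every FFT has the same resolution. Ratios
#' with zero denominator are defined as 0.
#'
#' @param trace numeric vector: one conditioned channel at the working rate.
#' @param sample_rate working rate, Hz.
#' @param feature_window centred window length in samples (default 256,
#'   about 1 Hz spectral resolution at 1 kHz).
#' @param wamp_threshold amplitude-difference threshold (mV) for the Willison
#'   amplitude and slope-sign-change counts.
#' @return tibble with `n = length(trace)` rows and 18 named columns.
#' @export
extract_features <- function(trace, sample_rate = 1000, feature_window = 256,
                             wamp_threshold = 0.01) {
  n <- length(trace)
  if (feature_window < 32) abort("feature window below 32 samples: spectral features meaningless")
  if (n < feature_window) abort("trace shorter than the feature window")
  w <- feature_window

  ## -- time-domain via rolling sums (shrink edges) --------------------------
  rs_abs <- rolling_sum_shrink(abs(trace), w)
  rs_sq  <- rolling_sum_shrink(trace^2, w)
  mav  <- rs_abs$sum / rs_abs$count
  rms  <- sqrt(rs_sq$sum / rs_sq$count)
  rs_x <- rolling_sum_shrink(trace, w)
  vrr  <- pmax(0, rs_sq$sum / rs_sq$count - (rs_x$sum / rs_x$count)^2)
  dif  <- c(abs(diff(trace)), 0)
  rs_d <- rolling_sum_shrink(dif, w)
  wl   <- rs_d$sum
  zc_i <- c(as.numeric(trace[-n] * trace[-1] < 0), 0)
  zc   <- rolling_sum_shrink(zc_i, w)$sum
  d1 <- c(0, diff(trace)); d2 <- c(diff(trace), 0)
  ssc_i <- as.numeric(d1 * d2 < 0 & (abs(d1) >= wamp_threshold | abs(d2) >= wamp_threshold))
  ssc  <- rolling_sum_shrink(ssc_i, w)$sum
  wamp_i <- c(as.numeric(abs(diff(trace)) >= wamp_threshold), 0)
  wamp <- rolling_sum_shrink(wamp_i, w)$sum
  iemg <- rs_abs$sum

  ## -- frequency-domain: hann-windowed FFT per (edge-replicated) window ----
  half_lo <- floor((w - 1) / 2); half_hi <- w - 1 - half_lo
  padded <- c(rep(trace[1], half_lo), trace, rep(trace[n], half_hi))
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  nf <- floor(w / 2)                       # positive-frequency bins 1..nf
  freqs <- (seq_len(nf)) * sample_rate / w # exclude DC
  mnf <- mdf <- pkf <- tp <- sent <- bpr <- numeric(n)
  band_lo <- freqs >= 20 & freqs < 100
  band_hi <- freqs >= 100 & freqs <= 450
  chunk <- 4096L
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    idx <- s:e
    # window matrix w x m
    wm <- matrix(padded[outer(0:(w - 1), idx, `+`)], nrow = w)
    wm <- (wm - rep(colMeans(wm), each = w)) * hann
    P <- Mod(stats::mvfft(wm))^2
    P <- P[2:(nf + 1), , drop = FALSE]     # drop DC
    tot <- colSums(P)
    ok <- tot > 0
    Pn <- sweep(P, 2, pmax(tot, .Machine$double.xmin), "/")
    mnf[idx] <- ifelse(ok, colSums(P * freqs) / pmax(tot, .Machine$double.xmin), 0)
    cumP <- apply(Pn, 2, cumsum)
    mdf_k <- apply(cumP >= 0.5, 2, function(v) which(v)[1])
    mdf[idx] <- ifelse(ok, freqs[mdf_k], 0)
    pkf[idx] <- ifelse(ok, freqs[apply(P, 2, which.max)], 0)
    tp[idx] <- tot
    sent[idx] <- ifelse(ok, -colSums(ifelse(Pn > 0, Pn * log(Pn), 0)) / log(nf), 0)
    hi_pow <- colSums(P[band_hi, , drop = FALSE])
    bpr[idx] <- ifelse(hi_pow > 0, colSums(P[band_lo, , drop = FALSE]) / hi_pow, 0)
  }

  ## -- time-frequency: stationary db4 band energies over the window --------
  swt <- swt_db4(trace, 3)
  e1 <- rolling_sum_shrink(swt$d[[1]]^2, w)$sum
  e2 <- rolling_sum_shrink(swt$d[[2]]^2, w)$sum
  e3 <- rolling_sum_shrink(swt$d[[3]]^2, w)$sum
  ea <- rolling_sum_shrink(swt$a^2, w)$sum
  etot <- e1 + e2 + e3 + ea
  rel <- function(e) ifelse(etot > 0, e / etot, 0)

  out <- tibble::tibble(
    mav = mav, rms = rms, var = vrr, wl = wl, zc = zc, ssc = ssc,
    wamp = wamp, iemg = iemg,
    mnf = mnf, mdf = mdf, pkf = pkf, tp = tp, sent = sent, bpr = bpr,
    rwe_d1 = rel(e1), rwe_d2 = rel(e2), rwe_d3 = rel(e3), rwe_a3 = rel(ea))
  stopifnot(!anyNA(out))
  out
}

#' Trailing 20-sample signal matrix of a channel
#'
#' Row `t` holds the filtered samples `[t - seg_len + 1, t]` (causal window,
#' stride 1); the first `seg_len - 1` rows are left-padded by edge
#' replication so the row count equals the trace length.
#'
#' @param trace conditioned channel vector.
#' @param seg_len window length (default 20).
#' @return tibble with `seg_len` columns `s1..s<seg_len>` (oldest to newest).
#' @export
segment_signal <- function(trace, seg_len = 20) {
  n <- length(trace)
  if (n < seg_len) abort("trace shorter than the segment window")
  padded <- c(rep(trace[1], seg_len - 1), trace)
  m <- matrix(padded[outer(seq_len(n) - 1L, seq_len(seg_len), `+`)], nrow = n)
  colnames(m) <- paste0("s", seq_len(seg_len))
  tibble::as_tibble(m)
}

canonical_channel_order <- function() {
  c(paste0("L", 1:6), paste0("R", 1:6))
}

#' Assemble the stacked EMG input matrix
#'
#' Per channel, horizontally concatenates the 18-column feature block and the
#' 20-column signal block (38 columns); channels are stacked left-to-right in
#' canonical order (`L1..L6, R1..R6`, restricted to the channels present).
#' For 12 channels the result has 456 columns. Column names are
#' `<channel>_<feature>` and `<channel>_s<k>`; the channel order and feature
#' set are recorded as attributes for provenance.
#'
#' @param cond conditioned EMG tibble.
#' @param feature_window,wamp_threshold passed to [extract_features()].
#' @param seg_len passed to [segment_signal()].
#' @return tibble `n x (38 * n_channels)` with attributes `channel_order`,
#'   `feature_set`, `block_size`.
#' @export
build_input_matrix <- function(cond, feature_window = 256, seg_len = 20,
                               wamp_threshold = 0.01) {
  fs <- attr(cond, "sample_rate") %||% 1000
  chans <- intersect(canonical_channel_order(), emg_channels(cond))
  if (length(chans) == 0) abort("no recognised channels")
  blocks <- purrr::map(chans, function(ch) {
    f <- extract_features(cond[[ch]], fs, feature_window, wamp_threshold)
    s <- segment_signal(cond[[ch]], seg_len)
    names(f) <- paste0(ch, "_", names(f))
    names(s) <- paste0(ch, "_", names(s))
    dplyr::bind_cols(f, s)
  })
  out <- dplyr::bind_cols(blocks)
  attr(out, "channel_order") <- chans
  attr(out, "feature_set") <- feature_names()
  attr(out, "block_size") <- 18 + seg_len
  class(out) <- c("emg_input_matrix", class(out))
  out
}

#' Assemble per-channel blocks into an input matrix
#'
#' Lower-level companion of [build_input_matrix()]: takes named lists of
#' already-computed feature and signal blocks and concatenates them in
#' canonical channel order.
#'
#' @param per_channel named list (channel -> list(features=, signal=)).
#' @return input-matrix tibble as in [build_input_matrix()].
#' @export
assemble_input <- function(per_channel) {
  chans <- intersect(canonical_channel_order(), names(per_channel))
  if (!length(chans)) abort("no recognised channels")
  ns <- vapply(per_channel[chans], function(b) nrow(b$features), integer(1))
  ns2 <- vapply(per_channel[chans], function(b) nrow(b$signal), integer(1))
  if (length(unique(c(ns, ns2))) != 1) {
    bad <- chans[ns != ns[1] | ns2 != ns[1]]
    abort(paste0("row-count mismatch in channel(s): ", paste(bad, collapse = ", ")))
  }
  blocks <- purrr::map(chans, function(ch) {
    f <- per_channel[[ch]]$features; s <- per_channel[[ch]]$signal
    names(f) <- paste0(ch, "_", names(f)); names(s) <- paste0(ch, "_", names(s))
    dplyr::bind_cols(f, s)
  })
  out <- dplyr::bind_cols(blocks)
  attr(out, "channel_order") <- chans
  attr(out, "block_size") <- ncol(out) / length(chans)
  class(out) <- c("emg_input_matrix", class(out))
  out
}

#' Column-slice an input matrix to a channel subset
#'
#' Equivalent, by construction, to assembling the matrix from that subset.
#'
#' @param V input-matrix tibble.
#' @param channels channel labels to keep.
#' @return input-matrix tibble restricted to those channels' blocks.
#' @export
subset_input_matrix <- function(V, channels) {
  have <- attr(V, "channel_order")
  if (!all(channels %in% have)) abort("requested channels not present")
  keep <- intersect(canonical_channel_order(), channels)
  cols <- unlist(lapply(keep, function(ch) grep(paste0("^", ch, "_"), names(V))))
  out <- V[, cols]
  attr(out, "channel_order") <- keep
  attr(out, "block_size") <- attr(V, "block_size")
  attr(out, "feature_set") <- attr(V, "feature_set")
  class(out) <- c("emg_input_matrix", class(out))
  out
}

#' Assemble the joint-angle output matrix
#'
#' Aligns a 1 kHz joint-angle series to the rows of an input matrix. A
#' mismatch of at most one sample (grid rounding) is repaired by
#' truncation/edge padding and reported via the `alignment` attribute;
#' anything larger is an error.
#'
#' @param angles joint-angle tibble with columns `theta1..theta4` (degrees).
#' @param n_rows row count of the input matrix to align to.
#' @return tibble `n_rows x 4` of `theta1..theta4`.
#' @export
assemble_output <- function(angles, n_rows) {
  th <- dplyr::select(angles, dplyr::all_of(paste0("theta", 1:4)))
  d <- nrow(th) - n_rows
  if (abs(d) > 1) abort("angle series misaligned with input rows by more than 1 sample")
  if (d > 0) th <- th[seq_len(n_rows), ]
  if (d < 0) th <- dplyr::bind_rows(th, th[nrow(th), ])
  attr(th, "alignment") <- d
  th
}
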