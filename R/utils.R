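#' @importFrom rlang %||% abort warn .data
#' @importFrom stats fft median sd var mad density optim quantile rnorm runif
#' @importFrom utils head tail
NULL

# Modified-Akima (makima) piecewise-cubic interpolation.
#
# Slopes follow the modified-Akima weighting
#   w1 = |d_{i+1} - d_i| + |d_{i+1} + d_i| / 2
# (d_i are secant slopes), which removes the classic Akima overshoot on flat
# runs; evaluation is cubic Hermite via stats::splinefunH. Reproduces the knot
# values exactly and polynomials of degree <= 1 everywhere.
interp_makima <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n == length(y))
  if (n < 2) abort("makima interpolation needs at least 2 points")
  if (any(diff(x) <= 0)) abort("timestamps must be strictly increasing")
  if (n < 4) {
    # too few points for Akima slopes; fall back to linear
    return(stats::approx(x, y, xout = xout, rule = 2)$y)
  }
  d <- diff(y) / diff(x)                      # secant slopes, length n-1
  # extend by quadratic extrapolation at both ends (MATLAB convention)
  d_ext <- c(2 * d[1] - d[2], d, 2 * d[n - 1] - d[n - 2])
  d_ext <- c(2 * d_ext[1] - d_ext[2], d_ext, 2 * d_ext[n + 1] - d_ext[n])
  # slopes at knots i use d_ext[i..i+3]
  m <- numeric(n)
  for (i in seq_len(n)) {
    dm2 <- d_ext[i]; dm1 <- d_ext[i + 1]; dp1 <- d_ext[i + 2]; dp2 <- d_ext[i + 3]
    w1 <- abs(dp2 - dp1) + abs(dp2 + dp1) / 2
    w2 <- abs(dm1 - dm2) + abs(dm1 + dm2) / 2
    m[i] <- if (w1 + w2 == 0) 0 else (w1 * dm1 + w2 * dp1) / (w1 + w2)
  }
  f <- stats::splinefunH(x, y, m)
  out <- f(xout)
  # clamp extrapolation to end values (we only ever evaluate inside the range,
  # but floating-point grid ends can fall epsilon outside)
  out[xout <= x[1]] <- y[1] + (xout[xout <= x[1]] - x[1]) * m[1]
  out[xout >= x[n]] <- y[n] + (xout[xout >= x[n]] - x[n]) * m[n]
  # exact knot reproduction
  hit <- match(round(xout, 12), round(x, 12))
  out[!is.na(hit)] <- y[hit[!is.na(hit)]]
  out
}

# Analytic signal by FFT half-spectrum doubling; returns complex vector.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x - mean(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# wrap degrees to (-180, 180]
wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

wrap_rad <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

circular_mean_deg <- function(x) {
  r <- x * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

# Centered moving average with shrinking windows at the edges (no zero-pad
# bias): value t averages samples [t-h, t+h] intersected with the trace.
moving_average_shrink <- function(x, width) {
  n <- length(x)
  if (width > n) abort("smoothing window longer than the trace")
  if (width <= 1) return(x)
  h_lo <- floor((width - 1) / 2)
  h_hi <- width - 1 - h_lo
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  lo <- pmax(idx - h_lo, 1)
  hi <- pmin(idx + h_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Rolling sum over centered windows with shrink edges; returns sum and count.
rolling_sum_shrink <- function(x, width) {
  n <- length(x)
  h_lo <- floor((width - 1) / 2)
  h_hi <- width - 1 - h_lo
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  lo <- pmax(idx - h_lo, 1)
  hi <- pmin(idx + h_hi, n)
  list(sum = cs[hi + 1] - cs[lo], count = hi - lo + 1)
}

# Welch power spectral density: hann-windowed overlapping segments, averaged
# one-sided periodograms. Returns tibble(freq, power).
welch_psd <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, max(256, 2^floor(log2(n / 4))))
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(w^2)
  nf <- floor(nperseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / (u * fs)
    acc <- acc + P[seq_len(nf)]
  }
  p <- acc / length(starts)
  # one-sided scaling
  if (nperseg %% 2 == 0) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)] else p[2:nf] <- 2 * p[2:nf]
  tibble::tibble(freq = (seq_len(nf) - 1) * fs / nperseg, power = p)
}

# Dominant spectral peak with parabolic (log-power) refinement.
dominant_frequency <- function(x, fs, nperseg = NULL) {
  psd <- welch_psd(x, fs, nperseg)
  k <- which.max(psd$power[-1]) + 1         # skip DC
  if (k > 1 && k < nrow(psd)) {
    lp <- log(pmax(psd$power[(k - 1):(k + 1)], .Machine$double.xmin))
    denom <- lp[1] - 2 * lp[2] + lp[3]
    delta <- if (abs(denom) > 1e-12) 0.5 * (lp[1] - lp[3]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
  } else delta <- 0
  df <- psd$freq[2] - psd$freq[1]
  list(freq = psd$freq[k] + delta * df, bin_width = df, psd = psd)
}

`%||%` <- rlang::`%||%`

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}
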