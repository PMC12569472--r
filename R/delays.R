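# Local maxima with topographic prominence.
# Returns indices of peaks with prominence >= prom_min, then enforces a
# minimum pairwise separation by keeping the higher of any conflicting pair.
find_peaks_prominence <- function(x, prom_min = 0, min_sep = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # plateau-safe local maxima: first index of each rising-then-falling run
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (!length(nz)) return(integer(0))
  cand <- integer(0)
  prev_sign <- 0; prev_idx <- 0
  for (k in nz) {
    # plateau maxima: rise ends at prev_idx, fall starts at k; take the middle
    if (prev_sign > 0 && s[k] < 0) cand <- c(cand, (prev_idx + 1L + k) %/% 2L)
    prev_sign <- s[k]; prev_idx <- k
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmin <- x[i]; j <- i
    while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1; lmin <- min(lmin, x[j]) }
    rmin <- x[i]; j <- i
    while (j < n && x[j + 1] <= x[i]) { j <- j + 1; rmin <- min(rmin, x[j]) }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= prom_min]
  if (length(keep) > 1 && min_sep > 1) {
    ord <- keep[order(x[keep], decreasing = TRUE)]
    chosen <- integer(0)
    for (i in ord) {
      if (!length(chosen) || all(abs(chosen - i) >= min_sep)) chosen <- c(chosen, i)
    }
    keep <- sort(chosen)
  }
  keep
}

#' Detect EMG onset peaks
#'
#' Prominence- and separation-based local-maxima search on each channel's
#' activation envelope. The prominence floor is `prominence_k` times the
#' median absolute deviation of that channel's envelope; of two candidates
#' closer than `min_sep_s`, the higher is kept.
#'
#' @param env envelope tibble (see [emg_envelope()]).
#' @param prominence_k prominence multiplier (default 3).
#' @param min_sep_s minimum peak separation, seconds. Sensible default:
#'   0.4 of the tail-beat period.
#' @return tibble of class `onset_peaks`: `channel`, `time_s`, `height`,
#'   ordered by channel then time; detection parameters as attributes.
#' @export
detect_onset_peaks <- function(env, prominence_k = 3, min_sep_s = 0.25) {
  chans <- emg_channels(env)
  if (!nrow(env)) abort("empty envelope")
  fs <- attr(env, "sample_rate") %||% round(1 / median(diff(env$time_s)))
  sep <- max(1, round(min_sep_s * fs))
  out <- purrr::map_dfr(chans, function(ch) {
    x <- env[[ch]]
    idx <- find_peaks_prominence(x, prom_min = prominence_k * mad(x), min_sep = sep)
    tibble::tibble(channel = ch, time_s = env$time_s[idx], height = x[idx])
  })
  attr(out, "prominence_k") <- prominence_k
  attr(out, "min_sep_s") <- min_sep_s
  class(out) <- c("onset_peaks", class(out))
  out
}

#' Detect extrema of a lateral-displacement series
#'
#' Maxima and minima via the same prominence mechanism applied to the series
#' and its negation; alternation is then enforced by dropping the lesser of
#' two same-kind neighbours (for minima, the shallower).
#'
#' @param ld tibble `time_s`, `ld`.
#' @param prominence_k prominence multiplier on the MAD (default 1).
#' @param min_sep_s minimum extremum separation, seconds.
#' @return list of class `ld_extrema`: `events` tibble (`time_s`, `value`,
#'   `kind` in `LD_max`/`LD_min`, alternating), plus `maxima`/`minima` times.
#' @export
detect_ld_extrema <- function(ld, prominence_k = 1, min_sep_s = 0.1) {
  x <- ld$ld
  if (mad(x) == 0 && sd(x) == 0) abort("flat lateral-displacement series")
  fs <- round(1 / median(diff(ld$time_s)))
  sep <- max(1, round(min_sep_s * fs))
  prom <- prominence_k * mad(x)
  imax <- find_peaks_prominence(x, prom, sep)
  imin <- find_peaks_prominence(-x, prom, sep)
  ev <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(time_s = ld$time_s[imax], value = x[imax], kind = "LD_max"),
    tibble::tibble(time_s = ld$time_s[imin], value = x[imin], kind = "LD_min")),
    .data$time_s)
  if (!nrow(ev)) abort("no extrema detected")
  # enforce alternation: among consecutive same-kind runs keep the extreme one
  repeat {
    same <- which(ev$kind[-1] == ev$kind[-nrow(ev)])
    if (!length(same)) break
    i <- same[1]
    drop_i <- if (ev$kind[i] == "LD_max") {
      if (ev$value[i] >= ev$value[i + 1]) i + 1 else i
    } else {
      if (ev$value[i] <= ev$value[i + 1]) i + 1 else i
    }
    ev <- ev[-drop_i, ]
  }
  structure(list(events = ev,
                 maxima = ev$time_s[ev$kind == "LD_max"],
                 minima = ev$time_s[ev$kind == "LD_min"]),
            class = "ld_extrema")
}

#' Match EMG onset peaks to lateral-displacement extrema
#'
#' For each extremum the nearest onset peak before and after are found; the
#' "before" peak is chosen iff
#' `|t_k - t_before| - |t_k - t_after| < epsilon`, otherwise the "after"
#' peak. The signed delay is `delta_t = t_extremum - t_peak` (positive: EMG
#' precedes kinematics). Left-side channels pair with LD minima, right-side
#' with LD maxima. Extrema with no peak inside the search horizon yield no
#' record. Note the rule as stated prefers "before" throughout the epsilon
#' band, even when "after" is marginally closer.
#'
#' @param peaks `onset_peaks` tibble (one or more channels).
#' @param extrema `ld_extrema` for the midline point paired with those
#'   channels.
#' @param side `"left"` or `"right"`; inferred from the channel prefix when
#'   all channels share one side.
#' @param epsilon_ms ambiguity threshold, ms (default 10).
#' @param horizon_s search horizon around each extremum, seconds; default one
#'   estimated period (twice the median same-kind extremum spacing).
#' @param flip_sides swap the left/min, right/max pairing (camera-orientation
#'   dependent).
#' @return tibble of delay records: `channel`, `side`, `extremum_kind`,
#'   `extremum_time_s`, `peak_time_s`, `delta_t_ms`, `branch`.
#' @export
match_delays <- function(peaks, extrema, side = NULL, epsilon_ms = 10,
                         horizon_s = NULL, flip_sides = FALSE) {
  ev <- extrema$events
  empty_records <- tibble::tibble(
    channel = character(0), side = character(0), extremum_kind = character(0),
    extremum_time_s = numeric(0), peak_time_s = numeric(0),
    delta_t_ms = numeric(0), branch = character(0))
  if (!nrow(peaks) || !nrow(ev)) {
    warn("no peaks or extrema to match")
    return(empty_records)
  }
  chans <- unique(peaks$channel)
  sides <- ifelse(grepl("^L", chans), "left", "right")
  if (is.null(side)) {
    if (length(unique(sides)) > 1) abort("mixed channel sides: pass side explicitly per call")
    side <- unique(sides)
  }
  kind <- if ((side == "left") != flip_sides) "LD_min" else "LD_max"
  tk <- ev$time_s[ev$kind == kind]
  if (is.null(horizon_s)) {
    horizon_s <- if (length(tk) > 2) 2 * median(diff(tk)) else Inf
  }
  eps <- epsilon_ms / 1000
  out <- purrr::map_dfr(chans, function(ch) {
    tp <- sort(peaks$time_s[peaks$channel == ch])
    if (!length(tp) || !length(tk)) {
      warn(paste0("no peaks or extrema to match for channel ", ch))
      return(empty_records)
    }
    purrr::map_dfr(tk, function(t0) {
      before <- tp[tp <= t0]; after <- tp[tp > t0]
      tb <- if (length(before)) max(before) else NA_real_
      ta <- if (length(after)) min(after) else NA_real_
      if (!is.na(tb) && t0 - tb > horizon_s) tb <- NA_real_
      if (!is.na(ta) && ta - t0 > horizon_s) ta <- NA_real_
      if (is.na(tb) && is.na(ta)) return(tibble::tibble())
      branch <- if (is.na(ta)) "before"
      else if (is.na(tb)) "after"
      else if (abs(t0 - tb) - abs(t0 - ta) < eps) "before" else "after"
      tc <- if (branch == "before") tb else ta
      tibble::tibble(channel = ch, side = side, extremum_kind = kind,
                     extremum_time_s = t0, peak_time_s = tc,
                     delta_t_ms = (t0 - tc) * 1000, branch = branch)
    })
  })
  out
}

# maximum-likelihood location-scale F fit (optional descriptive density)
fit_f_location_scale <- function(x) {
  loc0 <- min(x) - 0.25 * diff(range(x)) - 1e-6
  nll <- function(p) {
    d1 <- exp(p[1]); d2 <- exp(p[2]); loc <- p[3]; sc <- exp(p[4])
    if (loc >= min(x)) return(1e10)
    z <- (x - loc) / sc
    -sum(stats::df(z, d1, d2, log = TRUE) - log(sc))
  }
  fit <- tryCatch(
    optim(c(log(4), log(10), loc0, log(sd(x) + 1e-9)), nll, method = "Nelder-Mead",
          control = list(maxit = 2000)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  p <- fit$par
  pars <- list(d1 = exp(p[1]), d2 = exp(p[2]), loc = p[3], scale = exp(p[4]))
  # Kolmogorov-Smirnov distance as a descriptive goodness-of-fit
  z <- sort((x - pars$loc) / pars$scale)
  Fn <- seq_along(z) / length(z)
  ks <- max(abs(Fn - stats::pf(z, pars$d1, pars$d2)),
            abs(Fn - 1 / length(z) - stats::pf(z, pars$d1, pars$d2)))
  c(pars, list(ks = ks, converged = fit$convergence == 0))
}

#' Summarise a set of signed delays
#'
#' The headline statistic is the percentage of negative delays, computed from
#' the raw records (never from a fitted density). An empirical density and an
#' optional maximum-likelihood location-scale F fit are attached as
#' descriptive summaries of the delay distribution's shape.
#'
#' @param records delay-record tibble from [match_delays()].
#' @param fit_density fit the location-scale F density (default TRUE).
#' @return list of class `delay_summary`: `n`, `percent_negative`,
#'   `median_ms`, `per_channel` tibble, `density` (stats::density), `f_fit`
#'   (list or NULL).
#' @export
summarize_delays <- function(records, fit_density = TRUE) {
  if (!nrow(records)) abort("no delay records to summarise")
  x <- records$delta_t_ms
  per <- records |>
    dplyr::summarise(n = dplyr::n(),
                     percent_negative = 100 * mean(.data$delta_t_ms < 0),
                     median_ms = median(.data$delta_t_ms),
                     .by = c("channel", "extremum_kind"))
  f_fit <- if (fit_density && length(x) >= 20 && sd(x) > 0) fit_f_location_scale(x) else NULL
  structure(list(
    n = length(x),
    percent_negative = 100 * mean(x < 0),
    median_ms = median(x),
    per_channel = per,
    density = if (length(x) >= 2 && sd(x) > 0) density(x) else NULL,
    f_fit = f_fit,
    delta_t_ms = x), class = "delay_summary")
}

#' @export
print.delay_summary <- function(x, ...) {
  cat(sprintf("<delay_summary> n = %d, %.2f%% negative, median %.1f ms\n",
              x$n, x$percent_negative, x$median_ms))
  invisible(x)
}

#' @rdname summarize_delays
#' @param x a `delay_summary`.
#' @param ... unused.
#' @export
tidy.delay_summary <- function(x, ...) x$per_channel

#' @rdname summarize_delays
#' @export
glance.delay_summary <- function(x, ...) {
  tibble::tibble(n = x$n, percent_negative = x$percent_negative,
                 median_ms = x$median_ms,
                 f_fit_ks = if (!is.null(x$f_fit)) x$f_fit$ks else NA_real_)
}
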