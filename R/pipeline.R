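#' Analysis configuration
#'
#' Every constant of the processing chain, surfaced as a named key: the
#' 50 Hz notch, the 20-450 Hz band, the 0.9 pose-likelihood floor, the 10 ms
#' delay-matching epsilon, the 20-sample segment window, the electrode
#' stations, and the detection parameters. Serialisable to/from YAML;
#' [config_hash()] fingerprints a configuration so reports are traceable.
#'
#' @param ... overrides of the default keys.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    notch_hz = 50, band_hz = c(20, 450), band_order = 4, notch_q = 30,
    working_rate_hz = 1000,
    envelope_window_ms = 50,
    likelihood_min = 0.9,
    feature_window = 256, segment_window = 20,
    channel_positions = seq(0.5, 1, by = 0.1),
    prominence_k = 3, min_sep_period_frac = 0.4,
    epsilon_ms = 10, flip_sides = FALSE,
    joint_landmarks = c(1, 4, 6, 8, 10, 12))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  structure(utils::modifyList(cfg, over), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
config_hash <- function(cfg) rlang::hash(unclass(cfg))

#' Simulate a trial to disk
#'
#' Wraps [generate_trial()] and prints a one-line ground-truth summary.
#'
#' @inheritParams generate_trial
#' @param quiet suppress the summary line.
#' @return the one-row manifest tibble, invisibly.
#' @export
simulate_trial <- function(condition = "laminar", seed = 1, out_dir = tempdir(),
                           overrides = list(), quiet = FALSE) {
  tr <- generate_trial(condition, seed, out_dir, overrides)
  if (!quiet) {
    b <- tr$truth$bursts
    cat(sprintf("%s seed %d: %d bursts, %.1f%% lagging, tau = %s ms\n",
                condition, seed, nrow(b), 100 * mean(b$label == "lagging"),
                paste(unique(abs(b$true_lag_ms)), collapse = "/")))
  }
  invisible(tr$manifest)
}

# landmark arclength fractions estimated from the trial-mean x positions
estimate_landmark_fractions <- function(track) {
  ids <- pose_landmark_ids(track)
  mx <- vapply(ids, function(i) mean(track[[paste0("p", i, "_x")]]), numeric(1))
  (mx - mx[1]) / (mx[length(mx)] - mx[1])
}

# process one trial: conditioning -> envelope -> kinematics -> delays
process_trial <- function(row, cfg) {
  stage <- "read"
  emg <- read_emg_csv(row$emg_path)
  pose <- read_pose_csv(row$pose_path)

  stage <- "condition"
  fc <- filter_config(cfg$band_hz, cfg$band_order, cfg$notch_hz, cfg$notch_q,
                      cfg$working_rate_hz)
  cond <- condition_emg(emg, attr(emg, "sample_rate"), fc)
  env <- emg_envelope(cond, cfg$envelope_window_ms)

  stage <- "kinematics"
  pose <- clean_pose(pose, cfg$likelihood_min)
  pose_hi <- resample_to_rate(pose, cfg$working_rate_hz)
  fracs <- estimate_landmark_fractions(pose)
  tail_lm <- length(fracs)
  ld_tail <- lateral_displacement(pose_hi, tail_lm)
  ks <- kinematic_summary(ld_tail, row$flow_speed, row$body_length_cm)
  period <- ks$period_s

  stage <- "delays"
  min_sep <- cfg$min_sep_period_frac * period
  peaks <- detect_onset_peaks(env, cfg$prominence_k, min_sep)
  chans <- emg_channels(env)
  recs <- purrr::map_dfr(chans, function(ch) {
    k <- as.integer(sub("^[LR]", "", ch))
    pos <- cfg$channel_positions[k]
    lm <- which.min(abs(fracs - pos))
    ex <- detect_ld_extrema(lateral_displacement(pose_hi, lm),
                            min_sep_s = min_sep)
    match_delays(peaks[peaks$channel == ch, ], ex,
                 epsilon_ms = cfg$epsilon_ms, horizon_s = period,
                 flip_sides = cfg$flip_sides)
  })
  recs$trial_id <- row$trial_id
  recs$condition <- row$condition
  list(summary = ks, delays = recs, stage = stage)
}

#' Run the full analysis pipeline over a trial manifest
#'
#' For each trial: condition the EMG, extract envelopes, clean and upsample
#' the pose, summarise the tail-beat kinematics, detect EMG onset peaks and
#' lateral-displacement extrema, and match them into signed delay records.
#' A failing trial is reported with its stage and does not stop the rest.
#'
#' @param manifest manifest tibble (see [read_manifest()]) or a path to one.
#' @param cfg a [pipeline_config()].
#' @return list of class `run_report`: `trials` (per-trial kinematic
#'   summaries + delay counts), `delays` (all records), `summaries`
#'   (per-condition [summarize_delays()]), `errors`, `config`, `config_hash`,
#'   `version`.
#' @export
run_pipeline <- function(manifest, cfg = pipeline_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  results <- vector("list", nrow(manifest))
  errors <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch(process_trial(row, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1]] <- tibble::tibble(
        trial_id = row$trial_id, message = conditionMessage(res))
      results[[i]] <- NULL
    } else {
      results[[i]] <- res
    }
  }
  ok <- !vapply(results, is.null, logical(1))
  delays <- dplyr::bind_rows(purrr::map(results[ok], "delays"))
  trials <- purrr::map_dfr(which(ok), function(i) {
    g <- glance(results[[i]]$summary)
    g$trial_id <- manifest$trial_id[i]
    g$condition <- manifest$condition[i]
    g$n_delays <- nrow(results[[i]]$delays)
    g$percent_negative <-
      100 * mean(results[[i]]$delays$delta_t_ms < 0)
    g
  })
  summaries <- if (nrow(delays)) {
    lapply(split(delays, delays$condition), summarize_delays)
  } else list()
  structure(list(trials = trials, delays = delays, summaries = summaries,
                 errors = dplyr::bind_rows(errors), config = cfg,
                 config_hash = config_hash(cfg),
                 version = as.character(utils::packageVersion("emgkin"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d trial(s), %d delay record(s), config %s\n",
              nrow(x$trials), nrow(x$delays), substr(x$config_hash, 1, 8)))
  if (nrow(x$errors)) cat(sprintf("  %d trial(s) failed\n", nrow(x$errors)))
  invisible(x)
}

#' Compare delay-sign fractions across flow conditions
#'
#' Pooled and per-channel percent-negative table across two or more runs (or
#' one run spanning several conditions). Channels absent from a condition
#' appear as NA.
#'
#' @param ... `run_report` objects, or delay-record tibbles.
#' @return tibble: `condition`, `channel` (`pooled` first), `n`,
#'   `percent_negative`, ordered by condition.
#' @export
compare_conditions <- function(...) {
  parts <- purrr::map(list(...), function(x) {
    if (inherits(x, "run_report")) x$delays else x
  })
  delays <- dplyr::bind_rows(parts)
  if (!nrow(delays)) abort("no delay records to compare")
  conds <- unique(delays$condition)
  if (length(conds) < 2) warn("fewer than 2 conditions present")
  per <- delays |>
    dplyr::summarise(n = dplyr::n(),
                     percent_negative = 100 * mean(.data$delta_t_ms < 0),
                     .by = c("condition", "channel"))
  pooled <- delays |>
    dplyr::summarise(n = dplyr::n(),
                     percent_negative = 100 * mean(.data$delta_t_ms < 0),
                     .by = "condition") |>
    dplyr::mutate(channel = "pooled")
  all_ch <- unique(delays$channel)
  grid <- tidyr::expand_grid(condition = conds, channel = all_ch)
  per <- dplyr::left_join(grid, per, by = c("condition", "channel"))
  dplyr::bind_rows(pooled, per) |>
    dplyr::arrange(.data$condition, .data$channel != "pooled", .data$channel)
}
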