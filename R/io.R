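#' Read a raw EMG CSV
#'
#' Expected header: `time_s,L1,...,L6,R1,...,R6` (any subset of channels),
#' time in seconds and strictly increasing, voltages in mV.
#'
#' @param path file path.
#' @return EMG tibble with attribute `sample_rate` estimated from the time
#'   column.
#' @export
read_emg_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time_s" %in% names(d)) abort("EMG CSV must have a time_s column")
  extra <- setdiff(names(d), c("time_s", canonical_channel_order()))
  if (length(extra)) abort(paste0("unrecognised columns: ", paste(extra, collapse = ", ")))
  if (any(diff(d$time_s) <= 0)) abort("time_s must be strictly increasing")
  attr(d, "sample_rate") <- round(1 / median(diff(d$time_s)))
  d
}

#' @rdname read_emg_csv
#' @param emg EMG tibble.
#' @export
write_emg_csv <- function(emg, path) {
  readr::write_csv(emg, path, progress = FALSE)
  invisible(path)
}

#' Read a pose-track CSV
#'
#' Accepts two dialects: the DeepLabCut export (three header rows: scorer;
#' bodyparts repeated three times; coords x/y/likelihood; first column the
#' frame index) and a plain dialect with header
#' `frame,p1_x,p1_y,p1_l,...,p12_l`. Landmarks are renumbered `p1..pK` in
#' column order.
#'
#' @param path file path.
#' @param frame_rate frames per second used to derive `time_s` (default 100).
#' @return pose tibble: `frame`, `time_s`, `p<i>_x/_y/_l`; attribute
#'   `frame_rate`.
#' @export
read_pose_csv <- function(path, frame_rate = 100) {
  first <- readr::read_lines(path, n_max = 1)
  if (grepl("^scorer", first)) {
    hdr <- readr::read_lines(path, n_max = 3)
    parts <- strsplit(hdr, ",")
    bodyparts <- parts[[2]][-1]
    coords <- parts[[3]][-1]
    d <- readr::read_csv(path, skip = 3,
                         col_names = c("frame", paste(bodyparts, coords, sep = "|")),
                         show_col_types = FALSE, progress = FALSE)
    uniq <- unique(bodyparts)
    out <- tibble::tibble(frame = d$frame)
    for (k in seq_along(uniq)) {
      bp <- uniq[k]
      out[[paste0("p", k, "_x")]] <- d[[paste(bp, "x", sep = "|")]]
      out[[paste0("p", k, "_y")]] <- d[[paste(bp, "y", sep = "|")]]
      out[[paste0("p", k, "_l")]] <- d[[paste(bp, "likelihood", sep = "|")]]
    }
  } else {
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"frame" %in% names(out)) abort("plain pose CSV must have a frame column")
  }
  out <- dplyr::mutate(out, time_s = .data$frame / frame_rate, .after = "frame")
  lcols <- grep("_l$", names(out), value = TRUE)
  for (lc in lcols) {
    if (any(out[[lc]] < 0 | out[[lc]] > 1)) abort("likelihoods must lie in [0, 1]")
  }
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("pose_tbl", class(out))
  out
}

#' Write a pose track as a DeepLabCut-dialect CSV
#'
#' @param track pose tibble.
#' @param path file path.
#' @param scorer scorer string for the first header row.
#' @export
write_pose_csv_dlc <- function(track, path, scorer = "synthetic") {
  ids <- pose_landmark_ids(track)
  bp <- paste0("p", ids)
  hdr1 <- paste(c("scorer", rep(scorer, 3 * length(ids))), collapse = ",")
  hdr2 <- paste(c("bodyparts", rep(bp, each = 3)), collapse = ",")
  hdr3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(ids))), collapse = ",")
  body <- cbind(track$frame,
                do.call(cbind, lapply(ids, function(i) {
                  cbind(track[[paste0("p", i, "_x")]],
                        track[[paste0("p", i, "_y")]],
                        track[[paste0("p", i, "_l")]])
                })))
  con <- file(path, "w")
  writeLines(c(hdr1, hdr2, hdr3), con)
  utils::write.table(body, con, sep = ",", row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Write delay records to CSV
#'
#' Columns: `trial_id, condition, channel, side, extremum_kind,
#' extremum_time_s, peak_time_s, delta_t_ms, branch`.
#'
#' @param records delay-record tibble (trial_id/condition columns added if
#'   missing).
#' @param path file path.
#' @param trial_id,condition values filled in when absent.
#' @export
write_delays_csv <- function(records, path, trial_id = NA_character_,
                             condition = NA_character_) {
  if (!"trial_id" %in% names(records)) records$trial_id <- trial_id
  if (!"condition" %in% names(records)) records$condition <- condition
  cols <- c("trial_id", "condition", "channel", "side", "extremum_kind",
            "extremum_time_s", "peak_time_s", "delta_t_ms", "branch")
  readr::write_csv(dplyr::select(records, dplyr::all_of(cols)), path,
                   progress = FALSE)
  invisible(path)
}

#' Read a trial manifest CSV
#'
#' Columns: `trial_id, emg_path, pose_path, condition, flow_speed,
#' body_length_cm, pixel_scale, sync_offset, subject_id`. Paths are resolved
#' relative to the manifest's directory and must exist.
#'
#' @param path manifest CSV path.
#' @return manifest tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_id", "emg_path", "pose_path", "condition", "flow_speed",
            "body_length_cm")
  miss <- setdiff(need, names(m))
  if (length(miss)) abort(paste0("manifest missing columns: ", paste(miss, collapse = ", ")))
  bad <- !m$condition %in% c("laminar", "cyl5", "cyl7")
  if (any(bad)) abort(paste0("unknown condition: ", paste(unique(m$condition[bad]), collapse = ", ")))
  root <- dirname(path)
  m$emg_path <- ifelse(file.exists(m$emg_path), m$emg_path, file.path(root, m$emg_path))
  m$pose_path <- ifelse(file.exists(m$pose_path), m$pose_path, file.path(root, m$pose_path))
  gone <- c(m$emg_path[!file.exists(m$emg_path)], m$pose_path[!file.exists(m$pose_path)])
  if (length(gone)) abort(paste0("referenced files missing: ", paste(gone, collapse = ", ")))
  m
}

#' Persist an input/output matrix with a provenance comment header
#'
#' @param V input-matrix tibble.
#' @param path file path.
#' @export
write_input_matrix_csv <- function(V, path) {
  hdr <- sprintf("# channel_order=%s; block_size=%s",
                 paste(attr(V, "channel_order"), collapse = "|"),
                 attr(V, "block_size"))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  readr::write_csv(V, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_input_matrix_csv
#' @export
read_input_matrix_csv <- function(path) {
  hdr <- readr::read_lines(path, n_max = 1)
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (grepl("^# channel_order=", hdr)) {
    spec_part <- sub("^# channel_order=([^;]*);.*$", "\\1", hdr)
    attr(d, "channel_order") <- strsplit(spec_part, "\\|")[[1]]
    attr(d, "block_size") <- as.numeric(sub(".*block_size=", "", hdr))
  }
  class(d) <- c("emg_input_matrix", class(d))
  d
}
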