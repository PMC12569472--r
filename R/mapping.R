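#' Specification of an EMG-to-kinematics regressor
#'
#' Three families are available. `dense` is a multilayer perceptron on the
#' input matrix (default hidden plan 512-256-128). `recurrent` stacks simple
#' recurrent (Elman) layers over a trailing 20-step window (default 64-16).
#' `convolutional` treats the 20 x width window as an image: two 3x3
#' convolution blocks (default 32 then 64 filters, max-pooling between) and
#' a dense head (default 128 units). All train with Adam on mean-squared
#' error with early stopping on a held-out-within-train split, and are
#' deterministic given the seed.
#'
#' @param family `"dense"`, `"recurrent"` or `"convolutional"`.
#' @param layers hidden-layer widths (dense/recurrent families).
#' @param filters the two convolution filter counts.
#' @param dense_units width of the convolutional family's dense head.
#' @param pool pooling window (time, feature) for the convolutional family.
#' @param window trailing time steps per sequence sample (default 20).
#' @param seed integer; fixes initialisation and batch order.
#' @param epochs,batch_size,learning_rate,patience training budget.
#' @return an `emg_mapping_spec` list.
#' @export
emg_mapping_spec <- function(family = c("dense", "recurrent", "convolutional"),
                             layers = NULL, filters = c(32, 64),
                             dense_units = 128, pool = c(2, 4), window = 20,
                             seed = 1, epochs = 200, batch_size = 128,
                             learning_rate = 1e-3, patience = 20) {
  family <- match.arg(family)
  if (is.null(layers)) {
    layers <- switch(family, dense = c(512, 256, 128), recurrent = c(64, 16),
                     convolutional = NULL)
  }
  structure(list(family = family, layers = layers, filters = filters,
                 dense_units = dense_units, pool = pool, window = window,
                 seed = seed, epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, patience = patience),
            class = "emg_mapping_spec")
}

#' Subject-wise train/test split
#'
#' @param subjects vector of per-row subject identifiers.
#' @param test_subjects subjects held out entirely for testing.
#' @return a `subject_split` list with disjoint train/test row indices.
#' @export
make_subject_split <- function(subjects, test_subjects) {
  test_subjects <- unique(test_subjects)
  if (!all(test_subjects %in% subjects)) abort("test subjects not present")
  train_subjects <- setdiff(unique(subjects), test_subjects)
  if (!length(train_subjects)) abort("no training subjects left")
  structure(list(train_subjects = train_subjects,
                 test_subjects = test_subjects,
                 train_idx = which(!subjects %in% test_subjects),
                 test_idx = which(subjects %in% test_subjects),
                 subjects = subjects),
            class = "subject_split")
}

#' Build sequence and image tensors from an input matrix
#'
#' Slice `t` of the sequence tensor holds rows `[t - window + 1, t]` of the
#' matrix (earlier rows edge-replicated); the image tensor appends a trailing
#' singleton axis.
#'
#' @param V input-matrix tibble or matrix, `n >= window` rows.
#' @param window time steps (default 20).
#' @return list: `seq` array `(n, window, width)`, `image` array
#'   `(n, window, width, 1)`.
#' @export
make_sequences <- function(V, window = 20) {
  X <- as.matrix(V)
  if (nrow(X) < window) abort("fewer rows than the sequence window")
  rows <- seq_row_indices(seq_len(nrow(X)), window)
  sq <- array(0, c(nrow(X), window, ncol(X)))
  for (t in seq_len(window)) sq[, t, ] <- X[rows[, t], , drop = FALSE]
  list(seq = sq, image = array(sq, c(dim(sq), 1)))
}

# last-fraction-of-each-subject validation rows (time-ordered, no shuffling)
validation_rows <- function(idx, subjects = NULL, frac = 0.1) {
  if (is.null(subjects)) {
    k <- max(1, floor(length(idx) * frac))
    return(idx[(length(idx) - k + 1):length(idx)])
  }
  unlist(lapply(unique(subjects[idx]), function(s) {
    rows <- idx[subjects[idx] == s]
    k <- max(1, floor(length(rows) * frac))
    rows[(length(rows) - k + 1):length(rows)]
  }))
}

#' Fit an EMG-to-joint-angle regressor
#'
#' Inputs are standardised per column and targets per angle, both with
#' statistics computed on training rows only (no test-subject leakage);
#' validation for early stopping is the last 10% of each training subject's
#' rows, time-ordered. Deterministic given `spec$seed`.
#'
#' @param V input-matrix tibble (see [build_input_matrix()]).
#' @param Y target tibble `theta1..theta4`, degrees.
#' @param spec an [emg_mapping_spec()].
#' @param split optional [make_subject_split()]; defaults to training on all
#'   rows (with a time-ordered validation tail).
#' @return object of class `emg_mapping`.
#' @export
fit_emg_mapping <- function(V, Y, spec = emg_mapping_spec(), split = NULL) {
  X <- as.matrix(V); Ym <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Ym))
  chans <- attr(V, "channel_order")
  blk <- attr(V, "block_size")
  if (!is.null(chans) && !is.null(blk) && ncol(X) != blk * length(chans)) {
    abort("input width is not block_size x n_channels")
  }
  train_idx <- if (is.null(split)) seq_len(nrow(X)) else split$train_idx
  subj <- if (is.null(split)) NULL else split$subjects
  val_idx <- validation_rows(train_idx, subj)
  fit_rows <- setdiff(train_idx, val_idx)

  xc <- colMeans(X[fit_rows, , drop = FALSE])
  xs <- apply(X[fit_rows, , drop = FALSE], 2, sd); xs[xs == 0] <- 1
  yc <- colMeans(Ym[fit_rows, , drop = FALSE])
  ys <- apply(Ym[fit_rows, , drop = FALSE], 2, sd); ys[ys == 0] <- 1
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  Ys <- sweep(sweep(Ym, 2, yc), 2, ys, "/")

  fit <- fit_net(spec$family, Xs, Ys, fit_rows, val_idx, spec)
  structure(list(spec = spec, params = fit$params, log = fit$log,
                 best_epoch = fit$best_epoch, best_val = fit$best_val,
                 scaling = list(x_center = xc, x_scale = xs,
                                y_center = yc, y_scale = ys),
                 width = ncol(X), channel_order = chans, split = split),
            class = "emg_mapping")
}

#' @rdname fit_emg_mapping
#' @param object fitted `emg_mapping`.
#' @param newdata input-matrix tibble with the same width and channel order.
#' @param ... unused.
#' @export
predict.emg_mapping <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$width) {
    abort(sprintf("input width %d does not match the fitted width %d",
                  ncol(X), object$width))
  }
  Xs <- sweep(sweep(X, 2, object$scaling$x_center), 2, object$scaling$x_scale, "/")
  out <- net_predict(object$spec$family, object$params, Xs, seq_len(nrow(Xs)),
                     object$spec$window)
  out <- sweep(sweep(out, 2, object$scaling$y_scale, "*"), 2,
               object$scaling$y_center, "+")
  colnames(out) <- paste0("theta", 1:4)
  tibble::as_tibble(as.data.frame(out))
}

#' @export
print.emg_mapping <- function(x, ...) {
  cat(sprintf("<emg_mapping> %s family, width %d, best epoch %d (val MSE %.4g)\n",
              x$spec$family, x$width, x$best_epoch, x$best_val))
  invisible(x)
}

#' @rdname fit_emg_mapping
#' @param x fitted `emg_mapping`.
#' @export
tidy.emg_mapping <- function(x, ...) x$log

#' @rdname fit_emg_mapping
#' @export
glance.emg_mapping <- function(x, ...) {
  tibble::tibble(family = x$spec$family, width = x$width,
                 n_params = sum(vapply(x$params, length, numeric(1))),
                 epochs_trained = nrow(x$log), best_epoch = x$best_epoch,
                 best_val_mse = x$best_val, seed = x$spec$seed)
}

#' Evaluate a fitted mapping on held-out data
#'
#' Delegates to the kinematics module: per-joint RMSE, body-pose x-RMSE
#' after forward kinematics (when segment lengths are supplied), and the
#' mean instantaneous phase difference per joint.
#'
#' @param model fitted `emg_mapping`.
#' @param V_test,Y_test held-out input matrix and measured angles.
#' @param segment_lengths optional 5 link lengths (cm) for pose RMSE.
#' @return list of class `mapping_eval`: `rmse` tibble, `pose_rmse_x` (or
#'   NA), `phase` tibble (`joint`, `mean_dphi_deg`), `pred`.
#' @export
evaluate_mapping <- function(model, V_test, Y_test, segment_lengths = NULL) {
  pred <- predict(model, V_test)
  rmse <- rmse_angles(pred, Y_test)
  pose_rmse_x <- NA_real_
  if (!is.null(segment_lengths)) {
    mk <- function(th) {
      a <- tibble::as_tibble(th)
      a$time_s <- seq_len(nrow(a)) * 1e-3
      forward_kinematics(a, segment_lengths)
    }
    pr <- rmse_pose(mk(pred), mk(Y_test))
    pose_rmse_x <- attr(pr, "rmse_x")
  }
  phase <- purrr::map_dfr(paste0("theta", 1:4), function(j) {
    pd <- suppressWarnings(phase_difference(pred[[j]], Y_test[[j]]))
    tibble::tibble(joint = j, mean_dphi_deg = pd$mean_deg)
  })
  structure(list(rmse = rmse, pose_rmse_x = pose_rmse_x, phase = phase,
                 pred = pred),
            class = "mapping_eval")
}

#' @export
print.mapping_eval <- function(x, ...) {
  cat("<mapping_eval>\n")
  cat(sprintf("  mean joint RMSE: %.3f deg; pose x-RMSE: %s cm\n",
              mean(x$rmse$rmse),
              ifelse(is.na(x$pose_rmse_x), "-", sprintf("%.3f", x$pose_rmse_x))))
  invisible(x)
}

#' @rdname evaluate_mapping
#' @param x a `mapping_eval`.
#' @param ... unused.
#' @export
glance.mapping_eval <- function(x, ...) {
  tibble::tibble(mean_rmse_deg = mean(x$rmse$rmse),
                 max_rmse_deg = max(x$rmse$rmse),
                 pose_rmse_x_cm = x$pose_rmse_x,
                 mean_dphi_deg = circular_mean_deg(x$phase$mean_dphi_deg))
}

# declared channel subsets for the ablation study: symmetric left/right pairs
# spanning the body evenly
ablation_subsets <- function() {
  list(`4` = c("L1", "L6", "R1", "R6"),
       `6` = c("L1", "L3", "L6", "R1", "R3", "R6"),
       `8` = c("L1", "L3", "L4", "L6", "R1", "R3", "R4", "R6"),
       `10` = c("L1", "L2", "L3", "L4", "L6", "R1", "R2", "R3", "R4", "R6"),
       `12` = canonical_channel_order())
}

#' Channel-count ablation study
#'
#' For each channel count the input matrix is rebuilt (by block slicing, which
#' equals reassembly from the subset) from a declared symmetric subset, the
#' model retrained on a fixed seed schedule, and test RMSE recorded; results
#' are summarised as mean and SD over repeats.
#'
#' @param V full 12-channel input matrix.
#' @param Y target angles.
#' @param spec an [emg_mapping_spec()]; its seed seeds the repeat schedule.
#' @param split a [make_subject_split()] used for every fit.
#' @param counts even channel counts within 4..12.
#' @param n_seeds repeats per count.
#' @return list of class `ablation_result`: `runs` tibble (count, seed,
#'   mean_rmse_deg), `summary` tibble (count, mean, sd).
#' @export
channel_ablation <- function(V, Y, spec, split, counts = c(4, 6, 8, 10, 12),
                             n_seeds = 5) {
  stopifnot(all(counts %% 2 == 0), all(counts >= 4), all(counts <= 12))
  subsets <- ablation_subsets()
  have <- attr(V, "channel_order")
  runs <- purrr::map_dfr(counts, function(cnt) {
    chans <- subsets[[as.character(cnt)]]
    if (!all(chans %in% have)) abort(sprintf("count %d exceeds available channels", cnt))
    Vs <- subset_input_matrix(V, chans)
    purrr::map_dfr(seq_len(n_seeds), function(k) {
      sp <- spec
      sp$seed <- derive_seed(spec$seed, 1000 + k)
      m <- fit_emg_mapping(Vs, Y, sp, split)
      ev <- evaluate_mapping(m, Vs[split$test_idx, ], Y[split$test_idx, ])
      tibble::tibble(count = cnt, seed_rep = k,
                     mean_rmse_deg = mean(ev$rmse$rmse))
    })
  })
  summ <- runs |>
    dplyr::summarise(mean = mean(.data$mean_rmse_deg),
                     sd = sd(.data$mean_rmse_deg), .by = "count") |>
    dplyr::arrange(.data$count)
  structure(list(runs = runs, summary = summ,
                 subsets = subsets[as.character(counts)]),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname channel_ablation
#' @param x an `ablation_result`.
#' @param ... unused.
#' @export
tidy.ablation_result <- function(x, ...) x$runs
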