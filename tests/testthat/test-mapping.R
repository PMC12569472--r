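test_that("sequence tensors obey the trailing-window construction", {
  set.seed(50)
  V <- matrix(rnorm(30 * 4), 30, 4)
  s <- make_sequences(V, window = 20)
  expect_equal(dim(s$seq), c(30, 20, 4))
  expect_equal(dim(s$image), c(30, 20, 4, 1))
  # last slice of an n = 20 matrix is rows 1..20
  s20 <- make_sequences(V[1:20, ], window = 20)
  expect_equal(s20$seq[20, , ], V[1:20, ])
  # slice t+1 is slice t shifted by one row
  expect_equal(s$seq[25, 2:20, ], s$seq[26, 1:19, ])
  # constant matrix: all slices identical
  sC <- make_sequences(matrix(1, 25, 3), window = 20)
  expect_true(all(sC$seq == 1))
  expect_error(make_sequences(V[1:10, ], window = 20), "fewer rows")
})

test_that("analytic gradients match numerical gradients for all families", {
  set.seed(51)
  D <- 12; K <- 4; W <- 8; b <- 5
  Xs <- matrix(rnorm(40 * D), 40, D)
  Ys <- matrix(rnorm(40 * K), 40, K)
  idx <- 10:14
  fams <- list(
    dense = emgkin:::init_dense(D, c(6, 5), K),
    recurrent = emgkin:::init_rnn(D, c(6, 4), K),
    convolutional = emgkin:::init_conv(D, W, c(3, 4), 5, K, pool = c(2, 2)))
  for (family in names(fams)) {
    p <- jitter_params(fams[[family]])
    Xb <- emgkin:::build_batch_input(family, Xs, idx, W)
    Yb <- Ys[idx, ]
    f <- emgkin:::net_forward_out(family, p, Xb)
    dOut <- 2 * (f$out - Yb) / length(f$out)
    g <- emgkin:::net_backward(family, p, Xb, f$fw, dOut)
    eps <- 1e-5
    set.seed(52)
    for (nm in names(g)) {
      for (k in sample(seq_along(p[[nm]]), min(4, length(p[[nm]])))) {
        pp <- p; pp[[nm]][k] <- pp[[nm]][k] + eps
        lp <- mean((emgkin:::net_forward_out(family, pp, Xb)$out - Yb)^2)
        pm <- p; pm[[nm]][k] <- pm[[nm]][k] - eps
        lm_ <- mean((emgkin:::net_forward_out(family, pm, Xb)$out - Yb)^2)
        num <- (lp - lm_) / (2 * eps)
        expect_lt(abs(num - g[[nm]][k]) / max(1e-6, abs(num) + abs(g[[nm]][k])),
                  1e-4, label = paste(family, nm, k))
      }
    }
  }
})

test_that("subject splits are disjoint and leakage-free by recomputation", {
  subjects <- rep(1:5, each = 40)
  split <- make_subject_split(subjects, 5)
  expect_length(intersect(split$train_idx, split$test_idx), 0)
  expect_error(make_subject_split(subjects, 9), "not present")
  expect_error(make_subject_split(rep(1, 10), 1), "no training")

  set.seed(53)
  cond <- make_noise_cond(200, seed = 54)[c("time_s", "L1", "R1")]
  attr(cond, "sample_rate") <- 1000
  V <- build_input_matrix(cond, feature_window = 64)
  Y <- make_recoverable_targets(V, seed = 4)
  split <- make_subject_split(rep(1:4, each = 50), 4)
  spec <- emg_mapping_spec("dense", layers = c(8), epochs = 3, seed = 2,
                           batch_size = 64)
  m <- fit_emg_mapping(V, Y, spec, split)
  # recompute standardisation statistics on train-minus-validation rows only
  val <- emgkin:::validation_rows(split$train_idx, split$subjects)
  fit_rows <- setdiff(split$train_idx, val)
  expect_equal(m$scaling$x_center, colMeans(as.matrix(V)[fit_rows, ]))
  expect_false(isTRUE(all.equal(m$scaling$x_center,
                                colMeans(as.matrix(V)))))
})

test_that("fits are deterministic under a fixed seed", {
  cond <- make_noise_cond(150, seed = 55)[c("time_s", "L2")]
  attr(cond, "sample_rate") <- 1000
  V <- build_input_matrix(cond, feature_window = 64)
  Y <- make_recoverable_targets(V, seed = 5)
  spec <- emg_mapping_spec("dense", layers = c(8), epochs = 4, seed = 7,
                           batch_size = 64)
  m1 <- fit_emg_mapping(V, Y, spec)
  m2 <- fit_emg_mapping(V, Y, spec)
  expect_identical(m1$params, m2$params)
})

test_that("models reject inputs whose width disagrees with the fit", {
  cond <- make_noise_cond(150, seed = 56)[c("time_s", "L1", "L2")]
  attr(cond, "sample_rate") <- 1000
  V <- build_input_matrix(cond, feature_window = 64)
  Y <- make_recoverable_targets(V, seed = 6)
  spec <- emg_mapping_spec("dense", layers = c(4), epochs = 2, seed = 1,
                           batch_size = 64)
  m <- fit_emg_mapping(V, Y, spec)
  expect_error(predict(m, V[, 1:38]), "width")
  # width law at fit time: block_size x channels enforced
  Vbad <- V[, 1:50]
  attr(Vbad, "channel_order") <- c("L1", "L2")
  attr(Vbad, "block_size") <- 38
  expect_error(fit_emg_mapping(Vbad, Y, spec), "block_size")
})

test_that("each family learns a recoverable one-channel relation", {
  tr <- generate_trial("laminar", seed = 57, overrides = list(duration_s = 12))
  cond <- condition_emg(tr$emg, 2500)
  V <- subset_input_matrix(build_input_matrix(cond[c("time_s", "L6")]), "L6")
  Y <- make_recoverable_targets(V, seed = 7)
  split <- make_subject_split(rep(1:4, each = ceiling(nrow(V) / 4))[seq_len(nrow(V))], 4)
  sdY <- mean(apply(as.matrix(Y)[split$test_idx, ], 2, sd))
  specs <- list(
    emg_mapping_spec("dense", layers = c(16), seed = 1, epochs = 40,
                     batch_size = 256, learning_rate = 3e-3, patience = 40),
    emg_mapping_spec("recurrent", layers = c(12, 8), seed = 1, epochs = 25,
                     batch_size = 256, learning_rate = 3e-3, patience = 25),
    emg_mapping_spec("convolutional", filters = c(4, 8), dense_units = 16,
                     seed = 1, epochs = 12, batch_size = 256,
                     learning_rate = 3e-3, patience = 12))
  for (spec in specs) {
    m <- fit_emg_mapping(V, Y, spec, split)
    ev <- evaluate_mapping(m, V[split$test_idx, ], Y[split$test_idx, ])
    expect_lt(mean(ev$rmse$rmse) / sdY, 0.6, label = spec$family)
  }
})

test_that("evaluation of a perfect and an offset predictor is exact", {
  Y <- make_angle_series(300)[paste0("theta", 1:4)]
  fake <- structure(list(
    spec = emg_mapping_spec("dense", layers = 4), width = 4,
    scaling = list(x_center = rep(0, 4), x_scale = rep(1, 4),
                   y_center = rep(0, 4), y_scale = rep(1, 4))),
    class = "emg_mapping")
  # bypass the net: evaluate the rmse/phase path directly on predictions
  ev_identity <- rmse_angles(Y, Y)
  expect_equal(max(ev_identity$rmse), 0)
  off <- Y; off$theta4 <- off$theta4 + 5
  r <- rmse_angles(off, Y)
  expect_equal(r$rmse[4], 5)
})

test_that("ablation rejects impossible channel counts", {
  cond <- make_noise_cond(120, seed = 58)[c("time_s", "L1", "R1")]
  attr(cond, "sample_rate") <- 1000
  V <- build_input_matrix(cond, feature_window = 64)
  Y <- make_recoverable_targets(V, seed = 8)
  split <- make_subject_split(rep(1:2, each = 60), 2)
  spec <- emg_mapping_spec("dense", layers = c(4), epochs = 2, batch_size = 64)
  expect_error(channel_ablation(V, Y, spec, split, counts = 6, n_seeds = 1),
               "exceeds")
  expect_error(channel_ablation(V, Y, spec, split, counts = 5, n_seeds = 1))
})
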