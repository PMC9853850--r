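test_that("hysteresis binarization follows the two-threshold rule", {
  b1 <- binarize_trace(c(0, 0.9, 0.9, 0, 0, 0.9, 0))
  expect_identical(b1$states, c(F, T, T, F, F, T, F))
  # 0.4 is between the thresholds: state is retained (hysteresis)
  b2 <- binarize_trace(c(0, 0.9, 0.4, 0.9, 0))
  expect_identical(b2$states, c(F, T, T, T, F))
  b3 <- binarize_trace(rep(0.1, 6))
  expect_identical(b3$states, rep(FALSE, 6))
  expect_error(binarize_trace(0.5, theta_hi = 0.3, theta_lo = 0.5),
               "theta_hi")
  expect_error(binarize_trace(0.5, theta_hi = 1.2), "thresholds")
})

test_that("blinking descriptors match hand-computed values on a toy trace", {
  x <- c(0, 0.9, 0.8, 0, 0, 0.95, 0)
  b <- binarize_trace(x)
  f <- trace_features(b, x, frame_time = 0.05)
  expect_equal(unname(f["n_peaks"]), 2)
  expect_equal(unname(f["mean_peak_duration"]), 0.075)
  expect_equal(unname(f["photobleach_time"]), 0.30)
  expect_equal(unname(f["total_on_time"]), 0.15)
  expect_equal(unname(f["duty_cycle"]), 3 / 7)
  expect_equal(unname(f["longest_on"]), 0.10)
  expect_equal(unname(f["n_off_events"]), 3)
  expect_equal(unname(f["first_on_time"]), 0.05)
  expect_equal(unname(f["on_intensity_mean"]), mean(c(0.9, 0.8, 0.95)))

  all_off <- trace_features(binarize_trace(rep(0, 10)), rep(0, 10), 0.05)
  expect_equal(unname(all_off["n_peaks"]), 0)
  expect_equal(unname(all_off["duty_cycle"]), 0)
  expect_equal(unname(all_off["photobleach_time"]), 0)
  expect_equal(unname(all_off["total_on_time"]), 0)
})

test_that("measured peak durations agree with a noise-free discretization oracle", {
  spec <- kinetic_class_spec("o", k_on = 0.4, k_off = 1.5,
                             k_bleach = 0.05)
  cam <- camera_config(n_frames = 500L)
  # measured path: camera noise + normalization + hysteresis binarization
  measured <- vapply(1:300, function(s) {
    traj <- simulate_state_trajectory(spec, 25, rng_seed = s)
    x <- normalize_trace(integrate_trace(traj, cam))
    unname(trace_features(binarize_trace(x), x, 0.05)["mean_peak_duration"])
  }, numeric(1L))
  # oracle path: independent trajectories, exact frame ON-fractions,
  # same hysteresis on the noise-free signal
  oracle <- vapply(301:600, function(s) {
    traj <- simulate_state_trajectory(spec, 25, rng_seed = s)
    fr <- frame_on_fractions(traj, cam)
    unname(trace_features(binarize_trace(fr), fr, 0.05)["mean_peak_duration"])
  }, numeric(1L))
  m <- mean(measured[measured > 0])
  o <- mean(oracle[oracle > 0])
  expect_lt(abs(m - o) / o, 0.1)
  # and the oracle itself sits near the continuous-time dwell mean
  expect_lt(abs(o - 1 / (1.5 + 0.05)) / (1 / 1.55), 0.25)
})

test_that("raising the upper threshold never increases the ON time", {
  ts <- demo_small()$norm
  for (i in seq_len(20)) {
    x <- ts$values[i, ]
    lo <- sum(binarize_trace(x, theta_hi = 0.4, theta_lo = 0.3)$states)
    hi <- sum(binarize_trace(x, theta_hi = 0.7, theta_lo = 0.3)$states)
    expect_lte(hi, lo)
  }
})

test_that("feature extraction is deterministic", {
  ts <- demo_small()$norm[1:10]
  a <- feature_table(ts)
  b <- feature_table(ts)
  expect_identical(a, b)
})

test_that("Fourier magnitudes obey DC, Parseval and fundamental-frequency facts", {
  x <- rep(0.3, 64)
  mag <- fourier_magnitudes(x)
  expect_equal(mag[1], 0.3 * 64)
  expect_true(all(mag[-1] < 1e-10))
  set.seed(5)
  y <- runif(128)
  my <- fourier_magnitudes(y)
  expect_lt(abs(sum(my^2) - 128 * sum(y^2)) / (128 * sum(y^2)), 1e-6)
  # square wave with 4 periods: fundamental at index 5 (0-based freq 4)
  sq <- rep(c(rep(1, 16), rep(0, 16)), 4)
  ms <- fourier_magnitudes(sq)
  expect_equal(which.max(ms[-1]), 4L)
})

test_that("PCA embedding is orthonormal with unit-sum variance fractions", {
  ft <- feature_table(demo_small()$norm)
  p <- pca_embed(ft)
  expect_lt(abs(sum(p$var_fraction) - 1), 1e-9)
  expect_true(all(diff(p$var_fraction) <= 1e-12))
  # duplicated rows embed identically
  ft2 <- rbind(ft, ft[1, ])
  ft2$trace_id[nrow(ft2)] <- "dup"
  p2 <- pca_embed(ft2)
  expect_equal(unname(p2$scores[1, ]), unname(p2$scores[nrow(ft2), ]))
  # constant features are dropped with a warning
  ft3 <- ft
  ft3$n_peaks <- 1
  expect_warning(p3 <- pca_embed(ft3), "constant")
  expect_identical(p3$dropped, "n_peaks")
})

test_that("PCA cannot separate classes that differ only in temporal structure", {
  skip_if_not_installed("cluster")
  ts <- switchpair_slow()
  ft <- feature_table(ts)
  p <- suppressWarnings(pca_embed(ft))
  lab <- as.integer(factor(ft$label))
  sil <- cluster::silhouette(lab, dist(p$scores[, 1:2]))
  expect_lt(mean(sil[, 3]), 0.2)
})
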