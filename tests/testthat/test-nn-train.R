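test_that("the classifier masters a duty-cycle-separable two-class problem", {
  ts <- separable_pair()
  parts <- split_dataset(ts, split_spec(seed = 5))
  m <- build_model(tiny_arch(2L), ts$n_frames, init_seed = 5)
  fit <- train_model(m, parts$train,
                     train_config(max_epochs = 20L, batch_size = 32L,
                                  early_stop_patience = 20L, seed = 5))
  expect_gte(max(fit$history$val_acc), 0.99)
  pred <- predict_classes(fit$model, parts$test)
  expect_gte(mean(pred == parts$test$meta$label), 0.9)
  # optimization sanity: training loss decreases in most epoch steps
  dl <- diff(fit$history$train_loss)
  expect_gte(mean(dl <= 1e-6), 0.8)
  assign("separable_fit", list(fit = fit, parts = parts),
         envir = .fixture_env)
})

test_that("training is deterministic under a fixed seed", {
  ts <- separable_pair()[c(1:15, 61:75)]
  cfg <- train_config(max_epochs = 3L, batch_size = 16L, seed = 11L)
  m <- build_model(tiny_arch(2L), ts$n_frames, init_seed = 11L)
  f1 <- train_model(m, ts, cfg)
  f2 <- train_model(build_model(tiny_arch(2L), ts$n_frames,
                                init_seed = 11L), ts, cfg)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$model$layers[[1]]$params$W,
               f2$model$layers[[1]]$params$W, tolerance = 1e-12)
})

test_that("raw (non-normalized) tracesets are refused by the trainer", {
  raw <- demo_small()$raw
  m <- build_model(tiny_arch(4L), raw$n_frames)
  expect_error(train_model(m, raw, train_config(max_epochs = 1L)),
               "normalized")
})

test_that("Monte Carlo dropout predictions are calibrated simplices with entropy flags", {
  sf <- get("separable_fit", envir = .fixture_env)
  preds <- mc_predict(sf$fit$model, sf$parts$test, T = 15L, seed = 3)
  probs <- attr(preds, "mean_probs")
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_true(all(preds$uncertainty >= 0 &
                    preds$uncertainty <= log(2) + 1e-9))
  thr <- attr(preds, "entropy_threshold")
  expect_equal(thr, 0.5 * log(2))
  expect_identical(preds$accepted, preds$uncertainty <= thr)
  # reproducible under the same seed
  preds2 <- mc_predict(sf$fit$model, sf$parts$test, T = 15L, seed = 3)
  expect_identical(preds$uncertainty, preds2$uncertainty)
  expect_error(mc_predict(sf$fit$model, sf$parts$test, T = 1L), "T")
})

test_that("out-of-distribution noise is predicted with higher uncertainty", {
  sf <- get("separable_fit", envir = .fixture_env)
  # camera background noise (what empty regions of a movie yield),
  # normalized like any other trace
  set.seed(13)
  L <- sf$parts$test$n_frames
  noise <- t(vapply(seq_len(40), function(i) {
    normalize_trace(stats::rpois(L, 25) + stats::rnorm(L, 0, 2))
  }, numeric(L)))
  p_noise <- mc_predict(sf$fit$model, noise, T = 15L, seed = 4)
  p_in <- mc_predict(sf$fit$model, sf$parts$test, T = 15L, seed = 4)
  expect_gt(median(p_noise$uncertainty), median(p_in$uncertainty))
})

test_that("tightening the entropy threshold never hurts accepted-subset accuracy", {
  sf <- get("separable_fit", envir = .fixture_env)
  preds <- mc_predict(sf$fit$model, sf$parts$test, T = 15L, seed = 5)
  truth <- sf$parts$test$meta$label
  accs <- vapply(c(0.69, 0.5, 0.3, 0.15), function(thr) {
    keep <- preds$uncertainty <= thr
    if (!any(keep)) return(NA_real_)
    mean(preds$predicted_class[keep] == truth[keep])
  }, numeric(1L))
  accs <- accs[!is.na(accs)]
  expect_true(all(diff(accs) >= -1e-9))
})

test_that("grouped stratified folds partition traces and replicates", {
  ts <- demo_small()$norm
  fold <- blinkid:::.make_folds(ts$meta$label, ts$meta$replicate_id, 5L,
                                seed = 2)
  expect_true(all(fold %in% 1:5))
  expect_equal(length(fold), n_traces(ts))
  # every replicate sits in exactly one fold
  by_rep <- tapply(fold, ts$meta$replicate_id,
                   function(f) length(unique(f)))
  expect_true(all(by_rep == 1L))
  # with fewer replicates than folds, fall back with a warning
  expect_warning(
    blinkid:::.make_folds(ts$meta$label, rep("r1", n_traces(ts)), 5L, 2),
    "fewer replicates")
})

test_that("nested cross-validation reports per-fold accuracies on disjoint folds", {
  ts <- separable_pair()
  cvr <- nested_cross_validate(
    ts, k_outer = 3L, k_inner = 2L,
    grid = data.frame(learning_rate = 1e-3, dropout = 0.2),
    arch = tiny_arch(2L),
    config = train_config(max_epochs = 12L, batch_size = 16L,
                          early_stop_patience = 12L),
    seed = 9L)
  expect_length(cvr$fold_accuracy, 3L)
  expect_equal(sort(unique(cvr$outer_fold)), 1:3)
  expect_equal(nrow(cvr$selected), 3L)
  expect_gte(cvr$mean, 0.9)
})
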