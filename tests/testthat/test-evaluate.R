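test_that("the default splitter yields a grouped, stratified 80/20 partition", {
  labels <- rep(sprintf("c%d", 1:4), each = 100L)
  reps <- sprintf("%s_r%d", labels, rep_len(rep(1:5, each = 20L), 400L))
  idx <- split_indices(labels, reps, split_spec(seed = 3))
  expect_equal(length(idx$train), 320L)
  expect_equal(length(idx$test), 80L)
  expect_equal(sort(c(idx$train, idx$test)), 1:400)
  expect_true(all(table(labels[idx$test]) == 20L)) # exact stratification
  expect_length(intersect(reps[idx$train], reps[idx$test]), 0L)
})

test_that("splits are reproducible and respect replicate grouping", {
  labels <- rep(c("a", "b"), each = 50L)
  reps <- rep(sprintf("r%d", 1:10), each = 10L) # replicates span classes?
  reps <- sprintf("%s_%s", labels, rep(sprintf("r%d", 1:5), each = 10L))
  a <- split_indices(labels, reps, split_spec(seed = 7))
  b <- split_indices(labels, reps, split_spec(seed = 7))
  expect_identical(a, b)
  c <- split_indices(labels, reps, split_spec(seed = 8))
  expect_false(identical(a, c))
  expect_length(intersect(reps[a$train], reps[a$test]), 0L)
})

test_that("a single replicate falls back to a stratified split with a warning", {
  labels <- rep(c("a", "b"), each = 20L)
  reps <- rep("only", 40L)
  expect_warning(idx <- split_indices(labels, reps, split_spec(seed = 1)),
                 "one replicate")
  expect_equal(length(idx$test), 8L)
  expect_true(all(table(labels[idx$test]) == 4L))
})

test_that("split_dataset partitions a traceset without loss", {
  ts <- demo_small()$norm
  parts <- split_dataset(ts, split_spec(seed = 2))
  expect_equal(n_traces(parts$train) + n_traces(parts$test), n_traces(ts))
  expect_length(intersect(parts$train$meta$trace_id,
                          parts$test$meta$trace_id), 0L)
})

test_that("confusion matrices report counts, recall and accuracy correctly", {
  cm <- confusion(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(cm$accuracy, 1.0)
  expect_equal(unname(diag(cm$row_normalized)), rep(1, 3))

  # 2-class hand-built case: TP=3 FN=1 FP=2 TN=4
  true <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "pos", "neg", "pos", "pos", rep("neg", 4))
  cm2 <- confusion(true, pred)
  expect_equal(cm2$accuracy, 0.7)
  expect_equal(cm2$counts["pos", "pos"], 3L)
  expect_equal(cm2$counts["neg", "pos"], 2L)
  expect_equal(sum(cm2$counts), 10L)

  expect_error(confusion(c("a", "b"), c("a", "z"), classes = c("a", "b")),
               "class list")
})

test_that("full rejection yields NaN accuracy with a warning, not a crash", {
  expect_warning(
    cm <- confusion(c("a", "b"), c("a", "b"),
                    accepted = c(FALSE, FALSE), accepted_only = TRUE),
    "rejected")
  expect_true(is.nan(cm$accuracy))
  expect_equal(cm$rejection_rate, 1.0)
  expect_equal(cm$n, 0L)
})
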