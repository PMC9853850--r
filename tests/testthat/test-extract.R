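test_that("spot detection recovers planted molecules to sub-pixel accuracy", {
  mv <- demo_movie()
  spots <- detect_spots(mv$stack, extraction_config())
  truth <- mv$stack$truth
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((spots$x - truth$x[i])^2 + (spots$y - truth$y[i])^2)
    if (length(d) && min(d) <= 1) matched <- matched + 1L
  }
  expect_gte(matched, 19L) # 20 planted
  expect_lte(nrow(spots), nrow(truth) + 2L) # few false positives
})

test_that("a pure-noise movie yields essentially no detections", {
  set.seed(12)
  frames <- array(round(runif(128 * 128 * 10, 0, 100)),
                  dim = c(128L, 128L, 10L))
  stack <- movie_stack(frames)
  cfg <- extraction_config(detection_quantile = 0.999)
  spots <- suppressWarnings(detect_spots(stack, cfg))
  expect_lte(nrow(spots), 2L) # <= ~1 per 10^4 pixels
})

test_that("molecules closer than the separation limit are both discarded", {
  frames <- array(0, dim = c(64L, 64L, 3L))
  g <- function(cx, cy) {
    for (dx in -3:3) for (dy in -3:3) {
      frames[cy + dy, cx + dx, ] <<-
        frames[cy + dy, cx + dx, ] +
        500 * exp(-(dx^2 + dy^2) / (2 * 1.2^2))
    }
  }
  g(20L, 20L); g(24L, 20L) # two resolvable maxima 4 px apart
  g(45L, 45L)              # isolated control
  stack <- movie_stack(round(frames))
  spots <- detect_spots(stack,
                        extraction_config(min_separation = 5,
                                          detection_quantile = 0.9))
  expect_equal(nrow(spots), 1L)
  expect_lt(abs(spots$x - 44) , 2) # only the isolated molecule remains
})

test_that("trace extraction conserves intensity and subtracts background", {
  ts <- traceset(matrix(800, 1L, 10L), labels = "c", frame_time = 0.05)
  cfg <- movie_config(width = 64L, height = 64L,
                      extra_background_offset = 20)
  stack <- render_movie(ts, cfg, rng_seed = 6)
  tr <- extract_trace(stack, c(stack$truth$x, stack$truth$y),
                      extraction_config())
  # ~96% of the PSF mass lies within the r=3 disc
  expect_true(all(abs(tr - 800) / 800 < 0.08))
  empty <- extract_trace(stack, c(50, 10), extraction_config())
  expect_lt(abs(mean(empty)), 3)
})

test_that("spots too close to the field edge are skipped, not crashed", {
  mv <- demo_movie()
  expect_message(
    out <- extract_trace(mv$stack, c(2, 2), extraction_config()),
    "edge")
  expect_null(out)
})

test_that("percentile normalization has the contracted fixed points", {
  x <- c(rep(0, 90), rep(100, 10))
  expect_equal(sort(unique(normalize_trace(x))), c(0, 1))
  set.seed(3)
  y <- rpois(500, 30) + rbinom(500, 1, 0.1) * 250
  ny <- normalize_trace(y)
  expect_gte(min(ny), 0)
  expect_lte(max(ny), 1)
  expect_equal(max(ny), 1)
  # invariance under positive affine transforms of the raw counts
  expect_equal(normalize_trace(3.7 * y + 120), ny)
  # exact idempotence
  expect_identical(normalize_trace(ny), ny)
  expect_error(normalize_trace(rep(5, 100)), "flat")
})

test_that("dynamic-range QC separates noise from blinking traces and partitions the input", {
  set.seed(4)
  noise <- rnorm(400, 25, 5)
  blink <- rpois(400, 25) + rbinom(400, 1, 0.15) * 260
  ts <- traceset(rbind(noise, blink), labels = c("n", "b"),
                 frame_time = 0.05, trace_ids = c("noise1", "blink1"))
  res <- qc_filter(ts, min_dynamic_range = 8)
  expect_identical(res$kept$meta$trace_id, "blink1")
  expect_identical(res$rejected$trace_id, "noise1")
  expect_identical(res$rejected$reason, "low_dynamic_range")
  expect_equal(n_traces(res$kept) + nrow(res$rejected), n_traces(ts))
})

test_that("simulate -> render -> detect -> extract recovers planted molecules end to end", {
  mv <- demo_movie()
  cfg <- extraction_config()
  spots <- detect_spots(mv$stack, cfg)
  ext <- extract_traces(mv$stack, spots, cfg, truth = mv$stack$truth)
  matched_ids <- attr(ext$provenance$matched_truth_id, "ignore") # none
  matched <- !is.na(ext$provenance$matched_truth_id)
  expect_gte(sum(matched), ceiling(0.95 * nrow(mv$stack$truth)))
  cors <- vapply(which(matched), function(j) {
    src <- mv$traces$values[
      match(ext$provenance$matched_truth_id[j],
            mv$traces$meta$trace_id), ]
    stats::cor(ext$values[j, ], src)
  }, numeric(1L))
  expect_true(all(cors >= 0.9))
  # normalization flows through the extracted set
  nts <- normalize_traces(ext)
  expect_true(nts$normalized)
  expect_true(all(nts$values >= 0 & nts$values <= 1))
})
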