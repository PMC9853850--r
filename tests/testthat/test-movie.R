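const_traceset <- function(n_mol, value, n_frames = 20L) {
  traceset(matrix(value, n_mol, n_frames),
           labels = rep("c", n_mol), frame_time = 0.05)
}

test_that("the PSF conserves the photon count of a molecule", {
  ts <- const_traceset(1L, 1000)
  cfg <- movie_config(width = 64L, height = 64L,
                      extra_background_offset = 0)
  stack <- render_movie(ts, cfg, rng_seed = 1)
  sums <- apply(stack$frames, 3L, sum)
  expect_true(all(abs(sums - 1000) / 1000 < 0.01))
})

test_that("an empty field is exactly the background offset", {
  ts <- const_traceset(0L, 0, n_frames = 5L)
  cfg <- movie_config(width = 32L, height = 32L,
                      extra_background_offset = 7)
  stack <- render_movie(ts, cfg, rng_seed = 1)
  expect_true(all(stack$frames == 7))
})

test_that("molecule placement honors the minimum separation", {
  ts <- const_traceset(50L, 100)
  cfg <- movie_config(width = 256L, height = 256L, min_separation = 6)
  stack <- render_movie(ts, cfg, rng_seed = 2)
  d <- as.matrix(dist(cbind(stack$truth$x, stack$truth$y)))
  diag(d) <- Inf
  expect_gte(min(d), 6)
  expect_equal(nrow(stack$truth), 50L)
})

test_that("an overcrowded field is refused with advice", {
  ts <- const_traceset(200L, 10)
  cfg <- movie_config(width = 32L, height = 32L, min_separation = 6)
  expect_error(render_movie(ts, cfg, rng_seed = 1), "larger field")
})

test_that("photon totals decompose into offset plus molecule traces", {
  set.seed(8)
  vals <- matrix(rpois(5 * 10, 200), 5, 10)
  ts <- traceset(vals, labels = rep("c", 5), frame_time = 0.05)
  cfg <- movie_config(width = 96L, height = 96L,
                      extra_background_offset = 3)
  stack <- render_movie(ts, cfg, rng_seed = 3)
  total <- apply(stack$frames, 3L, sum)
  expected <- 3 * 96 * 96 + colSums(vals)
  # PSF truncation (<0.1%) plus integer rounding of every touched pixel
  expect_true(all(abs(total - expected) < 0.01 * colSums(vals) + 250))
})

test_that("16-bit TIFF round trip is bit-identical and carries the truth table", {
  set.seed(9)
  vals <- matrix(rpois(3 * 10, 500), 3, 10)
  ts <- traceset(vals, labels = c("a", "b", "a"), frame_time = 0.05)
  cfg <- movie_config(width = 16L, height = 16L, min_separation = 0,
                      edge_margin = 4, psf_sigma = 0.8)
  stack <- render_movie(ts, cfg, rng_seed = 4)
  path <- tempfile(fileext = ".tif")
  write_movie_tiff(stack, path)
  back <- read_movie_tiff(path)
  expect_identical(dim(back$frames), dim(stack$frames))
  expect_true(all(back$frames == stack$frames))
  truth <- read_truth_table(paste0(path, ".truth.tsv"))
  expect_equal(nrow(truth), 3L)
  expect_equal(names(truth), c("trace_id", "x", "y", "label"))
  unlink(c(path, paste0(path, ".truth.tsv")))
})

test_that("overflow beyond 16 bits and non-TIFF input give clear errors", {
  ts <- const_traceset(1L, 1e6, n_frames = 2L)
  cfg <- movie_config(width = 32L, height = 32L, psf_sigma = 0.4)
  stack <- render_movie(ts, cfg, rng_seed = 5)
  expect_error(write_movie_tiff(stack, tempfile()), "16-bit")
  txt <- tempfile(fileext = ".tif")
  writeLines("not a tiff", txt)
  expect_error(read_movie_tiff(txt), "TIFF")
  unlink(txt)
})
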