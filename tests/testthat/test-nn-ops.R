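# finite-difference gradient check of the full network against the
# analytic backward pass
gradcheck <- function(arch, L, n = 4L, n_per_param = 5L, seed = 42L,
                      tol = 1e-4) {
  set.seed(seed)
  m <- build_model(arch, L, init_seed = seed)
  x <- matrix(runif(n * L), n)
  y <- sample.int(arch$output_classes, n, replace = TRUE)
  mode <- list(training = TRUE, mc_dropout = FALSE)
  loss_of <- function(model) {
    z <- blinkid:::.model_forward(model,
                                  blinkid:::.prep_input(model, x),
                                  mode)$logits
    blinkid:::.softmax_ce(z, y)$loss
  }
  fwd <- blinkid:::.model_forward(m, blinkid:::.prep_input(m, x), mode,
                                  keep_cache = TRUE)
  sc <- blinkid:::.softmax_ce(fwd$logits, y)
  grads <- blinkid:::.model_backward(m, fwd$caches, sc$dlogits)
  eps <- 1e-5
  worst <- 0
  for (i in seq_along(m$layers)) {
    for (nm in names(m$layers[[i]]$params)) {
      p <- m$layers[[i]]$params[[nm]]
      for (j in sample(length(p), min(n_per_param, length(p)))) {
        mp <- m; mp$layers[[i]]$params[[nm]][j] <- p[j] + eps
        mm <- m; mm$layers[[i]]$params[[nm]][j] <- p[j] - eps
        num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
        ana <- grads[[i]][[nm]][j]
        worst <- max(worst,
                     abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
      }
    }
  }
  worst
}

test_that("analytic gradients match finite differences through the CNN-GRU stack", {
  arch <- architecture_config(
    conv_blocks = list(c(4L, 3L, 2L)), conv_dropout = 0,
    use_batch_norm = TRUE, gru_layers = 2L, gru_units = 5L,
    dense_units = 6L, output_classes = 3L, head_dropout = 0)
  expect_lt(gradcheck(arch, 16L), 1e-4)
})

test_that("analytic gradients match finite differences through the CNN-only stack", {
  arch <- architecture_config(
    conv_blocks = list(c(4L, 3L, 2L), c(6L, 3L, 2L)), conv_dropout = 0,
    use_batch_norm = TRUE, gru_layers = 0L, dense_units = 6L,
    output_classes = 3L, head_dropout = 0)
  expect_lt(gradcheck(arch, 20L), 1e-4)
})

test_that("the model emits probability simplices of the right width", {
  arch <- architecture_config(output_classes = 4L)
  m <- build_model(arch, 200L, init_seed = 1)
  set.seed(2)
  p <- predict_probs(m, matrix(runif(6 * 200), 6))
  expect_equal(dim(p), c(6L, 4L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
})

test_that("the deterministic forward pass is reproducible", {
  arch <- architecture_config(output_classes = 3L)
  m <- build_model(arch, 100L, init_seed = 5)
  x <- matrix(runif(4 * 100), 4)
  expect_equal(predict_probs(m, x), predict_probs(m, x),
               tolerance = 1e-12)
})

test_that("trace lengths are right-padded to the pooling granularity", {
  arch <- architecture_config(output_classes = 2L) # pool product 64
  m1 <- build_model(arch, 2000L)
  expect_equal(m1$padded_length, 2048L)
  m2 <- build_model(arch, 2048L)
  expect_equal(m2$padded_length, 2048L)
  expect_gt(m1$n_params, 1e4)
})

test_that("invalid architectures are rejected with the field named", {
  expect_error(architecture_config(conv_blocks = list()), "conv_blocks")
  expect_error(architecture_config(conv_blocks = list(c(8L, 4L, 2L))),
               "conv_blocks") # even kernel
  expect_error(architecture_config(conv_dropout = 1), "conv_dropout")
  expect_error(architecture_config(output_classes = 1L),
               "output_classes")
})

test_that("predictive entropy has the contracted fixed points", {
  expect_equal(predictive_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(predictive_entropy(rep(0.25, 4)), log(4))
  p <- matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE)
  expect_equal(predictive_entropy(p), c(0, log(2)))
})
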