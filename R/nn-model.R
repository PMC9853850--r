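#' Architecture configuration for the 1D-CNN-GRU classifier
#'
#' The network consumes normalized intensity traces directly: a stack of
#' one-dimensional convolutional blocks (convolution, batch normalization,
#' ReLU, max pooling, dropout) downsamples the trace and extracts local
#' blinking features; GRU layers then integrate information along the time
#' axis, retaining context over the entire acquisition; fully connected
#' layers with a softmax head produce the class probabilities.
#'
#' Setting `gru_layers = 0` builds the purely convolutional ablation
#' variant — the conv feature map is flattened and fed directly into the
#' fully connected head instead of the recurrence — used to demonstrate
#' the value of the recurrent layers.
#'
#' @param conv_blocks List of integer triples
#'   `(n_filters, kernel_size, pool_factor)`, one per block (>= 1 block;
#'   odd kernels).
#' @param conv_dropout Dropout probability inside conv blocks, in [0, 1).
#' @param use_batch_norm Insert batch normalization after each
#'   convolution?
#' @param gru_layers Number of GRU layers (0 = CNN-only ablation).
#' @param gru_units Hidden units per GRU layer.
#' @param dense_units Units of the fully connected layer before the
#'   softmax.
#' @param output_classes Number of classes (>= 2).
#' @param head_dropout Dropout probability in the dense head, in [0, 1).
#' @return An object of class `architecture_config`.
#' @export
architecture_config <- function(conv_blocks = list(c(32L, 9L, 4L),
                                                   c(64L, 9L, 4L),
                                                   c(64L, 9L, 4L)),
                                conv_dropout = 0.3, use_batch_norm = TRUE,
                                gru_layers = 2L, gru_units = 64L,
                                dense_units = 64L, output_classes = 4L,
                                head_dropout = 0.3) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid ArchitectureConfig field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.list(conv_blocks) || length(conv_blocks) < 1L ||
      !all(vapply(conv_blocks, length, integer(1L)) == 3L)) {
    stop_field("conv_blocks", "need >= 1 (filters, kernel, pool) triple")
  }
  for (b in conv_blocks) {
    if (any(b < 1) || b[2L] %% 2L != 1L) {
      stop_field("conv_blocks",
                 "filters/kernel/pool must be positive; kernels odd")
    }
  }
  if (conv_dropout < 0 || conv_dropout >= 1) {
    stop_field("conv_dropout", "must be in [0, 1)")
  }
  if (head_dropout < 0 || head_dropout >= 1) {
    stop_field("head_dropout", "must be in [0, 1)")
  }
  if (gru_layers < 0) stop_field("gru_layers", "must be >= 0")
  if (gru_layers > 0 && gru_units < 1) {
    stop_field("gru_units", "must be >= 1")
  }
  if (dense_units < 1) stop_field("dense_units", "must be >= 1")
  if (output_classes < 2) stop_field("output_classes", "must be >= 2")
  structure(
    list(conv_blocks = lapply(conv_blocks, as.integer),
         conv_dropout = conv_dropout, use_batch_norm = use_batch_norm,
         gru_layers = as.integer(gru_layers),
         gru_units = as.integer(gru_units),
         dense_units = as.integer(dense_units),
         output_classes = as.integer(output_classes),
         head_dropout = head_dropout),
    class = "architecture_config")
}

#' Build a 1D-CNN-GRU model
#'
#' Instantiates the layer stack of an [architecture_config()] for traces
#' of a given length, with seeded Glorot-uniform weight initialization.
#' Trace lengths that are not divisible by the product of pool factors are
#' right-padded with zeros; the padded length is recorded in the model
#' metadata.
#'
#' @param arch An [architecture_config()].
#' @param trace_length Input trace length in frames.
#' @param init_seed Integer seed for weight initialization.
#' @return An object of class `cnn_gru_model`; its `n_params` field
#'   reports the trainable parameter count.
#' @export
build_model <- function(arch, trace_length, init_seed = 1L) {
  stopifnot(inherits(arch, "architecture_config"), trace_length >= 1)
  set.seed(as.integer(init_seed))
  pool_prod <- prod(vapply(arch$conv_blocks, `[`, integer(1L), 3L))
  padded <- as.integer(ceiling(trace_length / pool_prod) * pool_prod)

  layers <- list()
  c_in <- 1L
  for (b in arch$conv_blocks) {
    layers <- c(layers, list(.layer_conv(c_in, b[1L], b[2L])))
    if (arch$use_batch_norm) layers <- c(layers, list(.layer_bn(b[1L])))
    layers <- c(layers, list(.layer_relu(b[1L])),
                list(.layer_pool(b[1L], b[3L])))
    if (arch$conv_dropout > 0) {
      layers <- c(layers, list(.layer_dropout(b[1L], arch$conv_dropout)))
    }
    c_in <- b[1L]
  }
  if (arch$gru_layers > 0L) {
    for (g in seq_len(arch$gru_layers)) {
      layers <- c(layers, list(
        .layer_gru(c_in, arch$gru_units,
                   return_seq = g < arch$gru_layers)))
      c_in <- arch$gru_units
    }
  } else {
    # purely convolutional ablation: the conv feature map is flattened
    # and fed directly into the fully connected head
    t_out <- padded %/% pool_prod
    layers <- c(layers, list(.layer_flatten(t_out * c_in)))
    c_in <- t_out * c_in
  }
  if (arch$head_dropout > 0) {
    layers <- c(layers, list(.layer_dropout(c_in, arch$head_dropout)))
  }
  layers <- c(layers, list(.layer_dense(c_in, arch$dense_units, "relu")))
  if (arch$head_dropout > 0) {
    layers <- c(layers,
                list(.layer_dropout(arch$dense_units, arch$head_dropout)))
  }
  layers <- c(layers,
              list(.layer_dense(arch$dense_units, arch$output_classes,
                                "linear")))

  n_params <- sum(vapply(layers, function(l) {
    sum(vapply(l$params, length, integer(1L)))
  }, integer(1L)))
  structure(
    list(arch = arch, trace_length = as.integer(trace_length),
         padded_length = padded, layers = layers, n_params = n_params,
         class_levels = NULL, trained = FALSE),
    class = "cnn_gru_model")
}

#' @export
print.cnn_gru_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_gru_model> input %d frames (padded to %d), %d classes, %s\n",
    x$trace_length, x$padded_length, x$arch$output_classes,
    if (x$trained) "trained" else "untrained"))
  cat(sprintf("  %d layers, %d trainable parameters\n",
              length(x$layers), x$n_params))
  invisible(x)
}

# traces (n x L matrix) -> input array (padded_length, n, 1)
.prep_input <- function(model, x) {
  n <- nrow(x)
  a <- array(0, dim = c(model$padded_length, n, 1L))
  a[seq_len(ncol(x)), , 1L] <- t(x)
  a
}

# full forward pass; returns logits plus per-layer caches (when
# keep_cache) and updated batch-norm running state (training mode)
.model_forward <- function(model, a, mode, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    res <- switch(l$type,
                  conv = .fwd_conv(l, a),
                  bn = .fwd_bn(l, a, mode),
                  relu = .fwd_relu(l, a),
                  pool = .fwd_pool(l, a),
                  dropout = .fwd_dropout(l, a, mode),
                  gru = .fwd_gru(l, a),
                  gap = .fwd_gap(l, a),
                  flatten = .fwd_flatten(l, a),
                  dense = .fwd_dense(l, a))
    a <- res$out
    if (keep_cache) caches[[i]] <- res$cache
    if (!is.null(res$state)) model$layers[[i]]$state <- res$state
  }
  list(logits = a, caches = caches, model = model)
}

# backward pass; returns per-layer gradient lists aligned with layers
.model_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  d <- dlogits
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    res <- switch(l$type,
                  conv = .bwd_conv(l, caches[[i]], d),
                  bn = .bwd_bn(l, caches[[i]], d),
                  relu = .bwd_relu(l, caches[[i]], d),
                  pool = .bwd_pool(l, caches[[i]], d),
                  dropout = .bwd_dropout(l, caches[[i]], d),
                  gru = .bwd_gru(l, caches[[i]], d),
                  gap = .bwd_gap(l, caches[[i]], d),
                  flatten = .bwd_flatten(l, caches[[i]], d),
                  dense = .bwd_dense(l, caches[[i]], d))
    d <- res$dinput
    grads[[i]] <- res$grads
  }
  grads
}

# Re-estimate the batch-normalization statistics with dropout disabled.
# Running statistics accumulated during training are collected under
# dropout noise and therefore overestimate the variance the network sees
# at inference; a few dropout-free passes over training traces, averaging
# the batch statistics, restore the match between training-mode and
# inference-mode behaviour.
.recalibrate_bn <- function(model, x, batch_size = 128L,
                            max_traces = 512L) {
  bn_idx <- which(vapply(model$layers, function(l) l$type == "bn",
                         logical(1L)))
  if (length(bn_idx) == 0L) return(model)
  n <- min(nrow(x), max_traces)
  # evenly spaced subsample: training sets are often ordered by class, so
  # the statistics must be estimated across the whole set, not its head
  sel <- unique(round(seq(1L, nrow(x), length.out = n)))
  # interleave so every collection batch spans the whole set too
  nb <- ceiling(length(sel) / batch_size)
  if (nb > 1L) {
    sel <- unlist(lapply(seq_len(nb), function(k) {
      sel[seq(k, length(sel), by = nb)]
    }), use.names = FALSE)
  }
  mode <- list(training = TRUE, mc_dropout = FALSE, no_dropout = TRUE)
  saved_mom <- vapply(model$layers[bn_idx], `[[`, numeric(1L), "momentum")
  b <- 0L
  for (start in seq(1L, length(sel), by = batch_size)) {
    b <- b + 1L
    for (j in bn_idx) model$layers[[j]]$momentum <- (b - 1) / b
    i <- sel[start:min(length(sel), start + batch_size - 1L)]
    model <- .model_forward(model,
                            .prep_input(model, x[i, , drop = FALSE]),
                            mode)$model
  }
  for (k in seq_along(bn_idx)) {
    model$layers[[bn_idx[k]]]$momentum <- saved_mom[k]
  }
  model
}

# ---- Adam optimizer -----------------------------------------------------

.adam_init <- function(model) {
  lapply(model$layers, function(l) {
    lapply(l$params, function(p) {
      list(m = array(0, dim = dim(p) %||% length(p)),
           v = array(0, dim = dim(p) %||% length(p)))
    })
  })
}

.adam_step <- function(model, grads, state, lr, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (length(g) == 0L) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      state[[i]][[nm]] <- st
      upd <- (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      model$layers[[i]]$params[[nm]] <-
        model$layers[[i]]$params[[nm]] - lr * array(upd, dim = dim(upd))
    }
  }
  list(model = model, state = state)
}

#' Class probabilities for a batch of traces
#'
#' Deterministic forward pass (dropout off, batch normalization at its
#' running statistics).
#'
#' @param model A trained [build_model()] object.
#' @param traces A normalized [traceset()] or a numeric matrix with one
#'   trace per row.
#' @param batch_size Mini-batch size of the forward pass.
#' @return Matrix of per-class probabilities (rows sum to 1); column
#'   names are the model's class levels when known.
#' @export
predict_probs <- function(model, traces, batch_size = 128L) {
  x <- if (inherits(traces, "traceset")) traces$values else traces
  n <- nrow(x)
  k <- model$arch$output_classes
  probs <- matrix(0, n, k)
  mode <- list(training = FALSE, mc_dropout = FALSE)
  for (start in seq(1L, n, by = batch_size)) {
    i <- start:min(n, start + batch_size - 1L)
    a <- .prep_input(model, x[i, , drop = FALSE])
    probs[i, ] <- .softmax(.model_forward(model, a, mode)$logits)
  }
  if (!is.null(model$class_levels)) colnames(probs) <- model$class_levels
  probs
}

#' @rdname predict_probs
#' @return `predict_classes()` returns a character vector of predicted
#'   labels (or column indices as characters for untrained class levels).
#' @export
predict_classes <- function(model, traces, batch_size = 128L) {
  p <- predict_probs(model, traces, batch_size)
  j <- max.col(p, ties.method = "first")
  if (!is.null(model$class_levels)) model$class_levels[j]
  else as.character(j)
}

#' Predictive entropy of a probability vector or matrix
#'
#' Shannon entropy in nats; for a K-class problem it lies in
#' `[0, log(K)]`, attaining 0 on a point mass and `log(K)` on the uniform
#' distribution.
#'
#' @param p Probability vector, or matrix with one distribution per row.
#' @return Numeric entropy (vector for matrix input).
#' @export
predictive_entropy <- function(p) {
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  if (is.matrix(p)) apply(p, 1L, ent) else ent(p)
}
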