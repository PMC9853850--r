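#' Training configuration for the deep classifier
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param max_epochs Maximum number of epochs (>= 1).
#' @param early_stop_patience Stop after this many epochs without
#'   validation-loss improvement; the best-validation weights are kept.
#' @param validation_fraction Fraction of the training traces held out
#'   for validation, in (0, 1).
#' @param lr_decay_factor Multiplicative learning-rate decay (1 = no
#'   decay), applied every `lr_decay_every` epochs.
#' @param lr_decay_every Epoch interval of the step decay.
#' @param seed Integer seed governing initialization order, shuffling and
#'   dropout; identical seed and data give identical training runs.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 30L, early_stop_patience = 5L,
                         validation_fraction = 0.15,
                         lr_decay_factor = 1, lr_decay_every = 8L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            early_stop_patience >= 1, lr_decay_factor > 0,
            lr_decay_factor <= 1, lr_decay_every >= 1)
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

# evaluate loss/accuracy in deterministic mode
.eval_model <- function(model, x, y, batch_size = 128L) {
  n <- nrow(x)
  mode <- list(training = FALSE, mc_dropout = FALSE)
  loss <- 0; correct <- 0
  for (start in seq(1L, n, by = batch_size)) {
    i <- start:min(n, start + batch_size - 1L)
    a <- .prep_input(model, x[i, , drop = FALSE])
    z <- .model_forward(model, a, mode)$logits
    sc <- .softmax_ce(z, y[i])
    loss <- loss + sc$loss * length(i)
    correct <- correct + sum(max.col(sc$probs, ties.method = "first") ==
                               y[i])
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train the deep classifier on normalized traces
#'
#' Mini-batch gradient optimization (Adam) of the cross-entropy loss,
#' with a seeded stratified validation split carved from the training set
#' and early stopping on the validation loss. The network sees only
#' normalized traces; raw input is refused.
#'
#' @param model A [build_model()] object.
#' @param train_set A normalized [traceset()] whose labels cover exactly
#'   the model's `output_classes` classes.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress?
#' @return List with `model` (weights of the best validation epoch,
#'   class levels attached) and `history` (data.frame of per-epoch train
#'   and validation loss/accuracy).
#' @export
train_model <- function(model, train_set, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "cnn_gru_model"),
            inherits(train_set, "traceset"))
  if (!train_set$normalized) {
    stop("the classifier is trained on normalized traces only; ",
         "call normalize_traces() first", call. = FALSE)
  }
  classes <- sort(unique(train_set$meta$label))
  if (length(classes) != model$arch$output_classes) {
    stop(sprintf("model expects %d classes but training set has %d",
                 model$arch$output_classes, length(classes)),
         call. = FALSE)
  }
  x <- train_set$values
  y <- match(train_set$meta$label, classes)
  set.seed(config$seed)

  # stratified validation split
  val_idx <- integer(0)
  for (cl in seq_along(classes)) {
    i_cl <- which(y == cl)
    k <- max(1L, round(config$validation_fraction * length(i_cl)))
    val_idx <- c(val_idx, i_cl[sample.int(length(i_cl), k)])
  }
  tr_idx <- setdiff(seq_len(nrow(x)), val_idx)
  xtr <- x[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  xval <- x[val_idx, , drop = FALSE]; yval <- y[val_idx]

  adam <- .adam_init(model)
  step <- 0L
  best_val <- Inf
  best_layers <- model$layers
  patience_left <- config$early_stop_patience
  hist <- data.frame()
  mode_train <- list(training = TRUE, mc_dropout = FALSE)

  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$learning_rate *
      config$lr_decay_factor^((epoch - 1L) %/% config$lr_decay_every)
    ord <- sample(length(ytr))
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      i <- ord[start:min(length(ord), start + config$batch_size - 1L)]
      a <- .prep_input(model, xtr[i, , drop = FALSE])
      fwd <- .model_forward(model, a, mode_train, keep_cache = TRUE)
      model <- fwd$model # batch-norm running stats
      sc <- .softmax_ce(fwd$logits, ytr[i])
      grads <- .model_backward(model, fwd$caches, sc$dlogits)
      step <- step + 1L
      res <- .adam_step(model, grads, adam, lr, step)
      model <- res$model; adam <- res$state
      ep_loss <- ep_loss + sc$loss * length(i)
      ep_correct <- ep_correct +
        sum(max.col(sc$probs, ties.method = "first") == ytr[i])
    }
    model <- .recalibrate_bn(model, xtr)
    val <- .eval_model(model, xval, yval)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = ep_loss / length(ytr),
      train_acc = ep_correct / length(ytr),
      val_loss = unname(val["loss"]), val_acc = unname(val["acc"])))
    if (verbose) {
      message(sprintf(
        "epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
        epoch, ep_loss / length(ytr), ep_correct / length(ytr),
        val["loss"], val["acc"]))
    }
    if (val["loss"] < best_val - 1e-6) {
      best_val <- val["loss"]
      best_layers <- model$layers
      patience_left <- config$early_stop_patience
    } else {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) break
    }
  }
  model$layers <- best_layers
  model$class_levels <- classes
  model$trained <- TRUE
  list(model = model, history = hist)
}

#' Monte Carlo dropout prediction with uncertainty filtering
#'
#' Runs `T` stochastic forward passes with dropout active at inference
#' (batch normalization stays at its running statistics), averages the
#' softmax outputs, and scores each trace by the predictive entropy of
#' the averaged distribution. Traces whose entropy exceeds the threshold
#' are flagged as rejected — the mechanism used to filter out low-quality
#' traces whose classification is uncertain.
#'
#' @param model A trained model.
#' @param traces A normalized [traceset()] or numeric trace matrix.
#' @param T Number of stochastic passes (>= 2).
#' @param entropy_threshold Acceptance threshold in nats; defaults to
#'   `0.5 * log(n_classes)`.
#' @param seed Integer seed for the dropout masks.
#' @param batch_size Forward-pass batch size.
#' @return data.frame with `trace_id`, `predicted_class`, one `p_<class>`
#'   column per class (the MC-mean probabilities), `uncertainty` (nats)
#'   and `accepted`; the mean-probability matrix is attached as attribute
#'   `"mean_probs"`.
#' @export
mc_predict <- function(model, traces, T = 50L, entropy_threshold = NULL,
                       seed = 1L, batch_size = 128L) {
  if (T < 2L) stop("T must be >= 2 for Monte Carlo dropout", call. = FALSE)
  stopifnot(isTRUE(model$trained))
  x <- if (inherits(traces, "traceset")) traces$values else traces
  ids <- if (inherits(traces, "traceset")) traces$meta$trace_id
         else sprintf("t%05d", seq_len(nrow(x)))
  k <- model$arch$output_classes
  if (is.null(entropy_threshold)) entropy_threshold <- 0.5 * log(k)
  set.seed(as.integer(seed))
  n <- nrow(x)
  acc_probs <- matrix(0, n, k)
  mode <- list(training = FALSE, mc_dropout = TRUE)
  for (pass in seq_len(T)) {
    for (start in seq(1L, n, by = batch_size)) {
      i <- start:min(n, start + batch_size - 1L)
      a <- .prep_input(model, x[i, , drop = FALSE])
      acc_probs[i, ] <- acc_probs[i, ] +
        .softmax(.model_forward(model, a, mode)$logits)
    }
  }
  mean_probs <- acc_probs / T
  unc <- predictive_entropy(mean_probs)
  j <- max.col(mean_probs, ties.method = "first")
  lev <- model$class_levels %||% as.character(seq_len(k))
  out <- data.frame(trace_id = ids, predicted_class = lev[j],
                    stringsAsFactors = FALSE)
  pm <- as.data.frame(mean_probs)
  names(pm) <- paste0("p_", lev)
  out <- cbind(out, pm)
  out$uncertainty <- unc
  out$accepted <- unc <= entropy_threshold
  attr(out, "mean_probs") <- mean_probs
  attr(out, "entropy_threshold") <- entropy_threshold
  out
}

# grouped, class-stratified k-fold assignment; falls back to stratified
# folds with a warning when there are fewer replicates than folds
.make_folds <- function(labels, replicates, k, seed) {
  set.seed(as.integer(seed))
  n <- length(labels)
  fold <- integer(n)
  reps <- unique(replicates)
  if (length(reps) < k) {
    warning("fewer replicates than folds; using stratified (ungrouped) ",
            "folds")
    for (cl in unique(labels)) {
      i_cl <- which(labels == cl)
      fold[i_cl] <- sample(rep_len(seq_len(k), length(i_cl)))
    }
    return(fold)
  }
  class_of_rep <- tapply(labels, replicates, function(l) l[1L])
  for (cl in unique(labels)) {
    reps_cl <- names(class_of_rep)[class_of_rep == cl]
    assign <- sample(rep_len(seq_len(k), length(reps_cl)))
    for (j in seq_along(reps_cl)) {
      fold[replicates == reps_cl[j]] <- assign[j]
    }
  }
  fold
}

#' Nested cross-validation of the deep classifier
#'
#' Outer folds (stratified by class and grouped by replicate) estimate
#' generalization; for each outer fold an inner cross-validation over a
#' small hyperparameter grid (learning rate x dropout) selects the
#' configuration, which is then retrained on the full outer-training
#' portion and evaluated once on the held-out fold. This keeps the
#' hyperparameter selection from biasing the reported accuracy.
#'
#' @param ts A normalized [traceset()].
#' @param k_outer,k_inner Numbers of outer/inner folds.
#' @param grid data.frame with columns `learning_rate` and `dropout`.
#' @param arch Base [architecture_config()] (its dropout fields are
#'   overridden by the grid).
#' @param config Base [train_config()] (its learning rate is overridden
#'   by the grid).
#' @param seed Integer seed.
#' @return List with `fold_accuracy` (numeric, one per outer fold),
#'   `selected` (data.frame of the winning grid row per fold), `mean`
#'   and `sd`.
#' @export
nested_cross_validate <- function(ts, k_outer = 5L, k_inner = 3L,
                                  grid = expand.grid(
                                    learning_rate = c(1e-3, 3e-4),
                                    dropout = c(0.2, 0.4)),
                                  arch = NULL, config = train_config(),
                                  seed = 1L) {
  stopifnot(inherits(ts, "traceset"), ts$normalized)
  labels <- ts$meta$label
  classes <- sort(unique(labels))
  if (is.null(arch)) {
    arch <- architecture_config(output_classes = length(classes))
  }
  outer_fold <- .make_folds(labels, ts$meta$replicate_id, k_outer, seed)

  run_one <- function(train_ts, lr, drop, train_seed) {
    a <- arch
    a$conv_dropout <- drop
    a$head_dropout <- drop
    cfg <- config
    cfg$learning_rate <- lr
    cfg$seed <- train_seed
    m <- build_model(a, train_ts$n_frames, init_seed = train_seed)
    train_model(m, train_ts, cfg)$model
  }

  fold_acc <- numeric(k_outer)
  selected <- grid[0, , drop = FALSE]
  for (fo in seq_len(k_outer)) {
    tr_ts <- ts[which(outer_fold != fo)]
    te_ts <- ts[which(outer_fold == fo)]
    inner_fold <- .make_folds(tr_ts$meta$label, tr_ts$meta$replicate_id,
                              k_inner, seed + fo)
    grid_score <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      accs <- numeric(k_inner)
      for (fi in seq_len(k_inner)) {
        itr <- tr_ts[which(inner_fold != fi)]
        ite <- tr_ts[which(inner_fold == fi)]
        m <- run_one(itr, grid$learning_rate[gi], grid$dropout[gi],
                     seed + 100L * fo + fi)
        pred <- predict_classes(m, ite)
        accs[fi] <- mean(pred == ite$meta$label)
      }
      grid_score[gi] <- mean(accs)
    }
    best <- which.max(grid_score)
    selected <- rbind(selected, grid[best, , drop = FALSE])
    m <- run_one(tr_ts, grid$learning_rate[best], grid$dropout[best],
                 seed + fo)
    pred <- predict_classes(m, te_ts)
    fold_acc[fo] <- mean(pred == te_ts$meta$label)
  }
  list(fold_accuracy = fold_acc, selected = selected,
       mean = mean(fold_acc), sd = stats::sd(fold_acc),
       outer_fold = outer_fold)
}

#' Scrambled-label control experiment
#'
#' Permutes the class labels of the training portion uniformly at random
#' (test labels stay intact), trains the deep classifier, and reports the
#' test accuracy — expected at chance, demonstrating that the model
#' cannot learn from label-free structure.
#'
#' @param ts A normalized, labelled [traceset()].
#' @param seed Integer seed (permutation, split and training).
#' @param arch Optional [architecture_config()].
#' @param config A [train_config()].
#' @param split A [split_spec()].
#' @return List with `accuracy`, `confusion`, `n_test`, `history`.
#' @export
control_scrambled_labels <- function(ts, seed = 1L, arch = NULL,
                                     config = train_config(),
                                     split = split_spec(seed = seed)) {
  stopifnot(inherits(ts, "traceset"), ts$normalized)
  classes <- sort(unique(ts$meta$label))
  if (is.null(arch)) {
    arch <- architecture_config(output_classes = length(classes))
  }
  parts <- split_dataset(ts, split)
  set.seed(as.integer(seed))
  scr <- parts$train
  scr$meta$label <- sample(scr$meta$label)
  cfg <- config
  cfg$seed <- seed
  m <- build_model(arch, ts$n_frames, init_seed = seed)
  fit <- train_model(m, scr, cfg)
  pred <- predict_classes(fit$model, parts$test)
  cm <- confusion(parts$test$meta$label, pred, classes = classes)
  list(accuracy = cm$accuracy, confusion = cm,
       n_test = n_traces(parts$test), history = fit$history)
}

#' Noise-training control experiment
#'
#' Trains the deep classifier on traces harvested from regions that
#' contain no molecule, randomly assigned to fake classes, and reports
#' the (chance-level) test accuracy together with the Monte Carlo dropout
#' uncertainty distribution on the test portion — which is expected to be
#' high, since noise supports no confident prediction.
#'
#' @param noise_ts A raw or normalized [traceset()] of noise traces (see
#'   [extract_noise_traces()]).
#' @param n_classes Number of fake classes to assign.
#' @param seed Integer seed.
#' @param arch Optional [architecture_config()].
#' @param config A [train_config()].
#' @param T Monte Carlo dropout passes for the uncertainty summary.
#' @return List with `accuracy`, `uncertainty` (numeric vector),
#'   `uncertainty_median`, `confusion`, `predictions`.
#' @export
control_noise_training <- function(noise_ts, n_classes = 4L, seed = 1L,
                                   arch = NULL, config = train_config(),
                                   T = 25L) {
  stopifnot(inherits(noise_ts, "traceset"))
  if (!noise_ts$normalized) noise_ts <- normalize_traces(noise_ts)
  set.seed(as.integer(seed))
  fake <- sprintf("fake%d", sample(rep_len(seq_len(n_classes),
                                           n_traces(noise_ts))))
  noise_ts$meta$label <- fake
  noise_ts$meta$replicate_id <-
    sprintf("%s_r%d", fake, sample(2L, n_traces(noise_ts), replace = TRUE))
  noise_ts$classes <- sort(unique(fake))
  if (is.null(arch)) {
    arch <- architecture_config(output_classes = n_classes)
  }
  parts <- split_dataset(noise_ts, split_spec(seed = seed))
  cfg <- config
  cfg$seed <- seed
  m <- build_model(arch, noise_ts$n_frames, init_seed = seed)
  fit <- train_model(m, parts$train, cfg)
  preds <- mc_predict(fit$model, parts$test, T = T, seed = seed)
  cm <- confusion(parts$test$meta$label, preds$predicted_class,
                  classes = sort(unique(fake)))
  list(accuracy = cm$accuracy, uncertainty = preds$uncertainty,
       uncertainty_median = stats::median(preds$uncertainty),
       confusion = cm, predictions = preds)
}
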