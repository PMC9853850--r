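#' Train classical supervised baselines on blinking features
#'
#' Fits four classical classifier families on the hand-crafted blinking
#' descriptors — a random-forest tree ensemble (`ranger`), an RBF-kernel
#' support vector machine (`e1071`), k-nearest neighbours (`class`), and a
#' multinomial ridge regression (`glmnet`) — on a replicate-aware
#' train/test split, and reports the per-model confusion matrix and test
#' accuracy. Features are standardized with training-set statistics before
#' fitting the SVM, kNN and ridge models.
#'
#' @param ft A [feature_table()] (columns `trace_id`, `label`,
#'   `replicate_id`, then features).
#' @param split A [split_spec()] controlling the train/test partition.
#' @param seed Integer seed for the model fits.
#' @param models Character subset of
#'   `c("random_forest", "svm_rbf", "knn", "multinomial_ridge")`.
#' @param knn_k Neighbourhood size for kNN.
#' @return List with one element per model (each a list with `confusion`,
#'   `accuracy`, `predicted`), plus `split` (the index partition used).
#' @export
train_baselines <- function(ft, split = split_spec(), seed = 1L,
                            models = c("random_forest", "svm_rbf", "knn",
                                       "multinomial_ridge"),
                            knn_k = 5L) {
  models <- match.arg(models, several.ok = TRUE)
  labels <- ft$label
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  idx <- split_indices(labels, ft$replicate_id, split)
  if (!all(classes %in% labels[idx$train])) {
    stop("a class is absent from the training fold; ",
         "adjust the split or provide more data", call. = FALSE)
  }
  cols <- .feature_columns(ft)
  x <- as.matrix(ft[, cols, drop = FALSE])
  xtr <- x[idx$train, , drop = FALSE]
  xte <- x[idx$test, , drop = FALSE]
  ytr <- factor(labels[idx$train], levels = classes)
  yte <- labels[idx$test]

  # standardize with training statistics; guard constant features
  mu <- colMeans(xtr)
  sds <- apply(xtr, 2L, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  ztr <- sweep(sweep(xtr, 2L, mu), 2L, sds, "/")
  zte <- sweep(sweep(xte, 2L, mu), 2L, sds, "/")

  out <- list()
  for (m in models) {
    set.seed(seed)
    pred <- switch(
      m,
      random_forest = {
        fit <- ranger::ranger(x = xtr, y = ytr, num.trees = 300L,
                              seed = seed)
        as.character(stats::predict(fit, data = xte)$predictions)
      },
      svm_rbf = {
        fit <- e1071::svm(x = ztr, y = ytr, kernel = "radial")
        as.character(stats::predict(fit, zte))
      },
      knn = {
        as.character(class::knn(ztr, zte, cl = ytr, k = knn_k))
      },
      multinomial_ridge = {
        fit <- glmnet::glmnet(ztr, ytr, family = "multinomial", alpha = 0,
                              lambda = 0.01)
        drop(stats::predict(fit, zte, type = "class"))
      })
    cm <- confusion(yte, pred, classes = classes)
    out[[m]] <- list(confusion = cm, accuracy = cm$accuracy,
                     predicted = pred)
  }
  out$split <- idx
  out
}
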