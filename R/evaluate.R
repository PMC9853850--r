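#' Train/test split specification
#'
#' Default is the 80/20 split with class stratification and replicate
#' grouping: no replicate (coverslip/day batch) ever spans both sides of
#' the split, which prevents batch effects from leaking between training
#' and evaluation.
#'
#' @param test_fraction Fraction of traces in the test set, in (0, 1).
#' @param stratify_by_class Keep per-class proportions close to the
#'   overall split?
#' @param group_by_replicate Keep each replicate wholly on one side?
#' @param seed Integer seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, stratify_by_class = TRUE,
                       group_by_replicate = TRUE, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(test_fraction = test_fraction,
                 stratify_by_class = stratify_by_class,
                 group_by_replicate = group_by_replicate,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Compute train/test indices for labelled, replicated traces
#'
#' With grouping, whole replicates are dealt to the test side (per class
#' when replicates are class-pure, globally otherwise) until the test
#' fraction is best approximated; with a single replicate, grouping is
#' impossible and the splitter falls back to a stratified split with a
#' warning.
#'
#' @param labels Character vector of class labels.
#' @param replicates Character vector of replicate ids (same length).
#' @param spec A [split_spec()].
#' @return List with integer index vectors `train` and `test` forming a
#'   disjoint partition of `seq_along(labels)`.
#' @export
split_indices <- function(labels, replicates, spec = split_spec()) {
  n <- length(labels)
  stopifnot(length(replicates) == n)
  set.seed(spec$seed)
  test <- integer(0)

  grouping <- spec$group_by_replicate
  if (grouping && length(unique(replicates)) < 2L) {
    warning("only one replicate present; falling back to a stratified ",
            "(ungrouped) split")
    grouping <- FALSE
  }

  pick_groups <- function(groups, sizes, target) {
    # seeded greedy: shuffle groups, take while below target, then decide
    # whether the next group brings the total closer
    ord <- sample(seq_along(groups))
    cum <- 0; chosen <- character(0)
    for (g in ord) {
      if (cum >= target) break
      if (abs(cum + sizes[g] - target) <= abs(cum - target)) {
        chosen <- c(chosen, groups[g])
        cum <- cum + sizes[g]
      }
    }
    chosen
  }

  if (grouping) {
    class_of_rep <- tapply(labels, replicates, function(l) {
      if (length(unique(l)) == 1L) unique(l) else NA_character_
    })
    class_pure <- spec$stratify_by_class && !anyNA(class_of_rep)
    if (class_pure) {
      for (cl in unique(labels)) {
        reps_cl <- names(class_of_rep)[class_of_rep == cl]
        sizes <- vapply(reps_cl, function(r) sum(replicates == r),
                        integer(1L))
        target <- spec$test_fraction * sum(labels == cl)
        chosen <- pick_groups(reps_cl, sizes, target)
        test <- c(test, which(replicates %in% chosen))
      }
    } else {
      reps <- unique(replicates)
      sizes <- vapply(reps, function(r) sum(replicates == r), integer(1L))
      chosen <- pick_groups(reps, sizes, spec$test_fraction * n)
      test <- which(replicates %in% chosen)
      if (spec$stratify_by_class) {
        message("replicates span multiple classes; grouped split is not ",
                "exactly stratified")
      }
    }
  } else if (spec$stratify_by_class) {
    for (cl in unique(labels)) {
      i_cl <- which(labels == cl)
      k <- round(spec$test_fraction * length(i_cl))
      k <- max(1L, min(max(length(i_cl) - 1L, 1L), k))
      test <- c(test, i_cl[sample.int(length(i_cl), k)])
    }
  } else {
    k <- max(1L, min(n - 1L, round(spec$test_fraction * n)))
    test <- sample.int(n, k)
  }
  test <- sort(unique(test))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Split a traceset into train and test sets
#'
#' @param ts A [traceset()] with >= 2 traces per class.
#' @param spec A [split_spec()].
#' @return List with [traceset()] elements `train` and `test`.
#' @export
split_dataset <- function(ts, spec = split_spec()) {
  stopifnot(inherits(ts, "traceset"))
  if (any(table(ts$meta$label) < 2L)) {
    stop("need at least 2 traces per class to split", call. = FALSE)
  }
  idx <- split_indices(ts$meta$label, ts$meta$replicate_id, spec)
  list(train = ts[idx$train], test = ts[idx$test])
}

#' Confusion matrix and accuracy
#'
#' Counts (rows = true class, columns = predicted class), the
#' row-normalized fractions (per-class recall on the diagonal), overall
#' accuracy, and — when predictions carry an accept/reject flag from
#' uncertainty filtering — the rejection rate.
#'
#' @param true Character vector of true labels.
#' @param predicted Character vector of predicted labels (same length),
#'   or a prediction data.frame with columns `predicted_class` and
#'   optionally `accepted`.
#' @param classes Ordered class labels; defaults to the sorted union of
#'   true labels.
#' @param accepted Optional logical vector; rejected traces are excluded
#'   from the counts when `accepted_only = TRUE`.
#' @param accepted_only Apply the accept/reject filter?
#' @return An object of class `confusion_matrix`: list with `classes`,
#'   `counts`, `row_normalized`, `accuracy`, `rejection_rate`, `n`.
#' @export
confusion <- function(true, predicted, classes = NULL, accepted = NULL,
                      accepted_only = FALSE) {
  if (is.data.frame(predicted)) {
    if (is.null(accepted) && "accepted" %in% names(predicted)) {
      accepted <- predicted$accepted
    }
    predicted <- predicted$predicted_class
  }
  true <- as.character(true)
  predicted <- as.character(predicted)
  stopifnot(length(true) == length(predicted))
  if (is.null(classes)) classes <- sort(unique(true))
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad)) {
    stop("label(s) not in the class list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_all <- length(true)
  rejection_rate <- 0
  if (accepted_only) {
    if (is.null(accepted)) {
      stop("accepted_only = TRUE requires an 'accepted' flag",
           call. = FALSE)
    }
    rejection_rate <- mean(!accepted)
    true <- true[accepted]
    predicted <- predicted[accepted]
  }
  counts <- table(factor(true, levels = classes),
                  factor(predicted, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(true = classes, predicted = classes))
  total <- sum(counts)
  if (total == 0L) {
    warning("all traces rejected; accuracy undefined")
    accuracy <- NaN
    rn <- counts * NaN
  } else {
    accuracy <- sum(diag(counts)) / total
    rs <- rowSums(counts)
    rn <- counts / ifelse(rs == 0L, NA_real_, rs)
  }
  structure(list(classes = classes, counts = counts, row_normalized = rn,
                 accuracy = accuracy, rejection_rate = rejection_rate,
                 n = total),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<confusion_matrix> %d traces, accuracy %.3f",
              x$n, x$accuracy))
  if (x$rejection_rate > 0) {
    cat(sprintf(" (rejection rate %.3f)", x$rejection_rate))
  }
  cat("\nrow-normalized (true x predicted):\n")
  print(round(x$row_normalized, digits))
  invisible(x)
}
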