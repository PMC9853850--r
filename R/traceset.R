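#' A labelled collection of single-molecule intensity traces
#'
#' The central container of the package: a numeric matrix with one trace
#' per row (all traces share the same number of frames) plus per-trace
#' metadata (`trace_id`, `label`, `replicate_id`), the frame time, a
#' normalization flag, and provenance (simulated vs extracted, seeds).
#'
#' @param values Numeric matrix, traces in rows, frames in columns.
#' @param labels Character vector of class labels (or `"unknown"`).
#' @param replicate_ids Character vector of replicate/batch identifiers.
#' @param trace_ids Unique trace identifiers; autogenerated when `NULL`.
#' @param frame_time Frame duration in seconds.
#' @param normalized Logical: are values normalized to `[0, 1]`?
#' @param provenance Named list describing where the data came from.
#' @return An object of class `traceset`.
#' @export
traceset <- function(values, labels, replicate_ids = rep("r1", nrow(values)),
                     trace_ids = NULL, frame_time = 0.05,
                     normalized = FALSE, provenance = list(source = "user")) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix (traces in rows)", call. = FALSE)
  }
  n <- nrow(values)
  if (is.null(trace_ids)) trace_ids <- sprintf("t%05d", seq_len(n))
  labels <- as.character(labels)
  replicate_ids <- as.character(replicate_ids)
  trace_ids <- as.character(trace_ids)
  if (length(labels) != n || length(replicate_ids) != n ||
      length(trace_ids) != n) {
    stop("labels, replicate_ids and trace_ids must match nrow(values)",
         call. = FALSE)
  }
  if (anyDuplicated(trace_ids)) {
    stop("trace_ids must be unique", call. = FALSE)
  }
  if (normalized && (min(values) < 0 || max(values) > 1)) {
    stop("normalized tracesets must have values in [0, 1]", call. = FALSE)
  }
  structure(
    list(values = unname(values),
         meta = data.frame(trace_id = trace_ids, label = labels,
                           replicate_id = replicate_ids,
                           stringsAsFactors = FALSE),
         n_frames = ncol(values), frame_time = frame_time,
         classes = sort(unique(labels)),
         normalized = isTRUE(normalized), provenance = provenance),
    class = "traceset")
}

#' @export
print.traceset <- function(x, ...) {
  cat(sprintf(
    "<traceset> %d traces x %d frames (%.3g s/frame)%s, source: %s\n",
    nrow(x$values), x$n_frames, x$frame_time,
    if (x$normalized) ", normalized" else ", raw",
    x$provenance$source %||% "unknown"))
  tab <- table(x$meta$label)
  cat("  classes:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
`[.traceset` <- function(x, i, ...) {
  traceset(x$values[i, , drop = FALSE], labels = x$meta$label[i],
           replicate_ids = x$meta$replicate_id[i],
           trace_ids = x$meta$trace_id[i], frame_time = x$frame_time,
           normalized = x$normalized, provenance = x$provenance)
}

#' Number of traces in a traceset
#' @param ts A [traceset()].
#' @return Integer count.
#' @export
n_traces <- function(ts) nrow(ts$values)

#' Bind two tracesets with the same frame grid
#' @param a,b [traceset()] objects with equal `n_frames`, `frame_time` and
#'   normalization state.
#' @return Combined [traceset()].
#' @export
bind_tracesets <- function(a, b) {
  stopifnot(inherits(a, "traceset"), inherits(b, "traceset"),
            a$n_frames == b$n_frames, a$frame_time == b$frame_time,
            a$normalized == b$normalized)
  ids <- c(a$meta$trace_id, b$meta$trace_id)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_dup")
  traceset(rbind(a$values, b$values),
           labels = c(a$meta$label, b$meta$label),
           replicate_ids = c(a$meta$replicate_id, b$meta$replicate_id),
           trace_ids = ids, frame_time = a$frame_time,
           normalized = a$normalized,
           provenance = list(source = "combined"))
}

# order-statistic (type-1) quantile; exact under monotone affine maps,
# which makes the normalization idempotent and affine-invariant
.q1 <- function(x, p) {
  n <- length(x)
  sort(x, partial = max(1L, ceiling(n * p)))[max(1L, ceiling(n * p))]
}

#' Normalize one intensity trace to [0, 1]
#'
#' Subtracts the 10th percentile of the trace and divides by the
#' (99.5th - 10th) percentile range, then clips to `[0, 1]`. Percentiles
#' are order statistics (no interpolation), which makes the operation
#' exactly idempotent and invariant to positive affine transforms of the
#' raw counts. Robust to the mostly-OFF character of spontaneous blinking:
#' the 10th percentile tracks the background level and the 99.5th the ON
#' level.
#'
#' @param x Numeric vector of raw counts with at least 2 distinct values.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_trace <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop("trace must be a numeric vector of length >= 2", call. = FALSE)
  }
  lo <- .q1(x, 0.10)
  hi <- .q1(x, 0.995)
  if (hi - lo <= 0) {
    stop("flat trace: (99.5th - 10th) percentile range is zero; ",
         "trace is unusable", call. = FALSE)
  }
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' Normalize every trace of a traceset
#'
#' Applies [normalize_trace()] row-wise. Flat traces (zero percentile
#' range) cannot be normalized; they are excluded and their count reported
#' in a message.
#'
#' @param ts A raw [traceset()].
#' @return A normalized [traceset()] (possibly with fewer traces).
#' @export
normalize_traces <- function(ts) {
  stopifnot(inherits(ts, "traceset"))
  if (ts$normalized) return(ts)
  rng <- apply(ts$values, 1L, function(x) .q1(x, 0.995) - .q1(x, 0.10))
  ok <- rng > 0
  if (!all(ok)) {
    message(sum(!ok), " flat trace(s) excluded during normalization")
  }
  vals <- ts$values[ok, , drop = FALSE]
  vals <- t(apply(vals, 1L, normalize_trace))
  out <- ts[which(ok)]
  out$values <- vals
  out$normalized <- TRUE
  out$provenance$normalized <- TRUE
  out
}
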