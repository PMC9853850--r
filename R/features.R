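#' Binarize a normalized trace with hysteresis thresholds
#'
#' A frame switches the molecule to ON only when the normalized intensity
#' rises above `theta_hi`, and back to OFF only when it falls below
#' `theta_lo` (`theta_hi > theta_lo`); intermediate values keep the
#' previous state. The initial state is OFF. Hysteresis makes the ON/OFF
#' segmentation robust to shot noise hovering near a single threshold.
#'
#' @param x Normalized trace (values in `[0, 1]`).
#' @param theta_hi,theta_lo Thresholds in (0, 1) with
#'   `theta_hi > theta_lo`.
#' @return An object of class `binarized_trace`: list with `states`
#'   (logical per frame, `TRUE` = ON), `theta_hi`, `theta_lo`.
#' @export
binarize_trace <- function(x, theta_hi = 0.5, theta_lo = 0.3) {
  if (theta_hi <= 0 || theta_hi >= 1 || theta_lo <= 0 || theta_lo >= 1) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  if (theta_hi <= theta_lo) {
    stop("theta_hi must exceed theta_lo", call. = FALSE)
  }
  cand <- rep(NA_real_, length(x))
  cand[x > theta_hi] <- 1
  cand[x < theta_lo] <- 0
  filled <- zoo::na.locf(cand, na.rm = FALSE)
  filled[is.na(filled)] <- 0 # initial state OFF
  structure(list(states = filled > 0.5, theta_hi = theta_hi,
                 theta_lo = theta_lo),
            class = "binarized_trace")
}

#' Hand-crafted blinking descriptors of one trace
#'
#' Thirteen summary features of a binarized blinking trace, spanning the
#' families a practitioner reads off a blinking record: event counts
#' (number of peaks and OFF events), durations (mean/median peak duration,
#' longest ON and OFF intervals, mean OFF duration, total ON time), timing
#' (time of first ON frame, photobleaching time), equilibrium (duty
#' cycle), and ON-level intensity statistics (mean, coefficient of
#' variation). A peak is a maximal run of ON frames. The photobleaching
#' time is the end of the last ON frame, the full acquisition length if
#' the trace ends ON, or 0 if the molecule was never ON. All durations are
#' in seconds.
#'
#' @param bin A [binarize_trace()] result.
#' @param x The corresponding normalized trace.
#' @param frame_time Frame duration in seconds.
#' @return Named numeric vector of length 13.
#' @export
trace_features <- function(bin, x, frame_time) {
  stopifnot(inherits(bin, "binarized_trace"),
            length(bin$states) == length(x))
  s <- bin$states
  nf <- length(s)
  acq <- nf * frame_time
  r <- rle(s)
  on_runs <- r$lengths[r$values]
  off_runs <- r$lengths[!r$values]
  n_peaks <- length(on_runs)
  total_on <- sum(on_runs) * frame_time
  last_on <- if (any(s)) max(which(s)) else 0L
  first_on <- if (any(s)) min(which(s)) else NA_integer_
  on_vals <- x[s]
  c(n_peaks = n_peaks,
    mean_peak_duration = if (n_peaks) mean(on_runs) * frame_time else 0,
    median_peak_duration =
      if (n_peaks) stats::median(on_runs) * frame_time else 0,
    longest_on = if (n_peaks) max(on_runs) * frame_time else 0,
    longest_off = if (length(off_runs)) max(off_runs) * frame_time else 0,
    total_on_time = total_on,
    duty_cycle = mean(s),
    photobleach_time = last_on * frame_time,
    n_off_events = length(off_runs),
    mean_off_duration =
      if (length(off_runs)) mean(off_runs) * frame_time else 0,
    on_intensity_mean = if (n_peaks) mean(on_vals) else 0,
    on_intensity_cv =
      if (length(on_vals) > 1L && mean(on_vals) > 0)
        stats::sd(on_vals) / mean(on_vals) else 0,
    first_on_time =
      if (is.na(first_on)) acq else (first_on - 1L) * frame_time)
}

#' Feature table of a normalized traceset
#'
#' Binarizes every trace and computes the 13 blinking descriptors of
#' [trace_features()], returning one row per trace alongside its metadata.
#'
#' @param ts A normalized [traceset()].
#' @param theta_hi,theta_lo Hysteresis thresholds, see [binarize_trace()].
#' @return data.frame with columns `trace_id`, `label`, `replicate_id`
#'   followed by the 13 feature columns.
#' @export
feature_table <- function(ts, theta_hi = 0.5, theta_lo = 0.3) {
  stopifnot(inherits(ts, "traceset"))
  if (!ts$normalized) {
    stop("feature extraction requires a normalized traceset; ",
         "call normalize_traces() first", call. = FALSE)
  }
  feats <- t(vapply(seq_len(n_traces(ts)), function(i) {
    x <- ts$values[i, ]
    trace_features(binarize_trace(x, theta_hi, theta_lo), x, ts$frame_time)
  }, numeric(13L)))
  cbind(ts$meta, as.data.frame(feats))
}

.feature_columns <- function(ft) {
  setdiff(names(ft), c("trace_id", "label", "replicate_id"))
}

#' Principal-component embedding of a feature table
#'
#' Standardizes every feature (zero mean, unit variance; features have
#' incommensurate units), drops constant columns with a warning, and
#' computes an orthonormal PCA. Explained-variance fractions are sorted in
#' decreasing order and sum to one.
#'
#' @param ft A [feature_table()] (or plain data.frame of features).
#' @return List with `scores` (traces x components), `var_fraction`,
#'   `rotation`, and `dropped` (names of constant features, if any).
#' @export
pca_embed <- function(ft) {
  cols <- .feature_columns(ft)
  x <- as.matrix(ft[, cols, drop = FALSE])
  if (nrow(x) < 2L) stop("need at least 2 traces for PCA", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  dropped <- cols[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping constant feature column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, var_fraction = vf, rotation = p$rotation,
       dropped = dropped)
}

#' Magnitude spectrum of a normalized trace
#'
#' Modulus of the discrete Fourier transform, zero-frequency term
#' included.
#'
#' @param x Normalized trace.
#' @return Numeric vector of `length(x)` magnitudes.
#' @export
fourier_magnitudes <- function(x) {
  Mod(stats::fft(x))
}
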