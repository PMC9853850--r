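#' Spot detection and trace extraction configuration
#'
#' @param detection_quantile Quantile of the temporal-maximum projection
#'   used as the detection threshold, in (0, 1).
#' @param roi_radius Radius (pixels) of the signal disc.
#' @param annulus_inner,annulus_outer Inner/outer radii (pixels) of the
#'   local-background ring; `annulus_outer > annulus_inner >= roi_radius`.
#' @param min_separation Spots closer than this (pixels) are all discarded
#'   (conservative single-molecule criterion).
#' @param min_dynamic_range Minimum ratio between a trace's
#'   (99.5th - 10th) percentile range and its noise scale (median absolute
#'   deviation) for the trace to pass QC.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(detection_quantile = 0.99, roi_radius = 3,
                              annulus_inner = 5, annulus_outer = 8,
                              min_separation = 6, min_dynamic_range = 8) {
  if (detection_quantile <= 0 || detection_quantile >= 1) {
    stop("detection_quantile must be in (0, 1)", call. = FALSE)
  }
  if (!(annulus_outer > annulus_inner && annulus_inner >= roi_radius)) {
    stop("need annulus_outer > annulus_inner >= roi_radius", call. = FALSE)
  }
  structure(
    list(detection_quantile = detection_quantile, roi_radius = roi_radius,
         annulus_inner = annulus_inner, annulus_outer = annulus_outer,
         min_separation = min_separation,
         min_dynamic_range = min_dynamic_range),
    class = "extraction_config")
}

# temporal maximum projection of a movie stack
.max_projection <- function(frames) {
  nf <- dim(frames)[3L]
  proj <- frames[, , 1L]
  for (f in seq_len(nf)[-1L]) proj <- pmax(proj, frames[, , f])
  proj
}

#' Detect single-molecule spots in a movie stack
#'
#' Finds local maxima of the temporal-maximum projection (blinking
#' molecules may be ON in only a few frames, so the maximum — not the mean
#' — projection is used) that exceed the `detection_quantile` of the
#' projection's intensity distribution. Any two maxima closer than
#' `min_separation` are both discarded. Positions are refined to sub-pixel
#' precision by the intensity centroid of the 3x3 neighbourhood and
#' reported as 0-based pixel-center coordinates.
#'
#' @param stack A [movie_stack()] (or object with `$frames`).
#' @param cfg An [extraction_config()].
#' @return data.frame with columns `x`, `y` (0-based, sub-pixel). Empty
#'   (with a warning) when nothing is found.
#' @export
detect_spots <- function(stack, cfg = extraction_config()) {
  frames <- stack$frames
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  proj <- .max_projection(frames)
  h <- nrow(proj); w <- ncol(proj)
  thr <- stats::quantile(proj, cfg$detection_quantile, names = FALSE)

  # strict-greater on half the neighbourhood, >= on the other half, to
  # break ties on plateaus without producing duplicate maxima
  core <- proj[2:(h - 1), 2:(w - 1)]
  sh <- function(dr, dc) proj[2:(h - 1) + dr, 2:(w - 1) + dc]
  is_max <- core > thr &
    core > sh(-1, -1) & core > sh(-1, 0) & core > sh(-1, 1) &
    core > sh(0, -1) &
    core >= sh(0, 1) &
    core >= sh(1, -1) & core >= sh(1, 0) & core >= sh(1, 1)
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("no spots detected")
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  rows <- idx[, 1L] + 1L # back to full-image 1-based coordinates
  cols <- idx[, 2L] + 1L

  # discard all members of any too-close pair
  if (cfg$min_separation > 0 && length(rows) > 1L) {
    d2 <- outer(cols, cols, "-")^2 + outer(rows, rows, "-")^2
    diag(d2) <- Inf
    keep <- apply(d2, 1L, min) >= cfg$min_separation^2
    rows <- rows[keep]; cols <- cols[keep]
  }
  if (length(rows) == 0L) {
    warning("no spots detected")
    return(data.frame(x = numeric(0), y = numeric(0)))
  }

  # sub-pixel centroid of the 3x3 neighbourhood (baseline-subtracted)
  xs <- numeric(length(rows)); ys <- numeric(length(rows))
  for (i in seq_along(rows)) {
    patch <- proj[(rows[i] - 1):(rows[i] + 1), (cols[i] - 1):(cols[i] + 1)]
    patch <- patch - min(patch)
    tot <- sum(patch)
    if (tot > 0) {
      ys[i] <- (rows[i] - 1) + sum((-1:1) * rowSums(patch)) / tot
      xs[i] <- (cols[i] - 1) + sum((-1:1) * colSums(patch)) / tot
    } else {
      ys[i] <- rows[i] - 1; xs[i] <- cols[i] - 1
    }
  }
  data.frame(x = xs, y = ys)
}

# disc / annulus pixel offsets around a center; a negative lower radius
# means a filled disc (center included)
.mask_offsets <- function(radius_lo, radius_hi) {
  r <- ceiling(radius_hi)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- g$dx^2 + g$dy^2
  keep <- if (radius_lo < 0) d2 <= radius_hi^2
          else d2 > radius_lo^2 & d2 <= radius_hi^2
  g[keep, , drop = FALSE]
}

#' Extract the raw intensity trace of one spot
#'
#' Per frame: summed counts in the disc of radius `roi_radius` around the
#' spot, minus disc area times the median of the background annulus.
#' Values may be negative in dark frames; they are clipped only at
#' normalization, so the OFF-level statistics remain unbiased.
#'
#' @param stack A [movie_stack()].
#' @param spot Numeric length-2 `(x, y)` (0-based) or one row of
#'   [detect_spots()] output.
#' @param cfg An [extraction_config()].
#' @return Numeric vector of background-subtracted counts per frame, or
#'   `NULL` (with a message) if the annulus does not fit in the field.
#' @export
extract_trace <- function(stack, spot, cfg = extraction_config()) {
  frames <- stack$frames
  if (is.data.frame(spot)) spot <- c(spot$x[1L], spot$y[1L])
  cx <- round(spot[1L]) + 1L # 1-based column
  cy <- round(spot[2L]) + 1L # 1-based row
  h <- dim(frames)[1L]; w <- dim(frames)[2L]; nf <- dim(frames)[3L]
  r_out <- ceiling(cfg$annulus_outer)
  if (cx - r_out < 1L || cx + r_out > w || cy - r_out < 1L ||
      cy + r_out > h) {
    message(sprintf("spot (%.1f, %.1f) too close to the edge; skipped",
                    spot[1L], spot[2L]))
    return(NULL)
  }
  disc <- .mask_offsets(-1, cfg$roi_radius)
  ann <- .mask_offsets(cfg$annulus_inner, cfg$annulus_outer)
  block <- frames[(cy - r_out):(cy + r_out), (cx - r_out):(cx + r_out), ,
                  drop = FALSE]
  bm <- matrix(block, ncol = nf) # pixels x frames
  side <- 2L * r_out + 1L
  lin <- function(off) (off$dx + r_out) * side + (off$dy + r_out) + 1L
  disc_idx <- lin(disc); ann_idx <- lin(ann)
  sig <- colSums(bm[disc_idx, , drop = FALSE])
  bg <- apply(bm[ann_idx, , drop = FALSE], 2L, stats::median)
  sig - length(disc_idx) * bg
}

#' Extract raw traces for a set of spots
#'
#' Applies [extract_trace()] to every spot; spots whose annulus does not
#' fit in the field are skipped. Labels default to `"unknown"` unless a
#' ground-truth table is supplied, in which case each spot is matched to
#' the nearest planted molecule within `match_dist` pixels.
#'
#' @inheritParams extract_trace
#' @param spots data.frame from [detect_spots()].
#' @param truth Optional ground-truth table (`trace_id`, `x`, `y`,
#'   `label`).
#' @param match_dist Maximum match distance in pixels.
#' @return A raw [traceset()]; matched truth ids are stored in the
#'   provenance as `matched_truth_id` (NA where unmatched).
#' @export
extract_traces <- function(stack, spots, cfg = extraction_config(),
                           truth = NULL, match_dist = 1) {
  vals <- list(); keep <- integer(0)
  for (i in seq_len(nrow(spots))) {
    tr <- extract_trace(stack, c(spots$x[i], spots$y[i]), cfg)
    if (!is.null(tr)) {
      vals[[length(vals) + 1L]] <- tr
      keep <- c(keep, i)
    }
  }
  if (length(vals) == 0L) {
    stop("no extractable spots (all at the field edge?)", call. = FALSE)
  }
  values <- do.call(rbind, vals)
  labels <- rep("unknown", length(keep))
  matched <- rep(NA_character_, length(keep))
  if (!is.null(truth)) {
    for (j in seq_along(keep)) {
      i <- keep[j]
      d <- sqrt((truth$x - spots$x[i])^2 + (truth$y - spots$y[i])^2)
      k <- which.min(d)
      if (d[k] <= match_dist) {
        labels[j] <- truth$label[k]
        matched[j] <- truth$trace_id[k]
      }
    }
  }
  traceset(values, labels = labels,
           replicate_ids = rep("extracted", length(keep)),
           trace_ids = sprintf("spot%04d", keep),
           frame_time = stack$frame_time %||% 0.05, normalized = FALSE,
           provenance = list(source = "extracted",
                             matched_truth_id = matched))
}

#' Quality-filter raw traces by dynamic range
#'
#' Rejects traces whose raw (99.5th - 10th) percentile range is below
#' `min_dynamic_range` times the trace's noise-scale estimate (median
#' absolute deviation). Pure-noise traces from empty regions fail this
#' test; genuine blinking traces, whose ON level towers over the noise,
#' pass. The kept and rejected sets partition the input exactly.
#'
#' @param ts A raw [traceset()].
#' @param min_dynamic_range Threshold ratio; defaults from
#'   [extraction_config()].
#' @return List with `kept` (a [traceset()]) and `rejected`
#'   (data.frame `trace_id`, `reason`).
#' @export
qc_filter <- function(ts, min_dynamic_range = 8) {
  stopifnot(inherits(ts, "traceset"))
  reasons <- character(0); rej_ids <- character(0)
  ok <- logical(n_traces(ts))
  for (i in seq_len(n_traces(ts))) {
    x <- ts$values[i, ]
    rng <- .q1(x, 0.995) - .q1(x, 0.10)
    scale <- stats::mad(x)
    if (scale <= 0) scale <- stats::sd(x)
    if (scale <= 0 || rng < min_dynamic_range * scale) {
      ok[i] <- FALSE
      rej_ids <- c(rej_ids, ts$meta$trace_id[i])
      reasons <- c(reasons, "low_dynamic_range")
    } else {
      ok[i] <- TRUE
    }
  }
  list(kept = ts[which(ok)],
       rejected = data.frame(trace_id = rej_ids, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Harvest noise traces from empty regions of a movie
#'
#' Samples positions on a grid away from any planted molecule and from the
#' field edge, and extracts a raw trace at each — the "signal" of regions
#' that contain no molecule, used for the noise-training control.
#'
#' @param stack A [movie_stack()] (its `truth`, if present, defines the
#'   exclusion zones).
#' @param n Number of noise traces wanted.
#' @param cfg An [extraction_config()].
#' @param rng_seed Integer seed for position sampling.
#' @param exclusion_radius Minimum distance (pixels) from any planted
#'   molecule.
#' @return A raw [traceset()] with label `"noise"`.
#' @export
extract_noise_traces <- function(stack, n, cfg = extraction_config(),
                                 rng_seed = 1L, exclusion_radius = 10) {
  set.seed(as.integer(rng_seed))
  h <- dim(stack$frames)[1L]; w <- dim(stack$frames)[2L]
  r_out <- ceiling(cfg$annulus_outer)
  vals <- list()
  attempts <- 0L
  while (length(vals) < n) {
    attempts <- attempts + 1L
    if (attempts > 500L * n) {
      stop("could not find enough empty regions", call. = FALSE)
    }
    x <- stats::runif(1L, r_out, w - 1 - r_out)
    y <- stats::runif(1L, r_out, h - 1 - r_out)
    if (!is.null(stack$truth) && nrow(stack$truth) > 0L) {
      d2 <- (stack$truth$x - x)^2 + (stack$truth$y - y)^2
      if (min(d2) < exclusion_radius^2) next
    }
    tr <- extract_trace(stack, c(x, y), cfg)
    if (!is.null(tr)) vals[[length(vals) + 1L]] <- tr
  }
  traceset(do.call(rbind, vals), labels = rep("noise", n),
           replicate_ids = rep("noise", n),
           trace_ids = sprintf("noise%04d", seq_len(n)),
           frame_time = stack$frame_time %||% 0.05, normalized = FALSE,
           provenance = list(source = "extracted_noise"))
}
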