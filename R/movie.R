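#' Synthetic TIRF movie configuration
#'
#' Geometry and optics for rendering simulated traces into an image stack:
#' field size, Gaussian point-spread-function width, a minimum separation
#' enforced between molecules during placement, an edge margin keeping
#' molecules far enough from the border for later ROI/annulus extraction,
#' and a constant background offset. By default no per-pixel noise is added
#' at render time — the camera noise is already carried by the input traces
#' — so the only background contribution is the constant offset.
#'
#' @param width,height Field size in pixels (>= 16).
#' @param psf_sigma Gaussian PSF standard deviation in pixels (> 0).
#' @param min_separation Minimum pairwise molecule distance (pixels, >= 0).
#' @param edge_margin Minimum distance from any image border (pixels).
#' @param extra_background_offset Constant background offset (counts).
#' @param placement_seed Optional default seed for molecule placement.
#' @return An object of class `movie_config`.
#' @export
movie_config <- function(width = 128L, height = 128L, psf_sigma = 1.2,
                         min_separation = 6, edge_margin = 8,
                         extra_background_offset = 0,
                         placement_seed = NULL) {
  if (width < 16L || height < 16L) {
    stop("field must be at least 16 x 16 pixels", call. = FALSE)
  }
  if (psf_sigma <= 0) stop("psf_sigma must be > 0", call. = FALSE)
  if (min_separation < 0) stop("min_separation must be >= 0", call. = FALSE)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         psf_sigma = psf_sigma, min_separation = min_separation,
         edge_margin = edge_margin,
         extra_background_offset = extra_background_offset,
         placement_seed = placement_seed),
    class = "movie_config")
}

#' Construct a movie stack object
#'
#' @param frames 3-D non-negative array, dimensions (row, column, frame).
#' @param truth Optional data.frame with columns `trace_id`, `x`, `y`,
#'   `label` (0-based pixel coordinates of planted molecules).
#' @param frame_time Frame duration in seconds.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, truth = NULL, frame_time = 0.05) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (min(frames) < 0) stop("frames must be non-negative", call. = FALSE)
  if (!is.null(truth)) {
    stopifnot(all(c("trace_id", "x", "y", "label") %in% names(truth)))
    if (any(truth$x < 0 | truth$x > dim(frames)[2L] - 1 |
            truth$y < 0 | truth$y > dim(frames)[1L] - 1)) {
      stop("truth positions must lie inside the field of view",
           call. = FALSE)
    }
  }
  structure(list(frames = frames, truth = truth, frame_time = frame_time),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> %d x %d px, %d frames%s\n", d[1L], d[2L], d[3L],
              if (is.null(x$truth)) "" else
                sprintf(", %d planted molecules", nrow(x$truth))))
  invisible(x)
}

# pixel-integrated 1-D Gaussian weights for pixel centers px (0-based) and
# sub-pixel position mu
.psf_weights_1d <- function(px, mu, sigma) {
  stats::pnorm(px + 0.5, mu, sigma) - stats::pnorm(px - 0.5, mu, sigma)
}

#' Render a traceset into a synthetic TIRF movie stack
#'
#' Each molecule is placed at a random sub-pixel position (rejection
#' sampling under the `min_separation` and `edge_margin` constraints) and
#' contributes, in every frame, its trace value spread over a 2-D Gaussian
#' PSF truncated at 4 sigma (< 0.1% mass loss). A constant background
#' offset is added and pixel values are rounded to non-negative integers.
#' With `noisy_background = TRUE` the constant offset is replaced by
#' per-pixel Poisson counts of that mean plus Gaussian read noise — the
#' realistic-background variant used to harvest noise traces from empty
#' regions for control experiments.
#'
#' @param traces A [traceset()] (raw counts).
#' @param movie_cfg A [movie_config()].
#' @param rng_seed Integer seed for placement (and background noise);
#'   defaults to `movie_cfg$placement_seed`.
#' @param noisy_background Logical, see above.
#' @param read_noise_sd Read noise used when `noisy_background = TRUE`.
#' @return A [movie_stack()] carrying the ground-truth molecule table.
#' @export
render_movie <- function(traces, movie_cfg = movie_config(),
                         rng_seed = movie_cfg$placement_seed,
                         noisy_background = FALSE, read_noise_sd = 2) {
  stopifnot(inherits(traces, "traceset"), inherits(movie_cfg, "movie_config"))
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  w <- movie_cfg$width; h <- movie_cfg$height
  nf <- traces$n_frames
  n_mol <- n_traces(traces)
  m <- movie_cfg$edge_margin

  # rejection-sample sub-pixel positions (0-based coordinates)
  xs <- numeric(n_mol); ys <- numeric(n_mol)
  placed <- 0L; attempts <- 0L
  max_attempts <- 2000L * max(1L, n_mol)
  while (placed < n_mol) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place all molecules at the requested density; ",
           "use a larger field or fewer molecules", call. = FALSE)
    }
    x <- stats::runif(1L, m, w - 1 - m)
    y <- stats::runif(1L, m, h - 1 - m)
    if (placed > 0L && movie_cfg$min_separation > 0) {
      d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
      if (min(d2) < movie_cfg$min_separation^2) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }

  stack <- array(0, dim = c(h, w, nf))
  r <- ceiling(4 * movie_cfg$psf_sigma)
  for (i in seq_len(n_mol)) {
    cx <- round(xs[i]); cy <- round(ys[i])
    px <- max(0, cx - r):min(w - 1, cx + r)
    py <- max(0, cy - r):min(h - 1, cy + r)
    wx <- .psf_weights_1d(px, xs[i], movie_cfg$psf_sigma)
    wy <- .psf_weights_1d(py, ys[i], movie_cfg$psf_sigma)
    patch <- outer(wy, wx) # rows = y, cols = x
    contrib <- outer(patch, traces$values[i, ])
    stack[py + 1L, px + 1L, ] <- stack[py + 1L, px + 1L, ] + contrib
  }

  off <- movie_cfg$extra_background_offset
  if (noisy_background) {
    bg <- stats::rpois(length(stack), off)
    if (read_noise_sd > 0) {
      bg <- bg + stats::rnorm(length(stack), 0, read_noise_sd)
    }
    stack <- stack + array(bg, dim = dim(stack))
  } else if (off != 0) {
    stack <- stack + off
  }
  stack <- round(stack)
  stack[stack < 0] <- 0

  truth <- data.frame(trace_id = traces$meta$trace_id, x = xs, y = ys,
                      label = traces$meta$label, stringsAsFactors = FALSE)
  movie_stack(stack, truth = truth, frame_time = traces$frame_time)
}

#' Write / read a movie stack as multi-page 16-bit TIFF
#'
#' One page per frame, 16-bit unsigned, uncompressed. The ground-truth
#' molecule table (if any) is written alongside as a tab-separated text
#' file with header `trace_id x y label`.
#'
#' @param stack A [movie_stack()].
#' @param path Output TIFF path.
#' @param truth_path Optional path for the truth table; defaults to the
#'   TIFF path with extension `.truth.tsv`.
#' @return `write_movie_tiff()` returns `path` invisibly; `read_movie_tiff()`
#'   returns a [movie_stack()] without truth (read it separately with
#'   [read_truth_table()]).
#' @export
write_movie_tiff <- function(stack, path, truth_path = NULL) {
  stopifnot(inherits(stack, "movie_stack"))
  mx <- max(stack$frames)
  if (mx > 65535) {
    stop("pixel values exceed the 16-bit range (max ", mx,
         "); lower the gain or photon rate", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(stack$frames)[3L]), function(f) {
    stack$frames[, , f] / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  if (!is.null(stack$truth)) {
    if (is.null(truth_path)) truth_path <- paste0(path, ".truth.tsv")
    utils::write.table(stack$truth, truth_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_time Frame duration to attach to the stack read back.
#' @export
read_movie_tiff <- function(path, frame_time = 0.05) {
  if (!file.exists(path)) {
    stop("TIFF file not found: ", path, call. = FALSE)
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) {
      stop("not a readable TIFF file: ", path, " (", conditionMessage(e),
           ")", call. = FALSE)
    })
  if (is.matrix(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]),
                             length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]]
  movie_stack(frames, truth = NULL, frame_time = frame_time)
}

#' @rdname write_movie_tiff
#' @export
read_truth_table <- function(truth_path) {
  if (!file.exists(truth_path)) {
    stop("truth table not found: ", truth_path, call. = FALSE)
  }
  utils::read.table(truth_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
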