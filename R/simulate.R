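#' Simulate a blinking state trajectory
#'
#' Exact (Gillespie) sampling of the coupled photophysical x conformational
#' continuous-time Markov chain of one molecule. The photophysical chain has
#' states ON, OFF and an absorbing BLEACHED state entered from ON at rate
#' `k_bleach`; the hidden conformational chain switches at
#' `conf_switch_rate` and multiplies the ON/OFF rates. Per-molecule
#' lognormal scatter (unit mean, CV `molecule_cv`) is drawn once per call.
#' The initial conformation is uniform; the initial photophysical state is
#' drawn from the stationary ON/OFF distribution of that conformation
#' (molecules equilibrate before acquisition starts).
#'
#' @param spec A [kinetic_class_spec()].
#' @param duration Trajectory length in seconds (> 0).
#' @param rng_seed Optional integer seed; when `NULL` the current RNG
#'   stream is used.
#' @return An object of class `state_trajectory`: a list with `intervals`
#'   (data.frame of alternating ON/OFF intervals with `state`, `start`,
#'   `duration`, tiling `[0, min(bleach_time, duration)]`), `bleach_time`
#'   (seconds, `Inf` if the molecule survived the acquisition) and
#'   `duration`.
#' @export
simulate_state_trajectory <- function(spec, duration, rng_seed = NULL) {
  if (!inherits(spec, "kinetic_class_spec")) {
    stop("invalid spec: expected a kinetic_class_spec", call. = FALSE)
  }
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration <= 0) {
    stop("invalid field 'duration': must be a single value > 0",
         call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))

  # per-molecule lognormal scatter, unit mean
  if (spec$molecule_cv > 0) {
    sdlog <- sqrt(log1p(spec$molecule_cv^2))
    scat <- exp(stats::rnorm(2L, mean = -sdlog^2 / 2, sd = sdlog))
  } else {
    scat <- c(1, 1)
  }
  kon <- spec$k_on * scat[1L] * spec$conf_on_multipliers
  koff <- spec$k_off * scat[2L] * spec$conf_off_multipliers
  kb <- spec$k_bleach
  ksw <- if (spec$n_conf > 1L) spec$conf_switch_rate else 0
  n_conf <- spec$n_conf

  conf <- if (n_conf > 1L) sample.int(n_conf, 1L) else 1L
  on <- stats::runif(1L) < kon[conf] / (kon[conf] + koff[conf])

  # grow-by-doubling interval storage
  cap <- 256L
  st <- character(cap); s0 <- numeric(cap); du <- numeric(cap)
  n_int <- 0L
  push <- function(state, start, dur) {
    n_int <<- n_int + 1L
    if (n_int > cap) {
      cap <<- cap * 2L
      length(st) <<- cap; length(s0) <<- cap; length(du) <<- cap
    }
    st[n_int] <<- state; s0[n_int] <<- start; du[n_int] <<- dur
  }

  t_now <- 0
  seg_start <- 0
  bleach_time <- Inf
  repeat {
    rate_flip <- if (on) koff[conf] else kon[conf]
    rate_bleach <- if (on) kb else 0
    total <- rate_flip + rate_bleach + ksw
    dt <- stats::rexp(1L, total)
    if (t_now + dt >= duration) {
      push(if (on) "ON" else "OFF", seg_start, duration - seg_start)
      break
    }
    t_now <- t_now + dt
    u <- stats::runif(1L) * total
    if (u < rate_flip) {
      push(if (on) "ON" else "OFF", seg_start, t_now - seg_start)
      seg_start <- t_now
      on <- !on
    } else if (u < rate_flip + rate_bleach) {
      push("ON", seg_start, t_now - seg_start)
      bleach_time <- t_now
      break
    } else {
      # conformational switch; photophysical state (and interval) continues
      if (n_conf == 2L) {
        conf <- 3L - conf
      } else {
        j <- sample.int(n_conf - 1L, 1L)
        conf <- if (j >= conf) j + 1L else j
      }
    }
  }

  structure(
    list(intervals = data.frame(state = st[seq_len(n_int)],
                                start = s0[seq_len(n_int)],
                                duration = du[seq_len(n_int)],
                                stringsAsFactors = FALSE),
         bleach_time = bleach_time,
         duration = duration,
         class_name = spec$class_name),
    class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf(
    "<state_trajectory> %d intervals over %.3g s; bleach at %s\n",
    nrow(x$intervals), x$duration,
    if (is.finite(x$bleach_time)) sprintf("%.3g s", x$bleach_time)
    else "(survived)"))
  invisible(x)
}

#' ON-state fraction of each camera frame
#'
#' For each frame, the fraction of the exposed window (the first
#' `exposure_fraction` of the frame) during which the molecule was ON.
#'
#' @param traj A [simulate_state_trajectory()] result.
#' @param cam A [camera_config()].
#' @return Numeric vector of length `n_frames` in `[0, 1]`.
#' @export
frame_on_fractions <- function(traj, cam) {
  ft <- cam$frame_time
  ef <- cam$exposure_fraction
  nf <- cam$n_frames
  on_time <- numeric(nf)
  iv <- traj$intervals
  on_iv <- iv[iv$state == "ON", , drop = FALSE]
  for (i in seq_len(nrow(on_iv))) {
    s <- on_iv$start[i]
    e <- s + on_iv$duration[i]
    j1 <- max(1L, floor(s / ft) + 1L)
    j2 <- min(nf, ceiling(e / ft))
    if (j1 > j2) next
    js <- j1:j2
    win_start <- (js - 1) * ft
    win_end <- win_start + ft * ef
    ov <- pmax(0, pmin(e, win_end) - pmax(s, win_start))
    on_time[js] <- on_time[js] + ov
  }
  on_time / (ft * ef)
}

#' Integrate a state trajectory through the camera model
#'
#' Converts a continuous-time ON/OFF trajectory into a raw intensity trace:
#' per frame, the expected photon count is
#' `(f_t * photon_rate_on + background_rate) * frame_time *
#' exposure_fraction` where `f_t` is the ON fraction of the exposed window;
#' shot noise is Poisson, counts are scaled by `gain`, and Gaussian read
#' noise is added.
#'
#' @inheritParams frame_on_fractions
#' @param rng_seed Optional integer seed.
#' @return Numeric vector of raw counts, length `n_frames`.
#' @export
integrate_trace <- function(traj, cam, rng_seed = NULL) {
  if (!inherits(traj, "state_trajectory")) {
    stop("expected a state_trajectory", call. = FALSE)
  }
  if (!inherits(cam, "camera_config")) {
    stop("expected a camera_config", call. = FALSE)
  }
  acq <- cam$n_frames * cam$frame_time
  if (traj$duration < acq) {
    stop(sprintf(
      paste("trajectory covers %.4g s but the acquisition needs %.4g s;",
            "simulate a longer trajectory"), traj$duration, acq),
      call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  f <- frame_on_fractions(traj, cam)
  lambda <- (f * cam$photon_rate_on + cam$background_rate) *
    cam$frame_time * cam$exposure_fraction
  counts <- stats::rpois(cam$n_frames, lambda) * cam$gain
  if (cam$read_noise_sd > 0) {
    counts <- counts + stats::rnorm(cam$n_frames, 0, cam$read_noise_sd)
  }
  counts
}

#' Simulate a labelled dataset of blinking traces
#'
#' Generates `n_per_class` molecules for each kinetics spec, integrates each
#' through the camera model, and assembles a labelled [traceset()].
#' Per-trace seeds are derived deterministically from `master_seed`, so the
#' same master seed yields a bit-identical dataset. Traces are assigned
#' round-robin to `n_replicates` replicate ids per class, emulating
#' per-peptide coverslips measured on different days.
#'
#' @param specs List of >= 2 [kinetic_class_spec()] with distinct names.
#' @param n_per_class Number of traces per class.
#' @param cam A [camera_config()].
#' @param master_seed Integer master seed.
#' @param n_replicates Replicates per class (>= 1).
#' @return A [traceset()] of `length(specs) * n_per_class` raw traces.
#' @export
simulate_dataset <- function(specs, n_per_class, cam = camera_config(),
                             master_seed = 1L, n_replicates = 5L) {
  if (!is.list(specs) || length(specs) < 2L ||
      !all(vapply(specs, inherits, logical(1L), "kinetic_class_spec"))) {
    stop("specs must be a list of >= 2 kinetic_class_spec objects",
         call. = FALSE)
  }
  cls <- vapply(specs, `[[`, character(1L), "class_name")
  if (anyDuplicated(cls)) {
    stop("duplicate class names in specs: ",
         paste(unique(cls[duplicated(cls)]), collapse = ", "), call. = FALSE)
  }
  stopifnot(n_per_class >= 1L, n_replicates >= 1L)
  n_total <- length(specs) * n_per_class
  duration <- cam$n_frames * cam$frame_time

  set.seed(as.integer(master_seed))
  trace_seeds <- sample.int(.Machine$integer.max - 1L, n_total)

  values <- matrix(0, nrow = n_total, ncol = cam$n_frames)
  labels <- character(n_total)
  reps <- character(n_total)
  ids <- character(n_total)
  idx <- 0L
  for (ci in seq_along(specs)) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      traj <- simulate_state_trajectory(specs[[ci]], duration,
                                        rng_seed = trace_seeds[idx])
      values[idx, ] <- integrate_trace(traj, cam) # continues seeded stream
      labels[idx] <- cls[ci]
      rj <- ((i - 1L) %% n_replicates) + 1L
      reps[idx] <- sprintf("%s_r%d", cls[ci], rj)
      ids[idx] <- sprintf("%s_r%d_t%05d", cls[ci], rj, i)
    }
  }
  traceset(values, labels = labels, replicate_ids = reps, trace_ids = ids,
           frame_time = cam$frame_time, normalized = FALSE,
           provenance = list(source = "simulated",
                             master_seed = as.integer(master_seed),
                             n_replicates = as.integer(n_replicates)))
}
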