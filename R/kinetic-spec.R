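#' Per-class blinking kinetics specification
#'
#' Defines the generative photophysics of one peptide class: a spontaneously
#' blinking fluorophore switches between a non-fluorescent (OFF) and a
#' fluorescent (ON) state, photobleaches irreversibly from ON, and its
#' switching rates are modulated by a hidden conformational state of the
#' peptide. Conformational modulation is a hidden continuous-time Markov
#' chain whose state multiplies `k_on` and `k_off`; it is the mechanism that
#' lets two classes share the same long-run duty cycle while differing in
#' the temporal correlation structure of their blinking.
#'
#' @param class_name Character label of the class (e.g. a peptide name).
#' @param k_on OFF-to-ON switching rate (1/s), strictly positive.
#' @param k_off ON-to-OFF switching rate (1/s), strictly positive.
#' @param k_bleach Irreversible ON-to-BLEACHED rate (1/s), non-negative.
#'   Bleaching is photo-induced and therefore only occurs from ON.
#' @param n_conf Number of hidden conformational states (>= 1).
#' @param conf_switch_rate Total rate (1/s) of leaving the current
#'   conformation (destination uniform among the others). Ignored when
#'   `n_conf == 1`.
#' @param conf_on_multipliers,conf_off_multipliers Strictly positive
#'   per-conformation multiplicative factors on `k_on` / `k_off`; length
#'   `n_conf`.
#' @param molecule_cv Coefficient of variation (unitless, >= 0) of the
#'   lognormal per-molecule scatter applied independently to `k_on` and
#'   `k_off` once per molecule (unit mean).
#'
#' @return An object of class `kinetic_class_spec`.
#' @seealso [simulate_state_trajectory()], [simulate_dataset()],
#'   [demo_class_specs()]
#' @export
kinetic_class_spec <- function(class_name, k_on, k_off, k_bleach = 0.01,
                               n_conf = 1L, conf_switch_rate = 0,
                               conf_on_multipliers = rep(1, n_conf),
                               conf_off_multipliers = rep(1, n_conf),
                               molecule_cv = 0) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid KineticClassSpec field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.character(class_name) || length(class_name) != 1L ||
      is.na(class_name) || !nzchar(class_name)) {
    stop_field("class_name", "must be a non-empty string")
  }
  chk_pos <- function(x, field, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (strict && x <= 0) || (!strict && x < 0)) {
      stop_field(field, if (strict) "must be a single rate > 0"
                 else "must be a single rate >= 0")
    }
  }
  chk_pos(k_on, "k_on")
  chk_pos(k_off, "k_off")
  chk_pos(k_bleach, "k_bleach", strict = FALSE)
  if (!is.numeric(n_conf) || length(n_conf) != 1L || is.na(n_conf) ||
      n_conf < 1 || n_conf != round(n_conf)) {
    stop_field("n_conf", "must be an integer >= 1")
  }
  n_conf <- as.integer(n_conf)
  chk_pos(conf_switch_rate, "conf_switch_rate", strict = FALSE)
  if (n_conf > 1L && conf_switch_rate <= 0) {
    stop_field("conf_switch_rate", "must be > 0 when n_conf > 1")
  }
  chk_mult <- function(m, field) {
    if (!is.numeric(m) || length(m) != n_conf || anyNA(m) || any(m <= 0)) {
      stop_field(field, sprintf(
        "must be %d strictly positive multipliers (one per conformation)",
        n_conf))
    }
  }
  chk_mult(conf_on_multipliers, "conf_on_multipliers")
  chk_mult(conf_off_multipliers, "conf_off_multipliers")
  chk_pos(molecule_cv, "molecule_cv", strict = FALSE)

  structure(
    list(class_name = class_name, k_on = k_on, k_off = k_off,
         k_bleach = k_bleach, n_conf = n_conf,
         conf_switch_rate = conf_switch_rate,
         conf_on_multipliers = as.numeric(conf_on_multipliers),
         conf_off_multipliers = as.numeric(conf_off_multipliers),
         molecule_cv = molecule_cv),
    class = "kinetic_class_spec")
}

#' @export
print.kinetic_class_spec <- function(x, ...) {
  cat(sprintf(
    "<kinetic_class_spec> %s: k_on=%.4g k_off=%.4g k_bleach=%.4g (1/s)\n",
    x$class_name, x$k_on, x$k_off, x$k_bleach))
  cat(sprintf("  duty cycle (base): %.3f; n_conf=%d, switch=%.3g/s, cv=%.2f\n",
              x$k_on / (x$k_on + x$k_off), x$n_conf, x$conf_switch_rate,
              x$molecule_cv))
  invisible(x)
}

#' Stationary ON fraction (duty cycle) of a kinetics spec
#'
#' Long-run fraction of (unbleached) time spent ON, averaged over the
#' uniform stationary distribution of conformations and ignoring bleaching.
#'
#' @param spec A [kinetic_class_spec()].
#' @return Duty cycle in `[0, 1]`.
#' @export
stationary_duty_cycle <- function(spec) {
  kon <- spec$k_on * spec$conf_on_multipliers
  koff <- spec$k_off * spec$conf_off_multipliers
  mean(kon / (kon + koff))
}

#' Camera acquisition configuration
#'
#' Fixed acquisition settings for frame-integrated detection of a blinking
#' molecule: frames of `frame_time` seconds, of which a fraction
#' `exposure_fraction` (at the start of the frame) is exposed; photons from
#' the fluorophore arrive at `photon_rate_on` while ON on top of a uniform
#' `background_rate`; counts are shot-noise limited (Poisson), scaled by
#' `gain` and corrupted by Gaussian read noise.
#'
#' Defaults correspond to a typical single-molecule TIRF regime
#' (20 Hz, 100 s acquisition, ~250 signal photons per ON frame).
#'
#' @param frame_time Frame duration in seconds (> 0).
#' @param exposure_fraction Exposed fraction of the frame, in (0, 1].
#' @param n_frames Number of frames (>= 1).
#' @param photon_rate_on Photon rate while ON (photons/s); must exceed
#'   `background_rate`.
#' @param background_rate Background photon rate (photons/s, >= 0).
#' @param read_noise_sd Read noise standard deviation (counts, >= 0).
#' @param gain Conversion gain (counts/photon, > 0).
#' @return An object of class `camera_config`.
#' @export
camera_config <- function(frame_time = 0.05, exposure_fraction = 1,
                          n_frames = 2000L, photon_rate_on = 5000,
                          background_rate = 500, read_noise_sd = 2,
                          gain = 1) {
  if (!is.numeric(frame_time) || frame_time <= 0) {
    stop("invalid CameraConfig field 'frame_time': must be > 0", call. = FALSE)
  }
  if (!is.numeric(exposure_fraction) || exposure_fraction <= 0 ||
      exposure_fraction > 1) {
    stop("invalid CameraConfig field 'exposure_fraction': must be in (0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(n_frames) || n_frames < 1 || n_frames != round(n_frames)) {
    stop("invalid CameraConfig field 'n_frames': must be an integer >= 1",
         call. = FALSE)
  }
  if (!is.numeric(photon_rate_on) || !is.numeric(background_rate) ||
      background_rate < 0 || photon_rate_on <= background_rate) {
    stop("invalid CameraConfig: need photon_rate_on > background_rate >= 0",
         call. = FALSE)
  }
  if (!is.numeric(read_noise_sd) || read_noise_sd < 0) {
    stop("invalid CameraConfig field 'read_noise_sd': must be >= 0",
         call. = FALSE)
  }
  if (!is.numeric(gain) || gain <= 0) {
    stop("invalid CameraConfig field 'gain': must be > 0", call. = FALSE)
  }
  structure(
    list(frame_time = frame_time, exposure_fraction = exposure_fraction,
         n_frames = as.integer(n_frames), photon_rate_on = photon_rate_on,
         background_rate = background_rate, read_noise_sd = read_noise_sd,
         gain = gain),
    class = "camera_config")
}

#' Built-in four-class demonstration kinetics
#'
#' Four peptide-like classes whose base duty cycles are 0.05, 0.10, 0.20
#' and 0.35, with class-specific dwell-time scales: `k_off` falls in
#' threefold steps (8, 8/3, 8/9, 8/27 per second, i.e. mean ON dwells of
#' 0.125 to 3.4 s) and `k_on` follows from the duty cycle. Each class has
#' two hidden conformations switching at 0.1 or 0.5 per second with
#' moderate modulation of the ON/OFF equilibrium, slow photobleaching
#' (`k_bleach` = 0.01/s) and 20% per-molecule rate scatter. Neighbouring
#' classes therefore differ in equilibrium (duty cycle), in blinking
#' timescale (dwell lengths), and in temporal structure (conformational
#' switching rate) — the multi-axis kind of difference expected between
#' distinct peptide microenvironments, where local interactions shift
#' both the equilibrium and the lifetimes of the fluorophore's isomers.
#'
#' @param class_names Character vector of four class labels.
#' @return List of four [kinetic_class_spec()] objects.
#' @export
demo_class_specs <- function(class_names = c("pepA", "pepB", "pepC", "pepD")) {
  stopifnot(length(class_names) == 4L)
  duty <- c(0.05, 0.10, 0.20, 0.35)
  k_off <- 8 / 3^(0:3)
  switch_rates <- c(0.1, 0.5, 0.1, 0.5)
  lapply(seq_len(4L), function(i) {
    kinetic_class_spec(
      class_name = class_names[i],
      k_on = duty[i] / (1 - duty[i]) * k_off[i],
      k_off = k_off[i],
      k_bleach = 0.01,
      n_conf = 2L,
      conf_switch_rate = switch_rates[i],
      conf_on_multipliers = c(0.75, 4 / 3),
      conf_off_multipliers = c(4 / 3, 0.75),
      molecule_cv = 0.2)
  })
}

#' Two classes distinguishable only by conformational switching rate
#'
#' Both classes share identical base rates, conformational multipliers and
#' stationary duty cycle; they differ solely in how fast the hidden
#' conformation mixes. Their single-trace feature marginals are therefore
#' nearly identical while their temporal correlation structure is not —
#' the construction used to show that static features (and PCA on them)
#' fail where a recurrent classifier succeeds.
#'
#' @param switch_rates Numeric length-2: conformational switching rates
#'   (1/s) of the slow and fast class.
#' @param duty Shared base duty cycle.
#' @param k_off Shared ON-to-OFF rate (1/s).
#' @return List of two [kinetic_class_spec()] objects.
#' @export
switchrate_pair_specs <- function(switch_rates = c(0.1, 2), duty = 0.2,
                                  k_off = 4) {
  stopifnot(length(switch_rates) == 2L, all(switch_rates > 0))
  lapply(seq_len(2L), function(i) {
    kinetic_class_spec(
      class_name = c("slow", "fast")[i],
      k_on = duty / (1 - duty) * k_off,
      k_off = k_off,
      k_bleach = 0,
      n_conf = 2L,
      conf_switch_rate = switch_rates[i],
      conf_on_multipliers = c(0.4, 2.5),
      conf_off_multipliers = c(2.5, 0.4),
      molecule_cv = 0)
  })
}
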