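# Shared fixtures, built lazily and cached for the duration of the run.
# All fixtures are generated in code with fixed seeds; nothing is stored
# on disk.

.fixture_env <- new.env(parent = emptyenv())

.cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# short-acquisition camera for fast tests
tiny_cam <- function(n_frames = 400L) {
  camera_config(n_frames = n_frames)
}

# compact architecture for fast training tests
tiny_arch <- function(k, gru_layers = 1L, conv_dropout = 0.2,
                      head_dropout = 0.2) {
  architecture_config(
    conv_blocks = list(c(8L, 9L, 4L), c(16L, 9L, 4L)),
    conv_dropout = conv_dropout, gru_layers = gru_layers,
    gru_units = 16L, dense_units = 16L, output_classes = k,
    head_dropout = head_dropout)
}

# small 4-class demo dataset (raw + normalized), 30 traces/class x 400
# frames
demo_small <- function() {
  .cached("demo_small", function() {
    raw <- simulate_dataset(demo_class_specs(), n_per_class = 30L,
                            cam = tiny_cam(), master_seed = 11L)
    list(raw = raw, norm = normalize_traces(raw))
  })
}

# two classes separable only in duty cycle (easy problem for training
# sanity checks): 0.05 vs 0.5
separable_pair <- function() {
  .cached("separable_pair", function() {
    # fast cycling and 40 s acquisitions make every trace's empirical
    # duty cycle concentrate tightly around its class value (0.05 vs
    # 0.5), so the pair is separable molecule by molecule
    specs <- list(
      kinetic_class_spec("sparse", k_on = 8 * 0.05 / 0.95, k_off = 8,
                         k_bleach = 0),
      kinetic_class_spec("dense", k_on = 4, k_off = 4, k_bleach = 0))
    raw <- simulate_dataset(specs, n_per_class = 60L,
                            cam = tiny_cam(800L), master_seed = 21L)
    normalize_traces(raw)
  })
}

# two classes identical in stationary statistics, differing only in the
# conformational switching rate (temporal structure only)
switchpair <- function() {
  .cached("switchpair", function() {
    # 80 s traces: enough conformational periods of the slow class for
    # its temporal structure to be statistically visible
    raw <- simulate_dataset(switchrate_pair_specs(), n_per_class = 100L,
                            cam = tiny_cam(1600L), master_seed = 31L)
    normalize_traces(raw)
  })
}

# same construction with both classes in the slow-switching (frozen)
# regime: observed per-trace feature marginals then coincide, which is
# the condition under which static features must fail
switchpair_slow <- function() {
  .cached("switchpair_slow", function() {
    raw <- simulate_dataset(
      switchrate_pair_specs(switch_rates = c(0.05, 0.5)),
      n_per_class = 100L, cam = tiny_cam(1600L), master_seed = 31L)
    normalize_traces(raw)
  })
}

# a small rendered movie with known ground truth
demo_movie <- function() {
  .cached("demo_movie", function() {
    specs <- demo_class_specs()
    raw <- simulate_dataset(specs, n_per_class = 5L,
                            cam = tiny_cam(300L), master_seed = 41L)
    cfg <- movie_config(width = 128L, height = 128L, min_separation = 8)
    stack <- render_movie(raw, cfg, rng_seed = 42L)
    list(traces = raw, stack = stack, cfg = cfg)
  })
}

# 99% binomial confidence half-width
binom_ci99 <- function(p, n) qnorm(0.995) * sqrt(p * (1 - p) / n)
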