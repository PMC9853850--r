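test_that("invalid kinetics specifications are rejected with the field named", {
  expect_error(kinetic_class_spec("x", k_on = -1, k_off = 1), "k_on")
  expect_error(kinetic_class_spec("x", k_on = 1, k_off = 0), "k_off")
  expect_error(kinetic_class_spec("x", k_on = 1, k_off = 1, n_conf = 0),
               "n_conf")
  expect_error(
    kinetic_class_spec("x", k_on = 1, k_off = 1, n_conf = 2,
                       conf_switch_rate = 0.5,
                       conf_on_multipliers = c(1, 2, 3)),
    "conf_on_multipliers")
  expect_error(
    kinetic_class_spec("x", k_on = 1, k_off = 1, n_conf = 2,
                       conf_switch_rate = 0),
    "conf_switch_rate")
  sp <- kinetic_class_spec("x", k_on = 1, k_off = 1)
  expect_error(simulate_state_trajectory(sp, duration = 0), "duration")
})

test_that("symmetric two-state switching spends half the time ON", {
  sp <- kinetic_class_spec("sym", k_on = 1, k_off = 1, k_bleach = 0)
  tr <- simulate_state_trajectory(sp, duration = 4000, rng_seed = 1)
  iv <- tr$intervals
  on_frac <- sum(iv$duration[iv$state == "ON"]) / 4000
  expect_lt(abs(on_frac - 0.5), 0.03)
})

test_that("dwell times follow the exponential law of the rates", {
  sp <- kinetic_class_spec("d", k_on = 5, k_off = 2, k_bleach = 0)
  on_d <- c(); off_d <- c()
  for (s in 1:4) {
    iv <- simulate_state_trajectory(sp, 2000, rng_seed = s)$intervals
    iv <- iv[-nrow(iv), ] # drop the right-censored final dwell
    on_d <- c(on_d, iv$duration[iv$state == "ON"])
    off_d <- c(off_d, iv$duration[iv$state == "OFF"])
  }
  expect_gt(length(on_d), 1e4)
  # sample mean of an exponential is its MLE; 3 standard errors
  expect_lt(abs(mean(on_d) - 1 / 2), 3 * sd(on_d) / sqrt(length(on_d)))
  expect_lt(abs(mean(off_d) - 1 / 5), 3 * sd(off_d) / sqrt(length(off_d)))
  # rate recovery within 10% relative error
  expect_lt(abs(1 / mean(on_d) - 2) / 2, 0.1)
  expect_lt(abs(1 / mean(off_d) - 5) / 5, 0.1)
})

test_that("trajectories tile the acquisition, alternate states, and stop at bleaching", {
  sp <- kinetic_class_spec("b", k_on = 1, k_off = 1, k_bleach = 0.5)
  for (s in 1:100) {
    tr <- simulate_state_trajectory(sp, 50, rng_seed = s)
    iv <- tr$intervals
    ends <- iv$start + iv$duration
    # contiguous tiling from 0
    expect_equal(iv$start[1], 0)
    if (nrow(iv) > 1) {
      expect_equal(iv$start[-1], ends[-nrow(iv)], tolerance = 1e-12)
      expect_true(all(iv$state[-1] != iv$state[-nrow(iv)]))
    }
    stop_at <- min(tr$bleach_time, tr$duration)
    expect_equal(ends[nrow(iv)], stop_at, tolerance = 1e-9)
    if (is.finite(tr$bleach_time)) {
      expect_true(all(ends <= tr$bleach_time + 1e-9))
      expect_identical(iv$state[nrow(iv)], "ON") # bleaching only from ON
    }
  }
})

test_that("bleach survival matches the ON-hazard exponential law", {
  kb <- 0.05
  sp <- kinetic_class_spec("s", k_on = 2, k_off = 2, k_bleach = kb)
  t_end <- 10
  n <- 400
  surv <- 0
  for (s in 1:n) {
    tr <- simulate_state_trajectory(sp, t_end, rng_seed = 1000 + s)
    surv <- surv + !is.finite(tr$bleach_time)
  }
  p_expect <- exp(-kb * 0.5 * t_end) # duty cycle 0.5, bleaching from ON
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(surv / n - p_expect), 3 * se)
})

test_that("identical seeds reproduce trajectories exactly", {
  sp <- demo_class_specs()[[2]]
  a <- simulate_state_trajectory(sp, 100, rng_seed = 99)
  b <- simulate_state_trajectory(sp, 100, rng_seed = 99)
  expect_identical(a, b)
})
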