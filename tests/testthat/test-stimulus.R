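test_that("dot fields honour the signal count and containment invariants", {
  set.seed(101)
  cases <- list(
    list(n = 400, coh = 50, expect_signal = 200L),
    list(n = 400, coh = 0, expect_signal = 0L),
    list(n = 100, coh = 33, expect_signal = 33L),
    list(n = 101, coh = 50, expect_signal = 51L), # half away from zero
    list(n = 300, coh = 100, expect_signal = 300L)
  )
  for (cs in cases) {
    p <- rdk_params(n_dots = cs$n, coherence_pct = cs$coh,
                    aperture = aperture(6, 6), n_frames = 6)
    trial <- generate_trial(p)
    for (f in trial) {
      expect_identical(sum(f$is_signal), cs$expect_signal)
      expect_true(all(abs(f$x) <= 3 + 1e-9 & abs(f$y) <= 3 + 1e-9))
      expect_length(f$x, cs$n)
      expect_length(f$age, cs$n)
    }
  }
})

test_that("signal dots move speed x frame_duration per transition and wrap", {
  p <- rdk_params(n_dots = 50, coherence_pct = 100, direction = "right",
                  speed_deg_per_s = 10.5, frame_duration_ms = 16.67,
                  dot_lifetime_frames = 5)
  step <- 10.5 * 16.67 / 1000
  expect_equal(step, 0.175035)
  set.seed(7)
  f1 <- fresh_field(p)
  f2 <- advance_frame(f1, p)
  dx <- f2$x - f1$x
  dx[dx < -3] <- dx[dx < -3] + 6 # unwrap
  expect_equal(dx, rep(step, 50), tolerance = 1e-12)
  expect_equal(f2$y, f1$y)

  # a dot near the right edge reappears near the left edge
  f1$x[1] <- 2.99
  f3 <- advance_frame(f1, p)
  expect_lt(f3$x[1], -2.8)
  expect_equal(f3$x[1], ((2.99 + step + 3) %% 6) - 3)
})

test_that("dot ages stay below the lifetime and reset on regeneration", {
  p <- rdk_params(n_dots = 200, coherence_pct = 50,
                  dot_lifetime_frames = 3, n_frames = 12, seed = 5)
  trial <- generate_trial(p)
  for (f in trial) {
    expect_true(all(f$age >= 0L & f$age < 3L))
  }
  # a dot at age 2 in frame t must be at age 0 in frame t+1
  for (t in seq_len(11)) {
    expiring <- trial[[t]]$age == 2L
    expect_true(all(trial[[t + 1]]$age[expiring] == 0L))
    expect_true(all(trial[[t + 1]]$age[!expiring] ==
                      trial[[t]]$age[!expiring] + 1L))
  }
})

test_that("trial generation is deterministic under a seed", {
  p <- rdk_params(n_dots = 120, coherence_pct = 40, seed = 123)
  t1 <- generate_trial(p)
  t2 <- generate_trial(p)
  expect_identical(t1, t2)
  expect_length(t1, p$n_frames)
  p1 <- rdk_params(n_dots = 10, n_frames = 1, seed = 1)
  expect_length(generate_trial(p1), 1L)
})

test_that("mean per-frame displacement scales with coherence", {
  # brute-force average over all surviving dots and frames
  step <- 10.5 * 16.67 / 1000
  mean_dx <- function(coh, n_trials = 100) {
    tot <- 0; cnt <- 0
    for (i in seq_len(n_trials)) {
      p <- rdk_params(n_dots = 200, coherence_pct = coh,
                      direction = "right", n_frames = 6,
                      dot_lifetime_frames = 2, seed = 9000 + i)
      tr <- generate_trial(p)
      for (t in seq_len(5)) {
        alive <- tr[[t + 1]]$age > 0L
        dx <- tr[[t + 1]]$x[alive] - tr[[t]]$x[alive]
        dx[dx > 3] <- dx[dx > 3] - 6
        dx[dx < -3] <- dx[dx < -3] + 6
        tot <- tot + sum(dx); cnt <- cnt + sum(alive)
      }
    }
    tot / cnt
  }
  for (coh in c(0, 25, 50, 100)) {
    # on the signal-proportion scale, to within 2 coherence points of MC noise
    expect_lt(abs(mean_dx(coh) / step - coh / 100), 0.02)
  }
})

test_that("printed dot densities are reproduced under the circular convention", {
  ap <- aperture(6, 6)
  expect_equal(round(compute_density(400, ap), 2), 14.15)
  expect_equal(round(compute_density(100, ap), 2), 3.54)
  expect_equal(compute_density(0, ap), 0)
  expect_equal(compute_density(400, ap, "literal_area"), 400 / 36)
})

test_that("prime sequences match their specification", {
  test_params <- rdk_presets("exp2_test")
  test_params$direction <- "right"
  test_params$seed <- 42

  same <- make_prime_sequence(prime_spec("coherent_same"), test_params)
  expect_length(same, 6L) # 96 ms at 16 ms/frame
  expect_true(all(same[[1]]$is_signal))
  expect_identical(attr(same, "params")$direction, "right")

  opp <- make_prime_sequence(prime_spec("coherent_opposite"), test_params)
  expect_identical(attr(opp, "params")$direction, "left")

  stat <- make_prime_sequence(prime_spec("stationary"), test_params)
  for (t in seq_along(stat)[-1]) {
    expect_identical(stat[[t]]$x, stat[[1]]$x)
    expect_identical(stat[[t]]$y, stat[[1]]$y)
  }

  expect_error(
    make_prime_sequence(prime_spec("coherent_same", duration_ms = 2),
                        test_params),
    "shorter than one animation frame")
})

test_that("parameter validation rejects impossible stimuli", {
  expect_error(rdk_params(n_dots = -5), "n_dots")
  expect_error(rdk_params(n_dots = 10, coherence_pct = 120), "coherence")
  expect_error(rdk_params(n_dots = 10, speed_deg_per_s = NaN), "speed")
  expect_error(aperture(-1), "width_deg")
})

test_that("trial export writes a faithful CSV manifest", {
  p <- rdk_params(n_dots = 20, coherence_pct = 50, n_frames = 3, seed = 8)
  trial <- generate_trial(p)
  dir <- withr::local_tempdir()
  paths <- export_stimulus(trial, dir)
  man <- utils::read.csv(paths[[1]])
  expect_equal(nrow(man), 20 * 3)
  expect_equal(man$x_deg[man$frame == 2], trial[[2]]$x)
  expect_equal(sum(man$is_signal), 3 * 10)
})
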