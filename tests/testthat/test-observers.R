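test_that("the psychometric function is anchored at the staircase equilibrium", {
  obs <- observer_params(alpha_pct = 30, beta = 3, lapse = 0)
  expect_equal(p_correct(30, obs), 0.5^(1 / 3), tolerance = 1e-12)
  expect_equal(p_correct(0, obs), 0.5)
  # the anchor holds at any alpha and slope
  for (a in c(5, 20, 47.09)) {
    for (b in c(1.5, 3, 5)) {
      o <- observer_params(a, beta = b, lapse = 0)
      expect_equal(p_correct(a, o), 0.5^(1 / 3), tolerance = 1e-12)
    }
  }
  # lapse ceiling: saturated accuracy approaches 1 - lapse from below
  lapsy <- observer_params(30, beta = 3, lapse = 0.02)
  expect_gte(p_correct(100, lapsy), 0.96)
  expect_lt(p_correct(100, lapsy), 0.98)
  expect_error(p_correct(150, obs), "coherence")
})

test_that("p_correct is monotone nondecreasing in coherence", {
  set.seed(21)
  grid <- seq(0, 100, by = 0.5)
  for (i in 1:25) {
    obs <- observer_params(alpha_pct = runif(1, 1, 90),
                           beta = runif(1, 0.5, 6),
                           lapse = runif(1, 0, 0.06))
    expect_true(all(diff(p_correct(grid, obs)) >= -1e-12))
  }
})

test_that("simulated responses match the psychometric function", {
  set.seed(31)
  obs <- observer_params(alpha_pct = 35, beta = 3, lapse = 0.01)
  n <- 10000
  for (coh in c(20, 35, 60)) {
    dirs <- ifelse(runif(n) < 0.5, "left", "right")
    hits <- vapply(dirs, function(d) respond(coh, d, obs) == d, logical(1))
    p <- p_correct(coh, obs)
    se <- sqrt(p * (1 - p) / n)
    expect_equal(mean(hits), p, tolerance = 3 * se / p + 1e-9)
  }
})

test_that("guessing at zero coherence follows the left-response bias", {
  set.seed(41)
  n <- 10000
  for (bias in c(0.5, 0.46)) {
    obs <- observer_params(alpha_pct = 30, bias_left = bias)
    lefts <- mean(replicate(n, respond(0, "right", obs) == "left"))
    expect_equal(lefts, bias, tolerance = 3 * sqrt(bias * (1 - bias) / n) / bias)
  }
})

test_that("prime shifts move alpha additively and preserve the condition order", {
  dys <- observer_params(20, group = "dyslexia")
  ctl <- observer_params(20, group = "control")
  s_dys <- prime_shifts(group = "dyslexia")
  s_ctl <- prime_shifts(group = "control")
  expect_equal(apply_prime_shift(dys, s_dys, "same")$alpha_pct, 32.63)
  expect_equal(apply_prime_shift(ctl, s_ctl, "opposite")$alpha_pct, 17.97)
  expect_equal(apply_prime_shift(dys, s_dys, "static")$alpha_pct, 20)
  for (s in list(s_dys, s_ctl)) {
    a <- vapply(c("same", "static", "opposite"), function(cond) {
      apply_prime_shift(dys, s, cond)$alpha_pct
    }, numeric(1))
    expect_true(a[["same"]] > a[["static"]] && a[["static"]] > a[["opposite"]])
  }
  # clamping keeps alpha in (0, 100]
  high <- observer_params(95, group = "dyslexia")
  expect_equal(apply_prime_shift(high, s_dys, "same")$alpha_pct, 100)
})

test_that("the undersampling observer reduces to a binomial vote counter", {
  # 5 dots, 1 signal, p_sample = 1, no internal noise, one transition:
  # total = 1 + sum of 4 independent +/-1 noise votes, so
  # P(respond right | rightward signal) = P(Binom(4, 1/2) >= 2) = 11/16
  # (an exact zero total is impossible because the sum is odd).
  set.seed(51)
  p <- rdk_params(n_dots = 5, coherence_pct = 20, direction = "right",
                  n_frames = 2, dot_lifetime_frames = 3)
  mech <- mechanistic_observer(p_sample = 1, internal_noise_sd = 0)
  n <- 5000
  hits <- replicate(n, {
    f1 <- fresh_field(p)
    f2 <- advance_frame(f1, p)
    mechanistic_respond(list(f1, f2), mech, p) == "right"
  })
  p_exact <- sum(stats::dbinom(2:4, 4, 0.5)) # 11/16
  expect_equal(p_exact, 11 / 16)
  expect_equal(mean(hits), p_exact,
               tolerance = 4 * sqrt(p_exact * (1 - p_exact) / n) / p_exact)
})

test_that("undersampling accuracy is deterministic-perfect in the noise-free coherent case", {
  set.seed(61)
  p <- rdk_params(n_dots = 50, coherence_pct = 100, direction = "left",
                  n_frames = 5, dot_lifetime_frames = 6)
  mech <- mechanistic_observer(p_sample = 1, internal_noise_sd = 0)
  for (i in 1:20) {
    expect_identical(mechanistic_respond(generate_trial(p), mech, p), "left")
  }
  expect_error(mechanistic_respond(list(make_dot_field(p)), mech, p),
               "at least 2 frames")
})

test_that("undersampling accuracy rises with p_sample and integration", {
  set.seed(71)
  stim <- rdk_presets("exp1_high_density")
  acc <- function(p_sample, n_frames, coh = 15, n = 350) {
    s <- stim; s$n_frames <- n_frames
    mech <- mechanistic_observer(p_sample = p_sample, internal_noise_sd = 40)
    mean(replicate(n, {
      d <- if (runif(1) < 0.5) "left" else "right"
      respond_trial(mech, coh, d, s) == d
    }))
  }
  by_p <- vapply(c(0.02, 0.1, 0.4), acc, numeric(1), n_frames = 8)
  expect_true(all(diff(by_p) > -0.03)) # monotone up to MC noise
  expect_gt(by_p[3], by_p[1] + 0.1)
  by_frames <- vapply(c(3, 6, 10), function(f) acc(0.1, f), numeric(1))
  expect_true(all(diff(by_frames) > -0.03))
  expect_gt(by_frames[3], by_frames[1] + 0.05)
})

test_that("cohorts reproduce their specified group structure", {
  spec0 <- cohort_spec(n_per_group = 4,
                       alpha_sd = c(control = 0, dyslexia = 0))
  cohort <- draw_cohort(spec0, seed = 3)
  expect_equal(nrow(cohort), 8)
  expect_equal(cohort$alpha_pct[cohort$group == "control"], rep(32.74, 4))
  expect_equal(cohort$alpha_pct[cohort$group == "dyslexia"], rep(47.09, 4))

  big <- draw_cohort(cohort_spec(n_per_group = 10000), seed = 4)
  for (g in c("control", "dyslexia")) {
    m <- mean(big$alpha_pct[big$group == g])
    target <- cohort_spec()$alpha_mean[[g]]
    expect_equal(m, target, tolerance = 0.01)
  }
  # reproducible under seed
  expect_identical(draw_cohort(spec0, seed = 3), cohort)
})
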