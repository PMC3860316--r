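test_that("the three-down/one-up update halves, doubles, clamps and logs reversals", {
  cfg <- staircase_config()
  s <- staircase_new(cfg)
  expect_equal(s$coherence_pct, 50)

  # two corrects leave coherence alone; the third halves it
  s <- staircase_update(s, TRUE, cfg)
  s <- staircase_update(s, TRUE, cfg)
  expect_equal(s$coherence_pct, 50)
  expect_equal(s$consecutive_correct, 2L)
  s <- staircase_update(s, TRUE, cfg)
  expect_equal(s$coherence_pct, 25)
  expect_equal(s$consecutive_correct, 0L)

  # an error doubles and logs a reversal at the pre-step value (25)
  s <- staircase_update(s, FALSE, cfg)
  expect_equal(s$coherence_pct, 50)
  expect_equal(s$reversals, 25)

  # doubling clamps at the cap and still counts toward reversal logic
  s2 <- staircase_new(cfg)
  s2$coherence_pct <- 60
  s2 <- staircase_update(s2, FALSE, cfg)
  expect_equal(s2$coherence_pct, 100)
  # ... and halving clamps at the floor
  cfg_floor <- staircase_config(coherence_floor_pct = 10)
  s3 <- staircase_new(cfg_floor)
  s3$coherence_pct <- 15
  for (i in 1:3) s3 <- staircase_update(s3, TRUE, cfg_floor)
  expect_equal(s3$coherence_pct, 10)
})

test_that("an error run pins coherence at the cap", {
  cfg <- staircase_config()
  s <- staircase_new(cfg)
  for (i in 1:10) s <- staircase_update(s, FALSE, cfg)
  expect_equal(s$coherence_pct, 100)
  expect_length(s$reversals, 0)
})

test_that("a perfect observer descends deterministically without reversals", {
  cfg <- exp1_cfg(max_trials = 60)
  block <- run_block(perfect_observer(), cfg = cfg, seed = 2)
  nc <- block$trials[!block$trials$is_catch, ]
  expect_true(all(nc$correct))
  # coherence sequence 50, 50, 50, 25, 25, 25, 12.5, ...
  expected <- 50 * 0.5^((seq_len(nrow(nc)) - 1) %/% 3)
  expect_equal(nc$coherence_pct, pmax(expected, cfg$coherence_floor_pct))
  expect_false(block$converged)
  expect_length(block$state$reversals, 0)
})

test_that("geometric-mean threshold estimation matches hand-computed values", {
  expect_equal(estimate_threshold(rep(c(40, 20), 4)), sqrt(800),
               tolerance = 1e-12)
  expect_equal(round(estimate_threshold(rep(c(40, 20), 4)), 2), 28.28)
  expect_equal(estimate_threshold(rep(7, 6)), 7)
  expect_equal(combine_thresholds(30, 40), sqrt(1200), tolerance = 1e-12)
  expect_equal(round(combine_thresholds(30, 40), 2), 34.64)
  expect_equal(estimate_threshold(c(10, 20, 40), discard_first_k = 1),
               sqrt(800))
  expect_error(estimate_threshold(numeric(0)), "empty")
  expect_error(estimate_threshold(c(10, 20), discard_first_k = 2),
               "no reversals")
})

test_that("response bias is the percentage of left catch responses", {
  log <- tibble::tibble(
    response = c(rep("left", 23), rep("right", 27), "left"),
    is_catch = c(rep(TRUE, 50), FALSE))
  expect_equal(response_bias(log), 46)
  log$response[log$is_catch] <- "right"
  expect_equal(response_bias(log), 0)
  expect_error(response_bias(tibble::tibble(response = "left",
                                            is_catch = FALSE)),
               "no catch trials")
})

test_that("every complete five-trial window contains a catch trial", {
  set.seed(12)
  obs <- observer_params(30)
  for (i in 1:10) {
    block <- run_block(obs, cfg = exp1_cfg())
    tr <- block$trials
    n_windows <- nrow(tr) %/% 5
    for (w in seq_len(n_windows)) {
      idx <- ((w - 1) * 5 + 1):(w * 5)
      expect_equal(sum(tr$is_catch[idx]), 1L)
      expect_equal(unique(tr$coherence_pct[idx][tr$is_catch[idx]]), 1)
    }
  }
})

test_that("catch trials never touch the staircase track", {
  # replaying only the non-catch responses through the bare update rule
  # reconstructs the block's final state exactly
  set.seed(13)
  cfg <- exp1_cfg()
  block <- run_block(observer_params(25), cfg = cfg)
  s <- staircase_new(cfg)
  nc <- block$trials[!block$trials$is_catch, ]
  for (i in seq_len(nrow(nc))) {
    expect_equal(nc$coherence_pct[i], s$coherence_pct)
    s <- staircase_update(s, nc$correct[i], cfg)
  }
  expect_equal(s$reversals, block$state$reversals)
  expect_equal(s$coherence_pct, block$state$coherence_pct)
})

test_that("blocks converge near the 79% equilibrium for a range of slopes", {
  set.seed(14)
  for (b in c(1.5, 3, 5)) {
    accs <- replicate(120, {
      bl <- run_block(observer_params(30, beta = b), cfg = exp1_cfg())
      nc <- bl$trials[!bl$trials$is_catch, ]
      mean(utils::tail(nc$correct, 20))
    })
    expect_gte(mean(accs), 0.76)
    expect_lte(mean(accs), 0.82)
  }
})

test_that("larger true thresholds yield stochastically larger estimates", {
  set.seed(15)
  alphas <- runif(60, 10, 70)
  ests <- vapply(alphas, function(a) {
    run_block(observer_params(a), cfg = exp1_cfg())$threshold_pct
  }, numeric(1))
  expect_gt(cor(alphas, ests, method = "spearman"), 0.5)
})

test_that("blocks are reproducible under a seed and flag non-convergence", {
  obs <- observer_params(30)
  b1 <- run_block(obs, cfg = exp1_cfg(), seed = 77)
  b2 <- run_block(obs, cfg = exp1_cfg(), seed = 77)
  expect_identical(b1$trials, b2$trials)
  expect_identical(b1$threshold_pct, b2$threshold_pct)
  short <- run_block(perfect_observer(), cfg = exp1_cfg(max_trials = 30),
                     seed = 1)
  expect_false(short$converged)
})
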