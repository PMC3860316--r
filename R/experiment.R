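# Experiment drivers: factorial density x frames paradigm (experiment 1)
# and coherent-prime contrast paradigm (experiment 2), plus summaries.

exp1_condition_table <- function() {
  tibble::tibble(
    condition = c("low_5", "low_8", "high_5", "high_8"),
    density = c("low", "low", "high", "high"),
    frames = c(5L, 8L, 5L, 8L))
}

# Per-condition additive offsets (coherence points) around the group
# marginal mean. Calibrated so that: the four-condition average is the
# printed marginal mean; the 5-minus-8-frame reduction at high density is
# the printed temporal-recruitment value r (7.5 dyslexia / 6.1 control);
# the reduction at low density is 0; and the density simple effect is 0 at
# 5 frames and r at 8 frames (matching the reported simple-effects
# pattern). Those constraints give (+r/4, +r/4, +r/4, -3r/4).
exp1_offsets <- function(group) {
  r <- switch(group, dyslexia = 7.5, control = 6.1)
  c(low_5 = r / 4, low_8 = r / 4, high_5 = r / 4, high_8 = -3 * r / 4)
}

# Cyclic Latin square: row i gives participant i's condition order.
latin_square_orders <- function(k, n) {
  t(vapply(seq_len(n), function(i) {
    (seq_len(k) + (i - 1L)) %% k + 1L
  }, integer(k)))
}

#' Run the dot-density x animation-frames experiment
#'
#' Each participant completes two staircase blocks (start 50%, 8
#' reversals) in each of the four conditions (low/high density x 5/8
#' frames), in a Latin-square counterbalanced order. With the
#' `"psychometric"` observer model, each participant's per-condition alpha
#' is their baseline alpha plus the calibrated condition offset; with the
#' `"mechanistic"` model the observer reads actual dot frames and
#' condition effects emerge from the stimulus alone.
#'
#' @param cohort A [cohort_spec()] (defaults to the calibrated groups).
#' @param seed Master seed; every block seed is derived from it and logged.
#' @param observer_model `"psychometric"` or `"mechanistic"`.
#' @param mech Named list of [mechanistic_observer()]s per group (only for
#'   the mechanistic model).
#' @return A tibble of class `experiment_result` (one row per participant
#'   x condition): `id`, `group`, `condition`, `density`, `frames`,
#'   `order_position`, `alpha_true_pct`, `block1_pct`, `block2_pct`,
#'   `combined_pct`, `response_bias_pct`, `converged`, `seed_block1`,
#'   `seed_block2`. The full per-trial log is in `attr(result, "trials")`.
#' @export
run_experiment1 <- function(cohort = default_cohort("exp1"), seed = NULL,
                            observer_model = c("psychometric", "mechanistic"),
                            mech = list(
                              control = mechanistic_observer(p_sample = 0.1),
                              dyslexia = mechanistic_observer(p_sample = 0.05))) {
  observer_model <- match.arg(observer_model)
  stopifnot(inherits(cohort, "cohort_spec"))
  with_seed(seed, {
    participants <- draw_cohort(cohort)
    conditions <- exp1_condition_table()
    orders <- latin_square_orders(nrow(conditions), nrow(participants))
    cfg <- staircase_config(start_coherence_pct = 50, n_reversals = 8)
    presets <- rdk_presets()
    rows <- list(); trial_logs <- list()
    for (i in seq_len(nrow(participants))) {
      p <- participants[i, ]
      for (pos in seq_len(nrow(conditions))) {
        cond <- conditions[orders[i, pos], ]
        stim <- presets[[paste0("exp1_", cond$density, "_density")]]
        stim$n_frames <- cond$frames
        obs <- if (observer_model == "psychometric") {
          o <- p$observer[[1L]]
          off <- exp1_offsets(p$group)[[cond$condition]]
          o$alpha_pct <- min(100, max(0.5, o$alpha_pct + off))
          o
        } else {
          mech[[p$group]]
        }
        s1 <- next_seed(); s2 <- next_seed()
        b1 <- run_block(obs, stim, cfg, seed = s1)
        b2 <- run_block(obs, stim, cfg, seed = s2)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = p$id, group = p$group, condition = cond$condition,
          density = cond$density, frames = cond$frames,
          order_position = pos, alpha_true_pct = p$alpha_pct,
          block1_pct = b1$threshold_pct, block2_pct = b2$threshold_pct,
          combined_pct = combine_thresholds(b1$threshold_pct,
                                            b2$threshold_pct),
          response_bias_pct = response_bias(
            dplyr::bind_rows(b1$trials, b2$trials)),
          converged = b1$converged && b2$converged,
          seed_block1 = s1, seed_block2 = s2)
        trial_logs[[length(trial_logs) + 1L]] <- dplyr::bind_rows(
          dplyr::mutate(b1$trials, block = 1L),
          dplyr::mutate(b2$trials, block = 2L)) |>
          dplyr::mutate(id = p$id, group = p$group,
                        condition = cond$condition)
      }
    }
    result <- dplyr::bind_rows(rows)
    attr(result, "trials") <- dplyr::bind_rows(trial_logs)
    attr(result, "experiment") <- "exp1"
    class(result) <- c("experiment_result", class(result))
    result
  })
}

#' Run the coherent-prime (motion segmentation) experiment
#'
#' Each participant completes two staircase blocks (start 25%, 6
#' reversals) in each prime condition (`same`, `opposite`, `static`), in a
#' per-participant random order. With the psychometric observer model the
#' prime condition shifts the participant's alpha additively via
#' [apply_prime_shift()] (static = baseline); with the mechanistic model a
#' 100%-coherent (or stationary) prime sequence is generated before each
#' 10-frame test.
#'
#' @inheritParams run_experiment1
#' @return An `experiment_result` tibble with `condition` in
#'   `c("same", "opposite", "static")` and the same threshold columns as
#'   [run_experiment1()].
#' @export
run_experiment2 <- function(cohort = default_cohort("exp2"), seed = NULL,
                            observer_model = c("psychometric", "mechanistic"),
                            mech = list(
                              control = mechanistic_observer(p_sample = 0.1),
                              dyslexia = mechanistic_observer(p_sample = 0.05))) {
  observer_model <- match.arg(observer_model)
  stopifnot(inherits(cohort, "cohort_spec"))
  with_seed(seed, {
    participants <- draw_cohort(cohort)
    conditions <- c("same", "opposite", "static")
    cfg <- staircase_config(start_coherence_pct = 25, n_reversals = 6)
    stim <- rdk_presets("exp2_test")
    primes <- list(same = rdk_presets("exp2_prime_same"),
                   opposite = rdk_presets("exp2_prime_opposite"),
                   static = rdk_presets("exp2_prime_static"))
    rows <- list(); trial_logs <- list()
    for (i in seq_len(nrow(participants))) {
      p <- participants[i, ]
      order <- sample(conditions)
      for (pos in seq_along(order)) {
        cond <- order[pos]
        obs <- if (observer_model == "psychometric") {
          apply_prime_shift(p$observer[[1L]],
                            default_cohort_shifts(cohort, p$group), cond)
        } else {
          mech[[p$group]]
        }
        s1 <- next_seed(); s2 <- next_seed()
        b1 <- run_block(obs, stim, cfg, prime = primes[[cond]], seed = s1)
        b2 <- run_block(obs, stim, cfg, prime = primes[[cond]], seed = s2)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = p$id, group = p$group, condition = cond,
          order_position = pos, alpha_true_pct = p$alpha_pct,
          block1_pct = b1$threshold_pct, block2_pct = b2$threshold_pct,
          combined_pct = combine_thresholds(b1$threshold_pct,
                                            b2$threshold_pct),
          response_bias_pct = response_bias(
            dplyr::bind_rows(b1$trials, b2$trials)),
          converged = b1$converged && b2$converged,
          seed_block1 = s1, seed_block2 = s2)
        trial_logs[[length(trial_logs) + 1L]] <- dplyr::bind_rows(
          dplyr::mutate(b1$trials, block = 1L),
          dplyr::mutate(b2$trials, block = 2L)) |>
          dplyr::mutate(id = p$id, group = p$group, condition = cond)
      }
    }
    result <- dplyr::bind_rows(rows)
    attr(result, "trials") <- dplyr::bind_rows(trial_logs)
    attr(result, "experiment") <- "exp2"
    class(result) <- c("experiment_result", class(result))
    result
  })
}

default_cohort_shifts <- function(cohort, group) {
  s <- cohort$shifts[[group]]
  if (is.null(s)) prime_shifts(group = group) else s
}

#' Summarise an experiment result
#'
#' Per group x condition: n, mean, SD and t-based 95% CI of the combined
#' thresholds. For the density/frames experiment, adds the
#' temporal-recruitment reduction (5-frame mean minus 8-frame mean, in
#' coherence points, per group x density). For the priming experiment,
#' adds within-participant difference scores (`same - static`,
#' `opposite - static`) averaged per group.
#'
#' @param result An `experiment_result`.
#' @param conf_level Confidence level of the CIs.
#' @return A list of class `threshold_summary` with elements `cells` and,
#'   depending on the experiment, `recruitment` or `prime_effects`.
#' @export
summarize_thresholds <- function(result, conf_level = 0.95) {
  stopifnot(inherits(result, "experiment_result"))
  cells <- result |>
    dplyr::group_by(group, condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pct = mean(combined_pct),
      sd_pct = stats::sd(combined_pct),
      .groups = "drop")
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, pmax(cells$n - 1, 1))
  half <- ifelse(cells$n > 1, tcrit * cells$sd_pct / sqrt(cells$n), 0)
  cells$ci_lo_pct <- cells$mean_pct - half
  cells$ci_hi_pct <- cells$mean_pct + half

  out <- list(cells = cells, experiment = attr(result, "experiment"))
  if (identical(attr(result, "experiment"), "exp1")) {
    out$recruitment <- result |>
      dplyr::group_by(group, density, id) |>
      dplyr::summarise(
        reduction_pct = combined_pct[frames == 5L] -
          combined_pct[frames == 8L],
        .groups = "drop") |>
      dplyr::group_by(group, density) |>
      dplyr::summarise(mean_reduction_pct = mean(reduction_pct),
                       sd_reduction_pct = stats::sd(reduction_pct),
                       .groups = "drop")
  } else if (identical(attr(result, "experiment"), "exp2")) {
    per_participant <- result |>
      dplyr::select(id, group, condition, combined_pct) |>
      tidyr_pivot(condition, combined_pct)
    diffs <- per_participant |>
      dplyr::mutate(delta_same_pct = same - static,
                    delta_opposite_pct = opposite - static)
    out$prime_effects <- diffs |>
      dplyr::group_by(group) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_delta_same_pct = mean(delta_same_pct),
        sd_delta_same_pct = stats::sd(delta_same_pct),
        mean_delta_opposite_pct = mean(delta_opposite_pct),
        sd_delta_opposite_pct = stats::sd(delta_opposite_pct),
        .groups = "drop")
    out$per_participant_deltas <- diffs
  }
  class(out) <- "threshold_summary"
  out
}

# Minimal wide pivot (id, group kept; one column per condition) without a
# tidyr dependency.
tidyr_pivot <- function(df, key, value) {
  key <- deparse(substitute(key)); value <- deparse(substitute(value))
  keys <- unique(df[[key]])
  base <- unique(df[, c("id", "group")])
  for (k in keys) {
    sub <- df[df[[key]] == k, c("id", value)]
    names(sub)[2] <- k
    base <- dplyr::left_join(base, sub, by = "id")
  }
  tibble::as_tibble(base)
}

#' @export
print.threshold_summary <- function(x, ...) {
  cat(sprintf("<threshold_summary> %s\n", x$experiment))
  print(x$cells)
  if (!is.null(x$recruitment)) {
    cat("\nTemporal recruitment (5-frame mean - 8-frame mean, points):\n")
    print(x$recruitment)
  }
  if (!is.null(x$prime_effects)) {
    cat("\nPrime difference scores (points, within participant):\n")
    print(x$prime_effects)
  }
  invisible(x)
}

#' Paired mechanistic temporal-recruitment simulation
#'
#' Runs the undersampling observer through one staircase block per frame
#' count (5 vs 8) at each dot density, with paired simulated participants,
#' and returns the per-pair thresholds. Used to probe whether the
#' capacity-limited observer reproduces density-dependent temporal
#' recruitment.
#'
#' @param n_pairs Simulated participants per density.
#' @param mech A [mechanistic_observer()].
#' @param densities Character subset of `c("high", "low")`.
#' @param seed Optional master seed.
#' @return A tibble: `sim`, `density`, `frames`, `threshold_pct`.
#' @export
simulate_recruitment <- function(n_pairs = 100,
                                 mech = mechanistic_observer(),
                                 densities = c("high", "low"),
                                 seed = NULL) {
  densities <- match.arg(densities, several.ok = TRUE)
  cfg <- staircase_config(start_coherence_pct = 50, n_reversals = 8)
  presets <- rdk_presets()
  with_seed(seed, {
    rows <- list()
    for (d in densities) {
      stim <- presets[[paste0("exp1_", d, "_density")]]
      for (i in seq_len(n_pairs)) {
        for (f in c(5L, 8L)) {
          stim$n_frames <- f
          b <- run_block(mech, stim, cfg, seed = next_seed())
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sim = i, density = d, frames = f,
            threshold_pct = b$threshold_pct)
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Threshold-by-condition figure
#'
#' @param result An `experiment_result`.
#' @return A ggplot: group means with 95% CIs per condition.
#' @export
plot_thresholds <- function(result) {
  s <- summarize_thresholds(result)
  ggplot2::ggplot(s$cells,
                  ggplot2::aes(x = condition, y = mean_pct,
                               colour = group, group = group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = ci_lo_pct, ymax = ci_hi_pct),
      width = 0.15, position = ggplot2::position_dodge(0.3)) +
    ggplot2::labs(x = "condition", y = "coherence threshold (%)",
                  colour = "group") +
    ggplot2::theme_minimal()
}
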