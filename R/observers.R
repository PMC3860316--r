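# Synthetic observers.
#
# Two layers, deliberately distinct:
#  * a descriptive psychometric observer (Weibull 2AFC with guess floor 0.5
#    and a lapse ceiling), whose threshold parameter alpha is the coherence
#    yielding 79.4% correct — the equilibrium of the three-down/one-up
#    staircase (0.5^(1/3));
#  * a mechanistic "undersampling" observer that reads actual dot frames,
#    registering each surviving dot's horizontal displacement sign with
#    probability p_sample and deciding by the sign of the noisy vote total.
# The descriptive layer carries the group calibration; the mechanistic layer
# embodies the capacity-limited-sampling hypothesis. The pipeline never
# infers mechanism from the descriptive layer.

# Weibull scale constant: F(alpha) must equal 2*(0.5^(1/3) - 0.5) so that
# 0.5 + 0.5*F(alpha) = 0.5^(1/3) (~0.7937) at lapse 0.
.weibull_k <- -log(1 - 2 * (0.5^(1 / 3) - 0.5))

#' Psychometric observer parameters
#'
#' @param alpha_pct Coherence (percent, in (0, 100\]) at which the observer
#'   is 79.4% correct with no lapses — the three-down/one-up staircase
#'   convergence level.
#' @param beta Weibull slope (> 0, dimensionless).
#' @param lapse Lapse probability in \[0, 0.06\]; accuracy saturates at
#'   `1 - lapse`.
#' @param bias_left Probability of responding "left" when guessing.
#' @param group `"control"` or `"dyslexia"` (bookkeeping label).
#' @return An object of class `psychometric_observer` (also `observer`).
#' @export
observer_params <- function(alpha_pct, beta = 3, lapse = 0.01,
                            bias_left = 0.5,
                            group = c("control", "dyslexia")) {
  group <- match.arg(group)
  if (!is.numeric(alpha_pct) || length(alpha_pct) != 1L || is.na(alpha_pct) ||
      alpha_pct <= 0 || alpha_pct > 100) {
    stop("`alpha_pct` must be in (0, 100]", call. = FALSE)
  }
  check_positive(beta, "beta")
  check_prob(lapse, "lapse")
  if (lapse > 0.06) stop("`lapse` must be <= 0.06", call. = FALSE)
  check_prob(bias_left, "bias_left")
  structure(
    list(alpha_pct = alpha_pct, beta = beta, lapse = lapse,
         bias_left = bias_left, group = group),
    class = c("psychometric_observer", "observer"))
}

#' @export
print.psychometric_observer <- function(x, ...) {
  cat(sprintf(
    "<psychometric_observer> alpha = %.4g%%, beta = %.3g, lapse = %.3g, bias_left = %.3g (%s)\n",
    x$alpha_pct, x$beta, x$lapse, x$bias_left, x$group))
  invisible(x)
}

# Probability that the observer "sees" the direction (0 at coherence 0,
# saturating at 1 - 2*lapse).
p_see <- function(coherence_pct, obs) {
  lambda <- obs$alpha_pct * .weibull_k^(-1 / obs$beta)
  (1 - 2 * obs$lapse) * (1 - exp(-(coherence_pct / lambda)^obs$beta))
}

#' Probability of a correct 2AFC direction response
#'
#' A Weibull psychometric function with guess floor 0.5 and ceiling
#' `1 - lapse`, anchored so that `p_correct(alpha_pct)` is 0.794
#' (= 0.5^(1/3), the three-down/one-up equilibrium) when `lapse = 0`.
#'
#' @param coherence_pct Coherence percent in \[0, 100\]; vectorised.
#' @param obs An [observer_params()].
#' @return Probability of a correct response (assuming unbiased guessing).
#' @examples
#' obs <- observer_params(alpha_pct = 30, lapse = 0)
#' p_correct(30, obs) # 0.794
#' @export
p_correct <- function(coherence_pct, obs) {
  stopifnot(inherits(obs, "psychometric_observer"))
  if (any(is.na(coherence_pct)) || any(coherence_pct < 0) ||
      any(coherence_pct > 100)) {
    stop("`coherence_pct` must be in [0, 100]", call. = FALSE)
  }
  0.5 + p_see(coherence_pct, obs) / 2
}

#' Simulate one direction response
#'
#' With probability `(1 - 2 * lapse) * F(coherence)` the observer sees the
#' direction and responds correctly; otherwise it guesses, responding
#' "left" with probability `bias_left`. At `bias_left = 0.5` the accuracy
#' equals [p_correct()] exactly, and as coherence tends to 0 the left-response
#' rate tends to `bias_left` (the quantity the catch trials estimate).
#'
#' @param coherence_pct Coherence percent in \[0, 100\].
#' @param direction True stimulus direction, `"left"` or `"right"`.
#' @param obs An [observer_params()].
#' @return `"left"` or `"right"`.
#' @export
respond <- function(coherence_pct, direction, obs) {
  stopifnot(direction %in% c("left", "right"))
  if (stats::runif(1) < p_see(coherence_pct, obs)) {
    direction
  } else if (stats::runif(1) < obs$bias_left) "left" else "right"
}

#' Additive prime-induced threshold shifts
#'
#' Condition effects of the coherent prime, in coherence points added to
#' the observer's alpha: positive for a same-direction prime (threshold
#' elevation), negative for an opposite-direction prime (facilitation),
#' zero by definition for the stationary baseline. Group defaults are the
#' calibrated mean difference scores: +12.63 / -2.76 points for the
#' dyslexia group and +7.87 / -2.03 for controls.
#'
#' @param delta_same_pct,delta_opposite_pct Shifts in coherence points.
#' @param group When given and the deltas are missing, fills in the group
#'   calibration defaults.
#' @return An object of class `prime_shifts`.
#' @export
prime_shifts <- function(delta_same_pct, delta_opposite_pct, group = NULL) {
  if (!is.null(group)) {
    group <- match.arg(group, c("control", "dyslexia"))
    defaults <- switch(group,
      dyslexia = c(same = 12.63, opposite = -2.76),
      control  = c(same = 7.87,  opposite = -2.03))
    if (missing(delta_same_pct)) delta_same_pct <- defaults[["same"]]
    if (missing(delta_opposite_pct)) {
      delta_opposite_pct <- defaults[["opposite"]]
    }
  }
  stopifnot(is.numeric(delta_same_pct), is.numeric(delta_opposite_pct))
  structure(list(delta_same_pct = delta_same_pct,
                 delta_opposite_pct = delta_opposite_pct,
                 delta_static_pct = 0),
            class = "prime_shifts")
}

#' Apply a prime condition to an observer
#'
#' Returns a copy of the observer whose alpha is shifted by the condition's
#' delta, clamped to (0, 100\].
#'
#' @param obs An [observer_params()].
#' @param shifts A [prime_shifts()].
#' @param condition `"same"`, `"opposite"`, or `"static"`.
#' @param floor_pct Lower clamp for the shifted alpha.
#' @return A shifted `psychometric_observer`.
#' @examples
#' obs <- observer_params(20, group = "dyslexia")
#' apply_prime_shift(obs, prime_shifts(group = "dyslexia"), "same")$alpha_pct # 32.63
#' @export
apply_prime_shift <- function(obs, shifts,
                              condition = c("same", "opposite", "static"),
                              floor_pct = 0.1) {
  condition <- match.arg(condition)
  stopifnot(inherits(obs, "psychometric_observer"),
            inherits(shifts, "prime_shifts"))
  delta <- switch(condition,
                  same = shifts$delta_same_pct,
                  opposite = shifts$delta_opposite_pct,
                  static = shifts$delta_static_pct)
  obs$alpha_pct <- min(100, max(floor_pct, obs$alpha_pct + delta))
  obs
}

#' Mechanistic undersampling observer
#'
#' Reads dot frames directly. For every frame transition and every dot that
#' survives it (age > 0 on the later frame, so its displacement is a real
#' motion signal rather than a regeneration), the observer registers the
#' sign of the dot's horizontal displacement as a +1/-1 vote with
#' probability `p_sample` — the capacity limit. Votes are pooled over up to
#' `integration_frames` transitions, zero-mean Gaussian internal noise is
#' added, and the response is the sign of the total (a guess on an exact
#' zero). Lower `p_sample` models a dyslexia-like observer that
#' undersamples the available motion signals.
#'
#' Defaults place the high-density 8-frame threshold of the density/frames
#' paradigm in the human range (roughly 25–45% coherence); see the package
#' vignette for the calibration reasoning.
#'
#' @param p_sample Per-dot, per-transition sampling probability in \[0, 1\].
#' @param internal_noise_sd SD (in votes) of the internal noise added to
#'   the pooled total.
#' @param integration_frames Maximum number of transitions pooled
#'   (`Inf` = all available).
#' @param bias_left Guess bias on a zero total.
#' @return An object of class `mechanistic_observer` (also `observer`).
#' @export
mechanistic_observer <- function(p_sample = 0.1, internal_noise_sd = 40,
                                 integration_frames = Inf, bias_left = 0.5) {
  check_prob(p_sample, "p_sample")
  check_positive(internal_noise_sd, "internal_noise_sd", strict = FALSE)
  stopifnot(integration_frames >= 1)
  check_prob(bias_left, "bias_left")
  structure(list(p_sample = p_sample, internal_noise_sd = internal_noise_sd,
                 integration_frames = integration_frames,
                 bias_left = bias_left),
            class = c("mechanistic_observer", "observer"))
}

#' @export
print.mechanistic_observer <- function(x, ...) {
  cat(sprintf(
    "<mechanistic_observer> p_sample = %.3g, internal noise sd = %.3g votes, integrates %s transitions\n",
    x$p_sample, x$internal_noise_sd,
    if (is.infinite(x$integration_frames)) "all" else x$integration_frames))
  invisible(x)
}

# Horizontal displacement of surviving dots across one transition,
# unwrapped on the aperture width.
transition_dx <- function(from, to, params) {
  alive <- to$age > 0L
  dx <- to$x[alive] - from$x[alive]
  w <- params$aperture$width_deg
  dx[dx > w / 2] <- dx[dx > w / 2] - w
  dx[dx < -w / 2] <- dx[dx < -w / 2] + w
  dx
}

#' Direction response of the undersampling observer
#'
#' @param frames A `dot_trial` (or plain list of `dot_field`s) with at
#'   least 2 frames.
#' @param mech A [mechanistic_observer()].
#' @param params The generating [rdk_params()]; defaults to the `params`
#'   attribute of `frames`.
#' @return `"left"` or `"right"`.
#' @export
mechanistic_respond <- function(frames, mech, params = attr(frames, "params")) {
  stopifnot(inherits(mech, "mechanistic_observer"))
  if (length(frames) < 2L) {
    stop("the undersampling observer needs at least 2 frames", call. = FALSE)
  }
  stopifnot(inherits(params, "rdk_params"))
  n_trans <- min(length(frames) - 1L, mech$integration_frames)
  total <- 0
  for (t in seq_len(n_trans)) {
    dx <- transition_dx(frames[[t]], frames[[t + 1L]], params)
    if (length(dx)) {
      sampled <- stats::runif(length(dx)) < mech$p_sample
      total <- total + sum(sign(dx[sampled]))
    }
  }
  if (mech$internal_noise_sd > 0) {
    total <- total + stats::rnorm(1, 0, mech$internal_noise_sd)
  }
  if (total > 0) "right"
  else if (total < 0) "left"
  else if (stats::runif(1) < mech$bias_left) "left" else "right"
}

#' Cohort specification
#'
#' Describes a synthetic participant group pair: per-group mean and SD of
#' alpha (alphas are log-normal across subjects, so thresholds stay
#' positive and right-skewed as empirical threshold distributions are),
#' shared slope/lapse/bias, and per-group prime shifts. The default
#' calibration uses the density/frames study's marginal group means
#' (control 32.74%, dyslexia 47.09%) and SDs implied by their printed 95%
#' CIs; `default_cohort("exp2")` switches to the priming study's scale.
#'
#' @param n_per_group Participants per group (>= 1).
#' @param alpha_mean,alpha_sd Named numeric vectors with elements
#'   `control` and `dyslexia` (percent coherence points).
#' @param beta,lapse,bias_left Shared psychometric parameters.
#' @param shifts Named list of [prime_shifts()] per group.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10,
                        alpha_mean = c(control = 32.74, dyslexia = 47.09),
                        alpha_sd = c(control = 11.5, dyslexia = 11.2),
                        beta = 3, lapse = 0.01, bias_left = 0.5,
                        shifts = list(
                          control = prime_shifts(group = "control"),
                          dyslexia = prime_shifts(group = "dyslexia"))) {
  stopifnot(n_per_group >= 1, n_per_group == round(n_per_group),
            all(c("control", "dyslexia") %in% names(alpha_mean)),
            all(c("control", "dyslexia") %in% names(alpha_sd)),
            all(alpha_mean > 0), all(alpha_sd >= 0))
  structure(list(n_per_group = as.integer(n_per_group),
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 beta = beta, lapse = lapse, bias_left = bias_left,
                 shifts = shifts),
            class = "cohort_spec")
}

#' Default cohorts for the two paradigms
#'
#' `"exp1"` uses the printed marginal group means of the density/frames
#' study as baseline alphas. `"exp2"` uses static-prime baselines on the
#' priming study's scale (control 15, dyslexia 22 coherence points; the
#' study prints only its difference scores, so the baselines are the
#' package's own calibration — see the vignette).
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param n_per_group Participants per group.
#' @return A [cohort_spec()].
#' @export
default_cohort <- function(experiment = c("exp1", "exp2"), n_per_group = 10) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    cohort_spec(n_per_group = n_per_group)
  } else {
    cohort_spec(n_per_group = n_per_group,
                alpha_mean = c(control = 15, dyslexia = 22),
                alpha_sd = c(control = 5, dyslexia = 6))
  }
}

#' Draw a cohort of psychometric observers
#'
#' Alphas are log-normal with the specified per-group arithmetic mean and
#' SD, truncated to (0, 100\] by clamping.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional seed (RNG state restored afterwards).
#' @return A tibble with columns `id`, `group`, `alpha_pct` and a list
#'   column `observer` of [observer_params()].
#' @export
draw_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    rows <- lapply(c("control", "dyslexia"), function(g) {
      m <- spec$alpha_mean[[g]]; s <- spec$alpha_sd[[g]]
      alpha <- if (s == 0) rep(m, spec$n_per_group) else {
        lp <- lognormal_params(m, s)
        stats::rlnorm(spec$n_per_group, lp$meanlog, lp$sdlog)
      }
      alpha <- pmin(100, pmax(0.5, alpha))
      tibble::tibble(group = g, alpha_pct = alpha)
    })
    cohort <- dplyr::bind_rows(rows)
    cohort$id <- sprintf("%s_%02d", substr(cohort$group, 1, 3),
                         stats::ave(seq_len(nrow(cohort)), cohort$group,
                                    FUN = seq_along))
    cohort$observer <- lapply(seq_len(nrow(cohort)), function(i) {
      observer_params(cohort$alpha_pct[i], beta = spec$beta,
                      lapse = spec$lapse, bias_left = spec$bias_left,
                      group = cohort$group[i])
    })
    cohort[, c("id", "group", "alpha_pct", "observer")]
  })
}
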