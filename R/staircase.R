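# Three-down/one-up adaptive coherence staircase with halving/doubling
# steps, reversal-based geometric-mean threshold estimation, and
# interleaved 1%-coherence catch trials for response-bias estimation.
#
# The rule converges where P(correct)^3 = 0.5, i.e. ~79.4% correct; the
# psychometric observer's alpha indexes exactly that level, so staircase
# estimates are directly comparable to the generating alphas.

#' Staircase configuration
#'
#' After three consecutive correct responses coherence is halved; after
#' each incorrect response it is doubled (clamped to
#' `[coherence_floor_pct, coherence_cap_pct]`; a clamped step still counts
#' toward the reversal logic). A block ends after `n_reversals` reversals,
#' or at `max_trials` with a non-convergence flag. Catch trials at
#' `catch_coherence_pct` are scheduled once per `catch_every`-trial window
#' at a uniformly drawn slot, so at least one occurs in every such window;
#' their responses never touch the staircase.
#'
#' @param start_coherence_pct Starting coherence (50 in the density/frames
#'   paradigm, 25 in the priming paradigm).
#' @param n_reversals Reversals per block (8 and 6 respectively).
#' @param step_down,step_up Multiplicative steps (0.5 / 2.0).
#' @param coherence_cap_pct,coherence_floor_pct Clamp bounds.
#' @param catch_coherence_pct Catch-trial coherence (1%).
#' @param catch_every Window length of the catch schedule (<= 5).
#' @param discard_first_k Reversals dropped from the head of the reversal
#'   list before the geometric mean (default 0: all reversals enter).
#' @param max_trials Hard trial cap per block.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(start_coherence_pct = 50, n_reversals = 8,
                             step_down = 0.5, step_up = 2,
                             coherence_cap_pct = 100,
                             coherence_floor_pct = 0.1,
                             catch_coherence_pct = 1, catch_every = 5,
                             discard_first_k = 0, max_trials = 400) {
  stopifnot(start_coherence_pct > 0,
            start_coherence_pct <= coherence_cap_pct,
            n_reversals >= 2, step_down > 0, step_down < 1, step_up > 1,
            coherence_floor_pct > 0,
            coherence_floor_pct < coherence_cap_pct,
            catch_every >= 1, catch_every <= 5,
            discard_first_k >= 0, max_trials > 0)
  structure(list(start_coherence_pct = start_coherence_pct,
                 n_reversals = as.integer(n_reversals),
                 step_down = step_down, step_up = step_up,
                 coherence_cap_pct = coherence_cap_pct,
                 coherence_floor_pct = coherence_floor_pct,
                 catch_coherence_pct = catch_coherence_pct,
                 catch_every = as.integer(catch_every),
                 discard_first_k = as.integer(discard_first_k),
                 max_trials = as.integer(max_trials)),
            class = "staircase_config")
}

#' Initialise a staircase track
#'
#' @param cfg A [staircase_config()].
#' @return An object of class `staircase_state`.
#' @export
staircase_new <- function(cfg) {
  stopifnot(inherits(cfg, "staircase_config"))
  structure(list(coherence_pct = cfg$start_coherence_pct,
                 consecutive_correct = 0L,
                 last_direction = "none",
                 reversals = numeric(0)),
            class = "staircase_state")
}

#' Update a staircase with one (non-catch) response
#'
#' A correct response increments the run; the third consecutive correct
#' halves coherence and resets the run. An incorrect response doubles
#' coherence and resets the run. Whenever the step direction flips, a
#' reversal is logged at the coherence at which the flip occurred (the
#' pre-step value).
#'
#' @param state A `staircase_state`.
#' @param correct Logical: was the response correct?
#' @param cfg The [staircase_config()].
#' @return The updated `staircase_state`.
#' @examples
#' cfg <- staircase_config()
#' s <- staircase_new(cfg)          # 50%
#' s <- staircase_update(s, TRUE, cfg)
#' s <- staircase_update(s, TRUE, cfg)
#' s <- staircase_update(s, TRUE, cfg)
#' s$coherence_pct                  # 25
#' @export
staircase_update <- function(state, correct, cfg) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  step_dir <- NULL
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 3L) {
      step_dir <- "down"
      new_c <- max(cfg$coherence_floor_pct,
                   state$coherence_pct * cfg$step_down)
      state$consecutive_correct <- 0L
    }
  } else {
    step_dir <- "up"
    new_c <- min(cfg$coherence_cap_pct, state$coherence_pct * cfg$step_up)
    state$consecutive_correct <- 0L
  }
  if (!is.null(step_dir)) {
    if (state$last_direction != "none" && state$last_direction != step_dir) {
      state$reversals <- c(state$reversals, state$coherence_pct)
    }
    state$last_direction <- step_dir
    state$coherence_pct <- new_c
  }
  state
}

#' Generic per-trial response of any observer
#'
#' Dispatches on the observer class. The psychometric observer responds
#' from its psychometric function (the stimulus parameters are not
#' consulted); the mechanistic observer gets an actual frame sequence
#' generated at the trial's coherence and direction, preceded by a prime
#' when `prime` is given (primes are generated for stimulus fidelity; the
#' undersampling observer judges the test frames, as instructed observers
#' judge the test).
#'
#' @param observer An `observer`.
#' @param coherence_pct Trial coherence.
#' @param direction True direction, `"left"` or `"right"`.
#' @param stim_params [rdk_params()] for the trial (required for the
#'   mechanistic observer).
#' @param prime Optional [prime_spec()].
#' @return `"left"` or `"right"`.
#' @export
respond_trial <- function(observer, coherence_pct, direction,
                          stim_params = NULL, prime = NULL) {
  UseMethod("respond_trial")
}

#' @export
respond_trial.psychometric_observer <- function(observer, coherence_pct,
                                                direction, stim_params = NULL,
                                                prime = NULL) {
  respond(coherence_pct, direction, observer)
}

#' @export
respond_trial.mechanistic_observer <- function(observer, coherence_pct,
                                               direction, stim_params,
                                               prime = NULL) {
  stopifnot(inherits(stim_params, "rdk_params"))
  p <- stim_params
  p$coherence_pct <- coherence_pct
  p$direction <- direction
  p$seed <- NULL
  if (!is.null(prime)) make_prime_sequence(prime, p) # presented, not judged
  frames <- generate_trial(p)
  mechanistic_respond(frames, observer, p)
}

#' Run one staircase block
#'
#' Alternates staircase trials with 1%-coherence catch trials (one per
#' `catch_every`-trial window, slot drawn uniformly; catch responses are
#' logged but never update the staircase). The stimulus direction of every
#' trial is drawn uniformly. The block terminates after
#' `cfg$n_reversals` reversals, or at `cfg$max_trials` trials with
#' `converged = FALSE`.
#'
#' @param observer Any `observer` ([observer_params()] or
#'   [mechanistic_observer()]).
#' @param stim_params [rdk_params()] of the test stimulus.
#' @param cfg A [staircase_config()].
#' @param prime Optional [prime_spec()] prepended to every trial's stimulus
#'   (mechanistic path only; the psychometric observer's prime sensitivity
#'   is modelled through [apply_prime_shift()]).
#' @param seed Optional seed for the whole block.
#' @return A list of class `staircase_block`: `state` (final
#'   `staircase_state`), `trials` (tibble: `trial`, `coherence_pct`,
#'   `direction`, `response`, `correct`, `is_catch`), `threshold_pct`
#'   (geometric mean of reversals), `response_bias_pct`, `converged`.
#' @export
run_block <- function(observer, stim_params = NULL,
                      cfg = staircase_config(), prime = NULL, seed = NULL) {
  stopifnot(inherits(observer, "observer"),
            inherits(cfg, "staircase_config"))
  with_seed(seed, {
    state <- staircase_new(cfg)
    n_max <- cfg$max_trials
    coherence <- numeric(n_max); direction <- character(n_max)
    response <- character(n_max); correct <- logical(n_max)
    is_catch <- logical(n_max)
    catch_slot <- sample.int(cfg$catch_every, 1L)
    t <- 0L
    while (length(state$reversals) < cfg$n_reversals && t < n_max) {
      t <- t + 1L
      pos_in_window <- (t - 1L) %% cfg$catch_every + 1L
      if (pos_in_window == 1L && t > 1L) {
        catch_slot <- sample.int(cfg$catch_every, 1L)
      }
      catch <- pos_in_window == catch_slot
      coh <- if (catch) cfg$catch_coherence_pct else state$coherence_pct
      dir <- if (stats::runif(1) < 0.5) "left" else "right"
      resp <- respond_trial(observer, coh, dir, stim_params, prime)
      ok <- identical(resp, dir)
      coherence[t] <- coh; direction[t] <- dir; response[t] <- resp
      correct[t] <- ok; is_catch[t] <- catch
      if (!catch) state <- staircase_update(state, ok, cfg)
    }
    idx <- seq_len(t)
    trials <- tibble::tibble(trial = idx, coherence_pct = coherence[idx],
                             direction = direction[idx],
                             response = response[idx],
                             correct = correct[idx], is_catch = is_catch[idx])
    converged <- length(state$reversals) >= cfg$n_reversals
    threshold <- if (length(state$reversals)) {
      estimate_threshold(state$reversals,
                         discard_first_k = cfg$discard_first_k)
    } else NA_real_
    bias <- if (any(trials$is_catch)) response_bias(trials) else NA_real_
    structure(list(state = state, trials = trials,
                   threshold_pct = threshold, response_bias_pct = bias,
                   converged = converged),
              class = "staircase_block")
  })
}

#' Geometric-mean threshold from reversal coherences
#'
#' @param reversals Numeric vector of reversal coherences (percent).
#' @param discard_first_k Reversals dropped from the head before averaging.
#' @return Geometric mean, percent.
#' @examples
#' estimate_threshold(rep(c(40, 20), 4)) # 28.28
#' @export
estimate_threshold <- function(reversals, discard_first_k = 0) {
  if (length(reversals) == 0) {
    stop("cannot estimate a threshold from an empty reversal list",
         call. = FALSE)
  }
  if (discard_first_k > 0) {
    if (discard_first_k >= length(reversals)) {
      stop("`discard_first_k` leaves no reversals", call. = FALSE)
    }
    reversals <- reversals[-seq_len(discard_first_k)]
  }
  geometric_mean(reversals)
}

#' Combine block thresholds
#'
#' Geometric mean of per-block geometric-mean thresholds, the two-block
#' combination rule of both paradigms.
#'
#' @param ... Block thresholds (percent).
#' @return Combined threshold, percent.
#' @examples
#' combine_thresholds(30, 40) # 34.64
#' @export
combine_thresholds <- function(...) {
  geometric_mean(c(...))
}

#' Response bias from catch trials
#'
#' Percentage of "left" responses on the 1%-coherence catch trials; about
#' 50% for an unbiased observer.
#'
#' @param trials A trial log with columns `response` and `is_catch` (e.g.
#'   `run_block(...)$trials`).
#' @return Percent left responses on catch trials.
#' @export
response_bias <- function(trials) {
  stopifnot(all(c("response", "is_catch") %in% names(trials)))
  catch <- trials[trials$is_catch, , drop = FALSE]
  if (nrow(catch) == 0) {
    stop("no catch trials in the log", call. = FALSE)
  }
  100 * mean(catch$response == "left")
}
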