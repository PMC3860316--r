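# Shared fixtures, built in code.

# An observer that is effectively always correct: tiny alpha, no lapses,
# so p_see = 1 at any presentable coherence.
perfect_observer <- function() {
  observer_params(alpha_pct = 1e-3, beta = 3, lapse = 0)
}

# A dot field with fully controlled ages (none expiring for `lifetime`
# frames), for transition-level checks.
fresh_field <- function(params) {
  f <- make_dot_field(params)
  f$age <- rep(0L, params$n_dots)
  f
}

exp1_cfg <- function(...) {
  staircase_config(start_coherence_pct = 50, n_reversals = 8, ...)
}

exp2_cfg <- function(...) {
  staircase_config(start_coherence_pct = 25, n_reversals = 6, ...)
}
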