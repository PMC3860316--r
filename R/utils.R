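# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Used wherever a `seed` argument is offered so that seeded calls do not
# perturb the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # initialise RNG so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Draw a fresh child seed from the current stream; kept below 2^31.
next_seed <- function() {
  sample.int(.Machine$integer.max - 1L, 1L)
}

# Round half away from zero. base::round() rounds half to even, which would
# make signal-count accounting depend on the parity of n_dots * coherence.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# Arithmetic mean/sd -> log-normal (meanlog, sdlog) parameters.
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  sdlog2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  x
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a finite %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  x
}
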