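# RDK stimulus engine: apertures, dot fields, frame advancement, primes.
#
# Coordinates are continuous degrees of visual angle, origin at the aperture
# centre, +x rightward, +y upward. Dots are geometric points; luminance and
# dot diameter are carried as presentation metadata only.

#' Stimulus aperture
#'
#' Describes the borderless region dots are drawn in. Square apertures wrap
#' modularly on x and y; circular apertures wrap through the centre
#' (a dot leaving the rim re-enters at the diametrically opposite point).
#'
#' @param width_deg,height_deg Extent in degrees of visual angle.
#' @param shape `"square"` (the default; the experiments use square panels)
#'   or `"circle"`, in which case `diameter_deg` is used.
#' @param diameter_deg Circle diameter in degrees; defaults to `width_deg`.
#' @return An object of class `aperture`.
#' @examples
#' aperture(6, 6)       # density/frames experiment
#' aperture(13.35, 13.35) # priming experiment
#' @export
aperture <- function(width_deg, height_deg = width_deg,
                     shape = c("square", "circle"),
                     diameter_deg = width_deg) {
  shape <- match.arg(shape)
  check_positive(width_deg, "width_deg")
  check_positive(height_deg, "height_deg")
  if (shape == "circle") check_positive(diameter_deg, "diameter_deg")
  structure(
    list(width_deg = width_deg, height_deg = height_deg, shape = shape,
         diameter_deg = diameter_deg),
    class = "aperture"
  )
}

#' Full RDK stimulus recipe
#'
#' All geometry, kinematics and timing needed to generate one animation
#' sequence. Signal dots translate along `direction` at `speed_deg_per_s`
#' and wrap at the aperture edge; noise dots step the same distance in a
#' random direction (`noise_rule = "random_walk"`, the "Brownian"
#' interpretation) or are repositioned uniformly
#' (`noise_rule = "random_reposition"`). Every dot lives
#' `dot_lifetime_frames` frames and is then regenerated at a uniformly
#' random location.
#'
#' @param n_dots Number of dots (>= 0).
#' @param aperture An [aperture()].
#' @param coherence_pct Percentage of signal dots, in \[0, 100\].
#' @param direction `"left"`, `"right"`, or `"static"` (no dot moves;
#'   used for the stationary prime).
#' @param speed_deg_per_s Dot speed in degrees per second.
#' @param frame_duration_ms Duration of one animation frame, milliseconds.
#' @param n_frames Number of animation frames in a trial sequence.
#' @param dot_lifetime_frames Dot lifetime in frames (>= 1).
#' @param signal_rule `"random_per_lifetime"`: signal/noise identity is
#'   re-drawn among the dots regenerated on each transition (the count of
#'   signal dots is always preserved). `"fixed_identity"`: flags persist.
#' @param noise_rule See above.
#' @param seed Optional integer; when set, [generate_trial()] is
#'   reproducible and leaves the caller's RNG untouched.
#' @return An object of class `rdk_params`.
#' @export
rdk_params <- function(n_dots,
                       aperture = rdksim::aperture(6, 6),
                       coherence_pct = 50,
                       direction = c("right", "left", "static"),
                       speed_deg_per_s = 10.5,
                       frame_duration_ms = 16.67,
                       n_frames = 8,
                       dot_lifetime_frames = 2,
                       signal_rule = c("random_per_lifetime", "fixed_identity"),
                       noise_rule = c("random_walk", "random_reposition"),
                       seed = NULL) {
  direction <- match.arg(direction)
  signal_rule <- match.arg(signal_rule)
  noise_rule <- match.arg(noise_rule)
  stopifnot(inherits(aperture, "aperture"))
  if (!is.numeric(n_dots) || length(n_dots) != 1L || is.na(n_dots) ||
      n_dots < 0 || n_dots != round(n_dots)) {
    stop("`n_dots` must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(coherence_pct) || length(coherence_pct) != 1L ||
      is.na(coherence_pct) || coherence_pct < 0 || coherence_pct > 100) {
    stop("`coherence_pct` must be in [0, 100]", call. = FALSE)
  }
  check_positive(speed_deg_per_s, "speed_deg_per_s", strict = FALSE)
  check_positive(frame_duration_ms, "frame_duration_ms")
  stopifnot(n_frames >= 1, n_frames == round(n_frames),
            dot_lifetime_frames >= 1,
            dot_lifetime_frames == round(dot_lifetime_frames))
  structure(
    list(n_dots = as.integer(n_dots), aperture = aperture,
         coherence_pct = coherence_pct, direction = direction,
         speed_deg_per_s = speed_deg_per_s,
         frame_duration_ms = frame_duration_ms,
         n_frames = as.integer(n_frames),
         dot_lifetime_frames = as.integer(dot_lifetime_frames),
         signal_rule = signal_rule, noise_rule = noise_rule, seed = seed),
    class = "rdk_params"
  )
}

#' @export
print.rdk_params <- function(x, ...) {
  cat(sprintf(
    "<rdk_params> %d dots, %.4g%% coherence %s, %g deg/s, %d frames x %g ms, lifetime %d\n",
    x$n_dots, x$coherence_pct, x$direction, x$speed_deg_per_s,
    x$n_frames, x$frame_duration_ms, x$dot_lifetime_frames))
  invisible(x)
}

# Number of signal dots implied by a recipe (half rounds away from zero so
# the count never depends on parity).
n_signal_dots <- function(params) {
  as.integer(round_half_up(params$n_dots * params$coherence_pct / 100))
}

# Per-frame step length in degrees.
frame_step_deg <- function(params) {
  params$speed_deg_per_s * params$frame_duration_ms / 1000
}

signed_direction <- function(direction) {
  switch(direction, right = 1, left = -1, static = 0)
}

uniform_positions <- function(n, ap) {
  if (ap$shape == "square") {
    list(x = stats::runif(n, -ap$width_deg / 2, ap$width_deg / 2),
         y = stats::runif(n, -ap$height_deg / 2, ap$height_deg / 2))
  } else {
    # uniform over the disc via sqrt radius
    r <- ap$diameter_deg / 2 * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    list(x = r * cos(th), y = r * sin(th))
  }
}

in_aperture <- function(x, y, ap, tol = 1e-9) {
  if (ap$shape == "square") {
    abs(x) <= ap$width_deg / 2 + tol & abs(y) <= ap$height_deg / 2 + tol
  } else {
    x^2 + y^2 <= (ap$diameter_deg / 2 + tol)^2
  }
}

# Modular wrap into [-half, half].
wrap_coord <- function(x, half) {
  ((x + half) %% (2 * half)) - half
}

# Reflect into [-half, half]; valid for overshoots smaller than the width.
reflect_coord <- function(x, half) {
  x <- ifelse(x > half, 2 * half - x, x)
  ifelse(x < -half, -2 * half - x, x)
}

#' Construct the initial dot field of a trial
#'
#' Positions are uniform over the aperture; exactly
#' `round(n_dots * coherence_pct / 100)` dots are flagged as signal; ages are
#' drawn uniformly over `0:(lifetime - 1)` so that regenerations are
#' staggered from the first transition on (steady state).
#'
#' @param params An [rdk_params()].
#' @return An object of class `dot_field`: a list with numeric vectors `x`,
#'   `y`, logical `is_signal`, and integer `age` (frames since
#'   (re)generation).
#' @export
make_dot_field <- function(params) {
  stopifnot(inherits(params, "rdk_params"))
  n <- params$n_dots
  pos <- uniform_positions(n, params$aperture)
  is_signal <- logical(n)
  is_signal[sample.int(n, n_signal_dots(params))] <- TRUE
  age <- if (params$dot_lifetime_frames == 1L) integer(n) else
    sample.int(params$dot_lifetime_frames, n, replace = TRUE) - 1L
  structure(list(x = pos$x, y = pos$y, is_signal = is_signal, age = age),
            class = "dot_field")
}

#' Advance a dot field by one animation frame
#'
#' Signal dots translate by `speed * frame_duration` along the stimulus
#' direction and wrap at the aperture edge. Noise dots take a step of the
#' same length in a uniformly random direction (reflected at the edge), or
#' are repositioned uniformly, depending on `noise_rule`. Dots whose age has
#' reached `lifetime - 1` are regenerated at a uniformly random location
#' with age 0; under `signal_rule = "random_per_lifetime"` the signal flags
#' of the regenerated cohort are reshuffled among them, so the total signal
#' count is invariant. A `"static"` direction returns the field unchanged
#' (stationary prime).
#'
#' @param field A `dot_field` consistent with `params`.
#' @param params The [rdk_params()] the field was built from.
#' @return The next `dot_field`.
#' @export
advance_frame <- function(field, params) {
  stopifnot(inherits(field, "dot_field"), inherits(params, "rdk_params"))
  if (params$direction == "static") return(field)

  ap <- params$aperture
  step <- frame_step_deg(params)
  n <- params$n_dots
  expired <- field$age >= params$dot_lifetime_frames - 1L
  x <- field$x; y <- field$y
  is_signal <- field$is_signal

  sig <- is_signal & !expired
  if (any(sig)) {
    x[sig] <- x[sig] + signed_direction(params$direction) * step
    if (ap$shape == "square") {
      x[sig] <- wrap_coord(x[sig], ap$width_deg / 2)
    } else {
      out <- x[sig]^2 + y[sig]^2 > (ap$diameter_deg / 2)^2
      x[sig][out] <- -x[sig][out]
      y[sig][out] <- -y[sig][out]
    }
  }

  noi <- !is_signal & !expired
  if (any(noi)) {
    if (params$noise_rule == "random_walk") {
      th <- stats::runif(sum(noi), 0, 2 * pi)
      nx <- x[noi] + step * cos(th)
      ny <- y[noi] + step * sin(th)
      if (ap$shape == "square") {
        nx <- reflect_coord(nx, ap$width_deg / 2)
        ny <- reflect_coord(ny, ap$height_deg / 2)
      } else {
        out <- nx^2 + ny^2 > (ap$diameter_deg / 2)^2
        if (any(out)) {
          rep <- uniform_positions(sum(out), ap)
          nx[out] <- rep$x; ny[out] <- rep$y
        }
      }
      x[noi] <- nx; y[noi] <- ny
    } else {
      rep <- uniform_positions(sum(noi), ap)
      x[noi] <- rep$x; y[noi] <- rep$y
    }
  }

  age <- field$age + 1L
  if (any(expired)) {
    rep <- uniform_positions(sum(expired), ap)
    x[expired] <- rep$x; y[expired] <- rep$y
    age[expired] <- 0L
    if (params$signal_rule == "random_per_lifetime") {
      is_signal[expired] <- sample(is_signal[expired])
    }
  }

  structure(list(x = x, y = y, is_signal = is_signal, age = age),
            class = "dot_field")
}

#' Generate a full trial: a sequence of animation frames
#'
#' Frame `t + 1` is [advance_frame()] applied to frame `t`. When
#' `params$seed` is set the sequence is reproducible and the caller's RNG
#' state is untouched.
#'
#' @param params An [rdk_params()].
#' @return A list of `n_frames` `dot_field`s, classed `dot_trial`, with the
#'   generating `rdk_params` attached as attribute `params`.
#' @export
generate_trial <- function(params) {
  stopifnot(inherits(params, "rdk_params"))
  with_seed(params$seed, {
    frames <- vector("list", params$n_frames)
    frames[[1L]] <- make_dot_field(params)
    if (params$n_frames > 1L) {
      for (t in seq_len(params$n_frames - 1L)) {
        frames[[t + 1L]] <- advance_frame(frames[[t]], params)
      }
    }
    structure(frames, class = "dot_trial", params = params)
  })
}

#' Prime specification for the motion-segmentation (priming) paradigm
#'
#' @param kind `"coherent_same"`, `"coherent_opposite"`, or `"stationary"`.
#' @param duration_ms Prime duration (default 96 ms).
#' @param isi_ms Blank inter-stimulus interval before the test
#'   (default 32 ms).
#' @return An object of class `prime_spec`.
#' @export
prime_spec <- function(kind = c("coherent_same", "coherent_opposite",
                                "stationary"),
                       duration_ms = 96, isi_ms = 32) {
  kind <- match.arg(kind)
  check_positive(duration_ms, "duration_ms", strict = FALSE)
  check_positive(isi_ms, "isi_ms", strict = FALSE)
  structure(list(kind = kind, duration_ms = duration_ms, isi_ms = isi_ms),
            class = "prime_spec")
}

#' Generate the prime frame sequence for a priming trial
#'
#' Coherent primes are 100%-coherence versions of the test stimulus moving
#' in the same or opposite direction as the test; the stationary prime is a
#' dot field with no displacement (identical consecutive frames). The frame
#' count is `round(duration_ms / frame_duration_ms)`.
#'
#' @param spec A [prime_spec()].
#' @param test_params The [rdk_params()] of the test stimulus the prime
#'   precedes.
#' @return A `dot_trial` of prime frames.
#' @export
make_prime_sequence <- function(spec, test_params) {
  stopifnot(inherits(spec, "prime_spec"), inherits(test_params, "rdk_params"))
  n_frames <- round(spec$duration_ms / test_params$frame_duration_ms)
  if (n_frames < 1) {
    stop("prime duration is shorter than one animation frame", call. = FALSE)
  }
  dir <- switch(spec$kind,
    coherent_same = test_params$direction,
    coherent_opposite = switch(test_params$direction,
                               left = "right", right = "left",
                               stop("test direction must be left or right",
                                    call. = FALSE)),
    stationary = "static")
  prime_params <- rdk_params(
    n_dots = test_params$n_dots,
    aperture = test_params$aperture,
    coherence_pct = if (spec$kind == "stationary") 0 else 100,
    direction = dir,
    speed_deg_per_s = test_params$speed_deg_per_s,
    frame_duration_ms = test_params$frame_duration_ms,
    n_frames = n_frames,
    dot_lifetime_frames = test_params$dot_lifetime_frames,
    signal_rule = test_params$signal_rule,
    noise_rule = test_params$noise_rule,
    seed = test_params$seed)
  generate_trial(prime_params)
}

#' Dot density implied by a dot count and aperture
#'
#' Two conventions are supported. `"literal_area"` divides by the actual
#' aperture area. `"circular_effective"` divides by the area of a circle
#' whose diameter equals the aperture width — the convention under which the
#' published densities for 400 and 100 dots in a 6-degree panel (14.15 and
#' 3.54 dots/deg^2) are recovered exactly.
#'
#' @param n_dots Dot count.
#' @param aperture An [aperture()].
#' @param convention `"circular_effective"` (default) or `"literal_area"`.
#' @return Density in dots per square degree.
#' @examples
#' compute_density(400, aperture(6, 6)) # 14.15
#' compute_density(100, aperture(6, 6)) # 3.54
#' @export
compute_density <- function(n_dots, aperture,
                            convention = c("circular_effective",
                                           "literal_area")) {
  convention <- match.arg(convention)
  stopifnot(inherits(aperture, "aperture"), n_dots >= 0)
  area <- if (convention == "circular_effective") {
    pi * (aperture$width_deg / 2)^2
  } else if (aperture$shape == "circle") {
    pi * (aperture$diameter_deg / 2)^2
  } else {
    aperture$width_deg * aperture$height_deg
  }
  if (area <= 0) stop("aperture area must be positive", call. = FALSE)
  n_dots / area
}

#' Named stimulus parameter sets used by the experiment drivers
#'
#' `exp1_high_density` / `exp1_low_density`: 400 / 100 dots in a 6 x 6 deg
#' panel, 10.5 deg/s, 16.67 ms frames, 2-frame dot lifetime, 8 frames by
#' default (the drivers set 5 or 8). `exp2_test`: 300 dots in a
#' 13.35 x 13.35 deg panel, 3-frame lifetime, 10 frames of 16 ms.
#' `exp2_prime_same` / `exp2_prime_opposite` / `exp2_prime_static`:
#' [prime_spec()]s for the 96 ms prime and 32 ms blank interval.
#'
#' @param name Optional single preset name; omit to get the full named list.
#' @return A named list of `rdk_params` / `prime_spec` objects, or one
#'   element of it.
#' @export
rdk_presets <- function(name = NULL) {
  presets <- list(
    exp1_high_density = rdk_params(
      n_dots = 400, aperture = aperture(6, 6), coherence_pct = 50,
      speed_deg_per_s = 10.5, frame_duration_ms = 16.67, n_frames = 8,
      dot_lifetime_frames = 2),
    exp1_low_density = rdk_params(
      n_dots = 100, aperture = aperture(6, 6), coherence_pct = 50,
      speed_deg_per_s = 10.5, frame_duration_ms = 16.67, n_frames = 8,
      dot_lifetime_frames = 2),
    exp2_test = rdk_params(
      n_dots = 300, aperture = aperture(13.35, 13.35), coherence_pct = 25,
      speed_deg_per_s = 10.5, frame_duration_ms = 16, n_frames = 10,
      dot_lifetime_frames = 3),
    exp2_prime_same = prime_spec("coherent_same"),
    exp2_prime_opposite = prime_spec("coherent_opposite"),
    exp2_prime_static = prime_spec("stationary")
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  presets[[name]]
}

#' Tabulate a trial as a tidy per-dot manifest
#'
#' @param trial A `dot_trial` from [generate_trial()].
#' @return A tibble with columns `frame`, `dot`, `x_deg`, `y_deg`,
#'   `is_signal`, `age`.
#' @export
trial_manifest <- function(trial) {
  stopifnot(inherits(trial, "dot_trial"))
  n <- length(trial[[1L]]$x)
  dplyr::bind_rows(lapply(seq_along(trial), function(t) {
    f <- trial[[t]]
    tibble::tibble(frame = t, dot = seq_len(n), x_deg = f$x, y_deg = f$y,
                   is_signal = f$is_signal, age = f$age)
  }))
}

#' Export a trial to disk
#'
#' Writes a CSV manifest (`manifest.csv`, one row per dot per frame) and,
#' when the `png` package is available and `png = TRUE`, one PNG per frame
#' rasterised at `px_per_deg` pixels per degree with one white pixel per
#' dot.
#'
#' @param trial A `dot_trial`.
#' @param dir Output directory (created if missing).
#' @param png Also write PNG frames?
#' @param px_per_deg Raster resolution for the PNG export.
#' @return Invisibly, the paths written.
#' @export
export_stimulus <- function(trial, dir, png = FALSE, px_per_deg = 32) {
  stopifnot(inherits(trial, "dot_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- trial_manifest(trial)
  csv_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, csv_path, row.names = FALSE)
  paths <- csv_path
  if (png) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("PNG export requires the 'png' package", call. = FALSE)
    }
    ap <- attr(trial, "params")$aperture
    w <- max(1L, as.integer(ceiling(ap$width_deg * px_per_deg)))
    h <- max(1L, as.integer(ceiling(ap$height_deg * px_per_deg)))
    for (t in seq_along(trial)) {
      img <- matrix(0, nrow = h, ncol = w)
      col <- pmin(w, pmax(1L, as.integer(
        floor((trial[[t]]$x + ap$width_deg / 2) * px_per_deg) + 1L)))
      row <- pmin(h, pmax(1L, as.integer(
        floor((ap$height_deg / 2 - trial[[t]]$y) * px_per_deg) + 1L)))
      img[cbind(row, col)] <- 1
      p <- file.path(dir, sprintf("frame_%03d.png", t))
      png::writePNG(img, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
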