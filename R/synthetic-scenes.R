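#' Specify a synthetic textured scene undergoing known global motion
#'
#' The generator's world: a seeded white-noise texture blurred to a chosen
#' smoothness (guaranteeing a non-degenerate structural tensor almost
#' everywhere), warped once per scheduled step by a known global motion
#' parameter vector, with optional i.i.d. Gaussian sensor noise on each
#' emitted frame.
#'
#' @param width,height frame size in pixels (at least 16).
#' @param n_channels 1 (grayscale) or 3 (color-like; independent textures).
#' @param texture_seed integer seed for the texture.
#' @param texture_smoothness Gaussian blur sigma of the texture, pixels (> 0).
#' @param schedule list of [motion_params()] (or 6-vectors), one per frame
#'   transition; length at least 1.
#' @param noise_sigma additive intensity noise standard deviation (>= 0), on
#'   the `[0, 1]` intensity scale.
#' @param boundary_mode how warping samples beyond the frame edge:
#'   `"reflect"` (default), `"wrap"` or `"constant"`.
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(width, height, n_channels = 1L, texture_seed = 1L,
                       texture_smoothness = 2.0, schedule,
                       noise_sigma = 0, boundary_mode = c("reflect", "wrap", "constant")) {
  boundary_mode <- match.arg(boundary_mode)
  if (width < 16 || height < 16) stop("scene dimensions must be at least 16 x 16")
  if (!n_channels %in% c(1L, 3L)) stop("n_channels must be 1 or 3")
  if (texture_smoothness <= 0) stop("texture_smoothness must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (missing(schedule) || length(schedule) < 1L) stop("schedule must have length >= 1")
  schedule <- lapply(schedule, as_motion_params)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_channels = as.integer(n_channels),
                 texture_seed = as.integer(texture_seed),
                 texture_smoothness = texture_smoothness,
                 schedule = schedule, noise_sigma = noise_sigma,
                 boundary_mode = boundary_mode),
            class = "scene_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render the seeded base texture of a scene
#'
#' Unit white noise from `texture_seed`, Gaussian-blurred with
#' `texture_smoothness`, offset to mid-gray and clipped to `[0, 1]`. No
#' re-normalization is applied, so stronger smoothing genuinely flattens the
#' texture (gradient magnitude vanishes in the large-sigma limit); at the
#' default sigma of 2 px the blurred-noise standard deviation is ~0.14,
#' giving a smooth but spatially rich field whose gradient is nonzero almost
#' everywhere — which is what the structural tensor needs.
#'
#' @param spec a [scene_spec()].
#' @return a frame (`H x W x Nc` array) with values in `[0, 1]`.
#' @export
render_texture <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$texture_seed, {
    out <- array(0, c(spec$height, spec$width, spec$n_channels))
    for (c in seq_len(spec$n_channels)) {
      noise <- matrix(rnorm(spec$height * spec$width), spec$height, spec$width)
      sm <- gauss_blur_matrix(noise, spec$texture_smoothness)
      out[, , c] <- pmin(pmax(0.5 + sm, 0), 1)
    }
    out
  })
}

#' Warp a frame by a small global motion
#'
#' Applies the flow `v(x, y) = sum_u A_u v^u(x, y)` so that image content
#' moves by `+v`: the output is the input resampled at positions displaced by
#' `-v`, with Catmull-Rom cubic interpolation (exact for integer shifts and
#' linear ramps). Amplitudes are assumed small (displacements of a couple of
#' pixels at most) — this is the regime in which the linearized
#' brightness-constancy solve is valid.
#'
#' @param frame a frame.
#' @param params a [motion_params()] vector (or numeric 6-vector).
#' @param boundary_mode `"reflect"`, `"wrap"` or `"constant"`.
#' @param basis optional pre-built [make_generator_basis()] matching the frame.
#' @return the warped frame, same shape.
#' @export
warp_frame <- function(frame, params, boundary_mode = c("reflect", "wrap", "constant"),
                       basis = NULL) {
  boundary_mode <- match.arg(boundary_mode)
  frame <- as_frame(frame)
  a <- as.numeric(as_motion_params(params))
  d <- dim(frame)
  if (all(a == 0)) return(frame)
  if (is.null(basis)) basis <- make_generator_basis(d[1], d[2])
  vx <- matrix(0, d[1], d[2]); vy <- matrix(0, d[1], d[2])
  for (u in seq_along(PARAM_NAMES)) {
    if (a[u] == 0) next
    f <- generator_field(basis, PARAM_NAMES[u])
    vx <- vx + a[u] * f$vx
    vy <- vy + a[u] * f$vy
  }
  xs <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2]) - vx
  ys <- matrix(rep(seq_len(d[1]), times = d[2]), d[1], d[2]) - vy
  out <- array(0, d)
  for (c in seq_len(d[3])) {
    out[, , c] <- matrix(cubic_sample(frame[, , c], as.numeric(ys), as.numeric(xs),
                                      boundary_mode), d[1], d[2])
  }
  out
}

#' Render a full synthetic sequence with known per-step motion
#'
#' The clean scene is warped cumulatively through the schedule; sensor noise
#' (when `noise_sigma > 0`) is added independently to each emitted frame so
#' that the schedule stays the exact ground truth of the underlying motion.
#'
#' @param spec a [scene_spec()].
#' @return list with `frames` (length `length(schedule) + 1`) and `truth`
#'   (the schedule, unchanged).
#' @export
render_sequence <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  basis <- make_generator_basis(spec$height, spec$width)
  clean <- vector("list", length(spec$schedule) + 1L)
  clean[[1L]] <- render_texture(spec)
  for (t in seq_along(spec$schedule)) {
    nxt <- warp_frame(clean[[t]], spec$schedule[[t]], spec$boundary_mode, basis)
    if (stats::sd(nxt) < 1e-9) {
      stop(sprintf("cumulative motion destroyed all texture by step %d", t))
    }
    clean[[t + 1L]] <- nxt
  }
  frames <- clean
  if (spec$noise_sigma > 0) {
    frames <- with_seed(spec$texture_seed + 1L, {
      lapply(clean, function(f) {
        f + array(rnorm(length(f), sd = spec$noise_sigma), dim(f))
      })
    })
  }
  list(frames = frames, truth = spec$schedule)
}

#' Specify a labeled synthetic motion-window dataset
#'
#' Emulates what the motion extractor produces on real footage: slowly varying
#' low-amplitude background motion on all six parameters (normal activity),
#' with falls modeled as one abrupt high-magnitude transient hitting all six
#' parameters simultaneously — a fall is a fast whole-body event that
#' registers on every element of the flow vector.
#'
#' @param n_windows number of windows to generate.
#' @param window_length frames per window (default 150).
#' @param fall_fraction proportion of positive (fall) windows in `[0, 1]`;
#'   the positive count is `round(n_windows * fall_fraction)` exactly.
#' @param transient_amplitude burst amplitude as a multiple of the background
#'   standard deviation (default 10).
#' @param transient_duration burst length in frames (default 8; must be
#'   shorter than the window).
#' @param background_sd standard deviation of the background motion, in the
#'   same per-frame units as the motion parameters (default 0.02).
#' @param background_correlation temporal correlation length of the
#'   background, frames (default 5).
#' @param seed integer seed.
#' @return a list of class `motion_dataset_spec`.
#' @export
motion_dataset_spec <- function(n_windows, window_length = 150L,
                                fall_fraction = 0.5,
                                transient_amplitude = 10,
                                transient_duration = 8L,
                                background_sd = 0.02,
                                background_correlation = 5,
                                seed = 1L) {
  if (fall_fraction < 0 || fall_fraction > 1) stop("fall_fraction must be in [0, 1]")
  if (transient_duration >= window_length) {
    stop("transient_duration must be shorter than window_length")
  }
  if (n_windows < 1) stop("n_windows must be >= 1")
  structure(list(n_windows = as.integer(n_windows),
                 window_length = as.integer(window_length),
                 fall_fraction = fall_fraction,
                 transient_amplitude = transient_amplitude,
                 transient_duration = as.integer(transient_duration),
                 background_sd = background_sd,
                 background_correlation = background_correlation,
                 seed = as.integer(seed)),
            class = "motion_dataset_spec")
}

# One 6 x T block of temporally smooth background motion.
sim_background <- function(window_length, background_sd, corr_len) {
  raw <- matrix(rnorm(6 * (window_length + 6 * ceiling(corr_len))), nrow = 6)
  r <- max(1L, ceiling(3 * corr_len / 2))
  k <- exp(-((-r):r)^2 / (2 * (corr_len / 2)^2)); k <- k / sum(k)
  sm <- t(apply(raw, 1, function(row) {
    as.numeric(stats::filter(row, k, sides = 2))
  }))
  sm <- sm[, (3 * ceiling(corr_len) + 1):(3 * ceiling(corr_len) + window_length), drop = FALSE]
  # renormalize to the requested marginal sd (smoothing shrinks variance)
  sm * (background_sd / stats::sd(as.numeric(sm)))
}

# Hann-shaped burst of the given duration, amplitude per channel with a
# dominant random sign (a fall has a direction).
sim_transient <- function(duration, amplitude_abs) {
  shape <- 0.5 * (1 - cos(2 * pi * (seq_len(duration) - 0.5) / duration))
  signs <- sample(c(-1, 1), 6, replace = TRUE)
  outer(signs * amplitude_abs, shape)
}

#' Simulate a labeled motion-window dataset
#'
#' @param spec a [motion_dataset_spec()].
#' @return list with `windows` (a `6 x window_length x n_windows` array),
#'   `labels` (factor with levels `no_fall`, `fall`) and `onsets` (frame index
#'   of the transient start for positive windows, `NA` otherwise).
#' @export
#' @examples
#' ds <- simulate_motion_dataset(motion_dataset_spec(10, seed = 3))
#' table(ds$labels)
simulate_motion_dataset <- function(spec) {
  stopifnot(inherits(spec, "motion_dataset_spec"))
  n_pos <- round(spec$n_windows * spec$fall_fraction)
  if (spec$n_windows >= 2 && (n_pos == 0 || n_pos == spec$n_windows) &&
      spec$fall_fraction > 0 && spec$fall_fraction < 1) {
    stop("requested fractions leave one class empty; adjust n_windows or fall_fraction")
  }
  with_seed(spec$seed, {
    is_fall <- rep(c(TRUE, FALSE), c(n_pos, spec$n_windows - n_pos))
    is_fall <- sample(is_fall)
    amp <- spec$transient_amplitude * spec$background_sd
    windows <- array(0, c(6, spec$window_length, spec$n_windows))
    onsets <- rep(NA_integer_, spec$n_windows)
    margin <- spec$transient_duration  # keep bursts clear of window edges
    for (i in seq_len(spec$n_windows)) {
      w <- sim_background(spec$window_length, spec$background_sd,
                          spec$background_correlation)
      if (is_fall[i]) {
        onset <- sample(seq(margin, spec$window_length - 2L * margin), 1L)
        idx <- onset:(onset + spec$transient_duration - 1L)
        w[, idx] <- w[, idx] + sim_transient(spec$transient_duration, amp)
        onsets[i] <- onset
      }
      windows[, , i] <- w
    }
    dimnames(windows) <- list(PARAM_NAMES, NULL, NULL)
    list(windows = windows,
         labels = factor(ifelse(is_fall, "fall", "no_fall"), levels = CLASS_LEVELS),
         onsets = onsets)
  })
}

#' Build a motion schedule with injected fall transients
#'
#' The sequence-level counterpart of [simulate_motion_dataset()]: one long
#' 6 x T schedule of smooth background motion with abrupt transients at the
#' given onsets, usable directly as a [scene_spec()] schedule so that rendered
#' videos and simulated windows share one generative process.
#'
#' @param n_steps schedule length (frame transitions).
#' @param onsets integer vector of transient start indices (possibly empty).
#' @param transient_amplitude,transient_duration,background_sd,background_correlation
#'   as in [motion_dataset_spec()].
#' @param seed integer seed.
#' @return list with `schedule` (list of [motion_params()]) and `matrix`
#'   (6 x n_steps).
#' @export
simulate_motion_schedule <- function(n_steps, onsets = integer(0),
                                     transient_amplitude = 10,
                                     transient_duration = 8L,
                                     background_sd = 0.02,
                                     background_correlation = 5,
                                     seed = 1L) {
  stopifnot(all(onsets >= 1), all(onsets + transient_duration - 1 <= n_steps))
  with_seed(seed, {
    m <- sim_background(n_steps, background_sd, background_correlation)
    amp <- transient_amplitude * background_sd
    for (onset in onsets) {
      idx <- onset:(onset + transient_duration - 1L)
      m[, idx] <- m[, idx] + sim_transient(transient_duration, amp)
    }
    rownames(m) <- PARAM_NAMES
    list(schedule = lapply(seq_len(ncol(m)), function(j) as_motion_params(m[, j])),
         matrix = m)
  })
}
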