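#' Image stack container
#'
#' A time-ordered stack of 2-D frames for one channel: a numeric array
#' `[rows, cols, frames]` carrying the frame interval as an attribute.
#'
#' @param frames Numeric 3-D array `[rows, cols, frames]`.
#' @param frame_interval Seconds between frames.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval) {
  stopifnot(is.array(frames), length(dim(frames)) == 3,
            frame_interval > 0)
  structure(frames, frame_interval = frame_interval,
            class = c("image_stack", "array"))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %d x %d px, %d frames, dt = %g s\n",
              d[1], d[2], d[3], attr(x, "frame_interval")))
  invisible(x)
}

n_frames <- function(stack) dim(stack)[3]

frame_times <- function(stack) {
  (seq_len(n_frames(stack)) - 1) * attr(stack, "frame_interval")
}

#' Synthetic scene configuration
#'
#' Geometry, photometry and artifact parameters for one rendered
#' two-channel scene. The green (GCaMP) soma intensity is
#' `soma_baseline + gcamp_gain * true_trace(t)`; with the default
#' `gcamp_gain = soma_baseline` the extracted \eqn{\Delta R/R_0} equals
#' the ground-truth trace exactly in the noiseless limit.
#'
#' @param frame_shape Integer `(rows, cols)` in pixels.
#' @param n_frames Number of frames.
#' @param frame_interval Seconds per frame; default 0.1 s (10 Hz, the
#'   camera's 100 ms exposure).
#' @param neuron_path `n_frames x 2` matrix of (row, col) soma centers;
#'   default a confined smooth random walk from [simulate_path()].
#' @param soma_sigma Gaussian soma blob width, pixels.
#' @param soma_baseline Green soma intensity at zero calcium
#'   (intensity units).
#' @param gcamp_gain Green intensity per unit \eqn{\Delta R/R_0}.
#' @param rfp_level Red (calcium-independent) soma intensity.
#' @param background_level Mean background intensity, both channels.
#' @param background_texture_rel Relative amplitude of the static smooth
#'   background texture (0 disables it).
#' @param bleach_rate Photobleaching rate, per second; applied to the
#'   fluorophore (soma) terms only, not to the background offset, so
#'   background subtraction stays meaningful.
#' @param motion_gain_series Per-frame multiplicative illumination/focus
#'   artifact shared by both channels; default all 1. See
#'   [motion_gain_wave()].
#' @param noise_sd Additive Gaussian sensor noise SD, intensity units.
#' @param rng_seed Integer seed making the rendered scene deterministic.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(frame_shape = c(96, 96),
                         n_frames = 300,
                         frame_interval = 0.1,
                         neuron_path = NULL,
                         soma_sigma = 3,
                         soma_baseline = 150,
                         gcamp_gain = soma_baseline,
                         rfp_level = 120,
                         background_level = 30,
                         background_texture_rel = 0.05,
                         bleach_rate = 0.002,
                         motion_gain_series = NULL,
                         noise_sd = 2,
                         rng_seed = 1L) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 16),
            n_frames >= 1, frame_interval > 0, soma_sigma > 0,
            noise_sd >= 0, bleach_rate >= 0)
  if (is.null(neuron_path)) {
    set.seed(rng_seed)
    neuron_path <- simulate_path(n_frames, frame_shape)
  }
  neuron_path <- as.matrix(neuron_path)
  if (nrow(neuron_path) != n_frames || ncol(neuron_path) != 2) {
    stop("`neuron_path` must be an n_frames x 2 matrix")
  }
  if (any(neuron_path[, 1] < 1) || any(neuron_path[, 1] > frame_shape[1]) ||
      any(neuron_path[, 2] < 1) || any(neuron_path[, 2] > frame_shape[2])) {
    stop("`neuron_path` leaves the frame")
  }
  if (is.null(motion_gain_series)) motion_gain_series <- rep(1, n_frames)
  if (length(motion_gain_series) != n_frames) {
    stop("`motion_gain_series` must have one value per frame")
  }
  if (any(motion_gain_series <= 0)) {
    stop("`motion_gain_series` must be positive")
  }
  structure(
    list(frame_shape = as.integer(frame_shape), n_frames = as.integer(n_frames),
         frame_interval = frame_interval, neuron_path = neuron_path,
         soma_sigma = soma_sigma, soma_baseline = soma_baseline,
         gcamp_gain = gcamp_gain, rfp_level = rfp_level,
         background_level = background_level,
         background_texture_rel = background_texture_rel,
         bleach_rate = bleach_rate,
         motion_gain_series = as.numeric(motion_gain_series),
         noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "scene_config")
}

#' Confined smooth random-walk neuron path
#'
#' Emulates the residual soma motion of an animal that is trapped but
#' not immobilized: a Gaussian random walk smoothed with a short moving
#' average and reflected into a central box so the soma stays well away
#' from frame edges and the background ROI.
#'
#' @param n_frames Number of frames.
#' @param frame_shape `(rows, cols)` in pixels.
#' @param step_sd Per-frame step SD before smoothing, pixels.
#' @param margin Minimum distance kept from the frame edge, pixels.
#' @return `n_frames x 2` matrix of (row, col) positions.
#' @export
simulate_path <- function(n_frames, frame_shape, step_sd = 0.6,
                          margin = 28) {
  center <- (frame_shape + 1) / 2
  half <- pmax((frame_shape - 2 * margin) / 2, 1)
  smooth_walk <- function() {
    steps <- stats::rnorm(n_frames, sd = step_sd)
    w <- stats::filter(steps, rep(1 / 5, 5), sides = 2)
    w[is.na(w)] <- 0
    cumsum(as.numeric(w))
  }
  reflect <- function(x, h) {
    # fold the walk into [-h, h]
    x <- (x + h) %% (4 * h)
    ifelse(x > 2 * h, 4 * h - x, x) - h
  }
  cbind(center[1] + reflect(smooth_walk(), half[1]),
        center[2] + reflect(smooth_walk(), half[2]))
}

#' Slow multiplicative illumination artifact
#'
#' A smooth per-frame gain fluctuation (sum of two incommensurate
#' sinusoids) shared by both channels, used to exercise the ratiometric
#' correction.
#'
#' @param n_frames Number of frames.
#' @param frame_interval Seconds per frame.
#' @param amplitude Peak relative gain deviation.
#' @return Positive numeric vector of length `n_frames`.
#' @export
motion_gain_wave <- function(n_frames, frame_interval, amplitude = 0.15) {
  t <- (seq_len(n_frames) - 1) * frame_interval
  1 + amplitude * (0.7 * sin(2 * pi * t / 7.3) +
                   0.3 * sin(2 * pi * t / 2.1 + 1))
}

# static smooth texture field in [-1, 1]-ish range, deterministic given RNG
background_texture <- function(frame_shape) {
  r <- seq_len(frame_shape[1])
  c <- seq_len(frame_shape[2])
  ph <- stats::runif(4, 0, 2 * pi)
  fr <- stats::runif(2, 1.5, 3.5)
  fc <- stats::runif(2, 1.5, 3.5)
  outer(sin(2 * pi * fr[1] * r / frame_shape[1] + ph[1]) +
          0.5 * sin(2 * pi * fr[2] * r / frame_shape[1] + ph[2]),
        sin(2 * pi * fc[1] * c / frame_shape[2] + ph[3]) +
          0.5 * sin(2 * pi * fc[2] * c / frame_shape[2] + ph[4])) / 2.25
}

#' Render a synthetic two-channel scene
#'
#' Produces a green (GCaMP) and a red (RFP) image stack plus the ground
#' truth used to generate them. Per frame `k` at time `t`:
#' \preformatted{
#' green = gain_k * (background + bleach(t) *
#'                   (soma_baseline + gcamp_gain * trace(t)) * blob) + noise
#' red   = gain_k * (background + bleach(t) * rfp_level * blob) + noise
#' }
#' Both channels share the neuron path, the motion gain series and the
#' background field, so their ratio cancels the shared artifacts.
#' Deterministic given `config$rng_seed`.
#'
#' @param config A [scene_config()].
#' @param protocol A [stim_protocol()]; its duration must fit within the
#'   rendered frames.
#' @param model A [response_model()].
#' @param habituation Passed to [draw_amplitudes()].
#' @param amp_cv Trial-amplitude lognormal CV, passed to
#'   [draw_amplitudes()].
#' @param responders Optional logical override of the per-stimulus
#'   responder draw.
#' @return List with `green` and `red` [image_stack()]s and
#'   `ground_truth`: a list with `true_trace` (\eqn{\Delta R/R_0} per
#'   frame), `true_path`, `responder`, `per_stimulus_amplitude`, and
#'   `seed`.
#' @export
render_scene <- function(config, protocol, model,
                         habituation = "none", amp_cv = 0,
                         responders = NULL) {
  stopifnot(inherits(config, "scene_config"),
            inherits(protocol, "stim_protocol"),
            inherits(model, "response_model"))
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  if (protocol$record_duration > max(times) + config$frame_interval) {
    stop("protocol is longer than the rendered scene")
  }
  set.seed(config$rng_seed)
  texture <- background_texture(config$frame_shape)
  draw <- draw_amplitudes(protocol, model, habituation = habituation,
                          amp_cv = amp_cv, responders = responders)
  trace <- true_trace(times, protocol, draw$amplitude, model)

  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  bg <- config$background_level *
    (1 + config$background_texture_rel * texture)
  bleach <- exp(-config$bleach_rate * times)
  gain <- config$motion_gain_series
  w <- ceiling(5 * config$soma_sigma)       # blob support half-width
  green <- array(0, c(nr, nc, config$n_frames))
  red <- array(0, c(nr, nc, config$n_frames))

  for (k in seq_len(config$n_frames)) {
    gf <- gain[k] * bg
    rf <- gf                                # identical shared part
    pr <- config$neuron_path[k, 1]; pc <- config$neuron_path[k, 2]
    rows <- max(1, floor(pr - w)):min(nr, ceiling(pr + w))
    cols <- max(1, floor(pc - w)):min(nc, ceiling(pc + w))
    blob <- exp(-(outer((rows - pr)^2, (cols - pc)^2, "+")) /
                  (2 * config$soma_sigma^2))
    soma_g <- config$soma_baseline + config$gcamp_gain * trace[k]
    gf[rows, cols] <- gf[rows, cols] +
      gain[k] * bleach[k] * soma_g * blob
    rf[rows, cols] <- rf[rows, cols] +
      gain[k] * bleach[k] * config$rfp_level * blob
    green[, , k] <- gf
    red[, , k] <- rf
  }
  if (config$noise_sd > 0) {
    green <- green + array(stats::rnorm(length(green), 0, config$noise_sd),
                           dim(green))
    red <- red + array(stats::rnorm(length(red), 0, config$noise_sd),
                       dim(red))
  }
  list(green = image_stack(green, config$frame_interval),
       red = image_stack(red, config$frame_interval),
       ground_truth = list(true_trace = trace,
                           true_path = config$neuron_path,
                           responder = draw$responder,
                           per_stimulus_amplitude = draw$amplitude,
                           seed = config$rng_seed))
}
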