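#' Simulate a single normalized calcium trace
#'
#' Trace-level counterpart of [render_scene()]: draws per-stimulus
#' amplitudes, evaluates the transient kernel on the frame grid, adds
#' Gaussian trace noise and renormalizes to the pre-stimulus baseline —
#' the cheap generator behind ensemble, grid, habituation and screen
#' simulations where rendering full image stacks is unnecessary.
#' Uses the current RNG state; seed upstream.
#'
#' @param protocol A [stim_protocol()].
#' @param model A [response_model()].
#' @param frame_interval Seconds per frame (default 0.1).
#' @param noise_sd Additive trace noise SD, \eqn{\Delta R/R_0} units.
#' @param habituation,amp_cv,responders Passed to [draw_amplitudes()].
#' @return List with `trace` (a normalized `calcium_trace`) and
#'   `ground_truth` (amplitudes and responder flags).
#' @export
simulate_trace <- function(protocol, model, frame_interval = 0.1,
                           noise_sd = 0.05, habituation = "none",
                           amp_cv = 0, responders = NULL) {
  times <- seq(0, protocol$record_duration, by = frame_interval)
  draw <- draw_amplitudes(protocol, model, habituation = habituation,
                          amp_cv = amp_cv, responders = responders)
  dRR <- true_trace(times, protocol, draw$amplitude, model)
  if (noise_sd > 0) dRR <- dRR + stats::rnorm(length(dRR), 0, noise_sd)
  df <- data.frame(frame = seq_along(times),
                   I_G_roi = NA_real_, I_G_back = NA_real_,
                   I_R_roi = NA_real_, I_R_back = NA_real_,
                   R_or_F = 1 + dRR, valid = TRUE)
  tr <- new_calcium_trace(times, "synthetic", protocol, df)
  tr <- normalize_trace(tr)
  list(trace = tr,
       ground_truth = list(amplitude = draw$amplitude,
                           responder = draw$responder,
                           multiplier = draw$multiplier))
}

#' Simulate a pressure x duration trial grid
#'
#' Runs [simulate_trace()] over every cell of a pressure/duration grid
#' and collects per-trial peak responses, the input to
#' [summarize_grid()].
#'
#' @param pressures,durations Grid axes (psi, seconds).
#' @param n_per_cell Trials per cell.
#' @param model A [response_model()].
#' @param onset,baseline_window,record_after Protocol timing, seconds.
#' @param noise_sd,amp_cv Trial variability, as in [simulate_trace()].
#' @return `data.frame` with `pressure`, `duration`, `max_dRR`,
#'   `responder_truth` (the generator's Bernoulli draw).
#' @export
simulate_grid_trials <- function(pressures, durations, n_per_cell = 10,
                                 model = response_model(),
                                 onset = 10, record_after = 20,
                                 baseline_window = onset,
                                 noise_sd = 0.05, amp_cv = 0.25) {
  rows <- list()
  for (p in pressures) for (d in durations) {
    proto <- stim_protocol(onsets = onset, durations = d, pressures = p,
                           baseline_window = baseline_window,
                           record_duration = onset + d + record_after)
    for (i in seq_len(n_per_cell)) {
      sim <- simulate_trace(proto, model, noise_sd = noise_sd,
                            amp_cv = amp_cv)
      mt <- trial_metrics(sim$trace, 1)
      rows[[length(rows) + 1]] <-
        data.frame(pressure = p, duration = d, max_dRR = mt$max_dRR,
                   responder_truth = sim$ground_truth$responder[1])
    }
  }
  do.call(rbind, rows)
}

#' Simulate a drug screen
#'
#' Generates per-animal screen records for a control group and a set of
#' compounds with planted effects, across several experimental days. A
#' shared lognormal day factor scales every amplitude recorded that day
#' (controls included), which same-day control normalization is designed
#' to remove. Compound effects are expressed as modifications of the
#' response model:
#' \describe{
#'   \item{`respond_prob`}{overrides the responder probability}
#'   \item{`amp_mult`}{multiplies the response amplitude}
#'   \item{`tau_decay_mult`}{multiplies the decay time constant
#'     (scales the half-life)}
#' }
#'
#' @param effects Named list of per-compound effect lists (may be empty
#'   for a no-effect compound); the control group is added
#'   automatically.
#' @param n_per_group Animals per compound per screen.
#' @param days Number of experimental days (animals are spread evenly).
#' @param protocol A [stim_protocol()]; default a single 1 s, 40 psi
#'   stimulus at 10 s in a 40 s recording.
#' @param model Baseline [response_model()].
#' @param noise_sd,amp_cv Trace noise and amplitude CV per animal.
#' @param day_effect_cv Lognormal CV of the shared day factor.
#' @param threshold Responder threshold applied to measured peaks.
#' @return `data.frame` of screen records (one row per animal) with
#'   columns `animal_id`, `compound`, `day`, `max_dRR`, `delay_time`,
#'   `half_life`, `responder`.
#' @export
simulate_screen <- function(effects, n_per_group = 25, days = 3,
                            protocol = NULL, model = response_model(),
                            noise_sd = 0.05, amp_cv = 0.25,
                            day_effect_cv = 0.15, threshold = 0.5) {
  if (is.null(protocol)) {
    protocol <- stim_protocol(onsets = 10, durations = 1, pressures = 40,
                              record_duration = 40)
  }
  groups <- c(list(control = list()), effects)
  day_sd <- sqrt(log(1 + day_effect_cv^2))
  day_factor <- stats::rlnorm(days, -day_sd^2 / 2, day_sd)
  rows <- list()
  id <- 0L
  for (g in seq_along(groups)) {
    eff <- groups[[g]]
    gm <- model
    if (!is.null(eff$tau_decay_mult)) {
      gm$tau_decay <- gm$tau_decay * eff$tau_decay_mult
    }
    p_resp <- if (!is.null(eff$respond_prob)) eff$respond_prob
              else respond_probability(protocol$pressures[1], model)
    amp_mult <- if (!is.null(eff$amp_mult)) eff$amp_mult else 1
    for (i in seq_len(n_per_group)) {
      id <- id + 1L
      day <- ((i - 1L) %% days) + 1L
      responder <- stats::runif(1) < p_resp
      sim <- simulate_trace(protocol, gm, noise_sd = noise_sd,
                            amp_cv = amp_cv, responders = responder)
      # day factor and compound amplitude effect scale the whole trace
      sim$trace$data$dRR <- sim$trace$data$dRR *
        day_factor[day] * amp_mult
      mt <- trial_metrics(sim$trace, 1, threshold = threshold)
      rows[[id]] <- data.frame(
        animal_id = sprintf("a%04d", id),
        compound = names(groups)[g], day = sprintf("day-%d", day),
        max_dRR = mt$max_dRR, delay_time = mt$delay_time,
        half_life = mt$half_life, responder = mt$responder)
    }
  }
  do.call(rbind, rows)
}
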