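#' Phenomenological calcium response model
#'
#' Parameters controlling how a simulated mechanosensory neuron converts
#' an actuation pressure and stimulus duration into a calcium transient.
#' The dose side is a Hill function of pressure times a saturating
#' function of duration; the kinetic side is a saturating rise while the
#' stimulus is on (peaking shortly after stimulus end, as observed traces
#' do) followed by an exponential decay. Responding at all is stochastic:
#' each stimulus elicits a response with a logistic probability in
#' pressure, so response-fraction grids can be simulated. Habituation
#' under repeated stimulation is encoded as per-stimulus amplitude
#' multipliers, one set for short and one for long inter-stimulus
#' intervals.
#'
#' Defaults are the package's own calibration of the regime the device
#' operates in: peak \eqn{\Delta R/R_0} saturating near 3, a pressure
#' midpoint between the stochastic (<30 psi) and reliable (>40 psi)
#' regimes, and decay slow relative to the rise.
#'
#' @param amp_max Saturating peak amplitude, \eqn{\Delta R/R_0} units.
#' @param pressure_half Hill midpoint pressure, psi.
#' @param hill_coef Hill coefficient (unitless).
#' @param duration_sat Duration saturation constant, seconds.
#' @param tau_rise Rise time constant, seconds.
#' @param tau_decay Decay time constant, seconds.
#' @param respond_prob_slope Logistic slope of the responder probability,
#'   per psi.
#' @param respond_prob_mid Pressure of 50% responder probability, psi.
#' @param habituation_short_isi Per-stimulus amplitude multipliers for
#'   short inter-stimulus intervals (facilitation up to the second
#'   stimulus, then depression).
#' @param habituation_long_isi Multipliers for long intervals
#'   (monotone depression).
#'
#' @return An object of class `response_model`.
#' @export
response_model <- function(amp_max = 3,
                           pressure_half = 30,
                           hill_coef = 4,
                           duration_sat = 2,
                           tau_rise = 0.5,
                           tau_decay = 4,
                           respond_prob_slope = 0.5,
                           respond_prob_mid = 33,
                           habituation_short_isi = c(1, 1.3, 0.8, 0.5),
                           habituation_long_isi = c(1, 0.8, 0.65, 0.5)) {
  stopifnot(amp_max >= 0, tau_rise > 0, tau_decay > 0,
            pressure_half > 0, hill_coef > 0, duration_sat > 0,
            all(habituation_short_isi >= 0),
            all(habituation_long_isi >= 0))
  structure(
    list(amp_max = amp_max, pressure_half = pressure_half,
         hill_coef = hill_coef, duration_sat = duration_sat,
         tau_rise = tau_rise, tau_decay = tau_decay,
         respond_prob_slope = respond_prob_slope,
         respond_prob_mid = respond_prob_mid,
         habituation_short_isi = habituation_short_isi,
         habituation_long_isi = habituation_long_isi),
    class = "response_model")
}

#' Unit calcium transient kernel
#'
#' Kinetic shape of a single calcium transient as a function of time
#' since stimulus onset: zero before onset, a saturating rise with time
#' constant `tau_rise` while the stimulus is on and until the peak at
#' `duration + tau_rise` (shortly after stimulus end), then exponential
#' decay with `tau_decay`. Continuous and bounded by 1.
#'
#' @param t_rel Time since stimulus onset, seconds (vectorized).
#' @param duration Stimulus duration, seconds.
#' @param model A [response_model()].
#' @return Unitless activation values in \[0, 1\].
#' @export
calcium_kernel <- function(t_rel, duration, model) {
  stopifnot(duration > 0, inherits(model, "response_model"))
  t_pk <- duration + model$tau_rise
  peak <- 1 - exp(-t_pk / model$tau_rise)
  out <- numeric(length(t_rel))
  rising <- t_rel >= 0 & t_rel <= t_pk
  falling <- t_rel > t_pk
  out[rising] <- 1 - exp(-t_rel[rising] / model$tau_rise)
  out[falling] <- peak * exp(-(t_rel[falling] - t_pk) / model$tau_decay)
  out
}

# kernel value at its peak, used to rescale to unit peak
kernel_peak <- function(duration, model) {
  1 - exp(-(duration + model$tau_rise) / model$tau_rise)
}

#' Expected peak amplitude for a pressure/duration combination
#'
#' Dose--response surface of the simulated neuron:
#' \deqn{A(p, d) = A_{max} \frac{p^h}{p^h + p_{1/2}^h}
#'       \left(1 - e^{-d/d_{sat}}\right)}
#' Monotone nondecreasing in both pressure and duration.
#'
#' @param pressure Actuation pressure, psi (vectorized).
#' @param duration Stimulus duration, seconds (vectorized).
#' @param model A [response_model()].
#' @return Peak \eqn{\Delta R/R_0} amplitude(s).
#' @export
simulate_amplitude <- function(pressure, duration, model) {
  stopifnot(all(pressure >= 0), all(duration > 0),
            inherits(model, "response_model"))
  h <- model$hill_coef
  hill <- ifelse(pressure == 0, 0,
                 pressure^h / (pressure^h + model$pressure_half^h))
  model$amp_max * hill * (1 - exp(-duration / model$duration_sat))
}

#' Responder probability at a given pressure
#'
#' Logistic probability that a stimulus at `pressure` elicits any
#' response at all; the Bernoulli draw feeding response-fraction grids.
#'
#' @param pressure Actuation pressure, psi (vectorized).
#' @param model A [response_model()].
#' @return Probabilities in \[0, 1\].
#' @export
respond_probability <- function(pressure, model) {
  stats::plogis(model$respond_prob_slope *
                  (pressure - model$respond_prob_mid))
}

#' Ground-truth calcium trace for a protocol
#'
#' Sums unit-peak transient kernels over the protocol's stimuli, scaled
#' by the per-stimulus amplitudes, to give the true \eqn{\Delta R/R_0}
#' time series the scene generator embeds in the green channel.
#'
#' @param times Sample times in seconds.
#' @param protocol A [stim_protocol()].
#' @param amplitudes Per-stimulus peak amplitudes
#'   (\eqn{\Delta R/R_0} units).
#' @param model A [response_model()].
#' @return Numeric vector of \eqn{\Delta R/R_0} values, one per time.
#' @export
true_trace <- function(times, protocol, amplitudes, model) {
  stopifnot(inherits(protocol, "stim_protocol"),
            length(amplitudes) == n_stimuli(protocol))
  out <- numeric(length(times))
  for (i in seq_len(n_stimuli(protocol))) {
    d <- protocol$durations[i]
    out <- out + amplitudes[i] *
      calcium_kernel(times - protocol$onsets[i], d, model) /
      kernel_peak(d, model)
  }
  out
}

#' Draw per-stimulus amplitudes for one trial
#'
#' Combines the deterministic dose--response amplitude, optional
#' habituation multipliers, trial-to-trial lognormal variability and the
#' Bernoulli responder draw. Uses the current RNG state; seed upstream.
#'
#' @param protocol A [stim_protocol()].
#' @param model A [response_model()].
#' @param habituation One of `"none"`, `"short_isi"`, `"long_isi"`, or a
#'   numeric vector of per-stimulus multipliers.
#' @param amp_cv Lognormal coefficient of variation of trial amplitude
#'   (0 disables variability).
#' @param responders Optional logical vector overriding the Bernoulli
#'   responder draw (e.g. all `TRUE` for deterministic scenes).
#' @return List with `amplitude` (per stimulus), `responder` (logical),
#'   and `multiplier` as used.
#' @export
draw_amplitudes <- function(protocol, model, habituation = "none",
                            amp_cv = 0, responders = NULL) {
  k <- n_stimuli(protocol)
  mult <- if (is.numeric(habituation)) {
    if (length(habituation) != k) {
      stop("habituation multipliers must pair with stimuli")
    }
    habituation
  } else {
    switch(match.arg(habituation, c("none", "short_isi", "long_isi")),
           none = rep(1, k),
           short_isi = rep_len(model$habituation_short_isi, k),
           long_isi = rep_len(model$habituation_long_isi, k))
  }
  if (is.null(responders)) {
    responders <- stats::runif(k) <
      respond_probability(protocol$pressures, model)
  }
  stopifnot(length(responders) == k)
  base <- simulate_amplitude(protocol$pressures, protocol$durations, model)
  noise <- if (amp_cv > 0) {
    sdlog <- sqrt(log(1 + amp_cv^2))
    stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, k)
  list(amplitude = base * mult * noise * as.numeric(responders),
       responder = as.logical(responders),
       multiplier = mult)
}
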