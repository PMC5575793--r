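#' Peak response within a stimulus window
#'
#' Maximum of \eqn{\Delta R/R_0} over the window from the stimulus onset
#' to the next onset (or the end of the recording), using valid frames
#' only; ties are broken by the earliest time.
#'
#' @param trace A normalized `calcium_trace`.
#' @param stimulus_index Which stimulus (1-based).
#' @return List with `max_dRR` and `t_peak` (seconds).
#' @export
peak_response <- function(trace, stimulus_index = 1) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.null(trace$data$dRR)) stop("trace is not normalized")
  win <- stimulus_window(trace$protocol, stimulus_index)
  sel <- trace$time >= win[1] & trace$time < win[2] & trace$data$valid
  if (!any(sel)) stop("no valid frames in the stimulus window")
  v <- trace$data$dRR[sel]
  t <- trace$time[sel]
  i <- which.max(v)                      # first max: earliest-time tie-break
  list(max_dRR = v[i], t_peak = t[i])
}

#' Delay time: stimulus end to peak arrival
#'
#' \eqn{t_{peak} - (onset + duration)}. Negative values (peak during the
#' stimulus) are reported as-is; the companion flag in [trial_metrics()]
#' marks them.
#'
#' @param t_peak Peak time, seconds.
#' @param protocol A [stim_protocol()].
#' @param stimulus_index Which stimulus.
#' @return Delay in seconds (may be negative).
#' @export
delay_time <- function(t_peak, protocol, stimulus_index = 1) {
  t_peak - (protocol$onsets[stimulus_index] +
              protocol$durations[stimulus_index])
}

#' Half-life of the response decay
#'
#' First time after the peak at which \eqn{\Delta R/R_0} falls to half
#' the peak value, linearly interpolated between the bracketing frames,
#' minus the peak time. `NA` (with attribute `reason`) if the peak is
#' not positive or the trace never crosses half-maximum before the
#' recording ends.
#'
#' @param trace A normalized `calcium_trace`.
#' @param t_peak Peak time, seconds.
#' @param max_dRR Peak value.
#' @return Half-life in seconds, or `NA`.
#' @export
half_life <- function(trace, t_peak, max_dRR) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.na(max_dRR) || max_dRR <= 0) {
    return(structure(NA_real_, reason = "nonpositive peak"))
  }
  sel <- trace$time >= t_peak & trace$data$valid
  t <- trace$time[sel]
  v <- trace$data$dRR[sel]
  half <- max_dRR / 2
  below <- which(v <= half)
  below <- below[below > 1]              # need a bracketing frame above half
  if (length(below) == 0) {
    return(structure(NA_real_, reason = "no half-max crossing"))
  }
  j <- below[1]
  # linear interpolation between frames j-1 (above half) and j
  t_half <- t[j - 1] + (t[j] - t[j - 1]) *
    (v[j - 1] - half) / (v[j - 1] - v[j])
  t_half - t_peak
}

#' Responder classification
#'
#' A trial responds if its peak \eqn{\Delta R/R_0} is strictly greater
#' than the threshold (default 0.5).
#'
#' @param max_dRR Peak value(s) (vectorized).
#' @param threshold Responder threshold (default 0.5, strict).
#' @return Logical vector.
#' @export
classify_responder <- function(max_dRR, threshold = 0.5) {
  max_dRR > threshold
}

#' Response fraction of a set of trials
#'
#' Fraction of trials whose peak exceeds the threshold (strictly).
#'
#' @param peaks Vector of per-trial peak \eqn{\Delta R/R_0} values.
#' @param threshold Responder threshold (default 0.5).
#' @return Fraction in \[0, 1\].
#' @export
response_fraction <- function(peaks, threshold = 0.5) {
  if (length(peaks) == 0) stop("no trials")
  mean(classify_responder(peaks, threshold))
}

#' All per-trial metrics for one stimulus
#'
#' Bundles peak, delay time (with a flag when the peak arrives during
#' the stimulus), half-life (with a definedness flag) and responder
#' status for one stimulus of one trace.
#'
#' @param trace A normalized `calcium_trace`.
#' @param stimulus_index Which stimulus.
#' @param threshold Responder threshold.
#' @return One-row `data.frame`: `stimulus_index`, `max_dRR`, `t_peak`,
#'   `delay_time`, `delay_during_stimulus`, `half_life`,
#'   `half_life_defined`, `responder`.
#' @export
trial_metrics <- function(trace, stimulus_index = 1, threshold = 0.5) {
  pk <- peak_response(trace, stimulus_index)
  dl <- delay_time(pk$t_peak, trace$protocol, stimulus_index)
  hl <- half_life(trace, pk$t_peak, pk$max_dRR)
  data.frame(stimulus_index = stimulus_index,
             max_dRR = pk$max_dRR, t_peak = pk$t_peak,
             delay_time = dl, delay_during_stimulus = dl < 0,
             half_life = as.numeric(hl),
             half_life_defined = !is.na(hl),
             responder = classify_responder(pk$max_dRR, threshold))
}

#' Summarize trials over a pressure x duration grid
#'
#' Per tested (pressure, duration) cell: mean and median peak response,
#' response fraction, and trial count. Untested cells are simply absent
#' from the output.
#'
#' @param trials `data.frame` with columns `pressure`, `duration`,
#'   `max_dRR`.
#' @param threshold Responder threshold.
#' @return `data.frame` with columns `pressure`, `duration`,
#'   `mean_peak`, `median_peak`, `response_fraction`, `n`.
#' @export
summarize_grid <- function(trials, threshold = 0.5) {
  stopifnot(nrow(trials) > 0,
            all(c("pressure", "duration", "max_dRR") %in% names(trials)))
  key <- interaction(trials$pressure, trials$duration, drop = TRUE)
  out <- do.call(rbind, lapply(split(trials, key), function(d) {
    data.frame(pressure = d$pressure[1], duration = d$duration[1],
               mean_peak = mean(d$max_dRR),
               median_peak = stats::median(d$max_dRR),
               response_fraction = response_fraction(d$max_dRR, threshold),
               n = nrow(d))
  }))
  out <- out[order(out$pressure, out$duration), ]
  rownames(out) <- NULL
  out
}

#' Per-stimulus peak sequence under repeated stimulation
#'
#' Applies [peak_response()] to every inter-onset window of a repeated
#' stimulus protocol, the summary behind habituation analysis.
#'
#' @param trace A normalized `calcium_trace` whose protocol has at least
#'   two stimuli.
#' @return List with `per_stimulus_peaks`, `t_peaks`, `isi` (seconds
#'   between consecutive onsets minus the duration; the inter-stimulus
#'   gap of the first pair), and `n_stimuli`.
#' @export
habituation_series <- function(trace) {
  stopifnot(inherits(trace, "calcium_trace"))
  k <- n_stimuli(trace$protocol)
  if (k < 2) stop("habituation needs at least 2 stimuli")
  pk <- lapply(seq_len(k), function(i) peak_response(trace, i))
  list(per_stimulus_peaks = vapply(pk, `[[`, numeric(1), "max_dRR"),
       t_peaks = vapply(pk, `[[`, numeric(1), "t_peak"),
       isi = trace$protocol$onsets[2] - trace$protocol$onsets[1] -
         trace$protocol$durations[1],
       n_stimuli = k)
}

#' Frame-wise ensemble mean and SEM of aligned traces
#'
#' Averages \eqn{\Delta R/R_0} frame-wise over trials recorded under the
#' same protocol (the mean +/- SEM traces of ensemble figures). Invalid
#' frames are dropped per trial.
#'
#' @param traces List of normalized `calcium_trace`s of equal length.
#' @return `data.frame` with `time_s`, `mean_dRR`, `sem_dRR`, `n`.
#' @export
ensemble_mean <- function(traces) {
  stopifnot(length(traces) >= 1)
  nfr <- length(traces[[1]]$time)
  m <- vapply(traces, function(tr) {
    stopifnot(length(tr$time) == nfr)
    ifelse(tr$data$valid, tr$data$dRR, NA_real_)
  }, numeric(nfr))
  m <- matrix(m, nrow = nfr)
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  sem <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  })
  data.frame(time_s = traces[[1]]$time, mean_dRR = mu,
             sem_dRR = sem, n = n)
}
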