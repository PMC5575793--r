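#' Stimulus protocol
#'
#' Describes one imaging trial: when each mechanical stimulus starts, how
#' long it lasts, its nominal actuation pressure, the pre-stimulus baseline
#' window used for normalization, and the total recording length.
#'
#' @param onsets Numeric vector of stimulus onset times in seconds,
#'   strictly increasing. Time 0 is the first recorded frame.
#' @param durations Numeric vector of stimulus durations in seconds,
#'   one per onset, all positive.
#' @param pressures Numeric vector of nominal actuation pressures in psi,
#'   one per onset.
#' @param baseline_window Seconds of pre-stimulus recording; must be
#'   positive and no later than the first onset. Defaults to the first
#'   onset (all pre-stimulus frames are baseline).
#' @param record_duration Total recording length in seconds; must cover
#'   the last stimulus.
#'
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol(onsets = 10, durations = 1, pressures = 40,
#'               record_duration = 30)
#' @export
stim_protocol <- function(onsets, durations, pressures,
                          baseline_window = min(onsets),
                          record_duration) {
  stopifnot(is.numeric(onsets), length(onsets) >= 1,
            is.numeric(durations), is.numeric(pressures))
  if (length(durations) == 1L) durations <- rep(durations, length(onsets))
  if (length(pressures) == 1L) pressures <- rep(pressures, length(onsets))
  if (length(durations) != length(onsets) ||
      length(pressures) != length(onsets)) {
    stop("`durations` and `pressures` must pair with `onsets`")
  }
  if (length(onsets) > 1 && any(diff(onsets) <= 0)) {
    stop("`onsets` must be strictly increasing")
  }
  if (any(durations <= 0)) stop("`durations` must be positive")
  if (any(pressures < 0)) stop("`pressures` must be nonnegative")
  if (baseline_window <= 0) stop("`baseline_window` must be positive")
  if (baseline_window > onsets[1]) {
    stop("`baseline_window` extends past the first stimulus onset")
  }
  n <- length(onsets)
  if (record_duration < onsets[n] + durations[n]) {
    stop("`record_duration` must cover the last stimulus")
  }
  structure(
    list(onsets = as.numeric(onsets), durations = as.numeric(durations),
         pressures = as.numeric(pressures),
         baseline_window = as.numeric(baseline_window),
         record_duration = as.numeric(record_duration)),
    class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d stimulus(es), %.1f s recording\n",
              length(x$onsets), x$record_duration))
  cat(sprintf("  onsets (s):    %s\n", paste(x$onsets, collapse = ", ")))
  cat(sprintf("  durations (s): %s\n", paste(x$durations, collapse = ", ")))
  cat(sprintf("  pressures (psi): %s\n", paste(x$pressures, collapse = ", ")))
  invisible(x)
}

n_stimuli <- function(protocol) length(protocol$onsets)

# window [onset, next onset) used for per-stimulus metrics; last window
# runs to the end of the recording
stimulus_window <- function(protocol, stimulus_index) {
  k <- n_stimuli(protocol)
  if (stimulus_index < 1 || stimulus_index > k) {
    stop("invalid `stimulus_index`")
  }
  lo <- protocol$onsets[stimulus_index]
  hi <- if (stimulus_index < k) protocol$onsets[stimulus_index + 1]
        else protocol$record_duration
  c(lo, hi)
}
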