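proto1 <- stim_protocol(onsets = 10, durations = 1, pressures = 40,
                        record_duration = 30)

# index of the grid time closest to t (avoids exact float comparison)
at_t <- function(time, t) which.min(abs(time - t))

test_that("peak_response finds the window maximum with earliest-time ties", {
  time <- seq(0, 30, by = 0.1)
  # flat trace: peak 0 at the onset time
  tr <- trace_from_dRR(time, rep(0, length(time)), proto1)
  pk <- peak_response(tr)
  expect_equal(pk$max_dRR, 0)
  expect_equal(pk$t_peak, 10)

  # triangular pulse peaking 1.2 at t = 13
  d <- pmax(0, 1.2 * (1 - abs(time - 13) / 2))
  pk2 <- peak_response(trace_from_dRR(time, d, proto1))
  expect_equal(pk2$max_dRR, 1.2)
  expect_equal(pk2$t_peak, 13)

  # two equal maxima: earliest wins
  d3 <- rep(0, length(time))
  d3[at_t(time, 12)] <- 1
  d3[at_t(time, 14)] <- 1
  expect_equal(peak_response(trace_from_dRR(time, d3, proto1))$t_peak, 12)
})

test_that("peaks search inter-onset windows and respect locality", {
  proto <- stim_protocol(onsets = c(5, 15), durations = c(1, 1),
                         pressures = c(40, 40), record_duration = 30)
  time <- seq(0, 30, by = 0.1)
  d <- rep(0, length(time))
  d[at_t(time, 7)] <- 0.8
  d[at_t(time, 20)] <- 1.4
  tr <- trace_from_dRR(time, d, proto)
  expect_equal(peak_response(tr, 1)$max_dRR, 0.8)
  expect_equal(peak_response(tr, 2)$max_dRR, 1.4)
  # perturbing outside window 1 does not change window 1's peak
  d2 <- d; d2[at_t(time, 20)] <- 3
  expect_equal(peak_response(trace_from_dRR(time, d2, proto), 1)$max_dRR, 0.8)
  expect_error(peak_response(tr, 3), "stimulus_index")
})

test_that("delay time is the stimulus-end-to-peak interval, sign kept", {
  expect_equal(delay_time(12.5, proto1), 1.5)
  expect_equal(delay_time(11, proto1), 0)
  expect_equal(delay_time(10.6, proto1), -0.4)
  time <- seq(0, 30, by = 0.1)
  d <- rep(0, length(time)); d[at_t(time, 10.6)] <- 1
  mt <- trial_metrics(trace_from_dRR(time, d, proto1))
  expect_equal(mt$delay_time, -0.4)
  expect_true(mt$delay_during_stimulus)
})

test_that("half-life matches the exponential closed form", {
  tau <- 2
  # closed form tau * ln 2, interpolated within one 10 Hz step
  time <- seq(0, 30, by = 0.1)
  d <- ifelse(time >= 12, exp(-(time - 12) / tau), 0)
  tr <- trace_from_dRR(time, d, proto1)
  pk <- peak_response(tr)
  hl <- half_life(tr, pk$t_peak, pk$max_dRR)
  expect_lt(abs(as.numeric(hl) - tau * log(2)), 0.01)

  # interpolation error shrinks with the sampling interval
  errs <- vapply(c(0.2, 0.1, 0.02), function(dt) {
    t <- seq(0, 30, by = dt)
    d <- ifelse(t >= 12, exp(-(t - 12) / tau), 0)
    tr <- trace_from_dRR(t, d, proto1)
    pk <- peak_response(tr)
    abs(as.numeric(half_life(tr, pk$t_peak, pk$max_dRR)) - tau * log(2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[3], 1e-3)

  # clamped trace never crosses half-max
  d2 <- ifelse(time >= 12, 1, 0)
  tr2 <- trace_from_dRR(time, d2, proto1)
  expect_true(is.na(half_life(tr2, 12, 1)))
  # nonpositive peak is undefined with a reason
  hl3 <- half_life(tr, 12, 0)
  expect_true(is.na(hl3))
  expect_match(attr(hl3, "reason"), "peak")
})

test_that("responder threshold is strictly greater-than 0.5", {
  expect_false(classify_responder(0.5))
  expect_true(classify_responder(0.51))
  expect_false(classify_responder(0))
  expect_equal(response_fraction(c(0.4, 0.6, 1.2, 0.2)), 0.5)
  expect_equal(response_fraction(rep(0, 5)), 0)
  expect_error(response_fraction(numeric(0)), "no trials")
})

test_that("response_fraction is order-invariant, duplication-stable and
           consistent with classify_responder", {
  set.seed(12)
  peaks <- runif(40, 0, 2)
  f <- response_fraction(peaks)
  expect_equal(response_fraction(sample(peaks)), f)
  expect_equal(response_fraction(rep(peaks, 3)), f)
  expect_equal(f, mean(classify_responder(peaks)))
})

test_that("measured fraction of a seeded Bernoulli ensemble is near its
           responder probability", {
  model <- response_model()
  # pressure where the logistic responder probability is 0.9
  p90 <- model$respond_prob_mid + log(9) / model$respond_prob_slope
  proto <- stim_protocol(onsets = 10, durations = 1, pressures = p90,
                         record_duration = 30)
  set.seed(77)
  peaks <- replicate(200, {
    sim <- simulate_trace(proto, model, noise_sd = 0.05, amp_cv = 0.25)
    trial_metrics(sim$trace)$max_dRR
  })
  f <- response_fraction(peaks)
  expect_lt(abs(f - 0.9), 3 * sqrt(0.9 * 0.1 / 200))
})

test_that("summarize_grid aggregates cells and reports only tested ones", {
  one <- data.frame(pressure = 45, duration = 1, max_dRR = 1.0)
  g1 <- summarize_grid(one)
  expect_equal(g1$mean_peak, 1)
  expect_equal(g1$response_fraction, 1)
  expect_equal(g1$n, 1L)

  two <- data.frame(pressure = c(45, 45), duration = c(1, 1),
                    max_dRR = c(0.4, 0.8))
  g2 <- summarize_grid(two)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$mean_peak, 0.6)
  expect_equal(g2$median_peak, 0.6)
  expect_equal(g2$response_fraction, 0.5)
  # untested cells are absent
  mixed <- rbind(one, data.frame(pressure = 25, duration = 1, max_dRR = 0.1))
  expect_equal(nrow(summarize_grid(mixed)), 2)
})

test_that("simulated grids are graded in pressure and duration", {
  set.seed(42)
  trials <- simulate_grid_trials(pressures = c(25, 35, 40, 45),
                                 durations = c(1, 2, 5), n_per_cell = 12)
  g <- summarize_grid(trials)
  expect_gt(cor(g$pressure, g$mean_peak, method = "spearman"), 0)
  expect_gt(cor(g$pressure, g$response_fraction, method = "spearman"), 0)
  expect_gt(cor(g$duration, g$mean_peak, method = "spearman"), 0)
  # high-pressure cells respond reliably, low-pressure cells rarely
  hi <- g$response_fraction[g$pressure >= 40]
  lo <- g$response_fraction[g$pressure <= 25]
  expect_gt(min(hi), 0.7)
  expect_lt(max(lo), 0.3)
})

test_that("habituation series recovers the generator's per-window peaks", {
  model <- response_model()
  short <- stim_protocol(onsets = c(10, 12, 14, 16), durations = rep(1, 4),
                         pressures = rep(40, 4), record_duration = 40)
  set.seed(5)
  sim <- simulate_trace(short, model, habituation = "short_isi",
                        noise_sd = 0.02, responders = rep(TRUE, 4))
  hs <- habituation_series(sim$trace)
  expect_equal(hs$n_stimuli, 4)
  expect_equal(hs$isi, 1)
  # oracle: per-window maxima of the noiseless ground-truth trace on a
  # dense grid
  tt <- seq(0, 40, by = 0.005)
  truth <- true_trace(tt, short, simulate_amplitude(40, 1, model) *
                        model$habituation_short_isi, model)
  expected <- vapply(1:4, function(i) {
    win <- c(short$onsets[i], if (i < 4) short$onsets[i + 1] else 40)
    max(truth[tt >= win[1] & tt < win[2]])
  }, numeric(1))
  expect_equal(hs$per_stimulus_peaks, expected, tolerance = 0.1)
})

test_that("per-stimulus ordering matches the multipliers when transients
           are well separated", {
  # fast decay: negligible carryover between consecutive windows
  model <- response_model(tau_decay = 0.8)
  short <- stim_protocol(onsets = c(10, 12, 14, 16), durations = rep(1, 4),
                         pressures = rep(40, 4), record_duration = 40)
  set.seed(6)
  sim <- simulate_trace(short, model, habituation = "short_isi",
                        noise_sd = 0.02, responders = rep(TRUE, 4))
  hs <- habituation_series(sim$trace)
  expect_equal(order(hs$per_stimulus_peaks, decreasing = TRUE),
               order(model$habituation_short_isi, decreasing = TRUE))

  # long intervals: strictly decreasing multipliers recovered as a
  # strictly decreasing peak series
  long <- stim_protocol(onsets = c(10, 40, 70, 100), durations = rep(2, 4),
                        pressures = rep(40, 4), record_duration = 140)
  sim2 <- simulate_trace(long, response_model(), habituation = "long_isi",
                         noise_sd = 0.02, responders = rep(TRUE, 4))
  hs2 <- habituation_series(sim2$trace)
  expect_true(all(diff(hs2$per_stimulus_peaks) < 0))

  # identical repeated responses give a constant series
  time <- seq(0, 40, by = 0.1)
  d <- rep(0, length(time))
  for (on in c(10, 12, 14, 16)) d[at_t(time, on + 1)] <- 1
  expect_equal(habituation_series(trace_from_dRR(time, d, short))$per_stimulus_peaks,
               rep(1, 4))
  mono <- stim_protocol(onsets = 10, durations = 1, pressures = 40,
                        record_duration = 30)
  keep <- time <= 30
  expect_error(habituation_series(trace_from_dRR(time[keep], d[keep], mono)),
               "at least 2")
})

test_that("ensemble_mean averages frame-wise with SEM", {
  time <- seq(0, 30, by = 0.1)
  trs <- lapply(c(0.5, 1.5), function(a) {
    trace_from_dRR(time, a * ifelse(time >= 11, exp(-(time - 11) / 2), 0),
                   proto1)
  })
  em <- ensemble_mean(trs)
  i <- at_t(time, 11)
  expect_equal(em$mean_dRR[i], 1)
  expect_equal(em$sem_dRR[i], sd(c(0.5, 1.5)) / sqrt(2))
  expect_true(all(em$n == 2))
})
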