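spec_at <- function(bg = c(15, 15), ...) {
  roi_spec(background_center = bg, ...)
}

test_that("roi_intensity reproduces hand-computed top-k means", {
  spec <- spec_at()
  # constant disc -> the constant
  fr <- matrix(5, 60, 60)
  expect_equal(as.numeric(roi_intensity(fr, c(30, 30), spec)), 5)

  # exactly 100 pixels at 10, rest 0 -> 10
  fr <- matrix(0, 60, 60)
  px <- which(outer((1:60 - 30)^2, (1:60 - 30)^2, "+") <= 100)[1:100]
  fr[px] <- 10
  expect_equal(as.numeric(roi_intensity(fr, c(30, 30), spec)), 10)

  # 50 pixels at 10, rest 0 -> mean of 50 tens and 50 zeros
  fr <- matrix(0, 60, 60)
  fr[which(outer((1:60 - 30)^2, (1:60 - 30)^2, "+") <= 100)[1:50]] <- 10
  expect_equal(as.numeric(roi_intensity(fr, c(30, 30), spec)), 5)
})

test_that("roi_intensity flags truncated discs and rejects empty ones", {
  spec <- spec_at()
  fr <- matrix(1, 40, 40)
  v <- roi_intensity(fr, c(1, 1), spec)    # corner disc < 100 px
  expect_true(isTRUE(attr(v, "truncated")))
  expect_error(roi_intensity(fr, c(-50, -50), spec), "outside")
})

test_that("roi_intensity is permutation-invariant, monotone, translation-equivariant", {
  set.seed(7)
  spec <- spec_at()
  fr <- matrix(runif(70 * 70, 0, 50), 70, 70)
  base <- as.numeric(roi_intensity(fr, c(35, 35), spec))

  # permuting pixels inside the disc leaves the statistic unchanged
  px <- which(outer((1:70 - 35)^2, (1:70 - 35)^2, "+") <= 100)
  fr_p <- fr
  fr_p[px] <- fr[sample(px)]
  expect_equal(as.numeric(roi_intensity(fr_p, c(35, 35), spec)), base)

  # raising any pixel cannot decrease it
  fr_up <- fr
  fr_up[px[13]] <- fr_up[px[13]] + 100
  expect_gte(as.numeric(roi_intensity(fr_up, c(35, 35), spec)), base)

  # shifting frame and center together changes nothing
  sh <- matrix(0, 70, 70)
  sh[6:70, 4:70] <- fr[1:65, 1:67]
  expect_equal(as.numeric(roi_intensity(sh, c(35 + 5, 35 + 3), spec)), base)
})

test_that("background_intensity is a plain mean and rejects overlap", {
  spec <- spec_at(bg = c(30, 30))
  fr <- matrix(50, 60, 60)
  expect_equal(background_intensity(fr, spec), 50)
  fr[, 1:30] <- 40; fr[, 31:60] <- 60
  # disc centered on the half boundary: halves average out
  expect_equal(background_intensity(fr, spec), 50, tolerance = 0.04)
  expect_error(background_intensity(fr, spec, signal_center = c(35, 30)),
               "overlap")
})

test_that("ratio and fluorescence follow the stated formulas", {
  # R = (I_G_roi - I_G_back) / (I_R_roi - I_R_back) on constructed stacks
  g <- array(50, c(60, 60, 3)); r <- array(50, c(60, 60, 3))
  soma <- outer((1:60 - 30)^2, (1:60 - 30)^2, "+") <= 100
  for (k in 1:3) {
    gk <- matrix(50, 60, 60); gk[soma] <- 200
    rk <- matrix(50, 60, 60); rk[soma] <- 100
    g[, , k] <- gk; r[, , k] <- rk
  }
  gs <- image_stack(g, 0.1); rs <- image_stack(r, 0.1)
  traj <- data.frame(frame = 1:3, time_s = (0:2) * 0.1,
                     row = 30, col = 30, confidence = "locked")
  proto <- stim_protocol(onsets = 0.2, durations = 0.05, pressures = 40,
                         record_duration = 0.3)
  spec <- spec_at()
  tr <- ratio_trace(traj, gs, rs, spec, proto)
  expect_equal(tr$data$R_or_F, rep((200 - 50) / (100 - 50), 3))

  # identical stacks -> R = 1 everywhere
  tr1 <- ratio_trace(traj, gs, gs, spec, proto)
  expect_equal(tr1$data$R_or_F, rep(1, 3))

  # F = I_G_roi - I_G_back
  trf <- fluor_trace(traj, gs, spec, proto)
  expect_equal(trf$data$R_or_F, rep(150, 3))

  # dialect without red background subtraction
  tr2 <- ratio_trace(traj, gs, rs, spec, proto,
                     subtract_red_background = FALSE)
  expect_equal(tr2$data$R_or_F, rep(150 / 100, 3))
})

test_that("frames with non-positive red denominator are flagged invalid", {
  g <- array(60, c(60, 60, 4)); r <- array(50, c(60, 60, 4))
  soma <- outer((1:60 - 30)^2, (1:60 - 30)^2, "+") <= 100
  for (k in 1:4) {
    gk <- matrix(50, 60, 60); gk[soma] <- 200; g[, , k] <- gk
    rk <- matrix(50, 60, 60); rk[soma] <- if (k == 3) 40 else 100
    r[, , k] <- rk
  }
  traj <- data.frame(frame = 1:4, time_s = (0:3) * 0.1,
                     row = 30, col = 30, confidence = "locked")
  proto <- stim_protocol(onsets = 0.3, durations = 0.05, pressures = 40,
                         record_duration = 0.4)
  tr <- ratio_trace(traj, image_stack(g, 0.1), image_stack(r, 0.1),
                    spec_at(), proto)
  expect_identical(tr$data$valid, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("normalization uses the pre-stimulus mean and centers it at zero", {
  proto <- stim_protocol(onsets = 1, durations = 0.2, pressures = 40,
                         record_duration = 2)
  time <- seq(0, 2, by = 0.1)
  R <- rep(2, length(time))
  tr <- trace_from_dRR(time, R - 1, proto)   # constant trace R = 2
  tr$data$R_or_F <- R; tr$data$dRR <- NULL
  tr <- normalize_trace(tr)
  expect_equal(tr$baseline, 2)
  expect_equal(tr$data$dRR, rep(0, length(time)))

  # baseline 1.0, peak 2.5 -> peak dRR 1.5
  R2 <- rep(1, length(time)); R2[15] <- 2.5
  tr2 <- trace_from_dRR(time, R2 - 1, proto)
  tr2$data$R_or_F <- R2; tr2$data$dRR <- NULL
  tr2 <- normalize_trace(tr2)
  expect_equal(max(tr2$data$dRR), 1.5)

  # pre-stimulus mean of dRR is exactly zero by construction
  set.seed(8)
  R3 <- 2 + rnorm(length(time), 0, 0.1)
  tr3 <- trace_from_dRR(time, R3 - 1, proto)
  tr3$data$R_or_F <- R3; tr3$data$dRR <- NULL
  tr3 <- normalize_trace(tr3)
  expect_equal(mean(tr3$data$dRR[time < 1]), 0, tolerance = 1e-12)

  expect_error(normalize_trace(tr3, min_baseline_frames = 50), "pre-stimulus")
})

test_that("gain fluctuations cancel in the ratiometric trace", {
  proto <- default_protocol(12)
  n <- 121
  path <- matrix(rep(c(48, 48), each = n), ncol = 2)
  mk <- function(gain) scene_config(
    n_frames = n, neuron_path = path, background_texture_rel = 0,
    bleach_rate = 0, noise_sd = 0, motion_gain_series = gain, rng_seed = 3)
  gain <- motion_gain_wave(n, 0.1, amplitude = 0.3)
  sc_g <- render_scene(mk(gain), proto, response_model(), responders = TRUE)
  sc_1 <- render_scene(mk(rep(1, n)), proto, response_model(),
                       responders = TRUE)
  spec <- spec_at()
  traj <- track_neuron(sc_g$red, c(48, 48))
  dRR <- normalize_trace(ratio_trace(traj, sc_g$green, sc_g$red,
                                     spec, proto))$data$dRR
  traj1 <- track_neuron(sc_1$green, c(48, 48), channel = "green")
  dFF <- normalize_trace(fluor_trace(traj1, sc_1$green, spec,
                                     proto))$data$dRR
  expect_lt(max(abs(dRR - dFF)), 1e-9)
  # and with no transient the ratio is flat despite the gain wave
  sc_0 <- render_scene(mk(gain), proto, response_model(),
                       responders = FALSE)
  tr0 <- normalize_trace(ratio_trace(track_neuron(sc_0$red, c(48, 48)),
                                     sc_0$green, sc_0$red, spec, proto))
  expect_lt(max(abs(tr0$data$dRR)), 1e-9)
})

test_that("end-to-end extraction recovers the ground-truth trace", {
  sc <- small_scene(55)
  out <- extract_scene(sc)
  rmse <- sqrt(mean((out$trace$data$dRR - sc$ground_truth$true_trace)^2))
  expect_lt(rmse, 0.05)
})
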