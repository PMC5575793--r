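# Shared fixtures: small frames and scenes built in code.

# Gaussian blob frame on a constant background
blob_frame <- function(shape = c(80, 80), center = c(40, 60),
                       sigma = 3, amplitude = 100, background = 0) {
  r <- seq_len(shape[1]); c <- seq_len(shape[2])
  background + amplitude *
    exp(-outer((r - center[1])^2, (c - center[2])^2, "+") / (2 * sigma^2))
}

# single-stimulus protocol used throughout: 1 s, 40 psi at t = 10 s
default_protocol <- function(record_duration = 25) {
  stim_protocol(onsets = 10, durations = 1, pressures = 40,
                record_duration = record_duration)
}

# small rendered scene with a moving soma; deterministic per seed
small_scene <- function(seed, protocol = default_protocol(),
                        n_frames = 250, noise_sd = 2, responders = TRUE,
                        ...) {
  cfg <- scene_config(n_frames = n_frames, rng_seed = seed,
                      noise_sd = noise_sd,
                      motion_gain_series = motion_gain_wave(n_frames, 0.1),
                      ...)
  render_scene(cfg, protocol, response_model(), responders = responders)
}

# run the full chain on a scene: track on red, extract ratio, normalize
extract_scene <- function(scene, protocol = default_protocol()) {
  start <- locate_neuron(scene$red[, , 1])
  traj <- track_neuron(scene$red, start)
  bg <- pick_background(scene$red[, , 1], avoid = start)
  spec <- roi_spec(background_center = bg)
  list(trace = normalize_trace(ratio_trace(traj, scene$green, scene$red,
                                           spec, protocol)),
       traj = traj, spec = spec)
}

# brute-force two-sided Mann-Whitney p by enumerating every assignment
# of the pooled ranks to the x sample (independent oracle)
enumerate_mw_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(N, n)          # tie-free: ranks are 1..N
  u_all <- colSums(combos) - n * (n + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
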