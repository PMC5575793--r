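# touchtrace

Quantification of stimulus-evoked calcium imaging in *C. elegans*
mechanosensory neurons.

When a trapped (but not immobilized) worm expressing GCaMP6 and a
calcium-independent RFP reference is given a controlled mechanical
stimulus, the recording is a two-channel time-lapse stack in which the
labeled soma drifts, the illumination fluctuates, the fluorophores bleach
and the camera adds noise. This package turns such stacks into calibrated
response measurements:

1. **Tracking** — locate the soma in every frame (brightest-region search
   with centroid refinement and coasting through dropouts).
2. **Extraction** — per frame, the mean of the 100 brightest pixels in a
   10 px-radius ROI, background-subtracted in each channel, and the ratio

   *R* = (*I*<sub>G,ROI</sub> − *I*<sub>G,back</sub>) / (*I*<sub>R,ROI</sub> − *I*<sub>R,back</sub>),

   which cancels motion/illumination artifacts shared by the channels
   (single-channel *F* = *I*<sub>G,ROI</sub> − *I*<sub>G,back</sub> when no
   reference is available).
3. **Normalization** — ΔR/R₀ = (R − R₀)/R₀ with R₀ the mean over all
   pre-stimulus frames.
4. **Metrics** — per trial: peak ΔR/R₀, delay time (stimulus end → peak),
   half-life of the decay, responder status (peak > 0.5); per ensemble:
   mean ± SEM traces, pressure × duration grids of mean peak and response
   fraction, habituation series under repeated stimulation.
5. **Screen statistics** — per-day control normalization, exact/corrected
   Mann–Whitney and tie-corrected Kruskal–Wallis tests with significance
   stars.

A synthetic two-channel scene generator (`render_scene()`) with exact
ground truth — neuron path, true ΔR/R₀ trace, responder draws — replaces
the microscope, so the entire chain is tested end to end with no recorded
data.

## Worked example

```r
library(touchtrace)

# one trial: 1 s, 40 psi stimulus at t = 10 s, 25 s recording at 10 Hz
protocol <- stim_protocol(onsets = 10, durations = 1, pressures = 40,
                          record_duration = 25)
config <- scene_config(n_frames = 250, rng_seed = 7,
                       motion_gain_series = motion_gain_wave(250, 0.1))
scene <- render_scene(config, protocol, response_model(), responders = TRUE)

start <- locate_neuron(scene$red[, , 1])
traj  <- track_neuron(scene$red, start)            # red channel: stable
spec  <- roi_spec(background_center =
                    pick_background(scene$red[, , 1], avoid = start))
trace <- normalize_trace(ratio_trace(traj, scene$green, scene$red,
                                     spec, protocol))
trial_metrics(trace)
#>   stimulus_index  max_dRR t_peak delay_time delay_during_stimulus
#> 1              1 0.889707   11.5        0.5                 FALSE
#>   half_life half_life_defined responder
#> 1  2.671606              TRUE      TRUE
```

The trial peaks at ΔR/R₀ ≈ 0.89 half a second after the stimulus ends and
decays with a ~2.7 s half-life — against a generator ground-truth peak of
0.897, i.e. <1% error; the extracted trace matches the true trace with
RMSE ≈ 0.007 despite the drifting soma, a ±30% illumination wave,
photobleaching and sensor noise. `summarize_grid()` +
`simulate_grid_trials()` reproduce graded dose–response behaviour (high
response fractions at ≥40 psi, rare responses at 25 psi), and
`screen_report()` + `simulate_screen()` recover planted compound effects
(see `analysis/`).

## Analysis workflow

The `analysis/` directory is a numbered narrative over the package:

| script | what it does |
|---|---|
| `01_simulate_scene.R` | render the demonstration scene; write split-frame TIFF + ground truth |
| `02_track_and_extract.R` | read it back, track, extract, normalize; compare to ground truth |
| `03_dose_response.R` | pressure × duration grid and habituation series |
| `04_calibration.R` | displacement-vs-pressure line fit on a synthetic table |
| `05_screen.R` | synthetic drug screen with planted effects, full report |

Each script prints what it found and writes tables under `results/`
(larger artifacts, e.g. TIFF stacks and figures, go to `scratch/`). Run
them in order from the repository root after installing the package.

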