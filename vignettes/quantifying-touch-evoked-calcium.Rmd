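---
title: "Quantifying touch-evoked calcium transients: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying touch-evoked calcium transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(touchtrace)
```

## The measurement problem

A *C. elegans* mechanosensory neuron (a gentle-touch cell such as AVM, or
the harsh-touch cell PVD) expressing the calcium indicator GCaMP6 and a
calcium-independent RFP reference is imaged at 10 Hz while a pressure-actuated
membrane delivers a controlled mechanical stimulus. The animal is trapped but
not immobilized, so the soma drifts within the field of view; illumination
and focus fluctuate; the fluorophores bleach; and the camera adds noise. The
quantity of interest is the relative change of the green/red intensity ratio
from its pre-stimulus baseline, $\Delta R/R_0$, and a handful of scalar
summaries per trial: the peak response, the delay from stimulus end to the
peak, the half-life of the decay, and whether the trial "responded" at all.

The package implements that chain — tracking, ROI extraction, ratio,
baseline normalization, metrics, ensemble summaries, and screen statistics —
together with a synthetic scene generator that stands in for the microscope
and provides exact ground truth, so every stage can be tested end to end
without any recorded data.

## The extraction model

For each frame, with the soma tracked at a position $c_t$:

* **Signal ROI**: the mean of the 100 brightest pixels within a disc of
  10-pixel radius around $c_t$, per channel. The top-$k$ statistic makes the
  measure insensitive to sub-pixel tracking error and to the exact disc
  rasterization; both $k$ and the radius are configurable in `roi_spec()`.
* **Background**: the plain mean over a fixed disc in a neuron-free region,
  per channel, subtracted from the ROI value to absorb frame-wide lighting
  changes. `pick_background()` proposes a center from the darkest decile of
  the first frame, as far from the neuron as possible.
* **Ratio**: $R_t = (I^G_{ROI} - I^G_{back}) / (I^R_{ROI} - I^R_{back})$.
  Because movement, focus and illumination artifacts multiply both channels
  by the same factor, they cancel exactly in $R$. Whether the red
  background is subtracted before dividing is a documented dialect
  (`subtract_red_background`, default `TRUE`); with a single channel,
  $F_t = I^G_{ROI} - I^G_{back}$ is used instead.
* **Normalization**: $R_0$ is the mean of $R_t$ over all valid frames
  before the first stimulus onset (at least 5 required), and
  $\Delta R/R_0 = (R_t - R_0)/R_0$. The pre-stimulus mean of
  $\Delta R/R_0$ is zero by construction.

Frames where the red denominator is not positive are flagged invalid and
excluded from all metric computations.

### Coordinates and rasterization

Positions are 1-based `(row, col)` pixel coordinates and frames are 1-based,
with `time = (frame - 1) * frame_interval` — the R convention, applied
consistently across trajectories, traces and CSV output. A pixel belongs to
a disc when its center lies within the radius of the *rounded* disc center;
ties at the top-$k$ cutoff are resolved by (row, col) scan order so the
statistic is reproducible bit for bit.

## Tracking

`track_neuron()` follows the soma frame by frame: the brightest pixel
within `search_radius` (default 15 px at 10 Hz — the animal's residual
motion is small but not zero) of the previous position, refined to an
intensity-weighted centroid over a 5 px disc after flooring at the local
background. Ties between equally bright pixels break deterministically by
smallest row, then column. If the candidate peak — smoothed over a 3×3
neighborhood so a single hot pixel cannot pass — fails to clear the local
background mean + 3 SD (estimated on a one-pixel ring around the search
window), the frame is marked `coasted` and the last locked position is
held; this tolerates transient defocus or blinking without letting the
tracker drift onto noise. Displacements between consecutive locked frames
are clipped to `search_radius`, so the reported trajectory can never jump
farther than the search allows. Tracking runs on the red channel when
available, since that signal does not change with the stimulus;
`locate_neuron()` initializes from the brightest connected region of the
first frame (threshold halfway between the frame minimum and maximum,
4-connected component containing the global maximum, intensity-weighted
centroid).

No sub-pixel interpolation beyond the centroid is attempted: the top-$k$
ROI statistic is insensitive to shifts below a pixel, and on rendered
scenes the tracker's median error is ~0.2 px.

## Response metrics

All metrics operate on the normalized trace:

* **Peak**: maximum of $\Delta R/R_0$ over the window from a stimulus onset
  to the next onset (or the recording end) — inter-onset windows keep
  repeated-stimulus analyses well defined; ties break to the earliest time.
* **Delay time**: $t_{peak} - (onset + duration)$. A peak during the
  stimulus yields a negative delay, reported as-is with a flag rather than
  clamped, so the edge case stays visible.
* **Half-life**: the first post-peak time where the trace falls to half the
  peak, linearly interpolated between the bracketing frames. Traces that
  never cross half-maximum before the recording ends give `NA` with a
  reason; undefined half-lives are excluded from screen statistics with
  reported counts rather than imputed.
* **Responder**: peak strictly greater than 0.5 (configurable). The strict
  inequality matters only at the boundary but is part of the definition.
* **Ensembles**: `ensemble_mean()` averages frame-wise across trials
  aligned on the common protocol; `summarize_grid()` reports mean *and*
  median peak per (pressure, duration) cell (the mean is the headline
  number; both are kept because the choice is not dictated by anything),
  the response fraction, and the trial count. Untested cells are simply
  absent.

## The synthetic scene generator

`render_scene()` produces, per frame $t$ at position $p_t$:

$$G_t = g_t\,[B + \beta_t\,(S_0 + \gamma\,a_t)\,\phi(p_t)] + \varepsilon,
\qquad
R_t = g_t\,[B + \beta_t\,\rho\,\phi(p_t)] + \varepsilon$$

with $\phi$ a Gaussian soma blob (σ = 3 px), $B$ a static textured
background, $g_t$ a shared multiplicative illumination artifact,
$\beta_t = e^{-\lambda t}$ photobleaching applied to the fluorophore terms
only (so background subtraction stays meaningful), $\varepsilon$ additive
Gaussian sensor noise, and $a_t$ the ground-truth $\Delta R/R_0$ trace.
With the default `gcamp_gain` $\gamma = S_0$, the noiseless pipeline output
equals $a_t$ exactly. Both channels share the path, gain and background, so
the ratio cancels what it is supposed to cancel — and the generator records
everything (`true_trace`, `true_path`, responder draws, per-stimulus
amplitudes) for comparison.

The kinetic model is deliberately phenomenological: a saturating rise with
time constant `tau_rise` (0.5 s) while the stimulus is on, a peak at
`duration + tau_rise` (shortly after stimulus end, as observed traces
peak), then exponential decay with `tau_decay` (4 s). Transients from
successive stimuli sum linearly, so at short inter-stimulus intervals the
measured window peaks ride on the preceding decay. The dose side is a Hill
function of pressure (midpoint 30 psi, coefficient 4, saturating amplitude
3 $\Delta R/R_0$ — the upper end of the observed response scale) times
$1 - e^{-d/2\,\mathrm{s}}$ in duration. Whether a stimulus elicits any
response is Bernoulli with a logistic probability in pressure (midpoint
33 psi, slope 0.5 psi⁻¹), which places the reliable regime (>95%) above
40 psi and the stochastic regime (<5%) below 25 psi. Habituation is encoded
as per-stimulus amplitude multipliers: facilitation to the second stimulus
then depression at short intervals, monotone depression at long intervals.
None of these functional forms or constants are measured quantities; they
are the package's own calibration of a plausible regime, and every one is a
`response_model()` argument.

Scene photometry defaults (96×96 px, 250–300 frames at 0.1 s, soma
baseline 150, RFP 120, background 30 with 5% static texture, noise SD 2,
bleach 0.002 s⁻¹) put the soma peak at roughly 75× the per-ROI noise —
high-contrast sparse labeling. Scenes are deterministic given `rng_seed`.

What the generator does *not* emulate, and what passing tests therefore do
not demonstrate about real recordings: body deformation during the stimulus
(motion is a smooth confined random walk, not worm locomotion), Poisson
photon statistics (noise is additive Gaussian — adequate because the
estimator chain never models noise), channel misregistration beyond a fixed
configured offset, neighboring fluorescent structures, and focal-plane
drift. Recovery numbers on synthetic scenes are a correctness check of the
estimator chain, not an accuracy claim for live imaging.

## Calibration

`calibration_fit()` is ordinary least squares of membrane displacement on
pressure, with intercept by default (a through-origin mode exists since
nothing pins the choice), reporting $R^2 = 1 - SS_{res}/SS_{tot}$. A
zero-variance displacement vector is flagged `degenerate` with `NA`
$R^2$ rather than silently reporting 0 or 1. Since no measured table is
shipped, `synthetic_calibration_table()` generates one from a linear model
with noise in the high-linearity regime the device operates in.

## Screen statistics

Per-animal metrics are normalized to the mean (or median) of the same-day
control group, which removes shared day factors exactly — the generator
plants a lognormal day effect to verify this. Group comparisons are
two-sided rank tests throughout (sidedness is not dictated by anything in
the design):

* `mann_whitney()`: U with midranks; the two-sided p is exact — computed
  from the full null distribution of U via a rank-sum counting recursion —
  when the pooled sample is ≤ 16 with no ties, otherwise a normal
  approximation with tie and continuity corrections. The exact branch is
  verified against brute-force enumeration of all rank assignments.
* `kruskal_wallis()`: tie-corrected H against χ² with k−1 degrees of
  freedom; all observations identical is flagged degenerate.
* `p_stars()`: strict tiers at 0.05 / 0.01 / 0.001 / 0.0001.

`screen_report()` reports per-compound responder fractions, the normalized
metric distributions, an omnibus Kruskal–Wallis across all groups per
metric, and unadjusted pairwise Mann–Whitney tests of each compound against
control with stars; a compound is "affected" when any of its three pairwise
tests falls below α = 0.05. No multiple-testing correction is applied by
default — matching how per-compound stars are conventionally presented —
but `p_adjust = "BH"` is available.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path with comfortable statistical
margins: 50 seeded scenes of 250 frames for recovery (trace RMSE < 0.05,
peak errors < 10%, tracker median error ≤ 1 px), exhaustive Mann–Whitney
enumeration to pooled n = 10, 2000-replicate null calibration of the
Kruskal–Wallis rejection rate, and 20 replicates of a 4-group × 25-animal
screen with planted effects. Tolerances follow from the mechanism being
checked: machine precision (1e-9) for the algebraic gain-cancellation
identity, one interpolation step for the half-life of a sampled
exponential, binomial intervals for simulated fractions.

Degenerate inputs are errors, not guesses: flat frames for
`locate_neuron()`, empty stimulus windows, non-positive ratiometric
baselines, missing same-day controls (named in the error), all-identical
pressures in calibration. TIFF output stores intensities as 32-bit floats
scaled by 2¹⁶, recorded in the JSON sidecar; the split-frame writer places
green left, red right with the channel column offset in the sidecar.

## Known limitations

Single soma per scene (no multi-neuron scenes, no process/axon ROIs); no
bleach detrending beyond what ratio and baseline provide; no deformable-body
or posture tracking; no kinetic curve fitting — the metrics are intentionally
nonparametric; no dose–response modeling of compounds (single
concentration); and the synthetic generator's realism limits listed above.
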