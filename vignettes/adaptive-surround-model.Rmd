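---
title: "An adaptive-surround model of MT motion integration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adaptive-surround model of MT motion integration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtsurround)
```

## The model in one page

`mtsurround` simulates a two-stage account of how area MT disambiguates
object motion. Small V1 receptive fields viewing a long edge can only sense
the edge-normal motion component (the aperture problem); unambiguous
direction signals exist only at two-dimensional features — a bar's own
end-points (intrinsic terminators) and the junctions created when objects
overlap (extrinsic terminators). The model's premise is that MT solves the
resulting conflict with an *adaptive* extra-classical surround: antagonistic
where the image is discontinuous or high-contrast (segmentation), and
facilitatory where it is coherent or weak (integration, propagation of
terminator signals).

Stage one computes three V1 populations on an `H × W` pixel grid, all with
activities in `[0, 1]`:

* **Complex cells** (`complex_v1_response()`): opponent motion energy in 8
  directions from quadrature Gabor pairs and a fast/slow pair of biphasic
  temporal filters (orders 6 and 9, time constant `tau_g`). Direction
  selectivity arises from the delay between the two temporal channels.
* **End-stopped cells** (`endstopped_step()`): shunting dynamics driven by
  the complex cells and inhibited by a thresholded Gaussian pool of
  like-tuned neighbours (`inhibition_field()`). Cells on extended contours
  recruit inhibition from the whole contour and equilibrate low; cells in
  compact terminator clusters stay high. After thresholding at `rho_es`
  this stream carries *only* unambiguous terminator motion.
* **ECRF cells** (`ecrf_response()`): oriented difference-of-Gaussians form
  responses. Because the suppressive surround loses half its drive at a
  line end, responses peak at intrinsic terminators; at crossing junctions
  the two bars stimulate the surround jointly and the response is
  suppressed. Summed over orientations, this field gates motion signals by
  form (`gated_motion()`).

Stage two integrates a recurrent MT sheet (`run_model()`, `mt_step()`) with
per-step Euler updates `v <- h(v + dt * rhs)`, where `h` clips to `[0, 1]`
and

```
rhs = Gmtcx v_cx + Gmtes v_es' + Gmtmt_ex λ + Gcsmt κ
      − Gmtmt_inter γ(t − T_in) − Gmtmt3 ξ(t − T_in) − tau_mt v_mt − χ .
```

`λ` is form-gated lateral excitation (7 × 7 window sum), `γ` the
same-location inter-directional inhibition (winner-take-all substrate), `ξ`
long-range inter-directional inhibition (13 × 13 window), both applied with
a fixed delay `T_in` through a ring buffer, and `χ` the adaptive surround:

```
χ = k S( a (k(Λ − c_r) − 1 + bΔ + αβ) ) − 1,  S(t) = 1/(1 + exp(−t)),
α = 1 − (Λ − c_r),  β = 1 − Δ .
```

`Λ` (`local_contrast()`) is the mean absolute intensity difference over the
7 × 7 surround (`M = 49`); `Δ` (`motion_discontinuity()`) a
direction-weighted census of complex-cell activity in the same window,
normalised by `10 M`. With `Δ = 0` the inner term reduces to `Λ − c_r`, so
the surround is facilitatory below the contrast threshold `c_r = 0.2`,
switches sign exactly there, and saturates at `k − 1 = 1`; with `Λ = 0` the
sign flips at `Δ = 1/6`. The field is gated by the centre: units at or
below the activity threshold `T_mt` receive no surround input.

## Parameters

`mt_params()` is the single source of truth. The neural constants (gains
`Gescx1 = 2`, `Gescx2 = 3`, `Gmtcx = 0.5`, `Gmtes = 1`, `Gcsmt = 2`,
`Gmtmt_ex = 0.1`, `Gmtmt_inter = 1`, `Gmtmt3 = 1`; thresholds
`rho_cx = 0.13`, `rho_es = 0.3`, `T_mt = 0.001`, `c_r = 0.2`; surround
shape `a = 10`, `b = 2.4`, `k = 2`; rates `tau_mt = tau_es = tau_g = 0.01`,
`dt = 0.01`, `T_in = 0.4`; filters `f = 1.1` cyc/deg, Gabor SDs `0.5°`, DoG
SDs `0.35/0.4/0.4/0.5°`, amplitudes `1` and `0.72`) are the model's
standard operating point and are not tuned per stimulus. Everything
round-trips through the YAML config
(`inst/config/default-params.yaml`).

Conventions the equations leave open were fixed once:

* **Time.** One simulation time unit maps to 1 s (`ms_per_time_unit =
  1000`), so `dt = 0.01` is a 10 ms step and `T_in` a 40-step delay. One
  stimulus frame advances one integration step.
* **Grid.** One model unit per stimulus pixel at `deg_per_pixel = 0.25°`;
  the 7 × 7 surround window realises `M = 49`.
* **Gain binding.** The lateral-excitation gain is 0.1 and the
  inter-directional inhibition gain 1 — bound by function (which term each
  constant describes), not by subscript order in the rate equation, whose
  printed indices conflict with the constants' descriptions.
* **Sign of `a`.** The slope constant is stored as magnitude 10 and enters
  the sigmoid so that `χ` *increases* with contrast and discontinuity;
  the opposite sign would make suppression decrease with contrast,
  contradicting the model's stated behaviour.
* **`O = 4` ECRF orientations** (0°, 45°, 90°, 135°).
* **`rho_es`** acts as an all-or-none transmission gate: end-stopped
  activity above it is relayed to MT at full strength, below it not at
  all. After thresholding the stream is sparse and purely veridical, and
  binary relay is what lets those few units seed MT against the much
  stronger aperture-driven drive. `apply_rho_es = FALSE` restores graded
  relay.
* **Long-range inhibition is a window mean.** As a raw 7 × 169-term sum,
  `ξ` reaches several hundred while every other term in the rate equation
  is O(1); the sheet then collapses and rebounds with period `2 T_in` and
  no structured steady state exists. Reading the spatial sum as a spatial
  average matches how the model normalises its other windowed quantities
  (`Λ` by `M`, `Δ` by `10M`).
* **Form gate threshold.** `κ` relays complex-cell activity where the
  summed ECRF response exceeds 0.65 of its map maximum. The form field is
  only ~40% stronger at line ends than along the contour, so a strict
  "any form activity" gate opens everywhere on the contour and simply
  amplifies the aperture response; the fractional threshold confines the
  form-motion drive to terminator zones, which is the stated function of
  this pathway. In pattern mode (`run_model(mode = "pattern")`) the ECRF
  drive is removed (`Gcsmt = 0`) and the lateral-excitation form gate is
  forced open so signals can propagate without form support.

## The complex-cell front end

The motion-energy construction is classic — per direction,
`E_θ = (even∗g_fast − odd∗g_slow)² + (odd∗g_fast + even∗g_slow)²`, opponent
subtraction `E_θ − E_{θ+180}`, half-wave rectification — but the raw
opponent energy of a thin bar is ~16× weaker at the bar's terminators than
along its edges, and a model whose whole premise is that terminator signals
can win needs them within reach of its thresholds. Four readout stages fix
the scale (all in `complex_v1_response()`, each with an argument to disable
or retune it):

1. **Amplitude readout**: the square root of the rectified opponent energy,
   so terminator responses are compressed toward the edge responses instead
   of being squared away.
2. **Divisive surround normalisation**: each channel is divided by
   `div_norm + pool`, where `pool` is the Gaussian-weighted mean of
   same-channel activity over a 17 × 17 neighbourhood. Extended edge ridges
   normalise themselves down; compact terminator clusters do not. This is
   also what makes the front end contrast-insensitive, as complex cells in
   this model are: contrast information enters only through the ECRF
   stream and the contrast field `Λ`.
3. **Per-sequence normalisation** to the steady-state maximum (the first 25
   frames are excluded — the temporal filters start from an empty history
   and the onset transient would otherwise set the scale), followed by a
   response **floor** of 0.25 that silences filter skirts.
4. **Spatial support**: responses are kept only where the local contrast
   `Λ ≥ c_r`. The units' receptive fields are small (1° centres), so
   activity several pixels from any luminance structure is kernel spread,
   not signal — and because such pixels sit in the facilitatory-surround
   zone (`Λ < c_r`, `χ < 0`), without this gate they self-ignite the MT
   sheet from numerically negligible seeds.

The normalisation constant can be frozen to a full-contrast grating
calibration (`v1_calibration()`) when absolute energies must be compared
across stimuli.

## The stimulus generator

All inputs are synthesised (`stimulus_spec()` + generators); nothing is
read from disk. The default two-bar configuration is a 64 × 64 frame
(16 × 16°), two 10° × 0.5° bars at 135° and 45° orientation crossing at the
centre, the 135° bar translating rightward and the 45° bar leftward at
0.5 deg per time unit for 300 frames, equal contrasts 0.8. The junction
then drifts upward — the classic plaid geometry. `occluded_plaid()` adds a
circular aperture (radius 3°) that hides all four intrinsic terminators;
`single_bar()` and `grating()` are validation stimuli.

Three rendering choices matter for the physics:

* **Coverage-ramp edges.** Bars get a one-pixel linear intensity ramp at
  their borders so sub-pixel translation is smooth. Hard-edged binary bars
  at these speeds jump a whole pixel every 12–25 frames, which modulates
  the motion energy ~10-fold at the jump frequency. Ground-truth masks
  remain binary rectangles.
* **Onset fade.** Stimulus contrast ramps up over the first 0.1 time units:
  a step onset is spectrally broadband and transiently drives all eight
  direction channels, which destabilises the delayed-inhibition dynamics.
* **Centred trajectories.** Bars start half their total excursion behind
  the frame centre so the configuration stays inside the reliable interior
  (away from the convolution border) for the whole run.

The generator emulates the geometry of bar and plaid experiments, not their
psychophysics: there are no random-dot fields, no noise, no disparity, and
contrast is a single scalar per bar. Conclusions from these stimuli
therefore speak to contour-motion integration, not to texture or
transparency phenomena.

The trajectory lengths were chosen from the model's own time constants: the
end-stopped shunting stage needs roughly 0.3–0.5 time units to cross
`rho_es`, and the delayed inhibition only becomes informative after
`T_in`, so default runs last 3 time units (300 steps) on the 64 × 64 grid.

## Numerical choices

Spatial convolutions are FFT-based, zero-padded, exact to rounding; the
border ring of half-kernel width is flagged invalid (`attr(x, "valid")`).
Temporal filtering is causal with zero history. Window sums use exact
integral-image box filters. The MT update clips the *state*, not the
derivative: applying the saturation to the derivative (a literal reading of
the rate equation, available via `literal_h_on_derivative = TRUE`) forces
monotone growth and cannot decay. Delayed terms read a ring buffer of past
activity and are zero during the first `T_in` warm-up. Ties in direction
decoding go to the lowest channel index; activity below the decode
threshold (default 0.05) is labelled "none". Everything is deterministic —
no operation consumes randomness.

## What the implementation does and does not reproduce

The analytic structure of the surround is reproduced exactly: the
facilitation-to-suppression crossover at `Λ = c_r` (root-finding recovers
0.2 to machine precision), strict monotonicity in both `Λ` and `Δ`,
saturation just below 1, and silence at inactive centres. The end-stopped
stage matches its closed-form equilibria to 1e-6 and concentrates activity
at terminators (terminator-to-edge ratio > 3.5 for the default bar). The
ECRF stage discriminates intrinsic from extrinsic terminators, and in the
full two-bar simulation MT activity at the crossing junction settles below
half the bar-body level — the segmentation signature.

Two figure-level behaviours are *not* reproduced, and the test suite marks
them as failures rather than hiding them. First, veridical direction coding
wins only in the terminator regions: along the bar interiors the
edge-normal (aperture) channels remain dominant, so the population never
reaches the 90%-correct criterion and the disambiguation latency is
reported as "never". The mechanism is an arrival-order lock: the aperture
channels are driven feed-forward from the first frames, while the
end-stopped seeds need ~0.3-0.5 time units of shunting integration to cross
`rho_es`; by the time they fire, the delayed same-location inhibition of
the established channels blocks their propagation, and no term in the rate
equation gives a propagating veridical front a per-pixel advantage over a
standing aperture drive. Second, for the same reason the occluded plaid
classifies as component motion in both modes: the upward junction seed
cannot displace the established oblique channels, so pattern selectivity
does not emerge. Both failures trace to the front end: the construction
here produces veridical terminator responses comparable to edge responses
(after the readout stages above), but the model dynamics would need them
*dominant over a neighbourhood* to seed a takeover. A front end with
orientation-pooled or feature-tracking terminator responses is the natural
next step.

## Known limitations

Besides the two above: the `Δ` pathway is effectively inert for bar stimuli
(window sums normalised by `10M` keep `Δ < 0.05`, so `bΔ` never competes
with the contrast term — visible in `sweep_chi()` versus simulated fields);
end-stopped activity decays with rate `tau_es = 0.01` and so leaves
long-lived trails behind moving terminators; and the winner-take-all
sharpness depends on the delayed inhibition, so transient multi-channel
coexistence is visible for up to `2 T_in` after structural changes in the
stimulus.
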