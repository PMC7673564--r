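---
title: "Quantifying perfusion from dynamic ICG fluorescence: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perfusion from dynamic ICG fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfquant)
```

## The measurement model

Dynamic ICG fluorescence imaging records the passage of an intravenously
injected dye bolus through the microcirculation of a tissue at video rate
(here 25 fps, 8-bit). The mean intensity of a region of interest (ROI)
over time, $I(t)$, is an indicator-dilution curve: flat at a baseline
level before the dye arrives, a steep first-pass rise to a peak, then a
slow decay with a smaller recirculation bump. Three parameters summarize
it:

* **BSFI** $= \max_{t \in (t_{inj},\, t_{inj}+W]} I(t) - \bar I_{base}$,
  the first-passage peak minus the pre-injection baseline mean. The
  subtraction is the point: residual ICG pooled in the tissue from
  earlier injections shifts the whole curve upward, and a raw peak would
  read falsely high. BSFI is invariant to any additive offset, and the
  test suite asserts this invariance on hundreds of randomized curves.
* **SFI**, the maximal rising slope between bolus onset and peak
  (a.u./s). Of the three parameters it is the most directly driven by
  feeding-vessel blood flow.
* **TTS**, the delay from injection to the first detectable signal
  increase. Absolute TTS depends on the injection-to-field transit time,
  which varies with catheter position and cardiac output, so TTS is
  reported as a **ratio to a reference ROI** at the arterial radix (D3);
  the reference's own ratio is 1 by construction.

"First passage" is operationalized as a bounded post-injection analysis
window (default $W = 60$ s): the recirculation bump of a typical curve is
far below the primary peak, so the window's global maximum is the
first-pass peak. The window length is configurable.

## The synthetic experiment

No raw recordings accompany the motivating in-vivo experiment, so the
package generates its own ground truth. The simulator emulates a
single-vessel gastric-tube preparation: one arterial arcade feeds three
ROIs — D3 (prepyloric, at the radix), D2 (corpus), D1 (fundus tip) — with
a proximal-to-distal flow gradient, measured at four hemodynamic states
(T0 baseline, T1 hypotension, T2 normotension, T3 hypertension).

The bolus kernel is the standard gamma-variate, peak-normalized so the
amplitude parameter is exact:

$$ I(t) = B + A\,u^{\alpha} e^{\alpha(1-u)}, \qquad
   u = \frac{t - t_0}{t_p}, $$

for $t \ge t_0$ and $I(t) = B$ before arrival, plus a delayed copy scaled
by the recirculation fraction. Flow maps to curve shape by the simplest
rule consistent with a flow-driven rise: amplitude $A \propto$ flow and
time-to-peak $t_p \propto 1/$flow, both relative to the D3 reference
values. This is a model assumption, not a measured fact, and it is
configurable.

Defaults (all in one place, `sim_defaults()` / `default_run_config()`):

| parameter | default | rationale |
|---|---|---|
| frame rate, bit depth, duration | 25 fps, 8 bit, 120 s | the emulated acquisition hardware |
| injection time | 10 s | leaves a 5 s baseline window plus margin |
| analysis window | 60 s | the emulated study's own analysis span |
| D3 amplitude, $t_p$, $\alpha$ | 100 a.u., 6 s, 3 | a first-pass rise of a few seconds, mid-range 8-bit |
| systemic lag (injection to D3) | 4 s | arbitrary but configurable; only TTS differences/ratios matter |
| relative flows D3:D2:D1 | 1 : 0.8 : 0.6 | proximal-to-distal gradient of the one-vessel model |
| arrival delays D2, D1 | +1.5 s, +4 s | produces TTS ratios near 1.4 and 2, the observed scale |
| state flow scales T0–T3 | 1, 0.9, 1, 1.2 | hypotension mildly impairs, hypertension mildly improves flow |
| D3 absolute flow | 1.2 mL/min/g | gastric-tube microsphere flows are of order 1 mL/min/g |
| noise SD | 2 a.u. (2 % of A) | video-rate shot/readout noise on ROI means |
| recirculation | 15 % at +30 s | a realistic second bump, so first-pass windowing is actually exercised |
| residual ICG accumulation | +3 a.u. per prior injection | hepatic clearance is incomplete between repeated injections |
| microsphere reference scale | 830 counts/(mL/min) | ~2600 spheres in the reference syringe at 3.18 mL/min withdrawal |

Signals are clipped to $[0, 2^{bits}-1]$ and quantized round-half-even,
mimicking a frame grabber. The frame-stack generator paints each ROI
rectangle with its curve plus iid pixel noise over a dim background.

**What the generator does not emulate** — and hence what a green test
does *not* establish: motion and breathing artifacts, spatial
heterogeneity within an ROI, depth-dependent attenuation, nonlinear
camera response, hepatic ICG clearance kinetics (pooling is a constant
additive offset per injection), rater variability, and any real
anatomy. Green tests establish that the *algorithms* recover known
truth under the stated noise model, not that the hardware would.

## Numerical choices

**Onset detection.** The detector finds the first post-injection frame
exceeding $\bar I_{base} + k\,\max(s_{base}, s_{min})$ for $m$
consecutive frames ($k=3$, $m=5$ ≈ 0.2 s at 25 fps; the floor
$s_{min} = 0.5$ a.u. guards noiseless curves whose sample SD is zero),
then **backtracks** to the first frame still above the baseline mean.
The two-stage rule matters: a pure threshold crossing is systematically
late, because the gamma-variate rises as $u^{\alpha}$ — with $\alpha = 3$
the signal stays within noise of baseline for several hundred
milliseconds after true arrival. Backtracking removes that delay
entirely on clean data (the acceptance suite asserts recovery to within
one frame on noiseless curves). On noisy or quantized data a residual,
physically inherent delay remains — near arrival the curve is
statistically indistinguishable from baseline, and no detector can do
better; for the same reason TTS on quantized curves retains a small
amplitude-dependent bias (the first representable intensity step above
baseline occurs later for smaller amplitudes). This is why TTS is used
as a *ratio between simultaneously recorded ROIs*, where the common part
of the delay cancels.

**Onset runs on the raw curve, not the smoothed one.** The centered
moving-average smoother (half-width 2 frames) leaks post-arrival signal
up to 2 frames backwards, which would bias onset early. Peak and slope,
which benefit from noise suppression and are insensitive to a 2-frame
blur, use the smoothed curve.

**Slope estimation.** Raw adjacent-frame differences on 8-bit data are
noise-dominated (one quantization step per frame is 25 a.u./s). SFI is
therefore the maximum over sliding least-squares regression slopes of
window 0.5 s (13 frames at 25 fps) fully inside [onset, peak]. The
window slope is computed exactly via the centered form
$\sum_k o_k y_{j+k} / \sum_k o_k^2$ with fixed offsets $o_k$, which is
numerically stable and verified against an exhaustive per-window `lm`
oracle to $10^{-9}$. A window of 2 frames reduces to finite differences.
A rising segment shorter than the window falls back to the full
segment's regression slope and flags `short_rise`.

**Ties and degenerate inputs.** Equal maxima and equal slopes always
resolve to the earliest time, making outputs deterministic. A curve with
no pre-injection frames is unusable (error); a curve that never crosses
the onset threshold yields a flagged no-onset result, not an error; a
truncated analysis window proceeds with a flag; more than 1 % of
analysis-window frames at the bit-depth ceiling sets `saturated`.

## Statistics: why permutation instead of mixed models

The classical analysis of such designs fits mixed models with random
rater/animal intercepts and autoregressive repeated-measures covariance.
With seven animals those covariance structures are barely identified
(non-positive-definite Hessians are a routine symptom). This package
deliberately replaces them with a **fixed-effects model plus restricted
permutation**: reciprocal-transformed metrics, categorical area, time
and interaction; the area (and interaction) null is tested by permuting
responses within animal-by-state blocks, the time null within
animal-by-area blocks. Under the null the block elements are
exchangeable, so the test is exact up to Monte-Carlo error — the
acceptance suite verifies type-I control at $\alpha = 0.05$ over 1000
null simulations and that small cases reproduce exhaustive enumeration
exactly. Two caveats are documented rather than hidden: the
interaction test uses the same permutation scheme as the area main
effect, so it is exact under the joint null of no area involvement but
only approximate under "interaction-free but area-present"; and the
fixed-effects F ignores between-animal variance components, which the
permutation scheme, not the F reference distribution, is responsible
for handling.

Marginal means are back-transformed by the reciprocal-of-the-mean
convention (1 / mean of transformed values); the alternative (mean of
reciprocals) is available behind a flag. Intervals are percentile
bootstrap over animals — the natural resampling unit — and are widened,
if necessary, to contain the point estimate. The metric–flow
correlation is Spearman by default (the metrics are monotone transforms
of flow under the simulator's own mapping, and ranks are robust to that
choice); Pearson is a switch away. All Monte-Carlo procedures take
explicit seeds; every stage of the pipeline derives an independent
substream from one root seed, so stages are individually reproducible
and a full run is bit-identical under a fixed seed.

## Limitations

* Fluorescence metrics are relative: no absolute perfusion calibration
  is attempted from fluorescence; absolute flow is the microsphere
  module's job.
* Microsphere inputs are assumed spillover-corrected per color channel;
  spectral unmixing is out of scope. The low-signal QC threshold
  (default 400, the conventional precision floor) is configurable and
  never silently applied.
* The TIFF codec is deliberately minimal (baseline uncompressed
  grayscale, 8/16-bit) because the package depends only on base R; it is
  cross-validated against an independent TIFF implementation in the test
  suite. Compressed, RGB, or tiled files are rejected with a clear
  error, not guessed at.
* The simulator's flow-to-shape mapping ($A \propto$ flow,
  $t_p \propto 1/$flow) is an assumption; conclusions about algorithm
  correctness transfer to real data only insofar as real curves behave
  like flow-scaled gamma-variates.
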