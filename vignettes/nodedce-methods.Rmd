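---
title: "Methods: enhancement-pattern analysis of lymph node DCE-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancement-pattern analysis of lymph node DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodedce)
```

`nodedce` analyzes a single-slice dynamic contrast-enhanced MRI series of a
lymph node: it corrects rigid motion, converts signal to normalized
differential enhancement (NDE), segments the node pixels into two
enhancement-pattern clusters, extracts semiquantitative curve parameters,
and compares them statistically across clusters and contrast agents. This
vignette explains the model behind each stage, the tunable parameters and
their defaults, the numerical choices, and what the bundled phantom does and
does not emulate.

## The measurement model

A dynamic series is a height × width × time stack of T1-weighted signal
intensities with `n_baseline` pre-contrast frames (default 3) and a bolus
arriving between frames `n_baseline` and `n_baseline + 1`. The default frame
interval is 46/70 min: a 70-frame series acquired over about 46 minutes.
All user-facing frame indices are 1-based.

Per pixel, enhancement is expressed as

$$\mathrm{NDE}(t) = \frac{SI(t) - SI_{PRE}}{(DE_{MAX})_{MUSCLE}}$$

with two conventions that the definition itself leaves open:

* $SI_{PRE}$ is the **mean of all pre-contrast frames** of the pixel (not a
  single frame) — averaging reduces baseline noise and guarantees that every
  NDE curve averages to zero over the baseline frames to machine precision.
* $(DE_{MAX})_{MUSCLE}$ is the maximal post-injection differential
  enhancement of the **ROI-mean** muscle curve. A per-pixel maximum would be
  biased upward by noise (the maximum of noisy values overshoots the
  maximum of their means). Post-injection means frames
  `n_baseline + 1 … n_frames`. A muscle region that never enhances is an
  error, not a silent division.

Dividing by muscle enhancement makes NDE invariant to global intensity
rescaling, which partially compensates dosage differences between sessions;
this invariance is enforced by a test.

## Motion correction

Frames are registered to a reference (default: frame `n_baseline + 2`, the
2nd post-injection frame) with a **translation-only** rigid model. On
single-slice abdominal data, breathing and peristalsis displace the node
mostly in-plane and translationally; rotations are deliberately out of
scope, and series that translation cannot fix are flagged rather than
warped.

The similarity metric is normalized cross-correlation (NCC), chosen because
it is insensitive to the global intensity changes a contrast bolus causes.
Estimation proceeds in three steps per frame: exhaustive NCC over integer
shifts up to `max_shift` (default 5 px), a 3-point parabolic interpolation
of the NCC surface as a subpixel start, and a Nelder-Mead polish of a
continuous NCC objective in which the reference is translated by **exact
spectral (FFT) shifts**. The spectral shifter matters: resampling by
bilinear interpolation inside the metric applies a low-pass filter whose
strength varies with the fractional shift, which measurably biases
fractional-shift estimates (toward offsets whose smoothing best matches the
data); an exact translation has no such artifact. For the same reason the
*correction* itself resamples frames spectrally — re-registering an
already-corrected series then moves nothing (idempotence within 0.05 px,
tested), whereas bilinear correction left a ~0.06 px re-estimation bias.
Spectral translation wraps content circularly at the image border; the
affected strip is as wide as the shift and lies far from any interior ROI.

After correction, each frame's shift is re-estimated; these **residual
shifts** quantify unrecovered motion. `flag_residual_motion()` flags the
series when any residual magnitude exceeds `motion_threshold` (default
1.0 px). The threshold is our construction — visual assessment is the
traditional criterion for discarding a displaced node — so it is exposed as
a parameter, and the pipeline excludes flagged nodes loudly rather than
silently.

Estimation accuracy has a floor worth stating: frames that were themselves
produced by bilinear resampling (as the phantom's motion is) are slightly
low-passed with a frequency-dependent phase error, so a pure-translation
estimator can be off by up to ~0.06 px at asymmetric fractional shifts.
Recovery of known shifts is tested at 0.1 px; identity on a motionless
series at 0.05 px.

## PCA screen and segmentation

`pca_screen()` reports the percentage of variance each principal component
of the centered NDE curve matrix explains. Its role is diagnostic: if two
components explain nearly all variance, two enhancement patterns dominate
the node and `k = 2` clusters are a justified (minimum) choice. A curve set
with zero variance is an error rather than a vacuous 100 %.

`kmeans_segment()` clusters the **raw NDE vectors** — no additional
standardization, since muscle normalization already puts all pixels on one
scale and the enhancement magnitude is exactly the discriminating signal —
and uses no spatial term: any anatomical coherence in the result is a
finding, not an input. The optimizer is Lloyd's algorithm (via
`stats::kmeans`) from k-means++ starts, best of `n_init = 20` restarts,
deterministic for a fixed `seed` (default 0). On every instance small
enough to enumerate exhaustively (≤ 8 curves) the restart scheme attains
the global optimum of the within-cluster sum of squares; this is tested
against a brute-force partition oracle.

Cluster *roles* need an operational rule because k-means labels are
arbitrary: the cluster whose cluster-averaged curve has the **larger AUC**
is called *inner*, the other *outer* — in normal nodes the medulla-adjacent
center accumulates more contrast, plausibly because lymphatic flow is
directed from cortex toward medulla and hilum. An exact AUC tie (measure
zero in practice) falls back to the larger peak, and the tie-break used is
recorded. Spatial position is never used, so the rule also works on
pathological geometries.

## Semiquantitative parameters

From each cluster-averaged NDE curve, with frame times in minutes:

* **AUC** — trapezoidal integral from the last baseline frame through the
  final frame. The integration window and rule are our conventions (the
  quantity is commonly reported without either being stated); absolute AUC
  values are therefore only comparable within these conventions. AUC is
  *not* divided by the node's maximal enhancement.
* **Wash-in rate** — the maximum slope between two consecutive time points
  in the window from the last baseline frame to the frame of maximal
  enhancement, divided by the node normalizer. A curve that never rises
  yields 0 with a warning.
* **Wash-out rate** — the ordinary least-squares slope over the final 40
  frames (scans 31–70 of a 70-frame series), divided by the node
  normalizer; negative when contrast clears. For series of other lengths
  the window stays 40 frames and shorter series are an error unless
  `washout_frames` is set explicitly.

The normalizer, `max_enhancement_node`, is the maximum of the **node-ROI
mean** NDE curve and is shared by both clusters of a node (normalization is
per node, not per cluster); a per-pixel maximum would again be
noise-inflated. Volume (%) is the cluster's share of node pixels on the
analyzed slice; the two shares sum to 100 by construction.

## Statistics

The node table has one inner and one outer row per node, each node measured
with one contrast agent. The only ANOVA design consistent with these paired
values is a **mixed (split-plot) two-way ANOVA**: cluster is a within-node
factor, agent a between-node factor, node the blocking unit —
`value ~ agent * cluster + Error(node)`. The agent main effect is tested in
the between-node stratum; cluster and the interaction in the within-node
stratum.

The within-agent inner-minus-outer contrast for agent $a$ with $n_a$ nodes
uses the pooled within-node residual mean square $s^2$:
$t = \bar d_a / \sqrt{2 s^2 / n_a}$ on the within-stratum residual degrees
of freedom, two-sided, **Bonferroni-adjusted by factor 2** (one contrast
per agent within each parameter family). Reports annotate p < 0.05 and
p < 0.01. An independent check against `emmeans` on the same model is part
of the test suite. Exactly-null effects are reported as F = 0, p = 1
(guarding against 0/0 floating-point dust), and sums of squares follow the
sequential decomposition, which is unambiguous here because cluster is
orthogonal to agent within strata.

With the packaged 15-node table this reproduces the expected structure:
inner AUC and wash-in higher in both agents (adjusted p < 0.01 and < 0.05),
wash-out steeper in the inner cluster (Gd-BOPTA adjusted p < 0.01), outer
volume larger (Gd-DTPA p < 0.05, Gd-BOPTA p < 0.01), and no significant
agent effect on any parameter. These are recomputed, not stored: the
acceptance script derives them from the table at run time.

## The phantom: what it emulates, and what it does not

`phantom_spec()` builds a 64 × 64 single-slice scene: an elliptical node
(semi-axes 12 × 10 px) with a **concentric inner compartment** holding
`inner_fraction` of the node area (default 0.3 — reference inner volumes
span roughly 14–49 % with mean ≈ 31 %), a rectangular muscle strip, and a
uniform background. Each compartment enhances as

$$E(t) = A\,(1 - e^{-k_{in}\Delta t})\,e^{-k_{out}\Delta t},$$

a product of mono-exponential uptake and washout. This is *not* a
pharmacokinetic model — no arterial input, no exchange constants — merely
the simplest smooth uptake-then-washout shape with interpretable rate
parameters, which is what recovery tests need. Defaults: inner
$A = 2.0,\ k_{in} = 1.5,\ k_{out} = 0.05$; outer $1.0 / 0.5 / 0.02$; muscle
$0.4 / 0.8 / 0.03$ (amplitudes relative to a baseline signal of 100 a.u.,
rates in 1/min, onset at frame 4). They encode the qualitative contrast the
analysis must detect — inner uptake higher and faster, washout steeper —
at amplitudes that put the node's NDE-scale AUC in the same ballpark as the
reference table.

Noise is additive Gaussian (default σ = 5 a.u.) with an optional Rician
mode (magnitude MRI noise is Rician; the Gaussian default keeps analytic
expectations simple). At the default level the curve-peak SNR of the weaker
(outer) compartment is ≈ 17, comfortably above the ≥ 10 regime in which
segmentation is required to stay essentially exact (tested over 20 seeds).
No acquisition SNR was available to copy, so these are testability choices,
not fidelity claims.

Two **static structure terms** are added to every frame: a smooth sinusoidal
background texture (`texture_amp`, default 10 a.u.) and constant baseline
offsets for node (+60 a.u.) and muscle (−30 a.u.) tissue
(`anatomy_contrast`). Being constant in time they cancel exactly from
$SI - SI_{PRE}$ and from the muscle normalizer — the NDE ground truth is
untouched — but they give pre-contrast frames the spatial structure real
anatomy has. Without them the baseline frames of the phantom are featureless
noise and *no* intensity-based registration could anchor them, which is a
property of the toy scene, not of the method.

Motion, when scheduled, is a per-frame 2D translation applied by bilinear
resampling after noise-free synthesis; the applied shifts are returned as
ground truth. The phantom does **not** emulate: 3D/multi-slice geometry,
rotations or deformations, fat signal or a fatty hilum, vascular input
heterogeneity within a compartment, spatially correlated noise, or scanner
drift. Passing tests on the phantom therefore show that the pipeline's
mathematics is correct under its stated assumptions — not that those
assumptions hold on any particular scanner's data.

## Numerical and degenerate-input choices

* Frame indices are 1-based at every interface, 0-based only internally.
* Trapezoidal AUC is linear in the curve; tested against a quadrature
  oracle.
* The OLS wash-out slope is computed in closed form and tested against the
  normal equations at 1e-10.
* Registration of a zero-variance (constant) frame warns and applies the
  identity; a zero-variance *reference* is an error.
* A muscle region with non-positive enhancement, a PCA input with fewer
  than 2 curves or zero variance, `k` exceeding the number of curves, and a
  parameter table whose cluster volumes do not sum to 100 ± 0.5 are all
  hard errors.
* Phantom YAML specs serialize numerics at full double precision
  (`%.17g`), so a written-and-reread spec regenerates bit-identical data.

## Problem sizes used in the tests

The bundled tests and the acceptance script run on the phantom's default
geometry (64 × 64 × 70; ~370 node pixels), with 15–20 independent noise
seeds where a claim is distributional and single runs where it is exact.
These sizes were chosen so the whole suite exercises every stage — including
registration, the most expensive step — in well under a minute on one core,
while leaving the phantom large enough that compartment discretization and
SNR are realistic for a ~2.5 mm mouse lymph node imaged at sub-100 µm
in-plane resolution.

## Known limitations

* Translation-only registration cannot express rotation or nonrigid motion;
  such series are flagged and excluded rather than rescued.
* Role assignment assumes exactly two clusters; `k > 2` is supported for
  exploration but gets no inner/outer naming.
* Absolute AUC values depend on our integration conventions and on the
  phantom's arbitrary amplitude scale; only comparisons within a consistent
  pipeline are meaningful.
* The mixed-ANOVA error structure is the simplest one consistent with
  paired clusters per node; heteroscedasticity across agents or nodes is
  not modeled (no mixed-effects extension, by design).
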