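---
title: "Quantifying myocardial perfusion with double-gated FAIR ASL: models and design"
author: "FAIRmbf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myocardial perfusion with double-gated FAIR ASL: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FAIRmbf)
```

## The measurement

Flow-sensitive alternating inversion recovery (FAIR) estimates myocardial
blood flow (MBF) without contrast agents. Two magnetization-prepared
short-axis images are compared: a *control* image preceded by a
slice-selective inversion (a 30 mm slab around the imaging slice, so
in-flowing arterial spins are unperturbed) and a *tagged* image preceded
by a nonselective inversion (in-flowing spins are inverted). After an
inversion time TI of roughly one cardiac cycle, perfused myocardium
differs slightly in signal between the two preparations; an unprepared
*M0* image provides the equilibrium magnetization for normalization. Six
control/tagged pairs are acquired — one pair per breath-hold, order
alternating between breath-holds — and averaged to build up sensitivity.

The sequence is *double gated*: the inversion pulse and the single-shot
readout are triggered to the same cardiac phase in adjacent cardiac
cycles, so the myocardium is imaged in the phase in which it was
inverted. With separate inversion times for the averaged control and
tagged images, MBF in 1/ms is

$$\mathrm{MBF} = \frac{1}{2\,M_0}\left[\frac{C}{TI_C}\,e^{-TI_C/T_1}
  - \frac{T}{TI_T}\,e^{-TI_T/T_1}\right],$$

with $T_1$ the longitudinal relaxation time of arterial blood
(1700 ms at 3 T). The package multiplies by 60000 and assumes a tissue
density of 1 g/ml, reporting ml/g/min. Negative values are kept: they
are informative noise, and clipping would bias ROI means. Pixels whose
M0 falls below 5 % of the M0 maximum are marked invalid rather than
zeroed, preventing $1/M_0$ blow-up outside the body.

Because every heartbeat differs slightly, each frame is acquired at its
own *actual* inversion time. Before averaging, each frame is moved to
the per-type mean inversion time ("nominal") with the
inversion-recovery signal model

$$I_{corr} = M_0 + (I - M_0)\,e^{\Delta TI/T_1},
  \qquad \Delta TI = TI_{actual} - TI_{nominal},$$

again at blood T1 — deliberately also over myocardial pixels, whose
recovery constant differs; the reference pipeline this package
implements does the same, and we do not substitute a tissue T1.

## Pipeline order

`preprocessSeries()` runs the stages in a fixed order: crop a 64 px ROI
around the left ventricle in the M0 frame and propagate it to all 13
frames; register controls 2–6 to control 1 and taggeds 2–6 to tagged 1
(mean-squares metric — the images of one series share contrast);
correct all 12 frames to the per-type mean TI against the cropped (not
yet registered) M0; average each type; register the two averages to the
M0 frame (mutual information — the contrasts differ). Correcting before
averaging matters: averaging first and correcting the average at its
mean TI is a different (and, by Jensen's inequality, biased) operation,
and the test suite guards the order.

For temporal-noise estimation, `perPairMaps()` instead quantifies each
breath-hold pair separately, feeding that pair's actual inversion times
straight into the quantification formula (no TI correction needed), with
the pair registered first internally (tagged to control, then the pair
to M0) — six maps whose ROI-mean spread defines the temporal SNR.

## Rigid registration

No registration backend with the required determinism was available as
an R dependency, so the package implements in-plane rigid registration
directly: translation plus rotation about the ROI center, bilinear
resampling, metric restricted to in-bounds pixels. Mean squares serves
within-series registration; a fixed 32-bin joint-histogram mutual
information (bin edges frozen from the full intensity range of each
image) serves the cross-contrast registration to M0. The optimizer is
deterministic: a coarse grid seed (±3 px in 1.5 px steps, ±4° at half
resolution), Nelder–Mead at two resolutions with fixed iteration caps
and one refinement restart, no stochastic metric sampling. Convergence
failure returns the best-found transform flagged `converged = FALSE`,
never an error.

One numerical subtlety: on sharp-edged images, bilinear interpolation
at sub-pixel offsets *inflates* mutual information by ~0.01–0.02 nats,
so an unconstrained optimizer walks away from a perfect alignment.
After optimization the metric is therefore re-evaluated at the identity
transform, which is kept unless the optimizer beat it by a clear margin
(0.05 nats for mutual information; numerical tolerance for mean
squares). Genuine misalignments of a pixel or more improve MI by an
order of magnitude more than the artifact, so the margin costs at most
a sub-pixel refinement — within the pipeline's stated 0.5 px accuracy —
and buys exact pass-through of already-aligned data.

Rotation about the center of a circularly symmetric phantom is close to
unidentifiable; translation recovery is unaffected, and rotation
accuracy is asserted on asymmetric content in the tests.

## The synthetic phantom

`PhantomSpec()` describes a short-axis left ventricle as an annulus on a
150 × 150 grid of 2 × 2 mm pixels: inner/outer myocardial radii
25/34 mm in diastole and 16/31 mm in systole, so the wall thickens and
the rasterized myocardium grows from ~417 to ~554 pixels (ratio ~1.33)
— systolic imaging "sees" more analyzable myocardium, the geometric
effect the three-protocol comparison rests on. The radii are
configuration, not anatomy: they were chosen once to land near the
observed systolic/diastolic pixel-count ratio of real segmentations.

Compartment baselines are 1000 (myocardium), 1400 (blood pool) and 50
(background, below the 5 % validity floor). Signals are signed real
values throughout: the phantom assumes a phase-sensitive reconstruction,
keeping the forward model exactly invertible (magnitude images would
fold the inverted signal). The tagged myocardium follows signed
inversion recovery at a myocardial T1 of 1500 ms; the control signal is
then *solved from the quantification formula* so that the pipeline's
output equals the configured true MBF exactly — the forward model is the
algebraic inverse of the quantifier, which is what makes sharp
round-trip tests (1e-9 relative) possible. The blood pool carries blood
inversion recovery with zero perfusion contrast; real FAIR cavities
show strong in-flow contrast, a known phantom simplification.

Corruptions are applied in a fixed order, all driven by one seed:

1. **Inversion-time jitter.** One RR deviation per breath-hold, uniform
   within ±5 % of the nominal TI, shared by the two frames of the pair
   (heart rhythm drifts between breath-holds rather than within one —
   the same granularity as the motion model). Frame signals follow the
   inversion-recovery family anchored at the per-type mean TI, so the
   pipeline's TI correction is exact by construction on noiseless data.
   On the per-pair path the actual TIs enter the quantification formula
   directly and its TI factors leave a residual per-pair spread of ~6 %
   — a phantom artifact playing the role of beat-to-beat variability.
   (Had each frame drawn its jitter independently, that artifact would
   reach ~23 % per pair and drown the physiological-noise differences
   between protocols; the breath-hold granularity keeps it below them.)
2. **Rigid motion.** One translation (±3 px per axis) and rotation
   (±3°) per breath-hold, applied to both frames of the pair — the pair
   shares its breath-hold, and so its body position. The M0 scan,
   acquired separately, stays unmoved and defines the reference frame.
3. **Physiological noise.** Independent zero-mean Gaussian perturbations
   of the myocardial pixels of each frame, SD
   $k \times \max(0, T_{acq} - T_{rest}) \times M_0^{local}$ with
   $k = 0.004$ per ms: cardiac-motion noise grows with how far the
   single-shot readout window overhangs the quiescent rest period, and
   vanishes when the readout fits inside it. This linear model is the
   package's own invention — the literature motivates the mechanism only
   qualitatively — and per-pixel independence is one of several
   defensible granularities; a spatially coherent per-frame perturbation
   would produce the same ordering with far smaller TSNR magnitudes.
4. **Thermal noise.** Gaussian, SD 2 % of the myocardial M0, on every
   pixel of every frame including M0.

Rest-period durations are simulation parameters on the protocol: 180 ms
for diastole and 90 ms for systole (within the ~80–100 ms end-systolic
range). With the protocol windows of 165 ms (parallel imaging factor 2)
and 110 ms (compressed sensing factor 3), the excess window is 0 ms for
diastolic PI2, 75 ms for systolic PI2 and 20 ms for systolic CS3 — the
mechanism by which systolic parallel imaging pays a temporal-noise
penalty and compressed sensing buys it back.

## The cohort experiment

`runExperiment()` simulates `nSubjects` (default 12) synthetic subjects,
each measured with all three protocols. Per subject it draws a heart
rate (Normal(64, 10) bpm truncated at 40; the nominal TI is one cardiac
cycle, 60000/HR ms), a true resting MBF (Normal(1.5, 0.3) ml/g/min
truncated at 0.5) and a geometry scale (Normal(1, 0.05) truncated to
[0.85, 1.15]) applied to all radii. The two latter draws are this
package's own additions to the corruption model: a cohort of *identical*
phantoms has essentially zero between-subject variance, which would let
the unpaired ANOVA on mean MBF flag sub-pixel partial-volume differences
between the diastolic and systolic geometries as "significant" — a
sensitivity no 12-subject human study has. The SDs mirror the
between-subject spreads reported for real cohorts (MBF ±0.4–0.6
ml/g/min; pixel counts ±55–82).

Analysis masks are the phase-matched ground-truth myocardium — no
automatic segmentation is attempted, mirroring manual segmentation in
practice. Per subject and protocol the experiment records the mask-mean
MBF, the analyzable-pixel count, and the temporal SNR:

$$\mathrm{TSNR} = \frac{\operatorname{mean}_i \overline{MBF}_i}
  {\operatorname{sd}_i \overline{MBF}_i}, \qquad i = 1,\dots,6$$

over the six per-pair ROI means, with the sample (n−1) SD; a per-pixel
TSNR map (median-summarized) is available as `tsnr(..., mode =
"pixel")`, but the ROI-level value is the headline metric. Zero
temporal variance yields a flagged undefined value, never an infinity.

Metrics are compared with a plain one-way ANOVA across protocols
(matching the reference analysis; not repeated-measures), followed —
only when the ANOVA rejects at α = 0.05 — by two-tailed *paired*
t-tests for the three protocol pairs without multiplicity correction.
Paired, because every subject underwent all three protocols; the
degenerate zero-variance cases that constructed fixtures produce (all
differences zero, or a constant shift) are mapped to p = 1 and p = 0
respectively rather than erroring.

Sector analysis (`regionalSectors()`) splits the annulus into four 90°
quadrants about the mask centroid — septal (centered on the
septum direction, default image left), anterior, lateral, inferior
("inferior" is this package's fixed alias for what some reports call
"posterior").

## Problem sizes and numerical choices

The shipped defaults are what the tests and the acceptance script run:
12 subjects × 3 protocols for the cohort comparison; 10 seeds for the
motion-correction ablation (with-registration RMSE vs without); 50
repetitions of a 6-subject, no-motion, no-physiological-noise cohort
for the null control of the TSNR ANOVA (nominal type-I behaviour). The
null control and the unbiasedness property test disable the
registration stages: with zero injected motion, registration is an
identity no-op under the identity-preference rule, and skipping it keeps
repetition counts high at desk scale. Tolerances: zero-corruption
round trip 1e-9 relative, TI-jitter round trip 1e-6, TI-correction
invertibility 1e-12, registration recovery 0.5 px / 0.5°.

## What passing tests do and do not show

The phantom emulates geometry, double-gated timing, TI jitter,
breath-hold motion and two noise channels. It does not emulate:
magnitude reconstruction, in-flow contrast in the cavity, through-plane
motion, coil sensitivities or undersampling artifacts (acceleration
enters only through the window duration and the noise model), fat
signal, respiratory drift within a breath-hold, or partial-volume
fractions at tissue interfaces beyond rasterization. Passing the cohort
criteria therefore shows that the *pipeline* reproduces the documented
directional findings under the stated noise model — not that the noise
model itself is a validated description of in-vivo physiology; absolute
TSNR levels in particular depend on invented coefficients and should
only be read comparatively.
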