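---
title: "Methods: simulating and analysing cardiac T2* mapping at 7 T"
author: "CardioT2Star"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing cardiac T2* mapping at 7 T}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(CardioT2Star)
```

# The measurement being modelled

Myocardial T2\* mapping acquires a train of spoiled gradient-echo images
at increasing echo times and fits each voxel's magnitude decay to

$$S(\mathrm{TE}) = S_0 \, e^{-\mathrm{TE}/T_2^*},$$

so that a parametric T2\* map can be read off voxel by voxel. At 7 T this
is attractive (susceptibility contrast grows with field strength, and the
fat–water in-phase echo spacing shrinks to
$1/(f_0 \cdot \delta) \approx 1.02$ ms at 297.2 MHz and 3.3 ppm, enabling
dense echo trains) but also fragile: myocardial T2\* is short (~10–18 ms),
and macroscopic B0 gradients at the epicardium/lung interface add
intravoxel dephasing that masquerades as shortened T2\*. The package
simulates the whole measurement chain on digital phantoms so that the
acquisition strategies and the post-processing can be validated against
known ground truth.

## Signal model and its assumptions

`greSignal` composes, per voxel and echo time:

* mono-exponential decay $e^{-\mathrm{TE}/T_2^*}$ — the working model of
  the fitting stage as well, so fitting error on clean data isolates
  solver behaviour;
* intravoxel dephasing under a **linear-phase (sinc) model**: a uniform
  frequency spread $d$ (Hz) across a voxel attenuates magnitude by
  $|\mathrm{sinc}(d \cdot \mathrm{TE})|$ ($d$ in kHz, TE in ms).
  Through-plane dispersion is $|\partial f/\partial z| \times$ slice
  thickness; each in-plane axis contributes $|\nabla f| \times$ voxel
  extent; the three factors multiply. An 80 Hz/voxel dispersion at
  TE = 10 ms loses ≈ 77% of the signal — the regime at the inferior
  epicardial border. The test suite checks the closed form against a
  brute-force sum of 10⁴ unit phasors to < 10⁻³;
* off-resonance phase $2\pi \, \Delta f \, \mathrm{TE}$ and a single-peak
  fat resonance at the configured ppm shift (fat fraction defaults to 0);
* an optional steady-state (T1 saturation) factor
  $\sin\alpha (1 - E_1)/(1 - \cos\alpha E_1)$, **off by default**: with a
  fixed TR and flip angle it is TE-independent and therefore absorbed into
  $S_0$; exposing it would only matter for inter-protocol amplitude
  comparisons, which the analysis never makes. The low default flip angle
  (20°) mirrors the in vivo protocol choice that limits T1 saturation;
* complex Gaussian receiver noise of standard deviation σ per channel,
  making magnitudes Rician. σ is quoted relative to a myocardial
  $S_0 = 1$, so SNR 50 means σ = 0.02.

Not modelled (deliberately): full Bloch dynamics, RF pulse profiles and
B1⁺ nonuniformity, flow and through-plane motion, multi-peak fat, and
parallel-imaging reconstruction — the artifacts of interest here are
segmentation-related motion inconsistency and dephasing, which this level
captures. A unipolar (flyback) readout is assumed, so no even/odd echo
phase alternation exists.

## Acquisition strategies

The engine is image-space-rendered and k-space-assembled: for every
cardiac cycle, the phantom is evaluated at the moment each k-space segment
is played out (nearest phantom frame in cycle time), the per-echo complex
image is rendered and Fourier-transformed, and exactly that cycle's
phase-encode lines are copied into the accumulating k-space of each echo
image. Motion between segments therefore produces genuine inconsistency
artifacts (blur/ghosting), while a static object reproduces the directly
rendered image to machine precision — a property the tests assert for all
five strategies.

The five presets follow the published protocol table: views per segment
10 (ME), 5 (MS), 3 (MB CINE), 2 (ME CINE), 1 (MS CINE) at 240 lines;
ME variants use 6 echoes spaced 3.06 ms, interleaved variants 9 echoes
spaced 1.02 ms split over three excitations (excitation 1 acquires echoes
1, 4, 7, etc.). Repetition times are not printed in the source protocol;
we infer one TR per preset from the printed acquisition windows
(205/192/36/38/36 ms divided by the lines acquired per cycle), giving
20.5 / 12.8 / 12 / 19 / 12 ms, and flag them as inferred. One preparatory
cardiac cycle is added to every protocol; with it, `scanDuration`
reproduces every printed phantom-study duration exactly (25/49/3×81/121/
241 s). Phase-encode ordering is linear; single-phase acquisition windows
default to diastasis (65% of the cycle); prospective triggering leaves a
100 ms end-diastolic gap, and CINE trigger delays divide the remainder
evenly (36 ms at 60 bpm and 25 phases).

## What the phantoms emulate — and what they do not

**Cylinders.** The long-T2\* phantom is a 150 mm uniform disc (T2\*
30 ms) with a 0.5 mm air capillary and a 5 mm water tube; the capillary
carries a 2D dipole-like perturbation $A (a/r)^2 \cos 2\theta$ whose
surface amplitude (2000 Hz) is a free parameter chosen to make the
near-capillary T2\* shortening clearly visible at 8 mm slices — the
true susceptibility difference is not recoverable from the source
material. The medium-T2\* phantom is an 80 mm disc at 20 ms. Both carry a
uniform 2 Hz/mm through-plane gradient, the value measured on a uniform
phantom after volume-selective shimming; this drives the slice-thickness
trend (apparent T2\* rising monotonically as slices thin from 8 to
2.5 mm) that the acceptance tests assert.

**Heart.** A mid-ventricular short-axis annulus (endo/epi radii 24/32 mm
at end-diastole) contracts radially and incompressibly (wall area
conserved analytically; end-systolic endocardial radius 14 mm, epicardial
radius derived). Contraction follows a raised-cosine weight peaking at
35% of the cycle, with a diastasis plateau from 60%. Each 60° sector
carries one AHA segment's T2\*, anchored at the reference end-diastolic
values (16.8/17.3/16.3/12.0/11.4/12.5 ms for segments 7–12) and modulated
over the cycle by $1 - A\,w(s)$ with the amplitude set so cycle max/min
= 1.27 — the reported ~27% systole-to-diastole increase, with the minimum
in systole and the maximum after the onset of diastole. A single smooth
modulation anchored at the end-diastolic row cannot simultaneously
reproduce the reported end-systolic row exactly (one segment's printed ES
value exceeds its ED value), so the ES row is carried as metadata and the
amplitude reading is taken as primary. The B0 field is a smooth
polynomial (several hundred Hz peak-to-peak across the heart, emulating a
global shim) plus a localized Gaussian perturbation (σ = 2 mm) at the
inferior/inferolateral epicardial border scaled to a 20 Hz/mm peak
in-plane gradient, with through-plane gradient rising from 3 to 20 Hz/mm
there. Breath-hold misalignment applies a seeded random shift (≤ 2
voxels/axis) and shear (≤ 0.05) per hold; because the heart phantom is
analytic, the displaced anatomy is re-rendered exactly on the transformed
grid rather than resampled, so the recorded transform is the exact ground
truth and no interpolation blur is introduced at generation time.

Not emulated: anatomically realistic myocardium (trabeculae, RV,
papillaries), blood flow, arrhythmia/trigger jitter, respiratory drift
within a hold, coil sensitivities. Passing tests therefore demonstrate
correctness of the measurement chain under the stated physics, not
robustness to anatomy- or hardware-specific confounders.

## Post-processing choices

**B0 mapping** uses the phase difference of the first two echoes
(ΔTE = 1.02 ms): $\Delta f = \mathrm{wrap}(\varphi_2 - \varphi_1)/(2\pi
\Delta\mathrm{TE})$, confining maps to ±490 Hz. No spatial unwrapping is
performed — post-shim cardiac fields fit comfortably in the band, and
aliasing outside it is documented rather than corrected. Ground-truth or
externally unwrapped fields can bypass the band via `unwrapped = TRUE`.

**Shimming** is defined purely as field-surface subtraction: a
least-squares fit of {offset, x, y} (order 1) plus {x² − y², xy}
(order 2) over the ROI, coordinates in mm from the ROI centroid (this
normalization affects coefficients, not residuals); z-dependent basis
terms are dropped in the 2D single-slice case. Least squares guarantees
the ROI RMS never increases; on the heart phantom's default field,
order-2 shimming reduces the ROI peak-to-peak by more than a factor of 4
(emulating the reported ~400 → ~80 Hz). Whether scanner shim units are
fields or currents is immaterial at this level. Histogram FWHM uses 10 Hz
bins with linear interpolation at the half-maximum crossings.

**Fitting** initializes from ordinary least squares on
$(\mathrm{TE}, \ln S)$ over strictly positive samples (T2\* = −1/slope,
clipped into (0.1, 200] ms and flagged when the slope degenerates), with
$S_0$ initialized from the minimum-TE sample — the quoted estimation rule
— rather than the log-linear intercept; the two differ by the decay over
TE_min, and only the initialization cares. The nonlinear stage is bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) on all samples (non-positive
samples are excluded from the log stage only), unweighted magnitude least
squares with no Rician floor term by default, matching the plain
mono-exponential analysis being reproduced. The solution is accepted only
if it does not worsen the initialization residual; otherwise the
initialization is retained and flagged. Bounds (0.1, 200] ms bracket all
values of interest (9–37 ms) with wide margin. Noiseless recovery is
exact to < 10⁻⁶ relative error; voxels are fitted independently with no
spatial regularization.

**Registration** implements "shift and shear" as the full 2D affine class
estimated by least squares from landmark pairs (exact at 3 non-collinear
pairs), with optional translation-only and shear-only restrictions since
the original parameterization is not stated. One transform per
breath-hold is estimated (not per cardiac phase). Images are resampled
once, bilinearly, with out-of-field voxels zeroed. In the simulation the
landmarks come from the generator's recorded ground-truth transforms —
standing in for the manual annotation of the original workflow — and the
CLI accepts a landmark CSV for real data.

**Segmentation** labels six 60° sectors counterclockwise (on the
displayed short-axis image, anterior → septal direction) from the
anterior RV-insertion angle, numbered 7–12. The ROI is re-derived at
every cardiac phase from that phase's myocardial mask and centroid, and
eroded by one voxel (4-connected) so only compact myocardium enters the
statistics — without this, boundary partial-volume voxels whose signal
mixes with constant-T2\* blood damp the apparent cycle modulation.
Segment means with fewer than 10 voxels are flagged, never dropped.
End-diastole/end-systole are identified as the phases of maximal/minimal
cavity area in the phantom truth — a proxy for the operator-matched phase
selection of the original analysis, not a claim about it. The paired
end-diastole vs end-systole comparison uses the closed-form paired t
statistic with the t CDF, two-sided, no multiple-testing correction.

## Problem sizes and numerical conventions

The simulation experiments run at desk scale by choice: cylinder
experiments at 128×128 over a 288 mm field of view (2.25 mm in-plane),
the strategy-equivalence experiment at the 4 mm in vivo slice thickness,
and the end-to-end CINE recovery at 192×192 (1.5 mm in-plane, 25 cardiac
phases, SNR 50). At 8 mm slices the 6-echo and 9-echo trains genuinely
diverge (dispersion bias grows with TE, and the trains sample different
TE ranges), mirroring the spread the original phantom table shows at
8 mm; at 4 mm all five strategies agree within 0.5 ms on the static
medium phantom. For the recovery experiment the macroscopic-gradient
terms of the heart phantom are switched off, because with them on the
*configured* relaxation modulation is no longer what the signal exhibits
near the inferior epicardium — the artifact is the measurement target of
the shim and bias-direction tests, not of the recovery test.

Conventions: voxel indices are 0-based with half-open extents
(x = column, y = row); the image row axis runs anterior → inferior in
short-axis views; phases are stored in radians in [−π, π); magnitudes are
non-negative and in arbitrary units (the stored dynamic range of scanner
images is not reproducible, so no scaling is applied). Each breath-hold's
volume is written as one NIfTI-1 magnitude/phase pair with a CSV sidecar
of per-frame echo time, cardiac phase and hold; configs are YAML; the
seed is recorded in every report. All randomness (noise, breath-hold
perturbations) flows from the run seed, and the pipeline is bit-for-bit
reproducible under it.

## Known limitations

* Apparent T2\* under dispersion is biased low by construction; the
  package reports the apparent value, as a scanner would, and quantifies
  the bias only through the slice-thickness and bias-direction tests.
* The sinc dephasing model assumes a *linear* phase ramp across the
  voxel; curved local fields (close to the capillary or the epicardial
  perturbation centre) are only piecewise-linearly approximated.
* Nearest-frame evaluation quantizes intra-window motion to the phantom's
  phase grid; with 25 phases and ~36 ms windows this slightly smooths the
  recovered cycle curves (the discrete max/min sits ~0.1–2 percentage
  points below the configured modulation).
* GRAPPA acceleration is not simulated; in vivo durations that depend on
  it are out of scope, and fully sampled timing is used instead.
* The paired t-test treats segments as independent paired observations,
  as in the original analysis; spatial correlation between segments is
  ignored.
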