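# CardioT2Star

Simulation and analysis of myocardial T2\* relaxation mapping with
cardiac-triggered, segmented multi-echo spoiled gradient-echo imaging at
ultrahigh field (7 T).

T2\* — the effective transverse relaxation time including reversible
dephasing from local field inhomogeneity — is an emerging quantitative
contrast for myocardial tissue characterization (iron load, oxygenation).
At 7 T, myocardial T2\* drops to roughly 10–18 ms and macroscopic B0
gradients near the epicardium/lung interface become strong enough to bias
the estimate, so protocol design questions (how to interleave echoes, how
thin to slice, how to shim, whether CINE mapping across the cardiac cycle
is feasible) are best explored quantitatively. This package provides a
tested, fully synthetic test bench for that methodology, aimed at MR
physicists and methods developers:

* **Digital phantoms** (`makeLongT2StarPhantom`, `makeMediumT2StarPhantom`,
  `makeHeartPhantom`): uniform agarose-like cylinders with an air capillary
  (dipole field perturbation) and water tube, and a contracting
  mid-ventricular short-axis heart with segment-specific T2\*
  (AHA segments 7–12), cyclic T2\* modulation across the cardiac cycle, a
  smooth background B0 field plus a localized ~20 Hz/mm epicardial
  gradient, and seeded inter-breath-hold misalignment
  (`perturbBreathHolds`).
* **Signal physics** (`greSignal`, `dephasingFactor`, `addNoise`): spoiled
  gradient-echo magnitude/phase evolution, mono-exponential decay,
  intravoxel dephasing under the linear-phase (sinc) model, fat–water
  phase modulation, Rician-magnitude receiver noise.
* **Acquisition engine** (`protocolPreset`, `acquire`): the five
  cardiac-triggered segmented strategies — single-phase multi-echo (ME),
  interleaved multi-shot (MS), and the CINE variants ME CINE, MS CINE and
  multi-breath-hold MB CINE (echoes interleaved over breath-holds) — with
  views-per-segment bookkeeping, scan-duration and acquisition-window
  accounting (`scanDuration`, `acquisitionWindow`).
* **Field tools** (`computeB0Map`, `fitShim`, `fieldStats`): dual-echo
  phase-difference B0 mapping and volume-selective shimming with a linear +
  second-order spatial basis.
* **T2\* fitting** (`loglinearInit`, `fitMonoexp`, `mapFit`): log-linear
  initialization followed by bounded nonlinear least squares of
  `S(TE) = S0 · exp(−TE / T2*)` on magnitude data, with quality flags.
* **Registration** (`estimateAffine`, `applyTransform`,
  `registerBreathHolds`): landmark-based affine (shift + shear) alignment
  of breath-hold series.
* **Segmental analysis** (`ahaSegments`, `trackROI`, `segmentStats`,
  `pairedComparison`): AHA mid-ventricular sectors tracked across the
  contracting cycle, per-segment statistics, and the paired end-diastole
  vs end-systole t-test.

`runPipeline` chains phantom → acquisition → registration → fitting →
segmentation → report from a YAML-serializable `RunConfig`, reproducibly
under a seed. A thin CLI over the same functions lives at
`inst/cli/t2starsim.R`.

## Worked example

Simulate the interleaved multi-shot (MS) protocol on the iron-doped
medium-T2\* cylinder (truth 20 ms) and map T2\*:

```r
library(CardioT2Star)
geom     <- imageGeometry(c(128L, 128L), c(288, 288), 4, "axial")
phantom  <- makeMediumT2StarPhantom(geom)       # uniform T2* = 20 ms
protocol <- protocolPreset("MS", nLines = 128L) # 3 excitations x 3 echoes
protocol
#> AcquisitionProtocol MS: 128 lines, 5 views/segment, 3 excitation(s) x 3 echo(es), TR 12.8 ms, 1 phase(s), 1 breath-hold(s)
#>   scan duration 27 s, acquisition window 192 ms

series <- acquire(phantom, protocol, noiseSigma = 0.01, seed = 1L)
cc  <- voxelCoordsMM(geom)
roi <- sqrt(cc$x^2 + cc$y^2) <= 30              # central ROI, d = 6 cm
map <- mapFit(series, roi)
map
#> T2StarMap: 1 phase(s), 556 fitted voxels/phase, bounds (0.1, 200] ms
#>   median T2* 19.51 ms, 100.0% voxels converged cleanly

v <- t2StarValues(map)[, , 1][roi]
sprintf("ROI mean T2* = %.2f +- %.2f ms", mean(v), sd(v))
#> "ROI mean T2* = 19.53 +- 0.66 ms"
```

The ~0.5 ms downward bias relative to the 20 ms truth is real physics, not
a defect: the phantom carries a 2 Hz/mm through-plane gradient, so a 4 mm
slice spans an 8 Hz intravoxel dispersion whose sinc attenuation steepens
the apparent decay. Thinner slices move the estimate toward the truth —
the same slice-thickness trend the test suite asserts.

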