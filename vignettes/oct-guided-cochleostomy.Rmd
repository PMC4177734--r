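---
title: "Simulating OCT-guided laser cochleostomy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating OCT-guided laser cochleostomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octguide)
```

## The guidance problem

A cochleostomy opens the bony shell of the cochlea (roughly 1 mm in
diameter) without damaging the endosteum, the membrane thinner than 50 µm
that lines the inner bone surface and holds back the perilymph. Optical
coherence tomography (OCT) can image the bone-endosteum-perilymph boundary
through roughly half a millimetre of compact bone, which makes a foresighted
control loop possible: scan, segment the still-buried boundary, measure the
residual bone thickness above a user-defined *stop surface*, plan laser
pulses proportional to the local thickness, fire, repeat — and stop before
the critical structure is ever exposed.

`octguide` implements this loop end to end in software. A digital phantom
and an OCT-like renderer replace the specimen and the scanner; everything
downstream of the photons — enhancement, segmentation, surface fitting,
thickness mapping, pulse planning, calibration, motion tracking, and the
loop itself — is the same machinery such a system needs, and is exercised
against ground truth the phantom knows exactly.

## The phantom and the imaging model

The phantom (`make_phantom()`) is a layered geometry on a 10 µm lateral
grid: a flat air-bone surface `z_b(x, y)` (depth `z` increases into the
tissue, 0 at the undisturbed surface), a bone-endosteum boundary
`z_e(x, y)` shaped as a spherical cap that is convex towards the surface
(apex depth 1.2 mm, curvature radius 1.5 mm by default — the scale of the
cochlear promontory wall), an endosteum of constant thickness (40 µm
default), and perilymph below.

The renderer (`render_oct()`) produces intensity volumes by a standard
incoherent forward model, per A-scan:

* per-voxel tissue classification against the (rigidly posed) phantom;
* backscatter level times cumulative round-trip Beer-Lambert attenuation
  `exp(-2 \int mu dz)`;
* an impulse-like specular reflex at the air-tissue interface, deposited
  with sub-voxel weighting so the blurred peak centre is unbiased by the
  sampling grid;
* separable Gaussian PSF blur, 18 µm axial and 35 µm lateral FWHM (the
  measured resolutions of the swept-source system being emulated);
* unit-mean multiplicative speckle, independent per voxel, Gamma-distributed
  with a configurable contrast (1 = fully developed speckle). Speckle is
  applied *after* the PSF blur so that the configured contrast equals the
  observed voxel-level coefficient of variation — applying it before the
  blur would make the effective contrast an opaque function of the PSF and
  the grid;
* an additive exponentially distributed noise floor and clipping to the
  dynamic range.

Default optics place the bone signal at the noise floor at 500 µm depth
(`0.3 exp(-2 * 0.008 * 500) = 1e-4`), reproducing the approximately half a
millimetre of usable imaging depth in compact bone. The endosteum scatters
twice as strongly as bone in both backscatter and attenuation; the
perilymph is nearly transparent. With these choices the boundary appears
exactly as in real scans: a thin bright band over dark fluid, drowned out
once the overlying bone exceeds the penetration depth.

The ablation model (`apply_pulse()`) is a Gaussian crater
`d(r) = d0 exp(-2 r^2 / w0^2)` with `w0 = 100` µm (the 1/e² radius of the
200 µm TEM00 spot) and `d0` equal to 1 µm per µs of pulse duration,
linearly mapping the tunable 20-100 µs durations onto the 20-100 µm
single-pulse ablation depths; pulse energies map linearly onto
4.2-28.5 mJ. Overlapping craters add; the crater is clipped at the
perilymph, and any crater reaching past `z_e` raises a `critical_hit` flag
that aborts a loop run. Refractive index defaults to 1 (geometric depth =
optical depth); it is configurable, and the loop is self-consistent for any
constant choice because both the measurement and the plan live in the same
optical-depth scale.

## Enhancement: history compounding and attenuation compensation

Speckle carries no information about the boundary, and fully developed
speckle has unit contrast, so single-frame gradient detection at depth is
hopeless. Two stages recover the contrast:

* **History compounding** (`history_compound()`): the loop re-scans the same
  field every round, and speckle decorrelates between rounds. Voxels whose
  lateral position has not been ablated since an earlier round can be
  averaged with that round's volume; the contrast drops as `1/sqrt(N)`.
  Change masks (pulse positions dilated by one spot diameter, 200 µm) keep
  outdated structure out of the average; the compounding window keeps the
  8 most recent rounds (a memory bound — older volumes contribute little
  once N is that large).
* **Attenuation compensation** (`compensate_attenuation()`): an
  energy-remaining normalization, `I^n / (2 sum_{deeper} I^n + eps)` with
  contrast exponent `n = 2`. For a Beer-Lambert medium this divides out the
  exponential decay and leaves a profile proportional to the local
  scattering. Below the penetration depth the remaining *signal* energy
  vanishes while noise does not, so the plain formula amplifies the noise
  floor without bound; the denominator here also carries the expected noise
  energy still to come, estimated per volume from the deepest tenth of the
  axial samples. Without this stabilization, deep noise out-amplifies the
  true boundary and segmentation locks onto garbage.

## Segmentation and surface fitting

The air-bone surface (`detect_bone_surface()`) rides on the strong specular
reflex: first suprathreshold sample per A-scan, parabolic sub-voxel
refinement to the reflex peak, then grayscale morphological closing/opening
and a median filter on the height map.

The critical boundary (`segment_critical_boundary()`) is detected per
B-scan frame on the *logarithm* of the laterally smoothed compensated
volume: the log turns multiplicative speckle into additive noise of
constant variance and backscatter steps into depth-independent log steps.
The detection statistic is a band feature — the axial rising-edge gradient
plus the magnitude of the steepest falling gradient within 80 µm below it —
because the endosteum is a thin bright band over dark fluid and the
edge-plus-cliff pair is far more discriminative than the rising edge alone.
The confirming fall must lie inside the measured range, which also prevents
false boundaries at the bottom of the scan range. Up to three candidate
maxima per A-scan are linked by dynamic programming with a bounded axial
jump (2 voxels) between adjacent A-scans, a one-A-scan gap tolerance and a
minimum chain length of 10; the confidence score is the fraction of channel
A-scans carrying a linked candidate. On speckled single volumes this chain
becomes confident when the overlying bone is thinner than roughly
400-430 µm, and degrades to below 0.2 beyond 500 µm — the imaging-depth
cliff of the optics.

`fit_boundary_surface()` pools candidates from all frames into one robust
bicubic B-spline (clamped cubic tensor basis, control-point spacing
150 µm, 5 iterations of Tukey-bisquare reweighting at 3 times the median
absolute residual). Candidate clouds cover a disc, so the corners of the
rectangular control lattice are unsupported and a pure least-squares fit is
rank-deficient; a mild second-difference penalty on the coefficient lattice
(P-spline, relative strength `1e-3`) keeps the unsupported lattice regions
tame while leaving densely supported regions essentially untouched. An
unpenalized fit (`smooth = 0`) is available and reproduces representable
bicubic surfaces to numerical precision.

The stop surface (`make_stop_surface()`) is the fitted boundary shifted
shallower by the target residual thickness — exactly, because the clamped
cubic basis sums to one, so the offset moves the control values. While the
boundary is still invisible, `fallback_virtual_structure()` supplies a
virtual critical structure parallel to the original surface at a nominal
depth standing in for "at infinity", and the loop caps per-round depth.

## Planning and the control loop

The planner (`plan_ablation()`) is the greedy coverage rule: apply the next
pulse at the in-mask position of maximal residual thickness not yet claimed
(a disc of the 150 µm minimum spacing is claimed around every pulse; ties
break lexicographically), until no position above target-plus-margin
remains. Durations are quasi-proportional to the local excess: clamped into
20-100 µs and quantized to the three classes short (20 µs, below 100 µm
excess), middle (60 µs, to 300 µm) and long (100 µs); a continuous
proportional mode exists behind a flag. A planned depth never exceeds the
local excess by more than the short-pulse depth.

Running the loop (`run_loop()`) against ground truth exposed three
systematic failure modes of the naive pipeline, and the controller carries
one guard for each; all three are measurement/geometry phenomena a physical
system faces as well:

1. **Wall smear.** Near the channel wall the surface height varies by
   hundreds of µm within one lateral PSF, the first-crossing detector
   biases shallow, and the planner over-fires the rim. Two complementary
   guards: the bottom estimate is the *deeper* of the detected surface and
   a dead-reckoned bottom (original surface plus the accumulated nominal
   craters the controller itself applied — the same 1 µm/µs model the
   planner uses), and the detection search is bounded below the previous
   round's bottom (ablation is monotone).
2. **Finite spot size at the channel edge.** A 200 µm spot cannot produce a
   vertical wall, so bringing the rim of the evaluated channel down to the
   stop surface requires pulses *outside* it. The loop plans over an
   overcut annulus 150 µm beyond the channel mask; the crater-limited wall
   cone then lies outside the evaluated channel bottom.
3. **Crater overlap near convergence.** A pulse deepens its neighbours too
   (93% of its depth 30 µm away), so pulses near already-converged
   positions must shrink. Collateral-aware capping reduces each duration so
   the predicted penetration of every neighbour stays within a 30 µm
   allowance; neighbours already past the allowance bound the per-pulse
   increment (1 µm) rather than vetoing the whole neighbourhood — the
   absolute veto freezes the rim into a pit-and-moat pattern that never
   converges.

Termination follows the reached-all-over reading on the *physical* surface:
both the bottom and the stop surface are band-limited by the PSF and the
200 µm spot, so the measured thickness map is smoothed to spot scale
(Gaussian, sigma 40 µm) and the loop stops when the 99th percentile of
channel positions is within the 10 µm tolerance. With a 20 µm minimum
crater the strict pointwise criterion at 10 µm is geometrically
unreachable — measured equilibrium surfaces hover within tens of
micrometres while isolated grid points keep toggling — so the percentile
criterion is the default and the strict one remains available
(`termination_quantile = 1`).

The loop stops with exactly one of four reasons: `converged`, `max_rounds`,
`tracking_lost`, or `critical_hit`. Results carry two evaluations: against
the ground-truth stop surface (`eval_gt`, the strict simulation-only
evaluation) and against the detected surfaces (`eval_detected`, emulating a
postoperative scan measurement).

## Calibration and tracking

`make_patterns()`/`fit_mapping()` reproduce the cross-scanner calibration:
a lateral grid pattern ablated at 5 equidistant axial planes, detected in
the imaging frame, and fitted with a tricubic B-spline
`(x, y, z) = f(u, v, w)`; the evaluation pattern (the 45°-rotated square
centres at the axial midplanes) probes the points farthermost from the
calibration data. The control lattice uses one knot interval per *two*
pattern cells laterally and per two plane spacings axially: one interval
per cell — the naive reading of "per cell" — makes ordinary least squares
underdetermined (more control points than data), so the coarser lattice is
the smallest one that keeps the fit a genuine overdetermined least-squares
problem, and it also smooths the detection noise. Fixture noise is
isotropic Gaussian with sigma 10 µm, between the 2-3 µm accuracy of the
scanning optics and the 18/35 µm imaging resolution; the synthetic
inter-scanner distortion is one low-order harmonic per axis with amplitude
up to 50 µm.

Tracking uses the imaging system itself: four landmark craters on an
800 µm ring around the channel (the centroid coincides with the channel
centre, so rotational errors are not amplified at the ablation site),
localized per round as depth-weighted centroids of the detected surface
height map (the weight keeps the top half of the crater, which makes the
estimate robust to window truncation), and aligned to the reference
positions by closed-form SVD rigid registration. Fewer than three valid,
non-collinear landmarks raise a tracking-lost error that halts ablation.
The motion-stage evaluation fixture is a 5x5 lateral grid of 100 µm steps
with ±2 µm uniform stage jitter.

## Problem sizes and what the tests show

The closed-loop study condition is the full-size one: 1.4 mm field of view
sampled at 20 x 20 x 6 µm (71 x 71 A-scans, 267 axial samples), a 1 mm
channel, apex depth 1.2 mm, default speckle, three seeds — a run takes
roughly one to two minutes and 30-40 rounds. Module tests use smaller
fields (typically 600 µm, 31 x 31 A-scans) so the suite stays fast; the
methods are resolution-independent at these scales.

The phantom emulates layered geometry, attenuation, speckle statistics,
PSF blur, specular reflexes and rigid motion. It does not emulate
biological texture (trabecular structure, vessels), wet-field imaging,
refractive-index heterogeneity, tissue dehydration, carbonization or
thermal damage, and the crater model is deterministic. Passing tests
therefore demonstrate that the *control and estimation machinery* achieves
the reported accuracy under the stated optics whenever the imaging physics
is as modelled — not that a physical system would; robustness to
real-tissue texture is exactly what the ex vivo experiments in the
literature address.

## Numerical choices worth knowing

* Axial sampling must satisfy Nyquist for the axial PSF (at most half the
  FWHM); the constructors enforce it.
* The IRLS cutoff guards exact fits (`max(3 * median |r|, 1e-3)` µm), so
  noise-free reproduction does not collapse to zero weights.
* All randomness flows through explicit seeds; renders are bit-reproducible
  given (phantom, geometry, seed), and `run_loop()` derives every render
  and jitter seed from the single config seed, so whole runs replay
  exactly.
* Degenerate inputs fail loudly and early: inconsistent phantom geometry,
  out-of-range durations, empty volumes, rank-deficient calibration
  coverage (naming the unsupported region), out-of-domain mapping queries
  (naming the offending pair), and sub-minimal landmark sets all raise
  errors rather than propagate.

## Known limitations

* The boundary detector assumes a single boundary complex per A-scan; it
  does not segment multiple stacked structures.
* Compounding assumes co-registered history; inside `run_loop()` with
  injected displacements the history is conservatively dropped for columns
  marked changed, not re-registered.
* The wall region just outside the evaluated channel converges to the
  clamped edge value of the fitted stop surface, i.e. it is deliberately
  left shallower than a full anatomical model of the widening cochleostomy
  cone would be.
* Runtime is dominated by rendering and was not engineered for real time.
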