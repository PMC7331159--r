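---
title: "Measuring cartilage contact strain and T2* in a synthetic joint: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cartilage contact strain and T2* in a synthetic joint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartstrain)
```

## The measurement problem

Articular cartilage responds to its mechanical environment: chronically
overloaded or unloaded regions change their collagen and proteoglycan
composition, which quantitative MRI can see as a change in the effective
transverse relaxation time T2*. Linking the two in vivo requires two
difficult measurements on the same joint:

1. **Contact strain during gait.** Bone-mounted marker triads are tracked by
   an optical motion-capture system at 120 frames/s; image-derived 3D bone
   and cartilage models are registered to the marker positions frame by
   frame. Because the bones are posed rigidly, the cartilage layers of the
   ball and socket interpenetrate; the interpenetration depth divided by the
   undeformed (combined) cartilage thickness is the *contact strain* — a
   geometric surrogate, not a constitutive strain tensor.
2. **Voxelwise T2\*.** A multi-echo gradient-echo acquisition is fitted
   voxel by voxel with a mono-exponential decay
   $S(\mathrm{TE}) = S_0 e^{-\mathrm{TE}/T_2^*}$; voxels with
   $T_2^* > 50$ ms are discarded as synovial-fluid dominated (fluid T2 is
   roughly 100 ms and T2* about half of T2), and the surviving values are
   projected onto the cartilage surface through the layer thickness.

Regional means of both quantities in 20° posterior-to-anterior bands, taken
before and after an intervention that redistributes joint load, give paired
regional changes (Δstrain, ΔT2*) whose correlation is the scientific
endpoint.

No deposited in vivo data exist for this chain, so the package's first-class
citizen is a **synthetic data module** that generates every input with known
ground truth, and the pipeline is validated against closed-form and
brute-force oracles on that world.

## The synthetic world

### Joint geometry

The joint is an idealized conforming ball-and-socket: the humeral head is a
sphere cap (subchondral radius 10 mm, cap half-angle 80°), the glenoid a
concentric socket (half-angle 45°) whose articulating surface coincides with
the humeral cartilage surface at the neutral pose — zero gap *and* zero
interpenetration, so any compressive relative displacement immediately
produces overlap with a closed-form profile
$\;\mathrm{ov}(\theta)=R+\delta\cos\theta-\sqrt{R^2-\delta^2\sin^2\theta}$
for approach $\delta$ along the socket axis. Cartilage thickness is a smooth
low-order harmonic random field with mean 0.819 mm and spatial SD 0.086 mm
(healthy canine shoulder scale); the generator exposes the continuous field
as the per-vertex ground truth. The idealization buys exact oracles for
thickness, overlap and strain; the analysis pipeline itself only ever sees
triangle meshes and makes no sphere assumption.

### Gait

Six-DOF glenohumeral trajectories are sums of one or two harmonics per DOF
(band-limited, like real capture traces), sampled at 120 frames/s with
80 frames per stride, default 40 strides per recording (the scale of a
multi-minute free-walking session). The approach DOF is non-negative with a
simple (non-tangential) zero so the joint loads and unloads once per cycle.
Marker coordinates are the rigid ground-truth poses applied to the four
triads plus isotropic Gaussian noise (0.05 mm, the scale consistent with
phantom audits of optical capture rigs).

Stride-to-stride variability has a deliberate structure:

* a **common amplitude factor** per stride (SD 5%): strides are bigger or
  smaller as a whole, the dominant mode of real variability;
* small per-DOF **DC offsets** and random-phase **shape perturbations**
  (≈2.5× the post-smoothing tracking jitter);
* every 7th stride is an **irregular stride** (gait initiation / turning):
  its amplitude excursion and per-DOF perturbations are drawn with random
  independent signs but magnitudes bounded away from zero, roughly 10× the
  regular scale (5× for the flexion-extension DOF that carries the stride
  rhythm, so that stride events remain detectable during a turn).

This structure is not incidental. The study's cycle filter — remove cycles
leaving the pointwise mean ± 1 SD band, keep > 70 % of recorded cycles — is
only satisfiable when most deviation modes are strongly correlated within a
stride and the band's width is set by a minority of grossly atypical
strides. If stride noise were iid Gaussian per DOF and sample, the very same
filter would reject nearly every cycle (a cycle with a 1.2 SD offset is
outside a ±1 SD band for most of its samples); we verified this
quantitatively before settling on the mixture structure. The generator
therefore encodes the world in which the published filter behaves as
reported; a green retention test establishes consistency of filter and
world, not a universal property of the filter.

### MR acquisition, phantom, coupled scenario

Multi-echo volumes use echo times 3.83/9.37/14.91/20.46/26.01 ms, voxel
0.3 mm (configurable), cartilage $T_2^*\sim\mathcal N(25, 3^2)$ ms, a
synovial-fluid shell at $\mathcal N(55, 2^2)$ ms (just above the 50 ms
cutoff so cutoff behavior is exercised), and Gaussian signal noise (Rician
optional; magnitudes are fit without noise-floor correction, matching the
measurement protocol). The accuracy phantom is two blocks with balls and two
triads each at 0°/30°/60°, rigidly waved through the capture volume; the
coupled scenario draws regional Δstrain uniformly and sets
ΔT2* = slope·Δstrain + ε with the noise SD derived in closed form so the
population correlation equals a requested value (default 0.726).

## Numerical and design choices

* **Pose estimation** is the Kabsch/Procrustes SVD fit with reflection
  correction; both triads of a bone are pooled into one six-point fit.
* **Euler convention** for 6-DOF decomposition is intrinsic Z-Y'-X''; the
  glenoid and humeral-head anatomical frames come from least-squares sphere
  fits with principal-direction in-plane axes. Neither is dictated by the
  measurement protocol; both are fixed here and surfaced in the run
  configuration.
* **Cycle segmentation**: boundaries are upward crossings of the mean level
  of the largest-amplitude DOF. Crossings are located coarse-to-fine —
  first on a half-period moving average (which nulls the second harmonic),
  then refined on progressively lighter smoothings down to a nearly raw
  reference, with sub-frame interpolation. Each cycle is resampled to 101
  samples over [start, start + spectral period]; using the *period* rather
  than the next crossing means one mislocated boundary (typically beside a
  grossly atypical stride) cannot linearly warp its neighbor. All six DOFs
  are low-passed with a 0.05 s moving average before resampling, the
  standard treatment of capture jitter prior to cycle averaging.
* **Cycle rejection** uses the pointwise mean ± 1 SD band over all cycles,
  single pass; a cycle is removed when any DOF has more than 5 % of its
  samples strictly outside the band (with a 10⁻⁹ absolute slack so
  bit-identical cycles are never rejected). The 5 % exceedance tolerance
  and the "any DOF" rule are our reading of an ambiguous published
  sentence; both are configurable.
* **Thickness** is ray-cast from each subchondral vertex along its outward
  normal to the articulating surface (Möller–Trumbore in C++).
  **Overlap** casts the line through each cartilage vertex along its
  subchondral normal against the *closed* opposing cartilage solid
  (articulating surface + subchondral interface + rim closure) and reports
  the depth of the vertex inside the solid's interval — robust at the
  conforming boundary where the vertex lies exactly on the surface.
* **Strain denominator** is the combined (both layers) local thickness by
  default, with an own-layer option; the contact threshold is 0.25 mm (the
  in-plane image resolution of the source protocol). **Cumulative** strain
  is the per-vertex maximum over the cycle (peak-load reading of
  "combined", frame-order invariant); per-vertex mean-over-contact-frames
  is available. Areas integrate by barycentric lumping (one third of each
  incident triangle per vertex).
* **T2\* fitting** is Gauss–Newton nonlinear least squares initialized from
  the log-linear regression (log-linear alone is biased low under additive
  noise; it remains selectable). Validity requires $0 < T_2^* \le 50$ ms
  and $R^2 \ge 0.7$ (the goodness-of-fit gate guards pure-noise voxels and
  is our addition; the source protocol states only the upper cutoff).
  Projection samples the valid-masked map by trilinear interpolation along
  the through-thickness segment at 0.1 mm steps.
* **ICP model fusion** is point-to-surface (closest point on triangle):
  vertex-to-vertex matching aliases on regular meshes and stalls in side
  minima. Iterations stop when the RMS improves by less than 10⁻⁵ mm.
* **ICC** is the two-way random-effects absolute-agreement single-measure
  form ICC(2,1) with the McGraw–Wong F-based confidence interval; ICC(3,1)
  is reported alongside. **Precision** of phantom quantities is ±1 SD by
  default (the published ± values never state their definition); a 95 %
  central range option exists.
* **Error propagation** applies the measured bias as a systematic offset of
  the relative pose (distance bias along the approach axis, angle bias
  about the medial-lateral axis) and samples 100 uniform draws from the
  ± precision box over the 6-DOF perturbation space, reporting the min/max
  envelope of mean cumulative strain and contact-area ratio.
* **Determinism**: one global seed is fanned out to per-generator
  substreams through a small string hash, so composite scenarios are
  bit-reproducible; two `run_study()` calls with one seed produce
  byte-identical CSV/JSON outputs.

## What a green test does and does not establish

The synthetic world matches the statistical *structure* of the study's data
(conforming layers with sub-millimetre thickness, periodic 6-DOF gait with
mostly-consistent strides plus occasional gross outliers, mono-exponential
decay with a fluid compartment above the cutoff, phantom capture noise at
the 0.1 mm scale). It does not emulate real anatomy (the head is a sphere),
soft-tissue artifact (markers ride on bone, as with surgical pins), B0/B1
field structure, orientation-dependent (magic-angle) relaxation, or
segmentation error of real images. Property tests against closed-form
oracles establish that the *measurement chain* is correct; they cannot
certify the published in vivo effect sizes, which derive from three animals'
recordings that are not available at desk scale.

## Known limitations

* Strain is the rigid-overlap surrogate; no tissue deformation model.
* The cycle filter's retention behavior depends on the deviation structure
  of real recordings; the 5 % tolerance may need adjustment on data whose
  jitter spectrum differs from the generator's.
* The fluid mask is purely a relaxation-time cutoff; partial-volume voxels
  at boundaries may survive it under noise.
* ICP here assumes a capture-range-good initialization, as in same-session
  model fusion; it is not a global registration.
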