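---
title: "Methods: simulating and validating MRI-guided small-animal radiotherapy"
author: "murt package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and validating MRI-guided small-animal radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem this package models

Small-animal irradiators deliver collimated kilovoltage X-ray beams under
cone-beam CT (CBCT) guidance.  CBCT is excellent for dose calculation and
mechanical targeting but has poor soft-tissue contrast at low kVp: abdominal
tumours, adrenal glands (1.5–3 mm) and pancreatic lesions are effectively
invisible.  MR-guided radiotherapy (MR-IGRT) closes that gap: the target is
delineated on MRI, the MR volume is registered to the planning CBCT, and the
plan is delivered on the irradiator.  Every step — animal repositioning
between scanner and irradiator, MR geometric distortion, multimodal
registration, operator target prescription — contributes to the final
targeting error, so the chain has to be validated end to end.

`murt` implements that entire chain on synthetic data: digital polymer-gel
dosimeter phantoms and a labelled abdominal mouse phantom, the registration
algorithms, a collimated-beam dose engine, a virtual gel readout, DVH
analysis, and an end-to-end targeting-accuracy evaluation.  Because every
phantom is generated analytically, every experiment has exact ground truth
(labels, displacement fields, poses, dose), which turns the validation
experiments into oracle-based tests.

Conventions: world coordinates are RAS millimetres; +y is vertical
(anterior for a supine animal; the zero-degree beam travels along −y);
+z is the subject's superior axis; voxel-to-world affines map 0-based
indices; doses are Gy in the engine's normalization-anchored model units.

# Phantoms: what they emulate and what they do not

## Gel dosimeter vial

`makeGelPhantom()` builds a water-equivalent gel column (default inner
diameter 25 mm, height 18 mm) in a glass vial.  The vial is "prepared at an
angle", so the set meniscus is a plane tilted by `meniscusTiltDeg`
(default 15°).  That tilt is the load-bearing design feature: it breaks the
rotational symmetry of the gel about the vial axis, which is what lets a
surface-driven registration recover all six rigid degrees of freedom
without fiducials.  With `meniscusTiltDeg = 0` the phantom is rotationally
symmetric, axial rotation is unobservable, and the generator records a
warning in the truth metadata.

The CT rendering shows gel (1000, water-equivalent scale) and glass (2000)
against air (0) with Gaussian noise (σ = 20); the MR rendering (CE-FAST-like
contrast) shows only the gel (signal 400) with Rician noise at SNR 20.
Default grids mirror the reference acquisition scales: 0.16 mm isotropic CT,
0.27 mm isotropic MR.  An optional rigid `pose` renders the MR volume with
the vial repositioned in the scanner — the misalignment the registration
must recover.

## Mouse abdomen

`makeMousePhantom()` voxelizes analytic shapes: a tapered superellipse
body, ellipsoidal liver, stomach, spleen, kidneys, adrenals (2.2 mm
equivalent diameter, within the 1.5–3 mm anatomical range), bladder, a
coiled bowel tube, and a 4.8 mm pancreatic-style tumour in the upper right
abdomen (the entry size at which such tumours are identified, about
4–5 mm).  Organs are checked for disjointness at voxel level; a collision
is an error naming the offending pair.

Contrast is table-driven per modality.  The CT table spans under 30
CT-number units across soft tissue, so with σ = 20 Gaussian noise the
adrenals and the tumour have contrast-to-noise ratio below 1 — invisible,
as on a real low-kVp CBCT.  The bSSFP table renders fluid bright (bladder,
stomach) and gives the adrenals CNR well above 5; the CPMG table gives the
tumour its highest contrast of any rendering, mirroring which sequence
guides tumour delineation.  MR noise is Rician (magnitude of a complex
Gaussian); because E[M²] = S² + 2σ², organ means can be background-corrected
with `riceCorrectedMean()`, and the generator's means are unbiased within
2% at the default SNR of 20 — this is tested.

## Motion models

`applyMotion()` implements three motion kinds, each returning the exact
displacement field or rigid transform it applied so that registration can
be tested against an oracle:

* **intrinsic** — gravity-induced body droop (zero at the cradle contact
  line, rising linearly to the full amplitude at the surface farthest from
  it; the reference scale is about 1 mm over 30 minutes), bladder filling
  (a radial dilation confined to 2.5 bladder radii), and gastrointestinal
  motility (six random Gaussian bumps anchored in the bowel, scaled to a
  peak amplitude).  The GI amplitude is a free parameter: the reference
  experiments report only a regional signal change, never millimetres.
* **extrinsic** — one rigid pose perturbation (cradle transfer between
  scanner and irradiator).
* **mr_distortion** — a smooth quadratic polynomial warp scaled to a peak
  amplitude, standing in for gradient-nonlinearity distortion.

Displacement fields use the backward (pull-back) convention of
`resample()`; a zero spec returns its input bit-identically.

What the phantoms deliberately omit: atlas-level anatomical realism,
respiration-resolved 4D motion, MR pulse-sequence physics (only contrast
behaviour is rendered), partial-volume/PSF blur at organ boundaries, and
CBCT reconstruction artefacts.  Tests passing on these phantoms show the
*chain* is correct and self-consistent at realistic contrast, noise and
geometry scales — not that any specific in-vivo accuracy would be attained.

# Registration

## Surface chain (gel phantoms)

CT gel segmentation uses 26-connected region growing within an intensity
window (850–1150), which keeps the gel and excludes glass and air; the MR
gel is thresholded and the largest component kept.  `maskToSurfacePoints()`
extracts boundary voxels, estimates the surface area from the gradient
magnitude of the smoothed mask, and draws `area / spacing²` points
systematically, with outward normals from the mask gradient.

`icpRegister()` alternates closest-point matching with a rigid update.
The default update is **point-to-plane** (linearized least squares on the
residuals along the fixed normals) rather than the classic point-to-point
Kabsch fit, which is retained as an option.  The reason is empirical and
geometric: on a cylinder with a tilted-plane meniscus, point-to-point ICP
lets correspondences slide tangentially along both the cylinder and the
meniscus plane, and for rotations about the vial axis beyond roughly ±4°
it settles into a stable wrong fixed point.  Point-to-plane measures error
along the normals, where the tilted meniscus actually constrains the
rotation, and converges in a handful of iterations over the full ±10°
repositioning range used here.  Trimming (default 10% in the pipeline)
guards against segmentation outliers; degenerate (collinear) geometry
raises a rank warning; a final RMS above about three voxel sizes raises a
registration-quality warning rather than an error, since near-symmetric
vials can produce plausible-looking local minima.

## Rigid intensity registration (in vivo chain)

`rigidRegisterIntensity()` optimizes six rigid parameters over a 3-level
coarse-to-fine pyramid with Nelder–Mead.  The default metric is mutual
information (32 bins, partial-volume binning for smoothness) — the standard
multimodal choice for MR-to-CBCT; a MIND-descriptor SSD metric is also
available.  Initialization aligns foreground intensity centroids.  On
phantom renderings the recovered pose is accurate to a few hundredths of a
millimetre in displacement; the rotation magnitude is resolvable only to
about 0.15–0.3° because a 0.1° rotation moves these phantoms' content by
less than a thirtieth of a voxel — displacement accuracy, not degrees, is
the quantity the workflow depends on.

## MIND deformable registration

`mindDescriptor()` computes the modality-independent neighbourhood
descriptor: Gaussian-weighted (σ = 0.8 voxel) patch distances to the six
axis neighbours, normalized by their mean (floored at 10⁻⁶ of the squared
dynamic range so constant images stay defined), exponentiated and scaled to
a maximum component of 1.  The descriptor is exactly invariant to affine
intensity maps — including contrast inversion — which is what makes
descriptor SSD a usable MR-to-CT metric; this invariance is asserted to
1e-6 in the tests.

`deformableRegisterMind()` minimizes descriptor SSD with demons-style
Gauss–Newton updates, Gaussian (diffusion) smoothing of the field
(σ = 3.16·√α voxels, α = 0.1 by default, i.e. about one voxel), a
per-iteration step cap of 0.4 voxel, and 3 pyramid levels.  Step
backtracking keeps the objective non-increasing across outer iterations; a
persistent increase is a convergence error.  The moving image is smoothed
to match each level's anti-aliasing kernel so that registering an image to
itself yields an exactly zero field.  On the phantoms it recovers a known
1.5 mm polynomial distortion with mean error below 0.3 mm inside the body
(cross-modality) and a 1 mm droop with mean error below 0.1 mm
(same-modality, noiseless).

`transferTransform()` applies the chain estimated on one MR contrast to a
co-acquired second contrast (bSSFP → CPMG), resampling it onto the CT grid
for planning import.  The two contrasts share the scanner frame by default;
a stored relative transform is accepted, and a declared frame mismatch is
refused.

# Dose engine

The engine is deliberately a *primary-beam* model: dose ∝
exp(−∫μ dl) · (SAD/s)², restricted to the collimator cone with a Gaussian
penumbra (erfc lateral profile; the 20–80% width is 1.683 σ).  No scatter,
no spectrum.  The commercial planning system it stands in for has
proprietary physics; the validation quantities reproduced here (geometric
targeting, DVH comparisons between plan geometries) are driven by geometry
rather than spectral detail, so a transparent analytic model is preferable
to an opaque approximation of one.

Parameters, all configurable through `doseEngine()`:

* `muWaterPerMm = 0.02` mm⁻¹ — effective water attenuation at a 220 kVp
  beam quality;
* `waterCT = 1000` — the water-equivalent CT number; CT-to-μ is a linear
  two-point calibration (background → 0), and the phantom renderers emit
  values on this scale;
* `penumbraSigmaMm = 0.3` — the platform's penumbra is sharp; 0.3 mm
  reproduces sub-millimetre edge widths;
* SAD (`beamSpec()`) defaults to 350 mm;
* ray-marching step: one voxel (midpoint rule along the source ray).

Arcs are discretized superpositions of static beams (midpoint angular
sampling, weight 1/N): conical arcs rotate the subject about the vertical
axis with the gantry fixed (45° for the gel treatment), gantry arcs sweep
the source in the axial plane.  Isocentre dose changes by less than 0.5%
when control points double beyond 36, so 36 per full rotation is the
default.  `normalizePlan()` anchors the dose scale: the prescription is
exact at the isocentre (or as the target mean), which is how the absolute
Gy scale is defined in this model.

The cross-beam target (`composeCrossBeams()`) normalizes each of two
orthogonal beams to 2 Gy at the crossing point, so the intersection
receives 4 Gy by construction and the test asserts the engine reproduces
this through its full geometry path.  Two target-volume conventions are
computed: the nominal sphere of the beam diameter (4.19 mm³ at 2 mm,
33.5 mm³ at 4 mm — the convention used when such targets are reported) and
the true orthogonal-cylinder Steinmetz volume 16r³/3 (5.33 mm³ at 2 mm).
They differ by about 27%; `nominalTargetVolume()` and `steinmetzVolume()`
expose both rather than resolving the discrepancy.

# Virtual gel readout

Polymer gels polymerize in proportion to absorbed dose and read out as an
MR signal change.  The response model is a saturating exponential,
ΔS = S_max·(1 − exp(−k·(D − D_vis)₊)) with S_max = 600, k = 0.35 Gy⁻¹ and a
1 Gy visibility threshold.  No quantitative response curve is published for
the reference workflow — only ordinal separability of raw gel, 2 Gy paths
and the 4 Gy intersection is needed — so k was chosen once such that those
three classes are separated by well over 3 noise standard deviations at
SNR 20, and the model is monotone by construction.

Segmentation thresholds follow from the response curve rather than from
tuning: the cross-beam intersection is segmented at the signal
corresponding to 1.5× the per-beam dose (3 Gy for 2+2 Gy), and the
arc-delivered region is segmented on the *dose-change* map obtained by
inverting the response curve on the pre- and post-treatment readouts,
thresholded at half its plateau.  Working in dose units linearizes the
saturating response and removes the centroid bias that the signal-change
map acquires where the arc overlaps the pre-irradiated beam paths.
Centroids are threshold-excess weighted, which recovers sub-voxel accuracy
from binary masks.

# End-to-end targeting evaluation

`gelTargetingExperiment()` chains everything per seeded run: phantom with a
random vial pose (rotation up to 8°, translation up to 3 mm), cross-beam
target formation (2 mm beams, 2 Gy each) at an off-centre, off-axis target
point (avoiding mirror-image symmetry), noisy CT and MR readouts,
region-growing segmentation, surface extraction, trimmed point-to-plane
ICP, isocentre prescription at the registered intersection centroid plus
Gaussian operator jitter, a 45° conical arc (5 mm collimator, 4 Gy,
36 control points) on a 0.3 mm working-resolution dose grid, a second
virtual readout, and offset measurement between the delivered high-dose
centroid and the target centroid in the readout frame.

The operator-jitter model (σ = 0.25 mm per axis) replaces the manual
"operator identifies the centre" step with an explicit error budget: the
radial mean of a 3D Gaussian is 2σ√(2/π) ≈ 0.40 mm, which dominates the
chain; registration contributes ~0.01–0.03 mm at the target and
segmentation a few hundredths of a millimetre.  Across five seeded runs at
the default acquisition-scale conditions the mean offset is about 0.37 mm —
within the 0.56 mm the physical experiment achieved, as it should be given
that the simulation omits error sources (image distortion during CBCT
acquisition, gel inhomogeneity) that the physical chain contains.  Both
readouts are rendered in a common scanner pose: measuring the offset within
one image makes the metric independent of any further repositioning, which
is also why the physical experiment could read it from the final scan.

# Planning and DVH analysis

`makeComparisonPlans()` builds the four comparative geometries: a single
45° conical arc; a single vertical beam; two conical arcs at 30° and 60°;
and two gantry arcs sweeping 0→120° and 0→−120° (240° of source travel).
All use a 10 mm collimator at 8 Gy for the abdominal comparison, isocentred
on the tumour centroid.  `computeDVH()` produces cumulative curves (0.1 Gy
bins) that are exact on piecewise-constant doses and satisfy the usual
invariants (100% at 0 Gy, monotone non-increasing, 0% above the maximum).
`kpcPlanComparison()` runs the comparison on the default mouse phantom at a
0.3 mm CT rendering and 0.4 mm dose grid — sizes chosen so the four-plan
comparison is a desk-scale computation — and extracts tumour D95, kidney
mean doses and the fraction of stomach+bowel receiving a low dose
(0.1–5 Gy; strictly zero-dose voxels are not "exposed").  The expected
ordinal findings hold: comparable tumour D95 across plans (within 5%),
highest right-kidney mean for the vertical beam, best left-kidney sparing
for the vertical beam, and more low-dose stomach/bowel exposure for the
double gantry arc.

# Numerical choices and degenerate inputs

* Interpolation is trilinear (nearest for labels); out-of-field fill is 0
  (air).  Resampling through a chain equals resampling through the
  composed transform to within interpolation error on smooth images.
* ICP: tolerance 1e-4 mm, cap 200 iterations (40 in the pipeline, where
  the accuracy floor is reached much earlier).
* Field inversion (`invertDeformationField()`) uses 15 fixed-point
  iterations; it is used only by oracle-based tests.
* Constant images: MIND's variance floor keeps descriptors defined; Otsu
  on a constant input is an error.
* A zero-sweep arc is a degenerate-arc error, except the single-control-
  point case kept for consistency checks, which equals the static beam
  exactly.
* Rotation matrices are re-orthonormalized (SVD) after composition so
  that long chains keep the validity invariants to 1e-9.
* Problem sizes: unit tests run phantoms at 0.35–0.8 mm; the acceptance
  evaluation runs the gel chain at the full 0.16/0.27 mm acquisition
  scales with the dose computed at 0.3 mm.

# Known limitations

* The dose engine is primary-only: no scatter tails, no spectral
  hardening, and Gy are model units anchored at the normalization point.
  Absolute dosimetry and film calibration are out of scope.
* The phantoms' hard-edged (non-PSF-blurred) renderings slightly limit
  rigid-registration rotation precision (see above) and make boundary
  voxels noisier in CNR estimates than real acquisitions would be.
* The gel response is a one-parameter saturating curve; real gels show
  dose-rate and temperature dependence, and their readout (R2 mapping)
  has structured noise this model does not attempt.
* Deformable registration is diffusion-regularized demons; it makes no
  diffeomorphic guarantee, which is acceptable for the ≤2 mm smooth
  motions modelled here.
* The bSSFP/CPMG relative transform is assumed identity unless a stored
  scanner offset is supplied; both paths are implemented, neither is
  asserted to be the scanner's behaviour.
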