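# murt — MRI-guided small-animal radiotherapy, simulated end to end

`murt` is an R toolkit for developing and validating **MR-IGRT**
(magnetic-resonance-image-guided radiotherapy) workflows for small-animal
irradiators, entirely on synthetic data with exact ground truth.  It is
aimed at preclinical radiotherapy physicists and methodologists who need to
quantify how much targeting error each link of the guidance chain — animal
repositioning, MR distortion, multimodal registration, manual target
prescription, arc delivery — contributes, before (or instead of) burning
scanner and irradiator time.

The package provides:

* **Digital phantoms** — a rotationally-asymmetric polymer-gel dosimeter
  vial (tilted meniscus; CT shows gel + glass, MR shows gel only) and a
  labelled abdominal mouse (tumour, stomach, bowel, spleen, liver, kidneys,
  adrenals, bladder) with modality-specific contrast, Rician/Gaussian
  noise, intrinsic motion (body droop, bladder filling, GI motility),
  extrinsic cradle-transfer pose jitter and polynomial MR distortion.
  Every generator returns truth labels and the exact transform or
  displacement field it applied.
* **Registration** — region-growing segmentation, surface point extraction,
  trimmed ICP (point-to-plane default), multi-resolution rigid mutual
  information, and MIND-descriptor deformable registration
  (self-similarity descriptors, demons-style diffusion-regularized
  optimization), plus transform transfer between co-acquired MR contrasts.
* **Dose engine** — collimated kV beams with primary attenuation
  (dose ∝ e^{−∫μ dl}·(SAD/s)²), Gaussian penumbra, static beams, conical
  arcs (subject rotation) and gantry arcs, prescription normalization.
* **Planning & analysis** — isocentre definition with an operator-jitter
  model, collimator size matching, the four standard comparative plan
  geometries, cumulative DVHs, and a virtual gel-dosimeter readout with an
  end-to-end targeting-accuracy evaluation.

## Worked example: how accurately does the chain hit an MR-only target?

The gel experiment forms a cross-beam target (two orthogonal 2 mm beams,
2 Gy each — visible in MR, invisible in CT), registers the gel's MR to its
CT by surface ICP, prescribes a 45° conical arc (5 mm collimator, 4 Gy) at
the registered target centre with 0.25 mm operator jitter, and measures the
offset between the delivered high-dose region and the target in the
post-treatment virtual readout:

```r
library(murt)
report <- gelTargetingExperiment(runs = 5, seed = 1, spec = gelPhantomSpec())
report
#> TargetingReport: 5 runs, mean offset 0.368 +/- 0.154 mm
#>   (1.36 +/- 0.57 voxels at 0.27 mm)
report@runs[, c("seed", "offsetMm", "regTransErrMm")]
#>   seed  offsetMm regTransErrMm
#> 1    1 0.4889276   0.011444939
#> 2    2 0.1436062   0.024249707
#> 3    3 0.2976126   0.024498861
#> 4    4 0.5246232   0.004113249
#> 5    5 0.3867837   0.010711451
```

The mean 3D offset (0.37 mm here) is the end-to-end targeting accuracy of
the simulated chain; the per-run `regTransErrMm` column shows that the
surface registration itself contributes only ~0.01–0.02 mm at the target —
the budget is dominated by the 0.25 mm/axis operator-jitter model (radial
mean 2σ√(2/π) ≈ 0.40 mm).  A physical version of this experiment reports
about half a millimetre; the simulation, which omits acquisition
distortions, sits below that, as it should.

Other one-liners:

```r
nominalTargetVolume(c(2, 4))   # 4.19, 33.51 mm^3 (sphere convention)
steinmetzVolume(2)             # 5.33 mm^3 (true orthogonal-cylinder volume)
cmp <- kpcPlanComparison()     # four abdominal plans at 8 Gy, 10 mm field
cmp$metrics                    # tumour D95, kidney means, low-dose bowel
```

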