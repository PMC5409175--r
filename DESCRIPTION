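Package: murt
Title: MRI-Guided Small-Animal Radiotherapy Planning and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for magnetic-resonance-image-guided
    radiotherapy (MR-IGRT) of small animals. Provides digital phantoms
    (rotationally-asymmetric polymer-gel dosimeter vials and a labelled
    abdominal mouse with modality-specific contrast, intrinsic motion and
    transfer pose jitter), multimodal registration (surface-point iterative
    closest point, multi-resolution rigid mutual information, and MIND
    descriptor-driven deformable registration), a collimated kilovoltage
    beam and arc dose engine with a primary-attenuation physics model,
    virtual gel-dosimeter readout, dose-volume histogram analysis, and an
    end-to-end targeting-accuracy evaluation of the full image-guidance
    chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
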