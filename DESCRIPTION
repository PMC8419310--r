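Package: tomomre
Title: Multifrequency MR Elastography Simulation, Inversion and Lesion-Mask Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying neuroinflammation-associated brain softening with
    multifrequency magnetic resonance elastography (MRE). Simulates shear-wave
    fields through brain-slice phantoms with known viscoelasticity (finite-difference
    frequency-domain Helmholtz solver and a fast phase-integration forward model),
    inverts them to shear-wave-speed (stiffness) and loss-angle (fluidity) maps by
    multifrequency wavenumber analysis and Laplacian-based direct inversion, builds
    contrast-agent lesion masks (gadolinium enhancement and iron-oxide hypointensity,
    with dilation, mutual exclusion and ventricle removal), computes cohort incidence
    maps, and runs region-wise paired statistics with a normality-gated choice between
    the paired t-test and the Wilcoxon matched-pairs signed-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    EBImage,
    RNifti,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
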