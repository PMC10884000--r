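Package: fetalmorph
Title: Landmark-Free Morphometry of Fetal Face Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical shape analysis of triangulated fetal face surfaces
    without dense landmarks. Provides mesh input/output and rigid alignment,
    a quantile-regression growth model for isotropic size normalisation, a
    Gaussian-kernel control-point deformation model with a varifold data
    term for template-to-subject registration and atlas estimation,
    momenta-space statistics (PCA, pointwise Hotelling T2 and multivariate
    likelihood-ratio fields with max-statistic permutation tests), per-cell
    standardized shape scores for individual subjects, a 3-D monogenic
    phase-asymmetry map for ultrasound volumes, and a synthetic
    face-population generator with known growth, mode, age and group
    effects for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
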