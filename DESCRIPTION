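Package: orbitometry
Title: Automated Orbital Cavity Segmentation and Morphometry from CT-Like Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of bony orbital cavities from CT-like
    attenuation volumes: bone thresholding with thin-wall gap bridging,
    bounded region growing with leak detection, automatic anterior and
    posterior closure construction, tetrahedral mesh volume, smoothed
    surface area and axial depth measurement, and a normalized depth-binned
    volume profile. Includes a phantom generator with analytic ground truth
    (hemisphere, cone, paraboloid cavities enclosed by a thin perforated
    bone shell, with optional lacrimal-channel and wall-fracture defects),
    a synthetic bilateral cohort simulator, left-right asymmetry screening,
    cohort statistics (Shapiro-Wilk normality, Welch and paired t tests,
    a gender-by-depth interaction regression, squared correlations), ANOVA
    based intraclass correlation coefficients, and a repeatability
    validation harness replaying a multi-operator measurement protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
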