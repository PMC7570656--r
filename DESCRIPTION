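Package: flavopk
Title: Response-Surface Optimization, Bioanalytical Validation and
    Noncompartmental Pharmacokinetics for LC-MS/MS Flavonoid Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain of LC-MS/MS small-molecule
    method development: Plackett-Burman screening and Box-Behnken
    response-surface optimization of electrospray source parameters
    (factor coding, main effects with Lenth/dummy/center significance
    testing, quadratic model fitting with lack-of-fit ANOVA, stationary
    point analysis and cube-constrained optimization); bioanalytical
    method validation statistics (calibration regression with
    confidence intervals, LOD/LOQ from residual standard deviation,
    intra/inter-day precision and accuracy, extraction recovery and
    matrix effect); and noncompartmental pharmacokinetic analysis of
    plasma concentration-time profiles (Cmax/Tmax, terminal slope,
    trapezoidal AUC/AUMC, MRT, CL/F, V/F, arm comparisons), including
    assembly of composite profiles from sparse destructive-sampling
    designs and seeded synthetic-data generators with known ground
    truth for all three stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
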