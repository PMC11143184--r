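Package: elpmech
Title: Effective Lens Position Mechanics of Intraocular Lens Power Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing why axial-length-modified, single-constant
    intraocular lens (IOL) power formulas drift myopic in long East Asian
    eyes.  Provides a thin-lens pseudophakic vergence engine (predicted
    refraction, emmetropic power, back-calculated effective lens position),
    the Cooke-modified axial length (CMAL) transform and its reversal,
    classical ELP predictors and refraction formulas (Haigis, SRK/T,
    Hoffer Q, Holladay 1) in conventional-AL and CMAL variants,
    single- and triple-constant lens-constant optimization, refractive
    prediction-error statistics, a synthetic biometric cohort generator
    with an East Asian anterior-chamber-depth plateau preset, and a study
    pipeline that reproduces the mechanism by which anterior-chamber
    plateauing plus axial-length modification yields overestimated lens
    positions, higher-powered lens recommendations and myopic outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
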