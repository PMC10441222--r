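Package: chemoscale
Title: kLa-Based Scale-Up Analysis for Continuous Archaeal Cultivations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for kLa-based scale-up of continuously stirred bioreactor
    cultivations: volumetric oxygen mass transfer coefficient (kLa)
    estimation from dynamic gassing-out dissolved-oxygen transients,
    stirred-tank power and mixing characterization, constant-kLa
    operating-point translation across scales, and the full chemostat
    physiology calculus (dilution rate, specific rates, off-gas CER/OUR/RQ,
    C-mol yields and carbon-balance closure) with steady-state selection and
    summary statistics. Includes a ground-truth synthetic chemostat
    simulator (batch, exponential fed-batch, chemostat phases with
    dual-substrate Monod kinetics) emitting the CSV schemas the analysis
    consumes, and one-way ANOVA with Bonferroni-adjusted post-hoc group
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
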