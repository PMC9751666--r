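Package: osteorad
Title: Internal Beta-Emitter Dosimetry, MicroCT Bone Morphometry, and
    Cohort Statistics for Chronic Low-Dose-Rate Exposure Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mouse radiobiology studies that compare chronic
    internal low-dose-rate exposure to bone-seeking beta emitters (such as
    Ca-45) with acute external irradiation.  Provides a closed-form internal
    dosimetry model (decay-corrected dose-rate and cumulative-dose time
    courses for an injection schedule), three-dimensional microCT trabecular
    and cortical morphometry (bone volume fraction, local thickness and
    separation, structure model index, Euler-characteristic connectivity
    density, midshaft cortical areas), the cohort statistics layer used in
    such studies (normality-gated two-group tests, one-way ANOVA with Tukey
    contrasts, Kaplan-Meier curves with the Gehan-Breslow-Wilcoxon test,
    marker fold-change summaries), and synthetic phantom and cohort
    generators with known analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    flexsurv,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
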