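Package: ftiruq
Title: Uncertainty-Aware Classification of ATR-FTIR Biofluid Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening-type classification of attenuated total
    reflectance Fourier-transform infrared (ATR-FTIR) spectra of biofluids
    such as saliva. Implements extended multiplicative signal correction
    (EMSC) with a polynomial baseline, a PCA-LDA chemometric baseline, a
    windowed dense neural classifier with Monte Carlo dropout uncertainty
    estimation, a two-phase uncertainty-based training-sample selection
    workflow for cohorts with ambiguous positive-class spectra,
    donor-stratified cross-validation with donor-level majority voting,
    and zone-level Shapley attribution over wavenumber regions. A
    hierarchical synthetic cohort generator emulates the donor structure,
    baseline drift, multiplicative scatter and ambiguous-spectrum
    mechanism the analysis assumes, so the full pipeline can be exercised
    and validated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pROC,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
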