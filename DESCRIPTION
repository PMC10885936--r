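Package: wbdwiNorm
Title: Automated Signal Standardisation for Whole-Body Diffusion-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for harmonising signal intensity in
    multi-station whole-body diffusion-weighted MRI (WBDWI). Fits the
    monoexponential diffusion model per voxel to obtain ADC and S0 maps,
    synthesises computed DWI (cDWI) at arbitrary b-values, segments the
    spinal canal with a built-in 2D U-Net trained under Dice, Combo,
    Tversky or Focal Tversky losses, characterises the canal with a
    two-component Gaussian mixture of ADC values (spinal cord versus
    cerebrospinal fluid), and standardises whole-body signal by
    CDF-matched inter-station scaling followed by division by the 90th
    percentile of in-canal cDWI signal. Includes a synthetic multi-station
    phantom generator with ground-truth masks for validation without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
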