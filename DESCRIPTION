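Package: ampmelt
Title: Amplification and Melting Curve Analysis for Quantitative PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-reaction analysis of raw qPCR fluorescence data: automated
    baseline estimation by iterative slope bisection on the exponential phase,
    PCR efficiency determination from a window-of-linearity shared per assay,
    skewness-directed Grubbs outlier screening of individual efficiencies,
    common-threshold quantification cycle (Cq) calling and efficiency-corrected
    target quantities (N0 = Nq / E^Cq).  Melting curves are smoothed with a
    simplified supersmoother, normalized (bilinear, exponential or combined),
    differentiated and screened for product peaks; peak fluorescence fractions
    validate the amplicon against its expected melting temperature and, with a
    saturating dye, correct Cq and N0 for co-amplified artifacts.  Includes a
    reader/writer for a practical subset of the RDML interchange format, flat
    instrument-table import, a synthetic plate simulator with known ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
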