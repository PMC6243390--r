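Package: cardioscreen
Title: Activity-Index Screening of Cardioprotective Compounds with
    Zebrafish Heart Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bioassay-guided deconvolution of active constituents from
    herbal extract fractions using an activity-index score.  Quantifies
    heartbeat rate and rhythm from fluorescence image stacks of
    transgenic (Cmlc2-GFP) zebrafish hearts, computes MTT survival and
    protection rates and per-fraction heart-rate recovery, combines a
    fraction-by-compound peak-area matrix with fraction recoveries into
    per-compound activity indexes, and validates an LC-HRMS compound
    catalog by recomputing monoisotopic masses, negative-mode adduct m/z,
    ppm errors, and neutral-loss fragment assignments.  Includes seeded
    synthetic generators for heart videos, electrocardiogram traces,
    fraction assay tables, and MTT plates so the whole pipeline is
    testable without microscope or mass-spectrometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
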