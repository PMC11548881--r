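Package: endoquant
Title: Ratiometric Quantification of Membrane Protein Density on Endocytic Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the surface density of membrane-associated
    proteins on endocytic vesicles relative to the plasma membrane from
    multi-channel confocal images, using a lipophilic membrane dye (an
    FM4-64/CellMask analog) as a surface-area standard. Implements line-profile
    extraction, plasma-membrane normalization, background subtraction and the
    resulting dye-normalized density-ratio estimator with t-based summaries;
    a synthetic confocal image generator with exhaustive ground truth (cell,
    nucleus, vesicles, Gaussian PSF, Poisson/read noise) for validating the
    estimator by parameter recovery; bioluminescence resonance energy transfer
    (BRET) ratio analytics (raw, net, bystander, kinetic) with matching
    simulators; and the statistical layer used alongside these measurements
    (pooled/Welch unpaired t, paired t with two-stage Benjamini-Krieger-
    Yekutieli false discovery rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
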