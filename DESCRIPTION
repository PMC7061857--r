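Package: lignoquant
Title: Quantitative Wiesner-Stain Imaging of Coniferaldehyde in Lignified Cell Walls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative in situ analysis of the Wiesner test
    (phloroglucinol/HCl) on plant sections: Beer-Lambert absorbance imaging
    from paired unstained/stained brightfield micrographs, image registration
    and subtraction, per-cell-type point sampling, cell-wall layer
    (CML/S1/S2/S3) profiling, adjacency-based cell-to-cell cooperativity
    networks using dependent-correlation (Williams') tests, genotype
    statistics (Tukey-HSD and Kruskal-Wallis compact letter displays,
    range-normalised hierarchical clustering, PCA with data ellipses),
    spectral colorimetry (hue from absorbance spectra, colour deconvolution),
    and gel-permeation polymer metrics including a phloroglucinol-condensation
    estimate. A synthetic section generator with known ground truth makes
    every stage testable without micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    igraph,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
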