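Package: denseFISH
Title: Design, Simulation and Quantification of Densely Labeled FISH Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fluorescence in situ hybridization (FISH) with
    enzymatically synthesized, densely labeled oligonucleotide probes.
    Covers probe-set design for genomic target regions (tiling, GC and
    homopolymer filters, barcode merging with cytosine-spacing
    constraints, extension-unit assembly, synthesis template/primer
    construction), a stochastic model of fluorophore incorporation and
    distance-dependent quenching with degree-of-labeling estimation from
    absorbance, a seeded synthetic microscopy generator producing
    ground-truth-annotated multi-channel z-stacks, a quantitative image
    analysis pipeline (Otsu nuclear segmentation, scale-normalized
    Laplacian-of-Gaussian spot detection, subpixel Gaussian PSF fitting
    by Levenberg-Marquardt, two-color colocalization and 3D distance
    measurement), and the accompanying statistical conventions (median
    normalization, exact and asymptotic Wilcoxon rank-sum tests with
    Bonferroni correction, percentile boxplot summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
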