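Package: phenomdiv
Title: Phenomic Descriptors and Functional Diversity for Genebank Accessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for image-based characterization of genebank
    germplasm. Extracts phenomic descriptors from organ photographs
    (elliptical-Fourier morphospaces of seed, leaf and pod outlines;
    k-means RGB colorimetry with earth-mover distances between color
    histograms), selects discriminating descriptors with random-forest
    mean minimal depth, and quantifies accession-level functional
    diversity (FSpe, FIde, FOri, convex-hull vertex accessions) over
    Gower/PCoA trait spaces for phenomic, classical and combined
    descriptor sets. Includes a synthetic accession generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    png,
    jsonlite,
    randomForest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    boot,
    cluster,
    tiff,
    ggplot2
Config/testthat/edition: 3
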