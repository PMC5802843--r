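Package: plishr
Title: Probe Design, Detection Modelling and Multiplexed Image
    Quantification for Proximity Ligation In Situ Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for proximity ligation in situ hybridization
    (PLISH) experiments. Designs barcoded H-probe panels against target
    transcripts (detection-site selection at AG/TA ligation junctions,
    nearest-neighbor melting-temperature arm adjustment, k-mer off-target
    screening, circle/bridge/imager assembly, pro-rated probe
    concentrations), models single-molecule detection efficiency (Poisson
    copies-per-FPKM calibration, per-site versus composite probe
    efficiency, negative-binomial puncta-intensity statistics), quantifies
    multi-cycle multi-channel micrographs into per-cell expression
    profiles (maximum projection, nuclear-stain registration, nuclei
    detection and propagation segmentation, peri-nuclear expansion,
    per-channel mean intensities), classifies cells without supervision
    (0:10 normalization, log transform, k-means, hierarchical clustering,
    t-SNE, marker-rule labelling) and remaps classes onto tissue images.
    Ships a synthetic-data layer that generates transcriptomes with
    planted off-target collisions, calibration curves and multi-cycle
    tissue images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    MASS,
    Rtsne,
    grDevices,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
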