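Package: synaptiq
Title: Quantification of Excitatory Synapses in Multiplexed Immunofluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-quantification and statistics pipeline for excitatory
    synapses in multiplexed immunofluorescence microscopy of cortical tissue.
    Segments PSD-95-positive synaptic puncta on confocal (~100 nm/px) and STED
    (~20 nm/px) images by combining histogram thresholding with prominence-based
    maxima splitting, measures per-synapse morphometry (area, fitted-ellipse
    aspect ratio, en-face/side-view class), nearest-neighbour distances and
    areal densities, performs rolling-ball background subtraction and
    PSD-95-normalised intensity measurements, counts Munc13-1 nanoclusters in
    dilated synaptic masks, quantifies receptor/PSD-95 ratios at synapses on
    parvalbumin-positive dendrites, and measures somatic parvalbumin intensity.
    A synthetic-cohort generator renders multi-channel fields with exhaustive
    ground truth so every stage can be validated without tissue images, and a
    statistics layer provides subject-level pooled t tests, Holm-Bonferroni
    correction, Spearman correlation, normality tests and covariate regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
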