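Package: ccparcel
Title: Unsupervised Corpus Callosum Parcellation from Midsagittal MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automatic, non-geometric parcellation of the corpus
    callosum (CC) in 2-D midsagittal brain MRI slices. The pipeline
    chains anisotropic diffusion filtering, unsupervised pixel
    classification (K-means pattern units scored by a probabilistic
    neural network, with an entropy-based validity index selecting the
    class count), spatial isolation of the CC with fornix removal and
    contour tracing, and subdivision of the CC into five parcels by
    grouping SLIC superpixels along the anterior-posterior axis.
    Witelson and Hofer geometric baselines, a five-metric evaluation
    harness (Dice, accuracy, sensitivity, specificity, precision), and
    a deterministic synthetic phantom generator with exact ground truth
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    tiff,
    RNifti,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
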