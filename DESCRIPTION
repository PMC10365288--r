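Package: relmap3d
Title: Relevance Maps: Weakly Supervised ROI Extraction from 3D Image
    Classifiers by Superpixel Perturbation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Model-agnostic saliency and region-of-interest extraction for
    pre-trained 3D image classifiers. Volumes are partitioned into 3D
    superpixels (SLIC), each superpixel is perturbed (blanking, local
    min/max filling, or a learned multiplicative "optimal" mask produced
    by an encoder-decoder generator trained with a perturbation loss),
    and the absolute change in the classifier's predicted probability
    scores each superpixel. Scores are normalized to 0-100 and ranked;
    unions of top-ranked superpixels yield weakly supervised
    segmentations evaluated with the Dice similarity coefficient.
    Includes minimal NIfTI-1 I/O, a synthetic multi-channel phantom
    generator with ellipsoidal lesions, a small trainable 3D CNN
    classifier, and the full evaluation protocol suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
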