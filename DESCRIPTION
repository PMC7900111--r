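Package: ildseg
Title: Input-Level Dropout Segmentation of Multisequence MRI with Missing Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates a compact 2.5D dilated-convolution network for
    voxel-wise lesion segmentation of co-registered multisequence brain MRI. The
    central mechanism is sequence-level input dropout: during training, entire
    pulse sequences (all slices of a 2.5D slab) are stochastically replaced by
    zeros and the surviving channels are upweighted by 1/(1-p), where p is the
    fraction of dropped sequences; the same reweighting is applied at inference,
    so one model segments under any subset of its training sequences. Includes a
    reproducible synthetic multisequence phantom generator with lesions and
    vessel-like confounders, NIfTI input/output, and a complete per-case
    detection/segmentation evaluation protocol: voxel-wise ROC/AUC, Youden-index
    threshold selection, Dice/IoU/precision/recall/FPR, lesion-wise false-positive
    counting via 26-connected components with an optional minimum-volume filter,
    cohort summaries with vertically averaged ROC bands, and Wilcoxon rank-sum
    model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
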