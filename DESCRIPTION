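Package: fdopaquant
Title: Semi-Automated F-DOPA PET/MRI Quantification of Pediatric Brain Gliomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated analysis of [18F]F-DOPA PET/MRI studies of
    pediatric brain gliomas. From a BIDS-organized dataset (static and
    optionally dynamic PET, FLAIR MRI, brain mask, labeled anatomical atlas,
    and a FLAIR-drawn lesion mask) the pipeline delineates the tumor volume
    by reference-normalized SUVr thresholding with a FLAIR-drawn fallback for
    low-uptake lesions, removes superior-sagittal-sinus contamination with a
    K-means + SVM voxel classifier, and extracts static (tumor-to-striatum,
    tumor-to-normal) and dynamic (time-activity curves, time-to-peak, slopes,
    dynamic slope ratio) parameters plus intra-tumor uptake sub-regions. A
    synthetic phantom generator with known ground truth makes every stage
    testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    igraph,
    e1071,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
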