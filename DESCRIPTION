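Package: transbrca
Title: Transethnic Breast Cancer Transcriptome Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparing breast cancer
    transcriptomes across cohorts of different ancestry. Implements
    microarray-style preprocessing (detection-p filtering, probe collapse,
    quantile normalization, IQR filtering), cross-cohort conservation of
    correlated gene and miRNA clusters, molecular subtyping (bimodal
    receptor thresholds, PAM50-gene hierarchical clustering, claudin-low
    rescue, Carey IHC classes), LAS biclustering of extracellular-matrix
    genes, SubMap-style subclass mapping with permutation FDRs, per-gene
    linear-model differential expression with a storage-time screen, and
    the clinico-pathological contingency statistics. Ships a synthetic
    paired-cohort generator with planted ground truth so every stage can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    limma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
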