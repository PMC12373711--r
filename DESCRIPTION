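Package: metaconn
Title: Metabolic Connectivity and Network Analysis of Brain FDG-PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Region-, edge-, and network-level analysis of brain FDG-PET
    glucose metabolism. Computes globally normalized SUVmean over an
    atlas parcellation partitioned into the seven canonical resting-state
    networks, compares groups region-wise and voxel-wise (pooled-variance
    t, Cohen's D, Benjamini-Hochberg FDR, cluster reporting in MNI
    coordinates), estimates inter-subject metabolic connectivity as
    Pearson correlation matrices with permutation-based edge comparison,
    and correlates whole-network metabolism with member regions. Includes
    a synthetic cohort generator with block-structured inter-subject
    covariance so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    Matrix,
    RNifti,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
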