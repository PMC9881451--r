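Package: tosomatic
Title: Tumor-Only Somatic Alteration Classification and Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classification of somatic versus germline small variants and
    structural variants in tumor-only whole-genome call sets using random
    forests over database, genomic-context and caller-derived features;
    multi-caller structural-variant consensus merging with panel-of-normals
    breakpoint annotation; post-processing of tumor-only copy-number segments
    (artifact-region exclusion, negative copy-number handling) with a
    matched-versus-tumor-only concordance benchmark; and cross-omic cohort
    quality control (sex validation from coverage, expression and methylation
    intensity; purity-estimate concordance). Ships a deterministic synthetic
    cohort generator with known truth so the whole pipeline is testable
    without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    ranger,
    vcfR,
    rtracklayer,
    withr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
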