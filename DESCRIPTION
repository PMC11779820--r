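Package: sangerbin
Title: Threshold Policies for Orthogonal Confirmation of Sequencing Variants
Version: 0.1.0
Authors@R: person("sangerbin", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Evaluates confirmation-testing policies for clinical sequencing
    variants. Extracts per-variant quality parameters (QUAL, FILTER, DP,
    allele fraction) from VCF files, joins orthogonal (Sanger) confirmation
    labels, bins variants into high-quality (no confirmation needed) and
    low-quality (confirmation required) bins under hard-filter threshold
    policies, scores the binning with confusion-matrix statistics in both
    orientations, searches threshold space for Pareto-optimal policies under
    a sensitivity constraint, evaluates consensus-caller validation, and
    generates calibrated synthetic labeled cohorts so the whole pipeline is
    testable without restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
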