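Package: cnadist
Title: Copy-Number Profile Distances and Heterogeneity for
    Primary-Metastasis Comparisons
Version: 0.1.0
Authors@R:
    person("Maarten", "Voss", email = "m.voss@example.org", role = c("aut", "cre"))
Description: Tools for comparing segmented somatic copy-number profiles of
    matched tumor lesions. Converts segmented log2-ratio profiles (SEG
    format, as produced by circular binary segmentation of shallow
    whole-genome sequencing or SNP-array logR) to absolute copy numbers
    under candidate purity/ploidy pairs, computes the copy-number
    heterogeneity (CNH) statistic by minimizing the distance of corrected
    segments to integer copy numbers over a purity-by-ploidy search grid,
    and computes an inter-profile clonality distance between two lesions
    minimized over purity and ploidy of both samples, with patient-level
    aggregation and cohort group comparison. Includes a clonal-seeding
    simulator (polyclonal versus monoclonal metastatic seeding) that
    generates segmented profiles with known ground truth for
    parameter-recovery and separation experiments, plus gain/loss
    frequency tracks and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
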