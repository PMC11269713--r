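Package: cmsscan
Title: Composite-of-Multiple-Signals Selection Scans with Simulated Ground Truth
Version: 0.1.0
Authors@R: person("cmsscan", "maintainers", email = "maintainers@cmsscan.org",
    role = c("aut", "cre"))
Description: Tools for detecting positive selection in a target population from
    phased SNP data: per-SNP selection statistics (FST, iHS, XPEHH, delta-iHH,
    nSL) with frequency-bin standardization, a composite-of-multiple-signals
    (CMS) score with genome-wide quantile thresholds, LD-based clumping of
    significant SNPs into candidate regions with peak-SNP gene calling,
    interval-class SNP annotation, blood-phenotype difference, correlation and
    altitude-response analyses, covariate-adjusted association with max-T
    permutation adjustment, organ/system enrichment via eQTL-interval overlap,
    and a forward Wright-Fisher sweep simulator that generates complete
    synthetic studies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
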