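Package: scnatrack
Title: Somatic Copy Number Aberration Profiling and Tracking in Circulating Tumour DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and tracks somatic copy number aberrations (SCNAs) from
    low-coverage whole-genome sequencing of cell-free DNA. Provides binned
    read-depth normalisation for GC content and mappability, joint estimation
    of ctDNA tumour fraction, tumour ploidy and per-bin integer copy number
    with a hidden Markov model fitted by expectation-maximisation over a grid
    of initialisations, focal-amplification calling on 50 kb bins, chromosomal
    instability and circulating-DNA metrics with tertile survival analysis,
    cohort gain/loss frequency and responder-unique region analysis, and
    paired pretreatment-versus-progression absolute copy number differencing.
    A synthetic-cohort generator emulating plasma lcWGS read counts drives the
    bundled analysis workflow and the test suite.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
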