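Package: clonotrace
Title: Clonal Tracking of Haematopoietic Stem Cells Through Gene Therapy
    from Colony Whole-Genome Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse whole-genome sequencing of single
    haematopoietic stem/progenitor cell (HSPC) colonies sampled before and
    after autologous gene therapy. Implements post-hoc somatic-variant
    filtering from per-colony read-count matrices (exact binomial germline
    filter, beta-binomial overdispersion filter, depth and VAF-support
    filters), colony quality control (peak-VAF clonality screening,
    phylogeny-consistency testing, duplicate detection from in vitro
    mutational signatures), perfect-phylogeny tree building with
    maximum-likelihood mutation-to-branch assignment, branch-length and
    burden correction from germline-polymorphism call sensitivity,
    mutational-signature exposure refitting, lentiviral vector copy-number
    and integration-site calling, approximate Bayesian computation of the
    number of engrafting long-term repopulating cells from post-therapy
    coalescences, and duplex-sequencing driver-clone trajectory and
    retrospective mutation-timing statistics. A synthetic-data module
    generates colony cohorts with the statistical structure the analysis
    assumes, so the full pipeline is testable without access-controlled
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    graphics,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
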