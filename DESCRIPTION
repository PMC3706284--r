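Package: deafscreen
Title: Variant Screening and Triage for GJB2 and Mitochondrial 12S rRNA
    Hearing-Loss Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a Sanger-style deafness-gene
    screening analysis for nonsyndromic sensorineural hearing loss cohorts.
    Calls GJB2 coding-region and mitochondrial 12S rRNA variants by global
    alignment against reference sequences, emits legacy-style variant names,
    classifies per-subject GJB2 genotypes, bands hearing severity from
    audiograms, computes case/control carrier frequencies and cohort
    aggregates, scores multi-species nucleotide conservation, triages
    mitochondrial variants into pathogenic/putative/polymorphism classes,
    and quantifies variant-induced RNA secondary-structure alteration by
    base-pair maximization.  Ships an embedded variant catalogue, synthetic
    stand-in references, and a synthetic-cohort generator that emulates the
    study conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
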