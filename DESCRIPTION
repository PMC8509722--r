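Package: varodds
Title: Bayesian Prior/Posterior Odds Classification of Rare Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variant-interpretation toolkit for rare missense variants in
    candidate genes, built around a Bayesian prior/posterior odds classifier.
    Annotates single-nucleotide variants against a transcript model (protein
    consequence and HGVS p. notation), applies a rare heterozygous missense
    filter, aggregates eight binary evidence descriptors (conservation,
    domain and motif context, sequence complexity, in-silico predictor
    consensus, database and literature annotation) into prediction and odd
    scores, multiplies a literature/frequency-informed prior odds ratio into
    a posterior odds ratio with a five-class pathogenicity call, and profiles
    internal conservation of repeat proteins by progressive self-alignment of
    their units. A synthetic-data module generates cohorts, variant tables
    with planted truth, repeat proteins and toy transcripts so the whole
    pipeline is testable without external downloads. Ships a ten-variant
    LRP5 case study from a male low-bone-mass screen as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    vcfR,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
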