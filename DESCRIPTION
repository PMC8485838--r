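Package: cpPhylogeo
Title: Chloroplast Haplotype Phylogeography and Coalescent Demographic Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogeographic analysis of chloroplast DNA sequence
    alignments: haplotype collapsing and median-joining networks, haplotype and
    nucleotide diversity, AMOVA with permutation tests, GST/NST phylogeographic
    structure tests, Mantel isolation-by-distance, neutrality tests (Tajima's D,
    Fu's Fs, R2) with coalescent p-values, mismatch-distribution fitting under
    the sudden-expansion model, and approximate Bayesian computation over
    competing three-lineage demographic scenarios simulated with a structured
    coalescent and HKY finite-sites mutation. Includes a synthetic-data
    generator so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    vegan,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'alignment-io.R'
    'haplotypes.R'
    'diversity.R'
    'distances.R'
    'amova.R'
    'gstnst.R'
    'neutrality.R'
    'mismatch.R'
    'scenarios.R'
    'abc.R'
    'synthetic.R'
    'pipeline.R'
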