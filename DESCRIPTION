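Package: cypminer
Title: Mining, Classification and Expression Screening of Cytochrome
    P450 Genes from Plant Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies, curates and classifies cytochrome P450 (CYP450)
    genes from assembled, strand-specific plant transcriptomes.  Provides
    sense-strand ORF extraction with domain-coverage based full/partial
    curation, CYP nomenclature assignment by nearest-reference amino-acid
    identity (40/55/97 percent family/subfamily/allelic-variant cutoffs),
    physicochemical characterization (length, molecular weight,
    isoelectric point) and conserved-motif detection, Neighbor-Joining
    phylogenies with Poisson-corrected distances and bootstrap support,
    FPKM-based expression profiling with marker-gene co-expression
    screening and qPCR concordance via the 2^-ddCt method, and
    antisense-transcript detection by opposite-strand local alignment.
    A seeded synthetic-data generator plants transcriptomes with known
    truth so every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
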