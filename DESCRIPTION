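Package: mhcassort
Title: MHC Class II Amplicon Genotyping, UniFrac Mate-Choice Tests, and
    Counting-Based Selection Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for hypervariable MHC class II exon 2
    repertoires in songbirds with many co-amplifying loci. Calls multilocus
    genotypes from per-individual amplicon read counts (read-frequency filter,
    region trim, translation, collapse to unique protein alleles); measures
    phylogeny-aware similarity of mated pairs with unweighted UniFrac on a
    neighbor-joining reference tree and tests nonrandom mating against a
    year-stratified Monte-Carlo randomized-pairing null; screens for positive
    selection with Nei-Gojobori counting (overall bootstrap Z-test and a
    SLAC-style per-codon test on Fitch-parsimony ancestors), AIC model
    bookkeeping and consensus-site intersection; surveys trans-species
    polymorphism by identity screening and conspecific-monophyly testing; and
    generates synthetic cohorts, read counts, pairings and codon alignments
    with known ground truth so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
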