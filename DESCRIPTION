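Package: bescope
Title: Scope of DNA and RNA Base Editing for Pathogenic Single Nucleotide Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies pathogenic single nucleotide variants by their
    amenability to DNA and RNA base editing. Implements the filtering cascade
    for ClinVar-style variant tables, direct versus complementary-strand
    editability calls for adenine (A-to-I(G)) and cytosine (C-to-U(T))
    deaminases, sequence-context analysis (ADAR 5' neighbour motif, NGG PAM
    discovery with editing windows, bystander enumeration with pluggable
    pathogenicity predictions), a local-alignment off-target search with
    identity and length thresholds, and a codon-improvement algorithm that
    finds the amino-acid substitution reachable by base editing which best
    improves a non-revertible missense or nonsense variant under BLOSUM62 or
    site-specific tolerance scores. Includes a deterministic synthetic-data
    generator with a ground-truth manifest for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
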