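Package: chimeraPep
Title: Chimeric Peptide Databases from Regular and Expanded Codons
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds theoretical databases of chimeric peptides translated
    from a circular (mito)genome partly according to regular tricodons and
    partly according to codons expanded by one or two silent nucleotides
    (tetra- and pentacodons). Sliding windows of 30 + 30 + 30 codons are
    translated under the vertebrate mitochondrial genetic code, stop codons
    are substituted by each of the 19 mass-distinguishable amino acids, and
    the resulting peptide pool is written as FASTA with provenance headers.
    Companion utilities cover in-silico protease cleavage with a missed
    cleavage budget, monoisotopic peptide masses with common modifications,
    reverse-decoy databases with simple target-decoy q-values, and an
    annotation pipeline that maps detected peptide sequences back to their
    chimeric templates, infers the tricodon/expanded-codon junction under a
    parsimony rule, applies a minimum-length chimera filter with expectation
    values, and maps regular-coded segments onto canonical mitochondrial
    proteins. Seeded generators for random genomes and planted detections
    make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Genetics, SequenceMatching
RoxygenNote: 7.3.3
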