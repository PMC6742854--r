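# Independent brute-force oracles and shared fixtures. These deliberately
# avoid the package's own code paths (and Biostrings where the package uses
# it) so the tests cross-check two routes to the same answer.

bruteRevcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
    collapse = "")
}

# wrap-aware subsequence on a strand, by string repetition
bruteFetch <- function(seq, strand, start, span) {
  s <- if (strand == "-") bruteRevcomp(seq) else seq
  reps <- strrep(s, ceiling((start + span) / nchar(s)))
  substr(reps, start + 1L, start + span)
}

# all digestion fragments by explicit cut-set enumeration
bruteDigest <- function(pep, residue, side, maxMissed) {
  n <- nchar(pep)
  aa <- strsplit(chartr("Ii", "Ll", toupper(pep)), "", fixed = TRUE)[[1L]]
  residue <- if (toupper(residue) == "I") "L" else toupper(residue)
  hit <- which(aa == residue)
  cuts <- if (side == "carboxyl") hit else hit - 1L
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  bounds <- c(0L, cuts, n)
  out <- NULL
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in i:(length(bounds) - 1L)) {
      if (j - i > maxMissed) next
      out <- rbind(out, data.frame(offset0 = bounds[i],
        length = bounds[j + 1L] - bounds[i], missed = j - i))
    }
  }
  out$fragment <- substring(pep, out$offset0 + 1L, out$offset0 + out$length)
  out[order(out$offset0, out$length), c("fragment", "offset0", "length", "missed")]
}

randomPeptide <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
    "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
  replace = TRUE), collapse = "")

# 30 tricodons + 30 expanded codons + 30 tricodons, all coding Met, with the
# silent tail making tricodon continuation diverge immediately (clean
# junctions on the + strand window at start 0)
chimeraFixtureGenome <- function(k, codon = "ATG") {
  CircularGenome(paste0(strrep(codon, 30L),
    strrep(paste0(codon, strrep("G", k)), 30L), strrep(codon, 30L)),
    id = "fixture")
}

mitoGeneTable <- function() {
  readGeneTable(system.file("extdata", "human_mito_cds.tsv",
    package = "chimeraPep"))
}
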