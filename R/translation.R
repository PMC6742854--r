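#' The 19 mass-distinguishable stop-substitution amino acids
#'
#' Leucine and isoleucine have identical monoisotopic masses and cannot be
#' distinguished by MS/MS, so the 20 standard amino acids collapse to 19
#' mass-distinguishable letters (I is merged into L). These are the letters
#' used to substitute translated stop codons.
#'
#' @return character(19) amino-acid letters, alphabetical.
#' @export
stopAlphabet <- function()
  c("A", "C", "D", "E", "F", "G", "H", "K", "L", "M",
    "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Fetch a genetic code table
#'
#' Thin wrapper over [Biostrings::getGeneticCode()]. The default is the
#' vertebrate mitochondrial code (NCBI table 2: AGA/AGG are stops, ATA is
#' Met, TGA is Trp), the code under which the human mitogenome is analysed.
#'
#' @param codeId NCBI genetic code identifier (default `"2"`).
#' @return named character(64): codon -> amino-acid letter, `*` for stops.
#' @export
geneticCode <- function(codeId = "2")
  Biostrings::getGeneticCode(codeId)

## split into codon-start groups; internal
.codonStarts <- function(n, step) seq.int(1L, n, by = step)

#' Translate a nucleotide string as regular tricodons
#'
#' One residue per 3 nucleotides. Stop codons yield `aa = "*"` with
#' `fromStop = TRUE`; the substituting amino acid is assigned later by
#' [substituteStops()].
#'
#' @param seq nucleotide string, length divisible by 3.
#' @param code genetic code table from [geneticCode()].
#' @return data.frame with columns `aa` (letter or `*`) and `fromStop`.
#' @examples
#' translateTricodons("ATGGCA")$aa  # "M" "A"
#' translateTricodons("AGA")$fromStop  # TRUE (mito code stop)
#' @export
translateTricodons <- function(seq, code = geneticCode()) {
  translateExpanded(seq, k = 0L, code = code)
}

#' Translate a nucleotide string as expanded codons
#'
#' Groups of `3 + k` nucleotides are each translated from their FIRST three
#' nucleotides; the trailing `k` nucleotides are silent. Equivalent to
#' deleting every 4th (k = 1), or every 4th and 5th (k = 2), nucleotide
#' after each nucleotide triplet and then translating regular tricodons.
#'
#' @param seq nucleotide string, length divisible by `3 + k`.
#' @param k expansion size: 1 (tetracodons) or 2 (pentacodons); 0 gives
#'   regular tricodon translation.
#' @param code genetic code table from [geneticCode()].
#' @return data.frame with columns `aa` and `fromStop`.
#' @examples
#' translateExpanded("ATGGTGAC", k = 1)$aa  # "M" "W" (TGA = Trp, mito code)
#' @export
translateExpanded <- function(seq, k = 1L, code = geneticCode()) {
  k <- as.integer(k)
  stopifnot(k %in% 0:2)
  seq <- toupper(chartr("U", "T", as.character(seq)))
  step <- 3L + k
  n <- nchar(seq)
  if (n == 0L || n %% step != 0L)
    stop(sprintf("sequence length %d is not a positive multiple of %d", n, step),
      call. = FALSE)
  starts <- .codonStarts(n, step)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(code[codons])
  if (anyNA(aa))
    stop("unknown codon '", codons[which(is.na(aa))[1L]], "'", call. = FALSE)
  data.frame(aa = aa, fromStop = aa == "*", stringsAsFactors = FALSE)
}

#' Delete the silent nucleotides after each transcribed triplet
#'
#' The delRNA transform: removes every 4th (k = 1), or every 4th and 5th
#' (k = 2), nucleotide after each nucleotide triplet, so that regular
#' tricodon translation of the result equals expanded-codon translation of
#' the input. Used as the translation oracle property.
#'
#' @param seq nucleotide string, length divisible by `3 + k`.
#' @param k 1 or 2.
#' @return nucleotide string of length `3 * length(seq) / (3 + k)`.
#' @export
deleteSilent <- function(seq, k = 1L) {
  k <- as.integer(k)
  stopifnot(k %in% 1:2)
  seq <- as.character(seq)
  n <- nchar(seq)
  if (n %% (3L + k) != 0L)
    stop(sprintf("sequence length %d is not a multiple of %d", n, 3L + k),
      call. = FALSE)
  keep <- rep(c(TRUE, TRUE, TRUE, rep(FALSE, k)), n / (3L + k))
  paste(strsplit(seq, "", fixed = TRUE)[[1L]][keep], collapse = "")
}

#' Substitute translated stops with one amino acid
#'
#' Every stop residue in a translated peptide is replaced by the SAME
#' amino acid, rendered lowercase to mark it as stop-translated (the
#' printed-table convention).
#'
#' @param residues data.frame from [translateTricodons()] /
#'   [translateExpanded()], or a peptide string with `*` at stops.
#' @param stopAa one letter from [stopAlphabet()].
#' @return character(1) peptide with stop positions lowercase.
#' @examples
#' substituteStops("M*K", "W")  # "MwK"
#' @export
substituteStops <- function(residues, stopAa) {
  stopifnot(length(stopAa) == 1L, stopAa %in% stopAlphabet())
  s <- if (is.data.frame(residues)) paste(residues$aa, collapse = "") else residues
  gsub("*", tolower(stopAa), s, fixed = TRUE)
}

#' Are two peptides mass-equivalent?
#'
#' TRUE iff the sequences are identical after mapping I to L in both;
#' case (the stop-translated flag) is ignored. Leucine and isoleucine are
#' isobaric, hence indistinguishable by MS.
#'
#' @param a,b amino-acid strings.
#' @return logical(1).
#' @examples
#' massEquivalent("MIL", "MLL")  # TRUE
#' @export
massEquivalent <- function(a, b) {
  collapseIL(toupper(a)) == collapseIL(toupper(b))
}

## I -> L in both cases; internal
collapseIL <- function(s) chartr("Ii", "Ll", s)
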