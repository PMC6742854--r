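#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   readBStringSet writeXStringSet reverseComplement getGeneticCode
#' @importFrom stats runif
#' @importFrom utils read.delim write.table
NULL

#' Circular genome
#'
#' A single nucleotide sequence over {A,C,G,T} with an identifier and a
#' circularity flag. When circular, index arithmetic is modulo the genome
#' length and subsequences may wrap around the origin. Coordinates are
#' 0-based half-open internally; user-facing reports are 1-based inclusive.
#'
#' @slot id character(1) sequence identifier.
#' @slot seq a [Biostrings::DNAString] over the unambiguous alphabet.
#' @slot circular logical(1); `TRUE` permits wraparound subsequences.
#'
#' @seealso [readGenome()], [fetchSubseq()], [enumerateWindows()]
#' @export
setClass("CircularGenome",
  representation(id = "character", seq = "DNAString", circular = "logical"))

setValidity("CircularGenome", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  bad <- gregexpr("[^ACGT]", as.character(object@seq))[[1L]]
  if (bad[1L] != -1L)
    msg <- c(msg, sprintf("sequence contains non-ACGT character at position %d", bad[1L]))
  if (length(object@seq) < 1L)
    msg <- c(msg, "sequence must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Theoretical chimeric peptide database
#'
#' The enumeration of sliding chimeric windows over a [CircularGenome],
#' translated into 90-residue template peptides (with defaults of 30 regular
#' tricodons, 30 codons expanded by `k` silent nucleotides, 30 regular
#' tricodons). Stop codons are carried as `*` in the stored templates;
#' stop-substitution variants are materialised on FASTA export and during
#' matching.
#'
#' @slot genomeId character(1) identifier of the source genome.
#' @slot genomeLength integer(1) genome length in basepairs.
#' @slot k integer(1) codon expansion (1 = tetracodons, 2 = pentacodons).
#' @slot segCodons integer(3) codon counts of the tricoded/expanded/tricoded
#'   segments (default 30,30,30).
#' @slot codeId character(1) NCBI genetic code identifier.
#' @slot templates data.frame with columns `strand` ("+"/"-"), `start0`
#'   (0-based offset on the strand's 5'->3' sequence), `peptide` (template
#'   string, `*` marking translated stops) and `nStops`.
#'
#' @seealso [buildChimeraDb()], [writeChimeraDb()], [matchTemplate()]
#' @export
setClass("ChimericPeptideDB",
  representation(genomeId = "character", genomeLength = "integer",
    k = "integer", segCodons = "integer", codeId = "character",
    templates = "data.frame"))

setValidity("ChimericPeptideDB", function(object) {
  msg <- character()
  if (!(object@k %in% c(1L, 2L)))
    msg <- c(msg, "'k' must be 1 or 2")
  if (length(object@segCodons) != 3L || any(object@segCodons < 1L))
    msg <- c(msg, "'segCodons' must be three positive codon counts")
  need <- c("strand", "start0", "peptide", "nStops")
  if (!all(need %in% names(object@templates)))
    msg <- c(msg, sprintf("'templates' must have columns %s",
      paste(need, collapse = ", ")))
  else {
    n <- sum(object@segCodons)
    if (nrow(object@templates) && any(nchar(object@templates$peptide) != n))
      msg <- c(msg, sprintf("all template peptides must have %d residues", n))
    if (!all(object@templates$strand %in% c("+", "-")))
      msg <- c(msg, "template strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})
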