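#' Construct a circular genome
#'
#' @param seq character(1) or [Biostrings::DNAString] nucleotide sequence.
#'   Lowercase is uppercased and U is mapped to T; any other non-ACGT
#'   character is an error naming the first offending 1-based position.
#' @param id character(1) sequence identifier.
#' @param circular logical(1); default `TRUE`.
#'
#' @return A [CircularGenome-class] object.
#' @examples
#' g <- CircularGenome("acgu", id = "toy")
#' as.character(genomeSeq(g))  # "ACGT"
#' @export
CircularGenome <- function(seq, id = "genome", circular = TRUE) {
  s <- toupper(as.character(seq))
  s <- chartr("U", "T", s)
  bad <- regexpr("[^ACGT]", s)
  if (bad != -1L)
    stop(sprintf("invalid nucleotide '%s' at position %d (only A/C/G/T/U accepted)",
      substr(s, bad, bad), bad), call. = FALSE)
  if (!nzchar(s)) stop("empty sequence", call. = FALSE)
  new("CircularGenome", id = id, seq = Biostrings::DNAString(s),
    circular = isTRUE(circular))
}

#' Read a genome from a FASTA file
#'
#' Reads a single-record FASTA file into a [CircularGenome-class]. If the
#' file holds several records the first is used with a warning. U is mapped
#' to T and lowercase is uppercased; ambiguity codes are rejected.
#'
#' @param path path to a FASTA file.
#' @param circular logical(1); treat the sequence as circular (default).
#' @return A [CircularGenome-class].
#' @export
readGenome <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ## read as raw bytes so U/lowercase survive to our own normalization
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("not a readable FASTA file: ", path,
      " (", conditionMessage(e), ")", call. = FALSE))
  if (length(ss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (length(ss) > 1L)
    warning("multiple FASTA records in ", path, "; using the first")
  id <- sub("\\s.*$", "", names(ss)[1L])
  CircularGenome(as.character(ss[[1L]]), id = id, circular = circular)
}

#' Write a genome to a FASTA file
#'
#' Writes the + strand sequence as a single FASTA record with 60-column
#' line wrapping.
#'
#' @param g a [CircularGenome-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(g, path) {
  ss <- Biostrings::DNAStringSet(g@seq)
  names(ss) <- g@id
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' @describeIn CircularGenome-class genome identifier.
#' @param g,object a `CircularGenome`.
#' @export
genomeId <- function(g) g@id

#' @describeIn CircularGenome-class genome length in basepairs.
#' @export
genomeLength <- function(g) length(g@seq)

#' @describeIn CircularGenome-class the + strand sequence as a `DNAString`.
#' @export
genomeSeq <- function(g) g@seq

#' @describeIn CircularGenome-class is the genome circular?
#' @export
isCircular <- function(g) g@circular

setMethod("show", "CircularGenome", function(object) {
  cat(sprintf("CircularGenome '%s': %d bp, %s\n", object@id,
    length(object@seq),
    if (object@circular) "circular" else "linear"))
})

#' @export
setMethod("length", "CircularGenome", function(x) length(x@seq))

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## strand sequence read 5'->3' ("-" = reverse complement of the + strand)
strandSeq <- function(g, strand = c("+", "-")) {
  strand <- match.arg(strand)
  s <- as.character(g@seq)
  if (strand == "-") revcomp(s) else s
}

#' Fetch a stranded, possibly wrapping subsequence
#'
#' Returns `span` nucleotides read 5'->3' on the requested strand starting
#' at 0-based offset `start` of that strand's own 5'->3' sequence (the -
#' strand sequence is the reverse complement of the + strand). On a circular
#' genome the subsequence wraps modulo the genome length; spans longer than
#' the genome repeat it.
#'
#' @param g a [CircularGenome-class].
#' @param strand `"+"` or `"-"`.
#' @param start 0-based offset on the strand, in `[0, L)`.
#' @param span number of nucleotides to return (>= 1).
#' @return character(1) nucleotide string of length `span`.
#' @examples
#' g <- CircularGenome("ACGT")
#' fetchSubseq(g, "+", 2, 4)  # "GTAC" (wraps)
#' fetchSubseq(g, "-", 0, 4)  # "ACGT" (revcomp of ACGT)
#' @export
fetchSubseq <- function(g, strand, start, span) {
  L <- genomeLength(g)
  start <- as.integer(start); span <- as.integer(span)
  if (span < 1L) stop("span must be >= 1", call. = FALSE)
  if (start < 0L || start >= L)
    stop(sprintf("start %d out of range [0, %d)", start, L), call. = FALSE)
  if (!g@circular && start + span > L)
    stop(sprintf("subsequence [%d, %d) exceeds linear genome of length %d",
      start, start + span, L), call. = FALSE)
  s <- strandSeq(g, strand)
  if (start + span <= L) return(substr(s, start + 1L, start + span))
  reps <- paste(rep(s, ceiling((start + span) / L)), collapse = "")
  substr(reps, start + 1L, start + span)
}

#' Convert a frame-translation amino-acid index to its codon locus
#'
#' Reading frames are numbered 1-6: frames 1-3 are the + strand at offsets
#' 0-2, frames 4-6 the - strand (reverse complement, read 5'->3') at offsets
#' 0-2, with offset = (frame - 1) mod 3. The amino acid at 1-based index
#' `aaIndex` of a frame's full-genome translation is encoded by the 3-nt
#' locus starting at strand offset `frameOffset + 3 * (aaIndex - 1)`,
#' modulo the genome length on a circular genome.
#'
#' @param strand `"+"` or `"-"`.
#' @param frameOffset 0, 1 or 2.
#' @param aaIndex 1-based amino-acid index within the frame translation.
#' @param gLength genome length in basepairs (for the modulo; use `NULL`
#'   to return the unreduced offset).
#' @return list with `strand`, `start0` (0-based strand offset of the codon),
#'   `start1`/`end1` (1-based inclusive nucleotide positions on the strand)
#'   and `span` (3).
#' @examples
#' frameTranslationLocus("+", 1, 5240, 16569)$start0  # 15718
#' @export
frameTranslationLocus <- function(strand, frameOffset, aaIndex, gLength = NULL) {
  stopifnot(frameOffset %in% 0:2, aaIndex >= 1)
  start0 <- frameOffset + 3 * (aaIndex - 1)
  if (!is.null(gLength)) start0 <- start0 %% gLength
  list(strand = strand, start0 = start0, start1 = start0 + 1,
    end1 = start0 + 3, span = 3L)
}

#' Map a frame number (1-6) to strand and offset
#'
#' @param frame integer in 1..6.
#' @return list with `strand` and `offset`.
#' @export
frameToStrand <- function(frame) {
  stopifnot(frame %in% 1:6)
  list(strand = if (frame <= 3) "+" else "-", offset = (frame - 1L) %% 3L)
}

#' Map strand and frame offset to a frame number (1-6)
#'
#' @param strand `"+"` or `"-"`.
#' @param offset 0, 1 or 2.
#' @return integer frame number.
#' @export
strandToFrame <- function(strand, offset) {
  stopifnot(strand %in% c("+", "-"), offset %in% 0:2)
  as.integer(offset + 1L + if (strand == "-") 3L else 0L)
}
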