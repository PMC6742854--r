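#' Nucleotide span of a chimeric window
#'
#' A chimeric window holds `n1` regular tricodons, `n2` codons expanded by
#' `k` silent nucleotides, and `n3` regular tricodons, hence
#' `3*n1 + (3+k)*n2 + 3*n3` nucleotides: 300 nt for tetracodons and 330 nt
#' for pentacodons at the default 30/30/30 segmentation.
#'
#' @param k expansion size, 1 or 2.
#' @param segCodons integer(3) codon counts per segment.
#' @return integer nucleotide span.
#' @examples
#' windowSpan(1)  # 300
#' windowSpan(2)  # 330
#' @export
windowSpan <- function(k, segCodons = c(30L, 30L, 30L)) {
  k <- as.integer(k)
  stopifnot(k %in% 1:2, length(segCodons) == 3L, all(segCodons >= 1L))
  as.integer(3L * segCodons[1L] + (3L + k) * segCodons[2L] + 3L * segCodons[3L])
}

## 0-based nt offset (relative to window start, on the strand) of each
## residue's codon; internal
.residueOffsets <- function(k, segCodons) {
  n1 <- segCodons[1L]; n2 <- segCodons[2L]; n3 <- segCodons[3L]
  c(3L * (seq_len(n1) - 1L),
    3L * n1 + (3L + k) * (seq_len(n2) - 1L),
    3L * n1 + (3L + k) * n2 + 3L * (seq_len(n3) - 1L))
}

## segment label per residue; internal
.residueSegments <- function(segCodons) {
  rep(c("tri5", "exp", "tri3"), segCodons)
}

#' Enumerate chimeric windows over a genome
#'
#' Windows advance by single-nucleotide steps along the complete genome on
#' both strands. On a circular genome every position starts a window, giving
#' exactly `2 * L` windows; on a linear genome only windows that fit, giving
#' `2 * (L - span + 1)`. Order is deterministic: + strand ascending start,
#' then - strand ascending start.
#'
#' @param g a [CircularGenome-class].
#' @param k expansion size, 1 or 2.
#' @param segCodons integer(3) codon counts per segment.
#' @return data.frame with columns `strand` and `start0` (0-based strand
#'   offset).
#' @examples
#' g <- CircularGenome(strrep("ACGT", 100))  # 400 bp
#' nrow(enumerateWindows(g, 1))  # 800
#' @export
enumerateWindows <- function(g, k, segCodons = c(30L, 30L, 30L)) {
  span <- windowSpan(k, segCodons)
  L <- genomeLength(g)
  if (isCircular(g)) {
    starts <- seq_len(L) - 1L
  } else {
    if (L < span)
      stop(sprintf("linear genome of %d bp is shorter than the %d nt window span",
        L, span), call. = FALSE)
    starts <- seq_len(L - span + 1L) - 1L
  }
  data.frame(strand = rep(c("+", "-"), each = length(starts)),
    start0 = rep(starts, 2L), stringsAsFactors = FALSE)
}

#' Translate one chimeric window
#'
#' Translates the window's two tricoded segments as regular tricodons and
#' its central segment as codons expanded by `k` silent nucleotides, under
#' the given genetic code. Stops are kept as `*` with `fromStop = TRUE`.
#'
#' @param g a [CircularGenome-class].
#' @param strand `"+"` or `"-"`.
#' @param start0 0-based window start on the strand.
#' @param k expansion size, 1 or 2.
#' @param segCodons integer(3) codon counts per segment.
#' @param code genetic code table from [geneticCode()].
#' @return A list of class `ChimericPeptide`: `strand`, `start0`, `k`,
#'   `segCodons`, `residues` (data.frame `aa`, `fromStop`, `segment`),
#'   `peptide` (template string with `*` at stops) and `stopPositions`
#'   (1-based residue indices).
#' @export
translateWindow <- function(g, strand, start0, k, segCodons = c(30L, 30L, 30L),
                            code = geneticCode()) {
  segCodons <- as.integer(segCodons)
  span <- windowSpan(k, segCodons)
  nt <- fetchSubseq(g, strand, start0, span)
  n1 <- segCodons[1L]; n2 <- segCodons[2L]; n3 <- segCodons[3L]
  r1 <- translateTricodons(substr(nt, 1L, 3L * n1), code)
  r2 <- translateExpanded(substr(nt, 3L * n1 + 1L, 3L * n1 + (3L + k) * n2),
    k, code)
  r3 <- translateTricodons(substr(nt, span - 3L * n3 + 1L, span), code)
  res <- rbind(r1, r2, r3)
  res$segment <- .residueSegments(segCodons)
  structure(list(strand = strand, start0 = as.integer(start0),
    k = as.integer(k), segCodons = segCodons, residues = res,
    peptide = paste(res$aa, collapse = ""),
    stopPositions = which(res$fromStop)),
    class = "ChimericPeptide")
}

#' Expand a chimeric peptide into its stop-substitution variants
#'
#' A peptide whose window contains stop codons is included once per
#' mass-distinguishable amino acid (19 variants, every stop in a variant
#' bearing the SAME letter, rendered lowercase). A stop-free peptide yields
#' a single unsubstituted record.
#'
#' @param p a `ChimericPeptide` from [translateWindow()], or a template
#'   string with `*` at stops.
#' @return data.frame with columns `stopAa` (letter or `NA`) and `peptide`.
#' @export
expandStopVariants <- function(p) {
  pep <- if (inherits(p, "ChimericPeptide")) p$peptide else as.character(p)
  if (!grepl("*", pep, fixed = TRUE))
    return(data.frame(stopAa = NA_character_, peptide = pep,
      stringsAsFactors = FALSE))
  letters19 <- stopAlphabet()
  data.frame(stopAa = letters19,
    peptide = vapply(letters19, function(l) substituteStops(pep, l), ""),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Nominal database size
#'
#' The nominal count of theoretical chimeric peptides for one expansion
#' type: `2 * L * nSubs` -- every single-nucleotide-step window on both
#' strands of a circular genome counted once per stop-substitution amino
#' acid, regardless of actual stop content. This is the normalization used
#' for expectation values. For the 16,569 bp human mitogenome and 19
#' substitutions this is 629,622.
#'
#' @param gLength genome length in basepairs.
#' @param nSubs number of stop-substitution letters (default 19).
#' @return numeric count.
#' @examples
#' nominalDbSize(16569)  # 629622
#' @export
nominalDbSize <- function(gLength, nSubs = 19L) {
  stopifnot(gLength >= 1)
  2 * as.numeric(gLength) * as.numeric(nSubs)
}

#' Build the theoretical chimeric peptide database
#'
#' Enumerates all chimeric windows of one expansion type over the genome
#' and translates them in bulk. Templates keep `*` at translated stops;
#' stop-substitution variants are materialised by [writeChimeraDb()] and
#' during matching.
#'
#' @param g a [CircularGenome-class].
#' @param k expansion size, 1 or 2.
#' @param segCodons integer(3) codon counts per segment.
#' @param codeId NCBI genetic code identifier (default `"2"`).
#' @return A [ChimericPeptideDB-class].
#' @examples
#' g <- randomGenome(400, seed = 1)
#' db <- buildChimeraDb(g, k = 1)
#' nrow(templates(db))  # 800
#' @export
buildChimeraDb <- function(g, k, segCodons = c(30L, 30L, 30L), codeId = "2") {
  segCodons <- as.integer(segCodons)
  k <- as.integer(k)
  code <- geneticCode(codeId)
  span <- windowSpan(k, segCodons)
  wins <- enumerateWindows(g, k, segCodons)
  L <- genomeLength(g)
  off <- .residueOffsets(k, segCodons)
  nres <- length(off)
  pieces <- lapply(c("+", "-"), function(strand) {
    s <- strandSeq(g, strand)
    ext <- if (isCircular(g))
      paste0(s, substr(strrep(s, ceiling(span / L) + 1L), 1L, span))
    else s
    ## aa of the tricodon starting at every 0-based offset p of ext
    p <- seq_len(nchar(ext) - 2L)
    aa <- unname(code[substring(ext, p, p + 2L)])
    starts <- wins$start0[wins$strand == strand]
    idx <- outer(starts, off, "+") + 1L          # rows = windows
    aaMat <- matrix(aa[idx], nrow = length(starts))
    peps <- do.call(paste0, lapply(seq_len(nres), function(j) aaMat[, j]))
    nStops <- as.integer(rowSums(aaMat == "*"))
    data.frame(strand = strand, start0 = starts, peptide = peps,
      nStops = nStops, stringsAsFactors = FALSE)
  })
  new("ChimericPeptideDB", genomeId = genomeId(g),
    genomeLength = as.integer(L), k = k, segCodons = segCodons,
    codeId = codeId, templates = do.call(rbind, pieces))
}

#' @describeIn ChimericPeptideDB-class the template table.
#' @param db a `ChimericPeptideDB`.
#' @export
templates <- function(db) db@templates

#' @describeIn ChimericPeptideDB-class the expansion size (1 or 2).
#' @export
expansionK <- function(db) db@k

#' @describeIn ChimericPeptideDB-class the segment codon counts.
#' @export
segmentCodons <- function(db) db@segCodons

setMethod("show", "ChimericPeptideDB", function(object) {
  cat(sprintf(paste0("ChimericPeptideDB: %d templates (k=%d, %s codons)",
      " over '%s' (%d bp)\n  %d templates contain translated stops\n"),
    nrow(object@templates), object@k,
    paste(object@segCodons, collapse = "/"), object@genomeId,
    object@genomeLength, sum(object@templates$nStops > 0L)))
})

## FASTA header for a database record; internal
.dbHeader <- function(genomeId, strand, start0, k, stopAa, segCodons, stopPos) {
  sp <- vapply(stopPos, function(x)
    if (length(x)) paste(x, collapse = ",") else "-", "")
  sprintf("%s|s=%s|p=%d|k=%d|stop=%s|seg=%s|sp=%s",
    genomeId, strand, start0 + 1L, k,
    ifelse(is.na(stopAa), "-", stopAa),
    paste(segCodons, collapse = ","), sp)
}

#' Write a chimeric peptide database as FASTA
#'
#' One record per stop-substitution variant: windows containing stops are
#' written 19 times (one per letter of [stopAlphabet()], stops lowercase);
#' stop-free windows once (or also 19 times identically when
#' `emitStopFreeOnce = FALSE`). Headers carry genome id, strand, 1-based
#' window start, k, stop letter (or `-`), segment codon counts and 1-based
#' stop residue positions. Record order follows the template order
#' (+ strand ascending start, then -), variants alphabetical within a
#' window, so repeated runs are byte-identical.
#'
#' @param db a [ChimericPeptideDB-class].
#' @param path output FASTA path.
#' @param dedupe collapse records with identical sequences into one record
#'   whose header concatenates the merged headers with `;`.
#' @param emitStopFreeOnce write stop-free windows once (default) rather
#'   than once per substitution letter.
#' @return integer: number of records written, invisibly.
#' @export
writeChimeraDb <- function(db, path, dedupe = FALSE, emitStopFreeOnce = TRUE) {
  tpl <- db@templates
  n <- nrow(tpl)
  letters19 <- stopAlphabet()
  nv <- length(letters19)
  hasStop <- tpl$nStops > 0L
  stopPos <- lapply(gregexpr("*", tpl$peptide, fixed = TRUE),
    function(x) if (x[1L] == -1L) integer() else as.integer(x))
  nvar <- ifelse(hasStop | !emitStopFreeOnce, nv, 1L)
  rowIdx <- rep.int(seq_len(n), nvar)
  within <- sequence(nvar)
  stopAa <- ifelse(hasStop[rowIdx], letters19[within],
    if (emitStopFreeOnce) NA_character_ else letters19[within])
  ## substituted sequences: one gsub pass per letter over the stop rows
  seqs <- tpl$peptide[rowIdx]
  if (any(hasStop)) {
    for (l in letters19) {
      sel <- !is.na(stopAa) & stopAa == l & hasStop[rowIdx]
      if (any(sel)) seqs[sel] <- gsub("*", tolower(l), seqs[sel], fixed = TRUE)
    }
  }
  headers <- .dbHeader(db@genomeId, tpl$strand[rowIdx], tpl$start0[rowIdx],
    db@k, stopAa, db@segCodons, stopPos[rowIdx])
  if (dedupe) {
    first <- !duplicated(seqs)
    merged <- vapply(split(headers, match(seqs, seqs[first])),
      paste, "", collapse = ";")
    headers <- merged[as.character(seq_len(sum(first)))]
    seqs <- seqs[first]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0(">", headers, "\n", seqs), con, sep = "\n")
  invisible(length(seqs))
}

#' Read a chimeric peptide database from FASTA
#'
#' Reconstructs a [ChimericPeptideDB-class] from a FASTA written by
#' [writeChimeraDb()] (without `dedupe`): lowercase stop-substituted
#' residues are restored to `*` template marks and the 19 variants of a
#' window collapse back to one template.
#'
#' @param path FASTA path.
#' @param genomeLength genome length in basepairs (recovered from the
#'   maximum start when omitted; supply it for linear or small genomes).
#' @return A [ChimericPeptideDB-class].
#' @export
readChimeraDb <- function(path, genomeLength = NULL) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0L) stop("no records in ", path, call. = FALSE)
  hdr <- names(ss)
  fld <- function(key) sub(sprintf(".*\\|%s=([^|]*).*", key), "\\1", hdr)
  genomeId <- sub("\\|.*$", "", hdr[1L])
  strand <- fld("s")
  start0 <- as.integer(fld("p")) - 1L
  k <- as.integer(fld("k")[1L])
  segCodons <- as.integer(strsplit(fld("seg")[1L], ",", fixed = TRUE)[[1L]])
  pep <- gsub("[a-z]", "*", as.character(ss))
  keep <- !duplicated(paste(strand, start0))
  tpl <- data.frame(strand = strand[keep], start0 = start0[keep],
    peptide = unname(pep[keep]),
    nStops = vapply(gregexpr("\\*", pep[keep]),
      function(x) if (x[1L] == -1L) 0L else length(x), 0L),
    stringsAsFactors = FALSE)
  if (is.null(genomeLength))
    genomeLength <- max(tpl$start0) + 1L
  new("ChimericPeptideDB", genomeId = genomeId,
    genomeLength = as.integer(genomeLength), k = k,
    segCodons = segCodons, codeId = "2", templates = tpl)
}

#' Count the FASTA records a database will produce
#'
#' The conservation invariant: records written equal the sum over windows
#' of 19 for stop-containing windows and 1 for stop-free windows (under the
#' emit-once policy), bounded above by [nominalDbSize()].
#'
#' @param db a [ChimericPeptideDB-class].
#' @param emitStopFreeOnce logical, as in [writeChimeraDb()].
#' @return numeric record count.
#' @export
expectedRecordCount <- function(db, emitStopFreeOnce = TRUE) {
  hasStop <- db@templates$nStops > 0L
  nv <- length(stopAlphabet())
  if (emitStopFreeOnce) sum(ifelse(hasStop, nv, 1L)) else nrow(db@templates) * nv
}
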