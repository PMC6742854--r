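#' Read detected peptides
#'
#' Accepts a TSV with at least a `sequence` column (optional `sample`,
#' `score`, `q`) or a bare text file with one peptide per line. Lowercase
#' letters mark claimed stop-translated residues.
#'
#' @param path input path.
#' @return data.frame with columns `sequence`, `sample`, `score`, `q`.
#' @export
readDetectedPeptides <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first) || grepl("^sequence\\b", first)) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"sequence" %in% names(d))
      stop("TSV must have a 'sequence' column", call. = FALSE)
  } else {
    d <- data.frame(sequence = readLines(path), stringsAsFactors = FALSE)
    d <- d[nzchar(d$sequence), , drop = FALSE]
  }
  for (col in c("sample", "score", "q"))
    if (!col %in% names(d)) d[[col]] <- NA
  d[, c("sequence", "sample", "score", "q")]
}

#' Read a canonical gene table
#'
#' A TSV with columns `gene`, `start`, `end`, `strand` (1-based inclusive
#' nucleotide coordinates on the + strand), or a GFF3 file whose CDS lines
#' are used (gene name taken from the `gene=`, `Name=` or `ID=` attribute).
#'
#' @param path input path.
#' @return data.frame with columns `gene`, `start`, `end`, `strand`.
#' @export
readGeneTable <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    f <- strsplit(ln, "\t", fixed = TRUE)
    f <- f[vapply(f, length, 0L) >= 9L]
    f <- f[vapply(f, function(x) x[3L] == "CDS", TRUE)]
    if (!length(f)) stop("no CDS lines in ", path, call. = FALSE)
    name <- vapply(f, function(x) {
      for (key in c("gene=", "Name=", "ID=")) {
        m <- regmatches(x[9L], regexpr(paste0(key, "[^;]+"), x[9L]))
        if (length(m)) return(sub(key, "", m, fixed = TRUE))
      }
      NA_character_
    }, "")
    tbl <- data.frame(gene = name,
      start = as.integer(vapply(f, `[`, "", 4L)),
      end = as.integer(vapply(f, `[`, "", 5L)),
      strand = vapply(f, `[`, "", 7L), stringsAsFactors = FALSE)
  } else {
    tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("gene", "start", "end", "strand")
  if (!all(need %in% names(tbl)))
    stop("gene table needs columns ", paste(need, collapse = ", "),
      call. = FALSE)
  stopifnot(all(tbl$start <= tbl$end), !anyDuplicated(tbl$gene),
    all(tbl$strand %in% c("+", "-")))
  tbl[, need]
}

## concatenated, I/L-collapsed template index for substring search; internal
.dbIndex <- function(db) {
  tpl <- db@templates
  list(big = paste(collapseIL(tpl$peptide), collapse = "#"),
    tlen = sum(db@segCodons), n = nrow(tpl))
}

#' Match a detected peptide against the template database
#'
#' Finds every template window in which the detected sequence occurs as a
#' contiguous substring under I/L collapse. Lowercase letters in the
#' detected sequence are claimed stop-translated residues: they align only
#' with template stop positions, and all lowercase letters of one peptide
#' must carry the same substitution letter (variants substitute every stop
#' with one amino acid). Uppercase letters never match stop positions.
#'
#' @param sequence detected amino-acid string.
#' @param db a [ChimericPeptideDB-class].
#' @param index optional precomputed index (internal use by [annotateAll()]).
#' @return data.frame with one row per hit: `templateRow`, `strand`,
#'   `start0`, `k`, `offset0` (0-based residue offset in the template),
#'   `stopAa` (substitution letter or `NA`) and `nStopsInSpan`; ordered by
#'   strand (+ first), start, stop letter.
#' @export
matchTemplate <- function(sequence, db, index = NULL) {
  empty <- data.frame(templateRow = integer(), strand = character(),
    start0 = integer(), k = integer(), offset0 = integer(),
    stopAa = character(), nStopsInSpan = integer(), stringsAsFactors = FALSE)
  sequence <- as.character(sequence)
  lowChars <- strsplit(gsub("[^a-z]", "", chartr("i", "l", sequence)),
    "", fixed = TRUE)[[1L]]
  low <- unique(toupper(lowChars))
  if (length(low) > 1L) return(empty)       # mixed substitution letters
  stopAa <- if (length(low)) low else NA_character_
  ## pattern: I -> L, claimed stops -> template stop mark
  pat <- collapseIL(sequence)
  pat <- gsub("[a-z]", "*", pat)
  if (is.null(index)) index <- .dbIndex(db)
  m <- gregexpr(pat, index$big, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  pos0 <- as.integer(m) - 1L
  tRow <- pos0 %/% (index$tlen + 1L) + 1L
  off <- pos0 %% (index$tlen + 1L)
  ok <- off + nchar(pat) <= index$tlen
  tRow <- tRow[ok]; off <- off[ok]
  if (!length(tRow)) return(empty)
  tpl <- db@templates[tRow, ]
  nSpan <- vapply(gregexpr("*", substring(tpl$peptide, off + 1L,
    off + nchar(pat)), fixed = TRUE),
    function(x) if (x[1L] == -1L) 0L else length(x), 0L)
  ## a peptide with no claimed stops must not sit on stop positions
  ## (guaranteed by the fixed match); with claimed stops the letter is fixed
  out <- data.frame(templateRow = tRow, strand = tpl$strand,
    start0 = tpl$start0, k = db@k, offset0 = off, stopAa = stopAa,
    nStopsInSpan = nSpan, stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$strand != "+", out$start0, out$offset0), , drop = FALSE]
}

## symbol (aa letter or "*") of the tricodon at strand offset p; internal
.triSymbolAt <- function(g, strand, p, code) {
  unname(code[fetchSubseq(g, strand, p %% genomeLength(g), 3L)])
}

## Lengths of the ambiguous runs at the two tricodon/expanded boundaries of
## a template window: expanded-segment residues reassignable to the
## tricoded side because continuing the tricodon reading frame over the
## genome reproduces the identical residues.
##
## At the tri5|exp boundary the first expanded codon's informative
## trinucleotide IS the tricodon continuation at the same position, so that
## comparison is vacuous; the run is decided by the comparisons that involve
## the silent nucleotides (tricodon j+1 of the continuation vs expanded
## residue j+1), and a junction whose first such comparison fails is clean
## (span 0). When every comparison holds the whole expanded segment is
## reassigned. The 5' extension takes precedence when the two runs would
## overlap.  internal
.ambiguousRuns <- function(db, templateRow, g, code = geneticCode(db@codeId)) {
  tpl <- db@templates[templateRow, ]
  segC <- db@segCodons
  n1 <- segC[1L]; n2 <- segC[2L]
  k <- db@k
  tSym <- strsplit(tpl$peptide, "", fixed = TRUE)[[1L]]
  base3 <- 3L * n1 + (3L + k) * n2
  c5 <- 0L                      # consecutive non-vacuous matches, j = 1, 2, ...
  while (c5 < n2 - 1L) {
    t <- n1 + c5 + 1L
    sym <- .triSymbolAt(g, tpl$strand, tpl$start0 + 3L * t, code)
    if (!identical(sym, tSym[t + 1L])) break
    c5 <- c5 + 1L
  }
  amb5 <- if (c5 == n2 - 1L) n2 else c5
  amb3 <- 0L
  while (amb3 < n2 - amb5) {
    t <- n1 + n2 - amb3 - 1L
    sym <- .triSymbolAt(g, tpl$strand,
      tpl$start0 + base3 + 3L * (t - n1 - n2), code)
    if (!identical(sym, tSym[t + 1L])) break
    amb3 <- amb3 + 1L
  }
  c(amb5 = amb5, amb3 = amb3)
}

#' Resolve the tricodon/expanded-codon junction of a matched peptide
#'
#' Labels the matched residues by template segment, then applies the
#' parsimony rule: starting at each tricoded/expanded boundary, the
#' tricoded label is extended residue-by-residue into the expanded segment
#' for as long as continuing the tricodon reading frame over the genome
#' reproduces the identical residue (the ambiguous run, assigned to the
#' tricoded side). Segment lengths, the junction side and the genomic locus
#' of the tricoded run are computed after this reassignment.
#'
#' @param sequence detected amino-acid string (lowercase = stop-translated).
#' @param db a [ChimericPeptideDB-class].
#' @param templateRow row index into `templates(db)`.
#' @param offset0 0-based residue offset of the match in the template.
#' @param g the source [CircularGenome-class].
#' @param stopAa substitution letter of the matched variant (or `NA`).
#' @param code genetic code table.
#' @return one-row data.frame: `strand`, `start0`, `k`, `offset0`,
#'   `triLen`, `expLen`, `ambiguousSpan`, `junctionSide`
#'   (`"5prime_noncanonical"`, `"3prime_noncanonical"` or `NA`),
#'   `junctionPos` (residues N-terminal of the junction, post-parsimony),
#'   `triStart0` (0-based strand offset of the tricoded run), `frame`
#'   (1-6), `posStart`/`posEnd` (1-based amino-acid range of the tricoded
#'   run in its frame translation), `stopAa`, `rendered` (peptide with `|`
#'   junction marks).
#' @export
resolveJunction <- function(sequence, db, templateRow, offset0, g,
                            stopAa = NA_character_, code = geneticCode(db@codeId)) {
  tpl <- db@templates[templateRow, ]
  segC <- db@segCodons
  n1 <- segC[1L]; n2 <- segC[2L]; n3 <- segC[3L]
  k <- db@k
  mlen <- nchar(sequence)
  base3 <- 3L * n1 + (3L + k) * n2
  amb <- .ambiguousRuns(db, templateRow, g, code)
  amb5 <- amb[["amb5"]]; amb3 <- amb[["amb3"]]
  ## post-parsimony labels over the template
  lab <- .residueSegments(segC)
  if (amb5 > 0L) lab[n1 + seq_len(amb5)] <- "amb5"
  if (amb3 > 0L) lab[n1 + n2 - amb3 + seq_len(amb3)] <- "amb3"
  tIdx <- offset0 + seq_len(mlen) - 1L          # 0-based template indices
  labM <- lab[tIdx + 1L]
  grp <- ifelse(labM == "exp", "E", "T")
  runs <- rle(grp)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L            # 1-based peptide positions
  rendered <- sequence
  if (length(runs$values) > 1L) {
    cutAt <- ends[-length(ends)]
    parts <- substring(sequence, c(1L, cutAt + 1L), c(cutAt, mlen))
    rendered <- paste(parts, collapse = "|")
  }
  expRuns <- which(runs$values == "E")
  ann <- data.frame(strand = tpl$strand, start0 = tpl$start0, k = k,
    offset0 = offset0, triLen = 0L, expLen = 0L, ambiguousSpan = 0L,
    junctionSide = NA_character_, junctionPos = NA_integer_,
    triStart0 = NA_integer_, frame = NA_integer_,
    posStart = NA_integer_, posEnd = NA_integer_, stopAa = stopAa,
    rendered = rendered, stringsAsFactors = FALSE)
  triLocus <- function(i) {    # strand locus of tri run i (frame of its head)
    t1 <- tIdx[starts[i]]
    fiveSide <- labM[starts[i]] %in% c("tri5", "amb5")
    rel <- if (fiveSide) 3L * t1 else base3 + 3L * (t1 - n1 - n2)
    s0 <- (tpl$start0 + rel) %% genomeLength(g)
    list(start0 = s0, fiveSide = fiveSide)
  }
  if (!length(expRuns)) {       # entirely tricoded after parsimony
    best <- which.max(runs$lengths)
    ann$triLen <- runs$lengths[best]
    loc <- triLocus(best)
    ann$triStart0 <- loc$start0
  } else {
    e <- expRuns[which.max(runs$lengths[expRuns])]
    leftLen <- if (e > 1L && runs$values[e - 1L] == "T") runs$lengths[e - 1L] else 0L
    rightLen <- if (e < length(runs$values) && runs$values[e + 1L] == "T")
      runs$lengths[e + 1L] else 0L
    ann$expLen <- runs$lengths[e]
    if (leftLen == 0L && rightLen == 0L) {      # match inside exp segment
      return(ann)
    }
    useLeft <- leftLen >= rightLen
    tr <- if (useLeft) e - 1L else e + 1L
    ann$triLen <- runs$lengths[tr]
    ann$junctionSide <- if (useLeft) "3prime_noncanonical" else "5prime_noncanonical"
    ann$junctionPos <- if (useLeft) starts[e] - 1L else ends[e]
    ann$ambiguousSpan <- sum(labM[starts[tr]:ends[tr]] %in% c("amb5", "amb3"))
    loc <- triLocus(tr)
    ann$triStart0 <- loc$start0
  }
  if (!is.na(ann$triStart0)) {
    offs <- ann$triStart0 %% 3L
    ann$frame <- strandToFrame(ann$strand, offs)
    ann$posStart <- ann$triStart0 %/% 3L + 1L
    ann$posEnd <- ann$posStart + ann$triLen - 1L
  }
  ann
}

#' Minimum-length chimera filter
#'
#' TRUE iff the annotation has at least `minLen` consecutive tricoded
#' residues AND at least `minLen` consecutive expanded-coded residues,
#' contiguous and adjacent across the junction.
#'
#' @param a annotation data.frame (rows from [resolveJunction()] /
#'   [annotateAll()]) or a list with `triLen` and `expLen`.
#' @param minLen minimum segment length in residues (default 8).
#' @return logical vector.
#' @export
passesFilter <- function(a, minLen = 8L) {
  a$triLen >= minLen & a$expLen >= minLen & !is.na(a$junctionSide)
}

#' Expectation value of the chimera filter
#'
#' The number of database entries times the chance of one segment of
#' `minLen` residues matching a random 19-letter peptide:
#' `dbSize * nSubs^(-minLen)`.
#'
#' @param dbSize database size (nominal count; see [nominalDbSize()]).
#' @param minLen segment length threshold.
#' @param nSubs alphabet size (default 19, L/I merged).
#' @return numeric expectation value.
#' @examples
#' chimeraEvalue(629622, 8)  # 3.707e-05
#' @export
chimeraEvalue <- function(dbSize, minLen, nSubs = 19) {
  stopifnot(dbSize >= 0, minLen >= 0)
  dbSize * nSubs^(-minLen)
}

#' Map a tricoded locus onto a canonical gene
#'
#' Pure coordinate arithmetic: a tricoded run of `triLen` residues starting
#' at 0-based strand offset `triStart0` maps into a gene when it lies
#' inside the gene's span on the same strand AND in the CDS reading frame.
#' Returns the 1-based residue range within the gene's protein.
#'
#' @param strand `"+"` or `"-"`.
#' @param triStart0 0-based strand offset of the first tricodon.
#' @param triLen number of tricoded residues.
#' @param genes gene table from [readGeneTable()].
#' @param gLength genome length in basepairs.
#' @return data.frame with columns `gene`, `residueStart`, `residueEnd`
#'   (zero rows when no gene matches).
#' @export
geneLocusHit <- function(strand, triStart0, triLen, genes, gLength) {
  none <- data.frame(gene = character(), residueStart = integer(),
    residueEnd = integer(), stringsAsFactors = FALSE)
  ntLen <- 3L * triLen
  if (triStart0 + ntLen > gLength) return(none)   # wrapped run: no gene hit
  if (strand == "+") {
    g1 <- triStart0 + 1L; g2 <- triStart0 + ntLen
    sel <- genes$strand == "+" & genes$start <= g1 & g2 <= genes$end &
      (g1 - genes$start) %% 3L == 0L
    rs <- (g1 - genes$start[sel]) %/% 3L + 1L
  } else {
    p2 <- gLength - triStart0                      # 1-based + strand end
    p1 <- gLength - (triStart0 + ntLen) + 1L
    sel <- genes$strand == "-" & genes$start <= p1 & p2 <= genes$end &
      (genes$end - p2) %% 3L == 0L
    rs <- (genes$end[sel] - p2) %/% 3L + 1L
  }
  if (!any(sel)) return(none)
  data.frame(gene = genes$gene[sel], residueStart = rs,
    residueEnd = rs + triLen - 1L, stringsAsFactors = FALSE)
}

#' Map a frame-translation position onto a canonical gene
#'
#' Converts a 1-based amino-acid range of a frame translation (frames 1-6,
#' the printed-table coordinate system) into the codon locus via
#' [frameTranslationLocus()] and maps it with [geneLocusHit()].
#'
#' @param frame frame number 1-6.
#' @param aaStart 1-based amino-acid index of the first residue.
#' @param aaLen number of residues.
#' @param genes gene table.
#' @param gLength genome length.
#' @return data.frame as [geneLocusHit()].
#' @examples
#' \dontrun{
#' genes <- readGeneTable(system.file("extdata", "human_mito_cds.tsv",
#'   package = "chimeraPep"))
#' frameLocusToGene(2, 5240, 9, genes, 16569)  # CytB, residues 325-333
#' }
#' @export
frameLocusToGene <- function(frame, aaStart, aaLen, genes, gLength) {
  fs <- frameToStrand(frame)
  loc <- frameTranslationLocus(fs$strand, fs$offset, aaStart, gLength)
  geneLocusHit(fs$strand, loc$start0, aaLen, genes, gLength)
}

#' Map an annotation's tricoded segment to a canonical protein
#'
#' Coordinate mapping via [geneLocusHit()]; when a genome is supplied the
#' hit is additionally verified by sequence concordance: the gene's CDS is
#' translated and compared residue-by-residue with the tricoded run of the
#' detected peptide under I/L collapse, stop-substituted (lowercase)
#' positions exempt. Discordant hits are dropped with a logged reason.
#'
#' @param a one-row annotation from [resolveJunction()].
#' @param genes gene table.
#' @param g optional [CircularGenome-class] for concordance checking.
#' @param triSeq the tricoded-run residues of the detected peptide
#'   (required for concordance checking).
#' @param code genetic code table.
#' @return data.frame with columns `gene`, `residueStart`, `residueEnd`.
#' @export
mapToGene <- function(a, genes, g = NULL, triSeq = NULL, code = geneticCode()) {
  gLength <- if (!is.null(g)) genomeLength(g) else attr(genes, "gLength")
  hits <- geneLocusHit(a$strand, a$triStart0, a$triLen, genes, gLength)
  if (!nrow(hits) || is.null(g) || is.null(triSeq)) return(hits)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    gr <- genes[genes$gene == hits$gene[i], ]
    cdsStart0 <- if (gr$strand == "+") gr$start - 1L else gLength - gr$end
    span <- gr$end - gr$start + 1L
    span <- span - span %% 3L
    cds <- fetchSubseq(g, gr$strand, cdsStart0, span)
    prot <- paste(translateTricodons(cds, code)$aa, collapse = "")
    ref <- substr(prot, hits$residueStart[i], hits$residueEnd[i])
    obs <- strsplit(triSeq, "", fixed = TRUE)[[1L]]
    refv <- strsplit(ref, "", fixed = TRUE)[[1L]]
    exempt <- obs %in% letters                 # stop-substituted positions
    same <- collapseIL(toupper(obs)) == collapseIL(refv)
    ok <- length(refv) == length(obs) && all(same | exempt)
    if (!ok)
      message("gene hit ", hits$gene[i], " dropped: sequence discordance")
    keep[i] <- ok
  }
  hits[keep, , drop = FALSE]
}

#' Annotate detected peptides against chimeric databases
#'
#' For every detected peptide: find all matching templates across the
#' supplied databases (typically one per expansion type), pick the best
#' template (fewest stop substitutions in the matched span, then + strand
#' before -, then ascending start, then ascending k), resolve the junction
#' with the parsimony rule, apply the minimum-length chimera filter,
#' attach the expectation value, and map the tricoded run onto canonical
#' genes when a gene table is given. Vendor score/q thresholds, when
#' supplied, are pass-through filters on the input columns.
#'
#' @param detected data.frame with column `sequence` (optional `sample`,
#'   `score`, `q`), e.g. from [readDetectedPeptides()].
#' @param dbs a [ChimericPeptideDB-class] or list of them.
#' @param g the source [CircularGenome-class].
#' @param genes optional gene table from [readGeneTable()].
#' @param minLen chimera filter threshold (default 8).
#' @param scoreMin,qMax optional vendor-score thresholds; peptides failing
#'   them are dropped before matching.
#' @return data.frame: one row per peptide (its best template), with
#'   matching, junction, filter, e-value and gene columns. Unmatched
#'   peptides keep a row with `matched = FALSE`.
#' @export
annotateAll <- function(detected, dbs, g, genes = NULL, minLen = 8L,
                        scoreMin = NULL, qMax = NULL) {
  if (is(dbs, "ChimericPeptideDB")) dbs <- list(dbs)
  if (!is.null(scoreMin) && "score" %in% names(detected))
    detected <- detected[is.na(detected$score) | detected$score > scoreMin, ]
  if (!is.null(qMax) && "q" %in% names(detected))
    detected <- detected[is.na(detected$q) | detected$q < qMax, ]
  idx <- lapply(dbs, .dbIndex)
  codes <- lapply(dbs, function(d) geneticCode(d@codeId))
  ev <- chimeraEvalue(nominalDbSize(genomeLength(g)), minLen)
  rows <- vector("list", nrow(detected))
  for (i in seq_len(nrow(detected))) {
    seqi <- detected$sequence[i]
    hits <- do.call(rbind, lapply(seq_along(dbs), function(j) {
      h <- matchTemplate(seqi, dbs[[j]], idx[[j]])
      if (nrow(h)) h$dbIdx <- j
      h
    }))
    base <- data.frame(sequence = seqi, sample = detected$sample[i],
      score = detected$score[i], q = detected$q[i],
      stringsAsFactors = FALSE)
    if (is.null(hits) || !nrow(hits)) {
      ann <- data.frame(matched = FALSE, multiK = FALSE,
        strand = NA_character_, start0 = NA_integer_, k = NA_integer_,
        offset0 = NA_integer_, triLen = NA_integer_, expLen = NA_integer_,
        ambiguousSpan = NA_integer_, junctionSide = NA_character_,
        junctionPos = NA_integer_, triStart0 = NA_integer_,
        frame = NA_integer_, posStart = NA_integer_, posEnd = NA_integer_,
        stopAa = NA_character_, rendered = NA_character_,
        passesFilter = FALSE, evalue = ev, gene = NA_character_,
        geneResidueStart = NA_integer_, geneResidueEnd = NA_integer_,
        stringsAsFactors = FALSE)
      rows[[i]] <- cbind(base, ann)
      next
    }
    hits <- hits[order(hits$nStopsInSpan, hits$strand != "+", hits$start0,
      hits$k, hits$offset0), , drop = FALSE]
    best <- hits[1L, ]
    j <- best$dbIdx
    ann <- resolveJunction(seqi, dbs[[j]], best$templateRow, best$offset0,
      g, best$stopAa, codes[[j]])
    ann$matched <- TRUE
    ann$multiK <- length(unique(hits$k)) > 1L
    ann$passesFilter <- passesFilter(ann, minLen)
    ann$evalue <- ev
    ann$gene <- NA_character_
    ann$geneResidueStart <- NA_integer_
    ann$geneResidueEnd <- NA_integer_
    if (!is.null(genes) && ann$passesFilter && !is.na(ann$triStart0)) {
      triSeq <- .triRunSeq(seqi, ann)
      gh <- mapToGene(ann, genes, g, triSeq, codes[[j]])
      if (nrow(gh)) {
        ann$gene <- gh$gene[1L]
        ann$geneResidueStart <- gh$residueStart[1L]
        ann$geneResidueEnd <- gh$residueEnd[1L]
      }
    }
    rows[[i]] <- cbind(base, ann[, c("matched", "multiK", "strand",
      "start0", "k", "offset0", "triLen", "expLen", "ambiguousSpan",
      "junctionSide", "junctionPos", "triStart0", "frame", "posStart",
      "posEnd", "stopAa", "rendered", "passesFilter", "evalue", "gene",
      "geneResidueStart", "geneResidueEnd")])
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sequence = character(), sample = character(),
      score = numeric(), q = numeric(), matched = logical(),
      multiK = logical(), strand = character(), start0 = integer(),
      k = integer(), offset0 = integer(), triLen = integer(),
      expLen = integer(), ambiguousSpan = integer(),
      junctionSide = character(), junctionPos = integer(),
      triStart0 = integer(), frame = integer(), posStart = integer(),
      posEnd = integer(), stopAa = character(), rendered = character(),
      passesFilter = logical(), evalue = numeric(), gene = character(),
      geneResidueStart = integer(), geneResidueEnd = integer(),
      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## residues of the annotated tricoded run within the detected peptide
.triRunSeq <- function(sequence, ann) {
  if (is.na(ann$junctionSide)) return(sequence)
  if (ann$junctionSide == "3prime_noncanonical")
    substr(sequence, ann$junctionPos - ann$triLen + 1L, ann$junctionPos)
  else
    substr(sequence, ann$junctionPos + 1L, ann$junctionPos + ann$triLen)
}
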