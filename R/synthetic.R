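## run expr under a local RNG state seeded with `seed`; restores the
## caller's global state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a random circular genome
#'
#' I.i.d. nucleotides at a given GC fraction (the 0.44 default approximates
#' the human mitogenome composition); deterministic per seed, leaving the
#' caller's random state untouched.
#'
#' @param L genome length in basepairs (>= 1).
#' @param seed integer seed.
#' @param gc GC fraction in `[0, 1]`.
#' @param id genome identifier.
#' @return A [CircularGenome-class].
#' @examples
#' identical(as.character(genomeSeq(randomGenome(50, 1))),
#'           as.character(genomeSeq(randomGenome(50, 1))))  # TRUE
#' @export
randomGenome <- function(L, seed, gc = 0.44, id = "synthetic") {
  stopifnot(L >= 1, gc >= 0, gc <= 1)
  nt <- .withSeed(seed, sample(c("A", "T", "G", "C"), L, replace = TRUE,
    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)))
  CircularGenome(paste(nt, collapse = ""), id = id)
}

#' Plant detectable chimeric fragments in a synthetic experiment
#'
#' Emulates a detected-peptide list: for each plant a chimeric window is
#' drawn from the database(s), a stop-substitution variant rendered, the
#' variant digested under the cleavage rule, and a fragment straddling a
#' tricodon/expanded junction with at least `minLen` residues on each side
#' selected (windows are resampled, up to `maxRetries`, when digestion
#' yields no such fragment). Random noise peptides over the 19-letter
#' alphabet are appended. A ground-truth table records every plant.
#'
#' @param g a [CircularGenome-class].
#' @param dbs list of [ChimericPeptideDB-class] to draw windows from
#'   (built from `g`); built on the fly for `kMix` when omitted.
#' @param nPlants number of planted fragments.
#' @param kMix numeric(2) proportions of k = 1 / k = 2 plants (sums to 1).
#' @param cleavage a [cleavageRule()] applied to the rendered variants.
#' @param minLen minimum residues on each side of the junction.
#' @param noisePeptides number of random decoy peptides to append.
#' @param seed integer seed.
#' @param maxRetries window resampling budget per plant.
#' @return list with `detected` (data.frame `sequence`, `sample`, `score`,
#'   `q`) and `truth` (data.frame per plant: `strand`, `start0`, `k`,
#'   `stopAa`, `fragOffset0` (residue offset in the template), `boundary`
#'   (template residue index of the junction) and `junctionInPeptide`
#'   (residues N-terminal of the planted junction)).
#' @export
plantDetections <- function(g, dbs = NULL, nPlants = 50L,
                            kMix = c(0.5, 0.5),
                            cleavage = cleavageRule("K", "carboxyl", 1L),
                            minLen = 8L, noisePeptides = 0L, seed = 1L,
                            maxRetries = 200L) {
  stopifnot(abs(sum(kMix) - 1) < 1e-9, nPlants >= 0, noisePeptides >= 0)
  if (is.null(dbs)) {
    ks <- which(kMix > 0)
    dbs <- lapply(ks, function(k) buildChimeraDb(g, k))
  }
  kOf <- vapply(dbs, expansionK, 0L)
  segC <- segmentCodons(dbs[[1L]])
  if (minLen > min(segC))
    stop("minLen exceeds the segment codon counts; no fragment can qualify",
      call. = FALSE)
  n1 <- segC[1L]; n2 <- segC[2L]
  .withSeed(seed, {
    det <- vector("list", nPlants)
    tru <- vector("list", nPlants)
    for (i in seq_len(nPlants)) {
      k <- sample(c(1L, 2L), 1L, prob = kMix)
      db <- dbs[[match(k, kOf)]]
      tpl <- templates(db)
      found <- FALSE
      code <- geneticCode(db@codeId)
      for (try in seq_len(maxRetries)) {
        r <- sample.int(nrow(tpl), 1L)
        pep <- tpl$peptide[r]
        stopAa <- NA_character_
        if (grepl("*", pep, fixed = TRUE)) {
          stopAa <- sample(stopAlphabet(), 1L)
          pep <- substituteStops(pep, stopAa)
        }
        ## parsimony-shifted boundaries: fragments must keep >= minLen
        ## residues on each side AFTER ambiguous runs move to the tri side
        amb <- .ambiguousRuns(db, r, g, code)
        b5 <- n1 + amb[["amb5"]]
        b3 <- n1 + n2 - amb[["amb3"]]
        frags <- digestPeptide(pep, cleavage)
        o <- frags$offset0; len <- frags$length
        ok5 <- (b5 - o) >= minLen & (o + len - b5) >= minLen &
          o + len <= b3                         # straddles tri5|exp only
        ok3 <- (b3 - o) >= minLen & (o + len - b3) >= minLen &
          o >= b5                               # straddles exp|tri3 only
        cand <- which(ok5 | ok3)
        if (!length(cand)) next
        pick <- cand[sample.int(length(cand), 1L)]
        b <- if (ok5[pick]) n1 else n1 + n2     # pre-parsimony boundary
        det[[i]] <- data.frame(sequence = frags$fragment[pick],
          sample = "plant", score = round(stats::runif(1, 2, 5), 2),
          q = 0, stringsAsFactors = FALSE)
        tru[[i]] <- data.frame(strand = tpl$strand[r],
          start0 = tpl$start0[r], k = k, stopAa = stopAa,
          fragOffset0 = frags$offset0[pick], boundary = b,
          junctionInPeptide = b - frags$offset0[pick],
          stringsAsFactors = FALSE)
        found <- TRUE
        break
      }
      if (!found)
        stop("no junction-straddling fragment found after ", maxRetries,
          " window draws; relax the cleavage rule or minLen", call. = FALSE)
    }
    detected <- do.call(rbind, det)
    truth <- do.call(rbind, tru)
    if (noisePeptides > 0L) {
      lens <- if (nPlants > 0L)
        sample(nchar(detected$sequence), noisePeptides, replace = TRUE)
      else rep(2L * minLen, noisePeptides)
      noise <- vapply(lens, function(n)
        paste(sample(stopAlphabet(), n, replace = TRUE), collapse = ""), "")
      detected <- rbind(detected, data.frame(sequence = noise,
        sample = "noise", score = round(stats::runif(noisePeptides, 2, 5), 2),
        q = 0, stringsAsFactors = FALSE))
    }
    if (is.null(detected))
      detected <- data.frame(sequence = character(), sample = character(),
        score = numeric(), q = numeric(), stringsAsFactors = FALSE)
    list(detected = detected, truth = truth)
  })
}
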