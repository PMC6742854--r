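test_that("template matching finds verbatim and I/L-collapsed substrings", {
  set.seed(41)
  g <- randomGenome(600, 17)
  db <- buildChimeraDb(g, 1)
  tpl <- templates(db)
  # a template with a stop-free 20-residue span at offset 25
  i <- which(!grepl("\\*", substr(tpl$peptide, 26, 45)))[1]
  expect_false(is.na(i))
  pep <- substr(tpl$peptide[i], 26, 45)
  hits <- matchTemplate(pep, db)
  expect_true(any(hits$templateRow == i & hits$offset0 == 25))
  # I where the template has L still matches
  pepIL <- chartr("L", "I", pep)
  hitsIL <- matchTemplate(pepIL, db)
  expect_true(any(hitsIL$templateRow == i & hitsIL$offset0 == 25))
  # hits are ordered + strand first, ascending start
  expect_false(is.unsorted(order(hits$strand != "+", hits$start0)))
})

test_that("template matching agrees with a brute-force scan", {
  set.seed(42)
  g <- randomGenome(150, 18)
  db <- buildChimeraDb(g, 1)
  tpl <- templates(db)
  collapsed <- chartr("I", "L", tpl$peptide)
  for (rep in 1:20) {
    pep <- randomPeptide(sample(c(4, 6, 20), 1))
    hits <- matchTemplate(pep, db)
    brute <- which(vapply(collapsed, function(t)
      grepl(chartr("I", "L", pep), t, fixed = TRUE), TRUE))
    expect_setequal(hits$templateRow, brute)
  }
})

test_that("lowercase letters match only stop positions with that letter", {
  set.seed(43)
  g <- randomGenome(600, 19)
  db <- buildChimeraDb(g, 1)
  tpl <- templates(db)
  i <- which(tpl$nStops >= 1)[1]
  v <- substituteStops(tpl$peptide[i], "W")
  sp <- as.integer(gregexpr("*", tpl$peptide[i], fixed = TRUE)[[1]])[1]
  lo <- max(1, sp - 8); hi <- min(90, sp + 8)
  frag <- substr(v, lo, hi)
  hits <- matchTemplate(frag, db)
  expect_true(any(hits$templateRow == i & hits$offset0 == lo - 1))
  expect_true(all(hits$stopAa == "W"))
  # the uppercase rendering must not align with the stop position
  fragUp <- toupper(frag)
  hitsUp <- matchTemplate(fragUp, db)
  expect_false(any(hitsUp$templateRow == i & hitsUp$offset0 == lo - 1))
  # mixed substitution letters cannot come from one variant
  fragMixed <- frag
  substr(fragMixed, sp - lo + 1, sp - lo + 1) <- "q"
  expect_equal(nrow(matchTemplate(paste0(fragMixed, "w"), db)), 0)
})

test_that("a disambiguating junction resolves with zero ambiguity", {
  g <- chimeraFixtureGenome(k = 1)
  db <- buildChimeraDb(g, 1)
  r <- which(templates(db)$strand == "+" & templates(db)$start0 == 0)
  # fragment covering template residues 21..50: 10 tricoded + 20 expanded
  frag <- substr(templates(db)$peptide[r], 21, 50)
  a <- resolveJunction(frag, db, r, 20L, g)
  expect_equal(a$ambiguousSpan, 0)
  expect_equal(a$junctionPos, 10)     # boundary at template position 30
  expect_equal(a$triLen, 10)
  expect_equal(a$expLen, 20)
  expect_identical(a$junctionSide, "3prime_noncanonical")
  expect_identical(a$rendered, paste0(strrep("M", 10), "|", strrep("M", 20)))
  expect_equal(a$triStart0, 60)       # codon of template residue 20
  expect_equal(a$frame, 1)            # offset 0 on the + strand
  expect_equal(a$posStart, 21)
})

test_that("a homopolymer genome collapses the expanded segment to tricoded", {
  g <- CircularGenome(strrep("A", 400))
  db <- buildChimeraDb(g, 1)
  frag <- strrep("K", 40)
  a <- resolveJunction(frag, db, 1, 20L, g)
  expect_equal(a$expLen, 0)
  expect_equal(a$triLen, 40)
  expect_false(passesFilter(a))
})

test_that("a match confined to one segment has no junction", {
  g <- chimeraFixtureGenome(k = 2)
  db <- buildChimeraDb(g, 2)
  r <- which(templates(db)$strand == "+" & templates(db)$start0 == 0)
  a <- resolveJunction(strrep("M", 12), db, r, 5L, g)   # inside tri5
  expect_equal(a$expLen, 0)
  expect_true(is.na(a$junctionSide))
  expect_false(passesFilter(a))
})

test_that("the chimera filter needs eight residues on both sides", {
  a <- data.frame(triLen = 8, expLen = 8, junctionSide = "3prime_noncanonical")
  expect_true(passesFilter(a))
  expect_false(passesFilter(data.frame(triLen = 30, expLen = 7,
    junctionSide = "3prime_noncanonical")))
  expect_false(passesFilter(data.frame(triLen = 7, expLen = 30,
    junctionSide = "5prime_noncanonical")))
  # monotone in the threshold
  counts <- vapply(6:10, function(m) sum(passesFilter(
    data.frame(triLen = c(8, 9, 30), expLen = c(8, 7, 30),
      junctionSide = "3prime_noncanonical"), m)), 0L)
  expect_false(is.unsorted(rev(counts)))
})

test_that("the expectation value implements the printed formula", {
  expect_equal(chimeraEvalue(629622, 8), 629622 / 19^8)
  expect_equal(chimeraEvalue(629622, 8), 3.707e-5, tolerance = 1e-3)
  expect_equal(chimeraEvalue(1000, 0), 1000)
  expect_equal(chimeraEvalue(0, 8), 0)
})

test_that("gene mapping on a toy gene table recovers residue indices", {
  # 60-nt gene at nt 10-69 (1-based, + strand) on a 200-nt genome
  genes <- data.frame(gene = "toy", start = 10, end = 69, strand = "+")
  # tricoded run covering codons 4-12: nt 19-45, strand offset 18
  h <- geneLocusHit("+", 18, 9, genes, 200)
  expect_identical(h$gene, "toy")
  expect_equal(c(h$residueStart, h$residueEnd), c(4, 12))
  # out of frame by one: rejected
  expect_equal(nrow(geneLocusHit("+", 19, 9, genes, 200)), 0)
  # wrong strand: rejected
  expect_equal(nrow(geneLocusHit("-", 18, 9, genes, 200)), 0)
  # round trip over every codon of the gene
  for (aa in 1:20) {
    loc <- frameTranslationLocus("+", (10 - 1) %% 3, (10 - 1) %/% 3 + aa, 200)
    h <- geneLocusHit("+", loc$start0, 1, genes, 200)
    expect_equal(h$residueStart, aa)
  }
})

test_that("minus-strand gene mapping measures frame from the gene end", {
  genes <- data.frame(gene = "rev", start = 11, end = 40, strand = "-")
  L <- 100
  # codon 1 of the minus-strand CDS: + nt 38-40 = - strand offset 60
  h <- geneLocusHit("-", L - 40, 1, genes, L)
  expect_equal(h$residueStart, 1)
  h3 <- geneLocusHit("-", L - 40 + 3, 2, genes, L)
  expect_equal(c(h3$residueStart, h3$residueEnd), c(2, 3))
  expect_equal(nrow(geneLocusHit("-", L - 40 + 1, 1, genes, L)), 0)
})

test_that("frame-translation positions map into the mitochondrial proteins", {
  genes <- mitoGeneTable()
  expect_equal(nrow(genes), 13)
  # frame 2, aa 5240-5248 -> CYTB residues 325-333
  h <- frameLocusToGene(2, 5240, 9, genes, 16569)
  expect_identical(h$gene, "CYTB")
  expect_equal(c(h$residueStart, h$residueEnd), c(325, 333))
  # frame 3, aa 1639-1658 -> ND2 residues 150-169
  h2 <- frameLocusToGene(3, 1639, 20, genes, 16569)
  expect_identical(h2$gene, "ND2")
  expect_equal(c(h2$residueStart, h2$residueEnd), c(150, 169))
})

test_that("sequence concordance vetoes coordinate-only gene hits", {
  set.seed(44)
  g <- randomGenome(300, 45)
  # a "gene" spanning nt 31-120 on the + strand, in frame with offset 30
  genes <- data.frame(gene = "syn", start = 31, end = 120, strand = "+")
  prot <- translateTricodons(fetchSubseq(g, "+", 30, 90))$aa
  a <- data.frame(strand = "+", triStart0 = 39, triLen = 8,
    junctionSide = "3prime_noncanonical", junctionPos = 8)
  triSeq <- paste(prot[4:11], collapse = "")
  h <- mapToGene(a, genes, g, triSeq)
  expect_equal(nrow(h), 1)
  expect_equal(h$residueStart, 4)
  # corrupt one residue: concordance check drops the hit
  bad <- triSeq
  substr(bad, 2, 2) <- if (substr(bad, 2, 2) == "G") "P" else "G"
  expect_message(h2 <- mapToGene(a, genes, g, bad), "discordance")
  expect_equal(nrow(h2), 0)
  # stop-substituted (lowercase) positions are exempt
  low <- triSeq
  substr(low, 2, 2) <- "w"
  expect_equal(nrow(mapToGene(a, genes, g, low)), 1)
})

test_that("annotateAll returns one row per peptide with correct bookkeeping", {
  set.seed(46)
  g <- randomGenome(1200, 47)
  dbs <- lapply(1:2, function(k) buildChimeraDb(g, k))
  empty <- annotateAll(data.frame(sequence = character(), sample = character(),
    score = numeric(), q = numeric()), dbs, g)
  expect_equal(nrow(empty), 0)
  sim <- plantDetections(g, dbs, nPlants = 12, noisePeptides = 6, seed = 8)
  anno <- annotateAll(sim$detected, dbs, g)
  expect_equal(nrow(anno), nrow(sim$detected))
  pl <- anno[anno$sample == "plant", ]
  expect_true(all(pl$matched))
  expect_true(all(pl$passesFilter))
  expect_true(all(anno$evalue == chimeraEvalue(nominalDbSize(1200), 8)))
  # planted window identity and junction recovered
  expect_true(all(pl$strand == sim$truth$strand &
    pl$start0 == sim$truth$start0 & pl$k == sim$truth$k))
  inferredPre <- ifelse(pl$junctionSide == "3prime_noncanonical",
    pl$junctionPos - pl$ambiguousSpan, pl$junctionPos + pl$ambiguousSpan)
  expect_equal(inferredPre, sim$truth$junctionInPeptide)
})

test_that("vendor thresholds act as pass-through filters", {
  set.seed(47)
  g <- randomGenome(800, 48)
  dbs <- list(buildChimeraDb(g, 1))
  sim <- plantDetections(g, dbs, nPlants = 6, kMix = c(1, 0), seed = 9)
  det <- sim$detected
  det$score <- c(3, 3, 3, 1.5, 1.5, 1.5)
  det$q <- c(0.01, 0.2, 0.01, 0.01, 0.2, 0.01)
  anno <- annotateAll(det, dbs, g, scoreMin = 1.99, qMax = 0.05)
  expect_equal(nrow(anno), 2)   # rows failing Xcorr or q are dropped
})

test_that("a peptide matching both expansion types is flagged multi-k", {
  # same codon repeated: windows of k=1 and k=2 translate identically
  g <- CircularGenome(strrep("A", 400))
  dbs <- lapply(1:2, function(k) buildChimeraDb(g, k))
  anno <- annotateAll(data.frame(sequence = strrep("K", 20),
    sample = NA, score = NA, q = NA), dbs, g)
  expect_true(anno$matched)
  expect_true(anno$multiK)
  expect_equal(anno$k, 1)       # ascending-k tie-break
})
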