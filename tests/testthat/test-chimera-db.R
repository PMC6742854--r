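test_that("window spans and counts follow the 30/30/30 design", {
  expect_identical(windowSpan(1), 300L)
  expect_identical(windowSpan(2), 330L)
  g <- CircularGenome(strrep("ACGT", 100))
  expect_equal(nrow(enumerateWindows(g, 1)), 800)
  expect_equal(nrow(enumerateWindows(g, 2)), 800)
  lin <- CircularGenome(randomDna(200), circular = FALSE)
  expect_error(enumerateWindows(lin, 1), "shorter")
})

test_that("a genome exactly one pentacodon window long wraps once per start", {
  set.seed(21)
  g <- CircularGenome(randomDna(330))
  w <- enumerateWindows(g, 2)
  expect_equal(nrow(w), 660)
  db <- buildChimeraDb(g, 2)
  # brute check: each window's residues equal direct translation of the
  # wrapped 330-nt subsequence under the segment structure
  for (i in sample(nrow(w), 10)) {
    nt <- bruteFetch(as.character(genomeSeq(g)), w$strand[i], w$start0[i], 330)
    exp <- paste(c(translateTricodons(substr(nt, 1, 90))$aa,
      translateExpanded(substr(nt, 91, 240), 2)$aa,
      translateTricodons(substr(nt, 241, 330))$aa), collapse = "")
    expect_identical(templates(db)$peptide[i], exp)
  }
})

test_that("a constructed all-Met window translates as expected", {
  g <- chimeraFixtureGenome(k = 1)
  p <- translateWindow(g, "+", 0, 1)
  expect_identical(p$peptide, strrep("M", 90))
  expect_length(p$stopPositions, 0)
  expect_identical(p$residues$segment, rep(c("tri5", "exp", "tri3"), each = 30))
  # replace the second tricodon with AGA (a mito-code stop)
  s <- as.character(genomeSeq(g))
  substr(s, 4, 6) <- "AGA"
  g2 <- CircularGenome(s)
  p2 <- translateWindow(g2, "+", 0, 1)
  expect_identical(p2$stopPositions, 2L)
  expect_identical(substr(p2$peptide, 2, 2), "*")
})

test_that("minus-strand windows translate the reverse complement", {
  set.seed(22)
  g <- CircularGenome(randomDna(500))
  db <- buildChimeraDb(g, 1)
  tpl <- templates(db)
  for (i in sample(which(tpl$strand == "-"), 8)) {
    nt <- bruteFetch(as.character(genomeSeq(g)), "-", tpl$start0[i], 300)
    exp <- paste(c(translateTricodons(substr(nt, 1, 90))$aa,
      translateExpanded(substr(nt, 91, 210), 1)$aa,
      translateTricodons(substr(nt, 211, 300))$aa), collapse = "")
    expect_identical(tpl$peptide[i], exp)
  }
})

test_that("bulk database translation matches per-window translation", {
  set.seed(23)
  g <- randomGenome(400, 99)
  for (k in 1:2) {
    db <- buildChimeraDb(g, k)
    tpl <- templates(db)
    expect_equal(nrow(tpl), 800)
    for (i in sample(nrow(tpl), 15)) {
      p <- translateWindow(g, tpl$strand[i], tpl$start0[i], k)
      expect_identical(tpl$peptide[i], p$peptide)
      expect_identical(tpl$nStops[i], length(p$stopPositions))
    }
  }
})

test_that("stop variants: 19 uniform substitutions, or a single record", {
  v <- expandStopVariants("MA*K*R")
  expect_equal(nrow(v), 19)
  expect_identical(v$stopAa, stopAlphabet())
  # all stops in one variant carry the same lowercase letter
  expect_identical(substr(v$peptide, 3, 3), tolower(v$stopAa))
  expect_identical(substr(v$peptide, 5, 5), tolower(v$stopAa))
  # variants identical away from stop positions
  expect_identical(unique(substr(v$peptide, 1, 2)), "MA")
  v0 <- expandStopVariants("MAKR")
  expect_equal(nrow(v0), 1)
  expect_true(is.na(v0$stopAa))
})

test_that("nominal database size reproduces the printed normalization", {
  expect_equal(nominalDbSize(16569, 19), 629622)
  expect_equal(nominalDbSize(1, 19), 38)
  expect_equal(nominalDbSize(100, 1), 200)
})

test_that("FASTA export obeys the conservation invariant and is deterministic", {
  g <- randomGenome(400, 3)
  db <- buildChimeraDb(g, 1)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  n1 <- writeChimeraDb(db, f1)
  n2 <- writeChimeraDb(db, f2)
  expect_identical(readLines(f1), readLines(f2))      # byte-identical
  tpl <- templates(db)
  expect_equal(n1, sum(ifelse(tpl$nStops > 0, 19, 1)))
  expect_equal(n1, expectedRecordCount(db))
  expect_lte(n1, nominalDbSize(genomeLength(g)))
  # header contract
  hdr <- grep("^>", readLines(f1), value = TRUE)
  expect_true(all(grepl("\\|s=[+-]\\|p=\\d+\\|k=1\\|stop=[A-Z-]\\|seg=30,30,30\\|sp=", hdr)))
  stopFree <- which(tpl$nStops == 0)
  if (length(stopFree)) {
    expect_equal(sum(grepl("\\|stop=-\\|", hdr)), length(stopFree))
  }
})

test_that("an emptied database writes a valid empty FASTA", {
  g <- randomGenome(400, 3)
  db <- buildChimeraDb(g, 1)
  db@templates <- db@templates[0, ]
  f <- withr::local_tempfile(fileext = ".fa")
  expect_equal(writeChimeraDb(db, f), 0)
  expect_identical(readLines(f), character(0))
})

test_that("dedupe collapses identical sequences and merges headers", {
  # poly-A: + strand windows all translate K^90, - strand (poly-T) all F^90
  g <- CircularGenome(strrep("A", 400))
  db <- buildChimeraDb(g, 1)
  f <- withr::local_tempfile(fileext = ".fa")
  n <- writeChimeraDb(db, f, dedupe = TRUE)
  expect_equal(n, 2)
  expect_true(grepl(";", readLines(f)[1]))
})

test_that("database of the reverse complement is the same peptide multiset", {
  set.seed(24)
  s <- randomDna(420)
  for (k in 1:2) {
    db1 <- buildChimeraDb(CircularGenome(s), k)
    db2 <- buildChimeraDb(CircularGenome(bruteRevcomp(s)), k)
    expect_identical(sort(templates(db1)$peptide), sort(templates(db2)$peptide))
  }
})

test_that("FASTA round trip reconstructs the template table", {
  g <- randomGenome(400, 5)
  db <- buildChimeraDb(g, 2)
  f <- withr::local_tempfile(fileext = ".fa")
  writeChimeraDb(db, f)
  db2 <- readChimeraDb(f, genomeLength = 400)
  expect_identical(templates(db2), templates(db))
  expect_identical(expansionK(db2), 2L)
  expect_identical(segmentCodons(db2), c(30L, 30L, 30L))
})
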