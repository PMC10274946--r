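## join classification, splitting, and overlap-window geometry

test_that("joined fragments within 10 bp classify as frameshift, beyond as other", {
  for (sep in 0:20) {
    cls <- classifyJoin(join_genome(sep), 1L)
    expected <- if (sep <= 10) "frameshift" else "other"
    expect_equal(cls$kind, expected, label = sprintf("separation %d", sep))
    if (sep <= 10) expect_equal(cls$separation, sep)
  }
  ## the documented annotation-error case: 72 bp apart is not a frameshift
  expect_equal(classifyJoin(join_genome(72L, L = 800L), 1L)$kind, "other")
})

test_that("join classification handles circular wraps, >2 fragments and strand flips", {
  sq <- random_dna(500)
  wrap <- GenomeRecord("c", sq, circular = TRUE, features = list(
    list(start = c(400L, 1L), end = c(500L, 90L), strand = 1L, product = "w")))
  expect_equal(classifyJoin(wrap, 1L)$kind, "circular_wrap")
  three <- GenomeRecord("t", sq, features = list(
    list(start = c(10L, 100L, 200L), end = c(90L, 180L, 290L), strand = 1L,
         product = "x")))
  expect_equal(classifyJoin(three, 1L)$kind, "other")
  ## invariant under strand complementation of the record
  for (sep in c(0L, 1L, 5L, 15L)) {
    expect_equal(classifyJoin(join_genome(sep), 1L)$kind,
                 classifyJoin(join_genome(sep, strand = -1L), 1L)$kind)
  }
  expect_error(classifyJoin(join_genome(0L), 99L))
})

test_that("splitting a frameshift join yields abutting 5'->3' fragments", {
  g <- join_genome(0L)
  fr <- splitJoined(g, 1L)
  expect_equal(nrow(fr), 2L)
  expect_false(any(fr$is_joined))
  expect_equal(IRanges::start(fr$locations[[1]]), 100L)
  expect_equal(IRanges::end(fr$locations[[1]]), 250L)
  expect_equal(IRanges::start(fr$locations[[2]]), 251L)
  ## union of spans equals the original compound location
  orig <- cdsFeatures(g)$locations[[1]]
  expect_equal(sort(c(IRanges::start(fr$locations[[1]]),
                      IRanges::start(fr$locations[[2]]))),
               sort(IRanges::start(orig)))
  ## non-frameshift join refuses to split
  expect_error(splitJoined(join_genome(15L), 1L), "frameshift")
  ## reverse-strand join: fragments stay in biological 5'->3' order
  gm <- join_genome(0L, strand = -1L)
  frm <- splitJoined(gm, 1L)
  expect_true(IRanges::start(frm$locations[[1]])[1] >
                IRanges::start(frm$locations[[2]])[1])
})

test_that("splitGenomeJoins records boundaries and directions", {
  fx <- makePRFGenome(21, prf = list(motif = "six", direction = -1L,
                                     N = 15L, sdSpacer = 6L, strand = 1L))
  sp <- splitGenomeJoins(fx$genome)
  expect_equal(nrow(sp$truth), 1L)
  expect_equal(sp$truth$direction, -1L)
  expect_equal(sp$truth$boundary, fx$truth$boundaryOriented)
  expect_equal(sum(cdsFeatures(sp$genome)$is_joined), 0L)
  expect_equal(nrow(cdsFeatures(sp$genome)),
               nrow(cdsFeatures(fx$genome)) + 1L)
})

test_that("opposite-strand neighbors produce no overlap region", {
  set.seed(31)
  sq <- random_dna(700)
  g <- pair_genome(sq, 100L, 300L, 305L, 500L, strandA = 1L, strandB = -1L)
  expect_equal(nrow(findOverlapRegions(g)), 0L)
})

test_that("the worked overlap layout yields a six-codon upstream stop offset", {
  ## geneA 10 codons (frame of position 1), geneB starts at the 10th codon
  ## (1-codon overlap, +1 frame); the nearest in-frame stop upstream of
  ## geneB's start is planted six codons away, everything else stop-free.
  base <- strsplit(random_dna(200, gc = 0.34), "")[[1]]
  startA <- 31L; endA <- 60L           # 10 codons incl. stop
  startB <- 59L                        # frame +1 relative to geneA
  ## clear both frames of stops in the relevant ranges
  sq0 <- paste(base, collapse = "")
  repeat {
    ok <- TRUE
    for (q in seq(startA, endA - 5L, 3)) {      # geneA coding, no stop
      if (substr(sq0, q, q + 2) %in% c("TAA", "TAG", "TGA")) {
        substr(sq0, q, q + 2) <- "GCA"; ok <- FALSE
      }
    }
    for (q in seq(startB - 15L, 140L, 3)) {     # geneB frame stop-free
      if (substr(sq0, q, q + 2) %in% c("TAA", "TAG", "TGA")) {
        substr(sq0, q, q + 2) <- "GCT"; ok <- FALSE
      }
    }
    if (ok) break
  }
  substr(sq0, endA - 2L, endA) <- "TGA"         # geneA stop
  substr(sq0, startB - 18L, startB - 16L) <- "TAA"  # six codons upstream
  substr(sq0, 140L, 142L) <- "TAA"              # geneB stop
  g <- pair_genome(sq0, startA, endA, startB, 142L)
  reg <- findOverlapRegions(g)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$upstreamStopOffset, 6L)
  expect_equal(reg$windowStart, startB - 15L)
  expect_equal(reg$windowEnd, endA)
  expect_equal(reg$direction, 1L)
})

test_that("window bounds match an exhaustive stop-scan oracle on random pairs", {
  stops <- c("TAA", "TAG", "TGA")
  hits <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    sq <- random_dna(600, gc = 0.55)
    startA <- 50L
    endA <- startA + 3L * sample(25:40, 1) - 1L
    off <- sample(c(7L, 8L, 10L, 11L), 1)
    startB <- endA - off
    g <- pair_genome(sq, startA, endA, startB, min(590L, startB + 120L))
    reg <- findOverlapRegions(g)
    ## oracle: scan every codon of geneB's frame for stops
    bstops <- Filter(function(q) substr(sq, q, q + 2) %in% stops,
                     seq(((startB - 1L) %% 3L) + 1L, startB - 3L, 3L))
    ws <- if (length(bstops)) max(unlist(bstops)) + 3L else ((startB - 1L) %% 3L) + 1L
    astops <- Filter(function(q) substr(sq, q, q + 2) %in% stops,
                     seq(startA + 3L * ceiling((endA - 2L - startA) / 3),
                         598L, 3L))
    dirOk <- (startB - startA) %% 3L != 0L
    if (!dirOk || !length(astops)) { expect_equal(nrow(reg), 0L); next }
    we <- min(unlist(astops)) + 2L
    if (ws > endA || we - ws < 2L) { expect_equal(nrow(reg), 0L); next }
    hits <- hits + 1L
    expect_equal(nrow(reg), 1L, label = sprintf("seed %d", seed))
    expect_equal(reg$windowStart, ws, label = sprintf("seed %d ws", seed))
    expect_equal(reg$windowEnd, we, label = sprintf("seed %d we", seed))
  }
  expect_gt(hits, 5L)  # the oracle actually exercised emitted regions
})
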