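test_that("the catalog has eight backward and two forward classes, ids 0-9", {
  cat <- motifCatalog()
  expect_equal(nrow(cat), 10L)
  expect_equal(sum(cat$direction == -1L), 8L)
  expect_equal(sum(cat$direction == 1L), 2L)
  expect_setequal(cat$id, 0:9)
  expect_true(all(vapply(cat$pattern, sum, 0L) %in% 3:7))
  ## forward classes are the single-run three and four
  expect_setequal(cat$name[cat$direction == 1L], c("three", "four"))
})

test_that("documented motif instances match their classes", {
  expect_equal(matchMotif("GGGGGAA")$name, "fivetwo")
  expect_equal(matchMotif("CCCGGAA")$name, "threetwotwo")
  expect_equal(matchMotif("AAAAAA")$name, "six")     # not threethree/five
  expect_equal(matchMotif("TTTAAA")$name, "threethree")
  expect_null(matchMotif("ACGACG"))
  ## maximal-run anchoring: a 7th identical base is surplus
  expect_equal(matchMotif("AAAAAAA")$name, "six")
  ## N blocks a required position
  expect_null(matchMotif("GGGNGAA"))
  ## direction filtering
  expect_equal(matchMotif("GGGG", directions = 1L)$name, "four")
  ## under maximal-run anchoring a 6-run still carries a forward "four"
  expect_equal(matchMotif("AAAAAA", directions = 1L)$name, "four")
  expect_null(matchMotif("GGG", directions = -1L))
})

test_that("matcher agrees with the regex oracle on random 7-mers", {
  set.seed(77)
  for (i in 1:2000) {
    w <- paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = "")
    got <- matchMotif(w)
    expect_identical(if (is.null(got)) NA_character_ else got$name,
                     regex_motif_oracle(w), label = w)
  }
})

test_that("region scanning finds a planted backward motif at the boundary", {
  fx <- makePRFGenome(42, prf = list(motif = "fivetwo", direction = -1L,
                                     N = 15L, sdSpacer = 6L, strand = 1L))
  sp <- splitGenomeJoins(fx$genome)
  regions <- findOverlapRegions(sp$genome)
  usage <- codonUsage(sp$genome)
  found <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
    scanRegion(regions[i, ], sp$genome, usage)))
  hit <- found[found$aSitePos == fx$truth$aSiteOriented, , drop = FALSE]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "fivetwo")
  expect_equal(hit$direction, -1L)
  ## every candidate's A-site is a geneA-frame codon boundary in its window
  for (i in seq_len(nrow(found))) {
    r <- regions[regions$geneA == found$geneA[i] &
                   regions$geneB == found$geneB[i], ]
    expect_true(found$aSitePos[i] >= r$windowStart &&
                  found$aSitePos[i] + 2 <= r$windowEnd)
    expect_equal((found$aSitePos[i] - r$startA) %% 3, 0)
  }
})

test_that("forward candidates always satisfy the A1 > A0 usage gate", {
  fx <- makePRFGenome(43, prf = list(motif = "three", direction = 1L,
                                     N = 15L, sdSpacer = 6L, strand = 1L))
  sp <- splitGenomeJoins(fx$genome)
  regions <- findOverlapRegions(sp$genome)
  usage <- codonUsage(sp$genome)
  seqc <- as.character(genomeSeq(sp$genome))
  any_fwd <- FALSE
  for (i in seq_len(nrow(regions))) {
    cc <- scanRegion(regions[i, ], sp$genome, usage)
    fwd <- cc[cc$direction == 1L & cc$strand == 1L, , drop = FALSE]
    for (j in seq_len(nrow(fwd))) {
      any_fwd <- TRUE
      p <- fwd$aSitePos[j]
      a0 <- substr(seqc, p, p + 2)
      a1 <- substr(seqc, p + 1, p + 3)
      expect_gt(usage[[a1]], usage[[a0]])
    }
  }
  expect_true(any_fwd)
})

test_that("labeling honors the 10 bp radius and direction match", {
  cands <- data.frame(geneA = 1L, geneB = 2L, strand = 1L,
                      aSitePos = c(100L, 103L, 111L, 92L),
                      motif = "threethree", motifId = 1L, direction = -1L)
  lab <- labelCandidates(cands, annotatedPos = 100L, annotatedDir = -1L)
  expect_equal(lab$label, c(-1L, -1L, 0L, -1L))   # 111 is 11 bp away
  lab2 <- labelCandidates(cands, annotatedPos = 100L, annotatedDir = 1L)
  expect_equal(lab2$label, rep(0L, 4))            # direction mismatch
  lab3 <- labelCandidates(cands)
  expect_equal(lab3$label, rep(0L, 4))            # no annotation
})
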