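test_that("codon usage counts every in-frame codon, stops included", {
  g <- GenomeRecord("u", "ATGAAATAA", features = list(
    list(start = 1L, end = 9L, strand = 1L, product = "one gene")))
  u <- codonUsage(g)
  expect_equal(length(u), 64L)
  expect_equal(unname(u[["ATG"]]), 1 / 3)
  expect_equal(unname(u[["AAA"]]), 1 / 3)
  expect_equal(unname(u[["TAA"]]), 1 / 3)
  expect_equal(sum(u), 1, tolerance = 1e-12)
  expect_error(codonUsage(GenomeRecord("e", "ACGTACGT")), "no CDS")
})

test_that("usage is strand-aware and joined genes count their fused frame", {
  ## same gene on the minus strand: reverse complement of ATGAAATAA
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAATAA")))
  gm <- GenomeRecord("m", rc, features = list(
    list(start = 1L, end = 9L, strand = -1L, product = "g")))
  um <- codonUsage(gm)
  expect_equal(unname(um[["ATG"]]), 1 / 3)
  expect_equal(unname(um[["AAA"]]), 1 / 3)
  ## joined feature: fragments concatenate before codon counting
  gj <- GenomeRecord("j", "ATGCCCTTTAAAGGGTAA", features = list(
    list(start = c(1L, 8L), end = c(7L, 18L), strand = 1L, product = "j")))
  uj <- codonUsage(gj)
  ## fused CDS = ATGCCCT + TTAAAGGGTAA -> ATG CCC TTT AAA GGG TAA
  expect_equal(unname(uj[["TTT"]]), 1 / 6)
  expect_equal(sum(uj > 0), 6L)
  ## usage sums to one on generated genomes
  for (s in 61:65) {
    fx <- makePRFGenome(s)
    expect_equal(sum(codonUsage(fx$genome)), 1, tolerance = 1e-12)
  }
})

test_that("feature vectors have the eleven columns within their ranges", {
  fx <- makePRFGenome(71, prf = list(motif = "twofive", direction = -1L,
                                     N = 21L, sdSpacer = 6L, strand = 1L))
  prep <- prepareGenome(fx$genome)
  f <- prep$features
  expect_true(all(featureColumns() %in% names(f)))
  expect_equal(length(featureColumns()), 11L)
  expect_true(all(f$DIR %in% c(-1, 1)))
  expect_true(all(f$RBS1 == round(f$RBS1) & f$RBS1 >= 0 & f$RBS1 <= 27))
  expect_true(all(f$RBS2 >= 0 & f$RBS2 <= 6.3))
  expect_true(all(f$MOTIF %in% 0:9))
  expect_true(all(f$A0 >= 0 & f$A0 <= 1))
  expect_true(all(f$A1 >= 0 & f$A1 <= 1))
  for (cc in c("LF50", "LF100", "HK50", "HK100")) {
    expect_true(all(f[[cc]] >= 0 & f[[cc]] <= 1))
  }
  expect_true(all(f$N >= 0))
})

test_that("N is the distance from the A-site codon to the in-frame stop", {
  ## hand-built: geneA frame anchored at 1; A-site at 10; +0 stop at 25,
  ## i.e. N = 15 (the stop-adjacent geometry of a polyprotein shift site)
  sq <- paste0("ATGCCCGCA", "TTTAAA", "GCA", "CCAGCAGCC", "TAA",
               random_dna(40, gc = 0.4))
  ## positions:    1-9        10-15   16-18  19-27      28-30
  g <- GenomeRecord("n", sq, features = list(
    list(start = 1L, end = 30L, strand = 1L, product = "x")))
  usage <- codonUsage(g)
  cand <- data.frame(geneA = 1L, geneB = 1L, strand = 1L, aSitePos = 16L,
                     motif = "threethree", motifId = 1L, direction = -1L)
  f <- featurize(cand, g, usage)
  expect_equal(f$N, 12)   # stop TAA at 28; 28 - 16 = 12
  ## move the A-site back one codon: N grows by 3
  cand$aSitePos <- 13L
  expect_equal(featurize(cand, g, usage)$N, 15)
})

test_that("A0/A1 pick the +0 and shifted A-site codons", {
  sq <- paste0(random_dna(30, 0.5), "TTTAAA", "CAG", random_dna(30, 0.5))
  g <- GenomeRecord("a", sq, features = list(
    list(start = 1L, end = 69L, strand = 1L, product = "x")))
  usage <- codonUsage(g)
  p <- 37L  # first base of CAG
  cand <- data.frame(geneA = 1L, geneB = 1L, strand = 1L, aSitePos = p,
                     motif = "threethree", motifId = 1L, direction = -1L)
  f <- featurize(cand, g, usage)
  expect_equal(f$A0, unname(usage[["CAG"]]))
  expect_equal(f$A1, unname(usage[["ACA"]]))  # -1 shift: codon at p-1
  cand$direction <- 1L
  f2 <- featurize(cand, g, usage)
  expect_equal(f2$A1, unname(usage[[substr(sq, p + 1, p + 3)]]))
})

test_that("featurization is deterministic and round-trips through TSV", {
  fx <- makePRFGenome(72, prf = list(motif = "six", direction = -1L,
                                     N = 15L, sdSpacer = 6L, strand = 1L))
  p1 <- prepareGenome(fx$genome)$features
  p2 <- prepareGenome(fx$genome)$features
  expect_identical(p1, p2)
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(p1, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(tf, stringsAsFactors = FALSE)
  expect_equal(back[, featureColumns()], p1[, featureColumns()],
               tolerance = 1e-10, ignore_attr = TRUE)
})
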