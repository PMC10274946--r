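## small labeled corpus reused across model tests (built once per run)
model_corpus <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      genomes <- list()
      truths <- list()
      cfg <- list(
        list(motif = "threethree", direction = -1L),
        list(motif = "fivetwo", direction = -1L),
        list(motif = "six", direction = -1L),
        list(motif = "three", direction = 1L),
        NULL, NULL
      )
      for (i in 1:12) {
        pr <- cfg[[(i - 1L) %% length(cfg) + 1L]]
        prf <- if (is.null(pr)) NULL else
          c(pr, list(N = 15L, sdSpacer = 6L, strand = 1L))
        fx <- makePRFGenome(3000 + i, prf = prf)
        genomes[[i]] <- fx$genome
        truths[[i]] <- fx$truth
      }
      preps <- lapply(genomes, prepareGenome)
      val <<- list(genomes = genomes, truths = truths, preps = preps,
                   features = do.call(rbind, lapply(preps, `[[`, "features")))
    }
    val
  }
})

test_that("training is deterministic and separates the planted signal", {
  cp <- model_corpus()
  f <- cp$features
  expect_gt(sum(f$label != 0), 5)
  m1 <- trainPRFModel(f)
  m2 <- trainPRFModel(f)
  p1 <- predictProb(m1, f)
  p2 <- predictProb(m2, f)
  expect_identical(p1, p2)          # byte-identical, early stopping off
  pred <- c(-1, 0, 1)[max.col(p1)]
  expect_gt(mean(pred == f$label), 0.95)
})

test_that("degenerate training inputs are refused with clear errors", {
  cp <- model_corpus()
  f <- cp$features
  expect_error(trainPRFModel(f, labels = rep(0L, nrow(f))), "two classes")
  bad <- f
  bad$LF50[3] <- NaN
  expect_error(trainPRFModel(bad), "row 3")
  expect_error(trainPRFModel(f, labels = rep(2L, nrow(f))), "labels")
  expect_error(trainPRFModel(f[, -which(names(f) == "N")]), "missing feature")
})

test_that("models persist and reload with their schema intact", {
  cp <- model_corpus()
  m <- trainPRFModel(cp$features)
  tf <- tempfile(fileext = ".rds")
  saveModel(m, tf)
  m2 <- loadModel(tf)
  expect_identical(predictProb(m, cp$features), predictProb(m2, cp$features))
  expect_identical(m2@featureNames, featureColumns())
  expect_equal(nrow(m2@motifTable), 10L)
  ## tampered schema refuses to load
  x <- readRDS(tf); x$featureNames <- rev(x$featureNames)
  saveRDS(x, tf)
  expect_error(loadModel(tf), "schema")
})

test_that("genome prediction applies the best-site rule per overlap", {
  cp <- model_corpus()
  m <- trainPRFModel(cp$features)
  found <- 0L
  for (i in seq_along(cp$genomes)) {
    calls <- predictGenome(cp$genomes[[i]], m)
    if (nrow(calls)) {  # at most one call per overlap
      expect_lte(max(table(paste(calls$geneA, calls$geneB))), 1L)
    }
    tt <- cp$truths[[i]]
    if (nrow(tt)) {
      hit <- any(abs(calls$aSitePos - tt$aSiteOriented) <= 10 &
                   calls$direction == tt$direction)
      found <- found + as.integer(hit)
    }
    ## reported score is the max over that overlap's qualifying candidates
    prep <- cp$preps[[i]]
    if (nrow(prep$features)) {
      probs <- predictProb(m, prep$features)
      sc <- pmax(probs[, "-1"], probs[, "1"])
      cls <- c(-1, 0, 1)[max.col(probs)]
      for (r in seq_len(nrow(calls))) {
        in_ov <- prep$features$geneA == calls$geneA[r] &
          prep$features$geneB == calls$geneB[r] & cls != 0
        expect_gte(calls$score[r], max(sc[in_ov]) - 1e-12)
      }
    }
  }
  expect_gte(found, 7L)  # 8 planted genomes in the corpus
  ## a genome with no overlap regions yields an empty call table
  bare <- GenomeRecord("bare", random_dna(300), features = list(
    list(start = 1L, end = 90L, strand = 1L, product = "only gene")))
  expect_equal(nrow(predictGenome(bare, m)), 0L)
})

test_that("leave-one-group-out bookkeeping double-enters the confusion", {
  cp <- model_corpus()
  groups <- rep(1:3, length.out = length(cp$genomes))
  v <- validateCorpus(cp$genomes, groups, preps = cp$preps, level = "G3")
  conf <- v$confusion
  ## independent recount from the merged calls and the truth tables
  TP2 <- FP2 <- FN2 <- 0L
  for (i in seq_along(cp$genomes)) {
    tt <- cp$preps[[i]]$truth
    gc <- v$calls[v$calls$genomeIdx == i, , drop = FALSE]
    used <- rep(FALSE, nrow(tt))
    for (r in seq_len(nrow(gc))) {
      j <- which(tt$geneA == gc$geneA[r] & tt$geneB == gc$geneB[r] &
                   abs(tt$boundary - gc$aSitePos[r]) <= 10)
      if (length(j)) { TP2 <- TP2 + 1L; used[j[1]] <- TRUE } else FP2 <- FP2 + 1L
    }
    FN2 <- FN2 + sum(!used)
  }
  expect_equal(unname(conf["TP"]), TP2)
  expect_equal(unname(conf["FP"]), FP2)
  expect_equal(unname(conf["FN"]), FN2)
  expect_equal(v$recall, TP2 / (TP2 + FN2))
  ## one group only -> no held-out training possible
  expect_error(validateCorpus(cp$genomes, rep(1L, length(cp$genomes)),
                              preps = cp$preps), "two groups")
})
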