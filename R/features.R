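## Assembly of the eleven-property feature vector for each candidate
## slippery site: DIR, RBS1, RBS2, MOTIF, A0, A1, LF50, LF100, HK50,
## HK100, N.

#' Feature column order
#' @return Character vector of the eleven feature column names.
#' @export
featureColumns <- function() {
  c("DIR", "RBS1", "RBS2", "MOTIF", "A0", "A1",
    "LF50", "LF100", "HK50", "HK100", "N")
}

#' Genome-wide codon usage
#'
#' Relative frequency of each of the 64 codons over all annotated coding
#' genes.  Joined features are counted over their fragment-concatenated
#' reading frame; reverse-strand genes over their coding-strand sequence.
#' Stop codons are counted as ordinary codons, so they appear as roughly
#' one-per-gene rare codons.  Codons containing N are ignored.
#'
#' @param genome A [GenomeRecord-class] with at least one CDS feature.
#' @return Named numeric vector of 64 relative frequencies summing to 1.
#' @export
codonUsage <- function(genome) {
  ft <- genome@features
  if (nrow(ft) == 0L) stop("genome has no CDS features")
  L <- length(genome@sequence)
  counts <- stats::setNames(rep(0, 64), .all_codons())
  total <- 0
  for (i in seq_len(nrow(ft))) {
    o <- .oriented_locs(ft$locations[[i]], ft$strand[i], L)
    seqc <- orientSeq(genome, ft$strand[i])
    cds <- paste(substring(seqc, o$start, o$end), collapse = "")
    nc <- nchar(cds) %/% 3L
    if (nc == 0L) next
    cods <- substring(cds, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
    cods <- cods[!grepl("N", cods, fixed = TRUE)]
    tb <- table(cods)
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
    total <- total + sum(tb)
  }
  if (total == 0) stop("no complete codons in any CDS")
  counts / total
}

.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  sort(as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0)))
}

#' Featurize candidate slippery sites
#'
#' Computes the eleven-property vector for each candidate of one genome:
#' DIR (shift direction), RBS1/RBS2 (Shine-Dalgarno scores at the P-site),
#' MOTIF (motif class id), A0/A1 (genome-wide usage of the +0 and shifted
#' A-site codons), LF50/LF100/HK50/HK100 (normalized downstream MFE at 50
#' and 100 bp under the two configured folding backends) and N (nt from the
#' A-site codon start to the first base of the +0 in-frame stop codon).
#'
#' @param candidates data.frame from [scanRegion()] (optionally with a
#'   `label` column, which is passed through).
#' @param genome The [GenomeRecord-class] the candidates came from.
#' @param usage Codon usage from [codonUsage()].
#' @param config A [prfConfig()] list.
#' @return data.frame with identifier columns (`genome`, `geneA`, `geneB`,
#'   `strand`, `aSitePos`, `motif`) then the eleven feature columns (and
#'   `label` if present).
#' @export
featurize <- function(candidates, genome, usage, config = prfConfig()) {
  n <- nrow(candidates)
  feats <- as.data.frame(matrix(NA_real_, n, length(featureColumns())))
  names(feats) <- featureColumns()
  seqs <- list(`1` = orientSeq(genome, 1L), `-1` = orientSeq(genome, -1L))
  for (i in seq_len(n)) {
    p <- candidates$aSitePos[i]
    dir <- candidates$direction[i]
    seqc <- seqs[[as.character(candidates$strand[i])]]
    a0 <- substr(seqc, p, p + 2L)
    a1 <- substr(seqc, p + dir, p + dir + 2L)
    ns <- .next_inframe_stop(seqc, p, p, maxScan = config$maxStopScan)
    feats$DIR[i] <- dir
    feats$RBS1[i] <- scoreRbsProdigal(seqc, p - 3L)
    feats$RBS2[i] <- scoreRbsRast(seqc, p - 3L)
    feats$MOTIF[i] <- candidates$motifId[i]
    feats$A0[i] <- if (a0 %in% names(usage)) usage[[a0]] else 0
    feats$A1[i] <- if (a1 %in% names(usage)) usage[[a1]] else 0
    feats$LF50[i] <- windowedMfe(seqc, p + 2L, config$windows[1],
                                 config$backendLF)
    feats$LF100[i] <- windowedMfe(seqc, p + 2L, config$windows[2],
                                  config$backendLF)
    feats$HK50[i] <- windowedMfe(seqc, p + 2L, config$windows[1],
                                 config$backendHK)
    feats$HK100[i] <- windowedMfe(seqc, p + 2L, config$windows[2],
                                  config$backendHK)
    feats$N[i] <- if (is.na(ns)) nchar(seqc) - p else ns - p
  }
  out <- cbind(
    data.frame(genome = rep(genome@name, n),
               geneA = candidates$geneA, geneB = candidates$geneB,
               strand = candidates$strand, aSitePos = candidates$aSitePos,
               motif = candidates$motif),
    feats
  )
  if (!is.null(candidates$label)) out$label <- candidates$label
  out
}

#' Pipeline configuration
#'
#' Bundles the tunable constants of the pipeline.  Defaults are the
#' method's stated values: 50/100 bp fold windows at offset 3, a 10 bp join
#' threshold and a 10 bp labeling radius.
#'
#' @param windows Fold window lengths (bp).
#' @param offset Offset from the motif to the fold window (the three A-site
#'   bases).
#' @param joinThreshold Maximum fragment separation for a frameshift join.
#' @param labelRadius Maximum distance from the annotated shift for a
#'   positive label.
#' @param backendLF,backendHK Folding backends for the hairpin-style and
#'   pseudoknot-style feature slots.
#' @param maxStopScan Maximum bases scanned for the +0 in-frame stop.
#' @return Named list of settings.
#' @export
prfConfig <- function(windows = c(50L, 100L), offset = 3L,
                      joinThreshold = 10L, labelRadius = 10L,
                      backendLF = "baseline_nested",
                      backendHK = "baseline_nested",
                      maxStopScan = 3000L) {
  list(windows = as.integer(windows), offset = as.integer(offset),
       joinThreshold = as.integer(joinThreshold),
       labelRadius = as.integer(labelRadius),
       backendLF = backendLF, backendHK = backendHK,
       maxStopScan = as.integer(maxStopScan))
}

#' Candidate generation + featurization for one genome
#'
#' The shared front half of training, validation and prediction: split
#' frameshift-class joins into pseudo gene pairs, find overlap regions,
#' scan them for motif candidates, label each candidate against the
#' annotated shifts (all 0 when none), and featurize.
#'
#' @param genome A [GenomeRecord-class] (joins still intact).
#' @param config A [prfConfig()] list.
#' @return List with `features` (labeled feature table), `regions`,
#'   `truth` (annotated shifts from split joins) and `genome` (the split
#'   genome).
#' @export
prepareGenome <- function(genome, config = prfConfig()) {
  sp <- splitGenomeJoins(genome, threshold = config$joinThreshold)
  regions <- findOverlapRegions(sp$genome, maxScan = config$maxStopScan)
  usage <- codonUsage(sp$genome)
  cands <- list()
  if (nrow(regions)) {
    for (i in seq_len(nrow(regions))) {
      cc <- scanRegion(regions[i, ], sp$genome, usage)
      if (!nrow(cc)) next
      ti <- which(sp$truth$geneA == regions$geneA[i] &
                  sp$truth$geneB == regions$geneB[i])
      if (length(ti)) {
        cc <- labelCandidates(cc, sp$truth$boundary[ti[1]],
                              sp$truth$direction[ti[1]],
                              radius = config$labelRadius)
      } else {
        cc <- labelCandidates(cc)
      }
      cands[[length(cands) + 1L]] <- cc
    }
  }
  feats <- if (length(cands)) {
    featurize(do.call(rbind, cands), sp$genome, usage, config)
  } else {
    cbind(data.frame(genome = character(), geneA = integer(),
                     geneB = integer(), strand = integer(),
                     aSitePos = integer(), motif = character()),
          stats::setNames(as.data.frame(
            matrix(numeric(), 0, length(featureColumns()))),
            featureColumns()),
          data.frame(label = integer()))
  }
  list(features = feats, regions = regions, truth = sp$truth,
       genome = sp$genome)
}
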