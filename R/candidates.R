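## Join classification, joined-gene splitting, and the search for
## codon-bounded overlap windows between consecutive same-strand genes.
##
## All computation on a gene pair happens in "oriented space": the coding
## strand read 5'->3'.  For plus-strand pairs oriented coordinates equal
## genome coordinates; for minus-strand pairs position g maps to
## L - g + 1 on the reverse complement.

STOP_CODONS <- c("TAA", "TAG", "TGA")

## oriented (coding-strand, 5'->3') sequence for a strand
orientSeq <- function(genome, strand) {
  if (strand == 1L) as.character(genome@sequence)
  else as.character(Biostrings::reverseComplement(genome@sequence))
}

## map genome coordinate(s) to oriented space (an involution)
orientPos <- function(pos, strand, genomeLength) {
  if (strand == 1L) pos else genomeLength - pos + 1L
}

## oriented [start, end] of the i-th location of a feature
.oriented_locs <- function(feature_ranges, strand, L) {
  st <- IRanges::start(feature_ranges)
  en <- IRanges::end(feature_ranges)
  if (strand == 1L) {
    data.frame(start = st, end = en)
  } else {
    ## biological order is already 5'->3' (descending genome start)
    data.frame(start = L - en + 1L, end = L - st + 1L)
  }
}

#' Classify a joined CDS feature
#'
#' Decides whether a compound (`join`) CDS location is the annotation
#' signature of a ribosomal frameshift, a gene wrapping the origin of a
#' circular genome, or something else (intein, intron, annotation error).
#' A frameshift requires exactly two fragments whose separation along the
#' coding strand is at most `threshold` bases (default 10); fragments
#' abutting the two ends of a circular molecule are a circular wrap;
#' everything else is "other".
#'
#' @param genome A [GenomeRecord-class].
#' @param featureIdx Index of a joined feature in `cdsFeatures(genome)`.
#' @param threshold Maximum fragment separation (bp) for a frameshift.
#' @param nFragments Required fragment count for a frameshift.
#' @return A list with elements `kind` (one of `"frameshift"`,
#'   `"circular_wrap"`, `"other"`), `separation` (signed bp between fragment
#'   1 end and fragment 2 start along the coding strand; `NA` unless two
#'   fragments) and `direction` (+1/-1 implied by the frame geometry of the
#'   two fragments, `NA` if not a frameshift).
#' @export
classifyJoin <- function(genome, featureIdx, threshold = 10L, nFragments = 2L) {
  ft <- genome@features
  stopifnot(featureIdx >= 1L, featureIdx <= nrow(ft))
  if (!ft$is_joined[featureIdx]) stop("feature is not joined")
  L <- length(genome@sequence)
  r <- ft$locations[[featureIdx]]
  strand <- ft$strand[featureIdx]
  nf <- length(r)

  ## circular wrap: fragments abut opposite genome ends of a circular record
  st <- IRanges::start(r); en <- IRanges::end(r)
  if (genome@circular && nf == 2L && any(en == L) && any(st == 1L)) {
    return(list(kind = "circular_wrap", separation = NA_integer_,
                direction = NA_integer_))
  }
  if (nf != nFragments) {
    return(list(kind = "other", separation = NA_integer_,
                direction = NA_integer_))
  }
  o <- .oriented_locs(r, strand, L)
  sep <- o$start[2] - o$end[1] - 1L
  dir <- .frame_direction(o$start[1], o$start[2])
  if (abs(sep) <= threshold && !is.na(dir)) {
    list(kind = "frameshift", separation = sep, direction = dir)
  } else {
    list(kind = "other", separation = sep, direction = NA_integer_)
  }
}

## shift direction implied by the reading frames of two 5' ends
## (oriented coordinates): frame(B) - frame(A) == 2 (mod 3) -> -1 backward,
## == 1 -> +1 forward, == 0 -> not a frameshift.
.frame_direction <- function(startA, startB) {
  d <- (startB - startA) %% 3L
  if (d == 1L) 1L else if (d == 2L) -1L else NA_integer_
}

#' Split a joined frameshift gene into its two fragments
#'
#' Replaces the compound location with two single-location, non-joined CDS
#' features in biological 5'->3' order.  The union of the fragment spans
#' equals the original compound location.
#'
#' @inheritParams classifyJoin
#' @return A `DataFrame` of two feature rows (same columns as
#'   `cdsFeatures()`).
#' @export
splitJoined <- function(genome, featureIdx, threshold = 10L) {
  cls <- classifyJoin(genome, featureIdx, threshold = threshold)
  if (cls$kind != "frameshift") {
    stop("splitJoined() requires a frameshift-class join, got '", cls$kind, "'")
  }
  ft <- genome@features[featureIdx, ]
  r <- ft$locations[[1]]
  S4Vectors::DataFrame(
    locations = IRanges::IRangesList(r[1], r[2]),
    strand = rep(ft$strand, 2L),
    product = rep(ft$product, 2L),
    is_joined = c(FALSE, FALSE)
  )
}

#' Split every frameshift-class join in a genome
#'
#' Builds the "pseudo gene pair" view used for training: every joined CDS
#' classified as a frameshift is replaced by its two fragments, and a truth
#' table records where each annotated shift occurs.
#'
#' @inheritParams classifyJoin
#' @return A list with `genome` (new [GenomeRecord-class]) and `truth`, a
#'   data.frame with one row per split join: `geneA`/`geneB` (feature
#'   indices in the new genome), `strand`, `direction`, `boundary` (oriented
#'   position of the last base of fragment 1 — where the shift is annotated
#'   to occur), and `separation`.
#' @export
splitGenomeJoins <- function(genome, threshold = 10L) {
  ft <- genome@features
  L <- length(genome@sequence)
  out <- S4Vectors::DataFrame(
    locations = IRanges::IRangesList(), strand = integer(),
    product = character(), is_joined = logical()
  )
  truth <- list()
  for (i in seq_len(nrow(ft))) {
    if (ft$is_joined[i]) {
      cls <- classifyJoin(genome, i, threshold = threshold)
      if (cls$kind == "frameshift") {
        frags <- splitJoined(genome, i, threshold = threshold)
        o <- .oriented_locs(ft$locations[[i]], ft$strand[i], L)
        truth[[length(truth) + 1L]] <- data.frame(
          geneA = nrow(out) + 1L, geneB = nrow(out) + 2L,
          strand = ft$strand[i], direction = cls$direction,
          boundary = o$end[1], separation = cls$separation,
          product = ft$product[i]
        )
        out <- rbind(out, frags)
        next
      }
    }
    out <- rbind(out, ft[i, ])
  }
  g2 <- new("GenomeRecord", name = genome@name, sequence = genome@sequence,
            circular = genome@circular, features = out)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(geneA = integer(), geneB = integer(), strand = integer(),
               direction = integer(), boundary = integer(),
               separation = integer(), product = character())
  list(genome = g2, truth = truth)
}

## first in-frame stop codon at an oriented codon boundary >= from,
## scanning boundaries congruent to `frameAnchor` (a codon-start position);
## returns the stop codon start or NA
.next_inframe_stop <- function(seqc, frameAnchor, from, maxScan = 3000L) {
  L <- nchar(seqc)
  q <- frameAnchor + 3L * ceiling((from - frameAnchor) / 3)
  lim <- min(L - 2L, from + maxScan)
  while (q <= lim) {
    if (substr(seqc, q, q + 2L) %in% STOP_CODONS) return(q)
    q <- q + 3L
  }
  NA_integer_
}

## nearest in-frame stop strictly 5' of `before` on boundaries of
## `frameAnchor`'s frame; returns stop start or NA
.prev_inframe_stop <- function(seqc, frameAnchor, before) {
  q <- frameAnchor + 3L * floor((before - 3L - frameAnchor) / 3)
  while (q >= 1L) {
    if (substr(seqc, q, q + 2L) %in% STOP_CODONS) return(q)
    q <- q - 3L
  }
  NA_integer_
}

#' Find candidate frameshift overlap regions
#'
#' Evaluates consecutive same-strand gene pairs and emits, for each pair in
#' different reading frames, the codon-bounded window in which a frameshift
#' could fuse them: bounded on the 5' side by the first base after the
#' nearest stop codon upstream of geneB in geneB's frame, and on the 3' side
#' by the last base of the first in-frame stop at/after geneA's end in
#' geneA's frame (geneA's own stop codon for a complete gene).  Pairs on
#' opposite strands, in the same frame, or whose stop-free window does not
#' reach into geneA produce nothing.  Genes wholly contained in another gene
#' are skipped; intervening opposite-strand genes do not break adjacency.
#'
#' @param genome A [GenomeRecord-class] whose frameshift joins have been
#'   split (see [splitGenomeJoins()]); remaining multi-location features are
#'   ignored.
#' @param maxScan Maximum bases to scan past geneA's end for the +0 stop.
#' @return A data.frame with one row per overlap region: feature indices
#'   `geneA`, `geneB`, `strand`, oriented coordinates `startA`, `endA`,
#'   `startB`, `endB`, `windowStart`, `windowEnd`, the shift `direction`
#'   implied by the frame geometry, and `upstreamStopOffset` (codons from
#'   geneB's start back to the nearest in-frame stop in geneB's frame).
#' @export
findOverlapRegions <- function(genome, maxScan = 3000L) {
  ft <- genome@features
  L <- length(genome@sequence)
  empty <- data.frame(
    geneA = integer(), geneB = integer(), strand = integer(),
    startA = integer(), endA = integer(), startB = integer(),
    endB = integer(), windowStart = integer(), windowEnd = integer(),
    direction = integer(), upstreamStopOffset = integer()
  )
  if (nrow(ft) < 2L) return(empty)
  rows <- list()
  for (strand in c(1L, -1L)) {
    idx <- which(ft$strand == strand & !ft$is_joined)
    if (length(idx) < 2L) next
    seqc <- orientSeq(genome, strand)
    st <- vapply(idx, function(i) {
      o <- .oriented_locs(ft$locations[[i]], strand, L); o$start[1]
    }, 1L)
    en <- vapply(idx, function(i) {
      o <- .oriented_locs(ft$locations[[i]], strand, L); o$end[1]
    }, 1L)
    o <- order(st, en)
    idx <- idx[o]; st <- st[o]; en <- en[o]
    ## drop genes wholly contained in an earlier gene
    keep <- rep(TRUE, length(idx))
    maxEnd <- -Inf
    for (i in seq_along(idx)) {
      if (en[i] <= maxEnd) keep[i] <- FALSE else maxEnd <- en[i]
    }
    idx <- idx[keep]; st <- st[keep]; en <- en[keep]
    if (length(idx) < 2L) next
    for (i in seq_len(length(idx) - 1L)) {
      a <- i; b <- i + 1L
      dir <- .frame_direction(st[a], st[b])
      if (is.na(dir)) next
      ## 5' bound: after nearest stop upstream of geneB's start, in B's frame
      ps <- .prev_inframe_stop(seqc, st[b], st[b])
      windowStart <- if (is.na(ps)) ((st[b] - 1L) %% 3L) + 1L else ps + 3L
      ## 3' bound: first +0 (geneA-frame) stop at/after geneA's end
      ns <- .next_inframe_stop(seqc, st[a], max(st[a], en[a] - 2L), maxScan)
      if (is.na(ns)) next
      windowEnd <- ns + 2L
      if (windowStart > en[a]) next          # window never reaches into geneA
      if (windowEnd - windowStart < 2L) next
      offs <- (st[b] - windowStart) %/% 3L + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        geneA = idx[a], geneB = idx[b], strand = strand,
        startA = st[a], endA = en[a], startB = st[b], endB = en[b],
        windowStart = windowStart, windowEnd = windowEnd,
        direction = dir, upstreamStopOffset = offs
      )
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
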