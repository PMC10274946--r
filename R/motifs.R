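## Slippery-sequence motif catalog, matcher, region scanner and labeling.
##
## A motif class is a run pattern read 5'->3': runs of one repeated
## nucleotide, adjacent runs of different nucleotides, anchored so the
## pattern's 3' end abuts the (empty) A-site codon boundary.  The 5'-most
## run is maximal: surplus identical bases further 5' are ignored, so
## AAAAAAA still matches "six".  Interior and 3' runs are exact.  Classes
## that are subsets of others are resolved by precedence: the class with the
## lower probability of occurring by chance wins (descending run-length sum;
## within a sum, "six" outranks "threethree"; ties otherwise broken by more
## runs first).

## catalog order IS precedence order; ids are the fixed 0-9 coding used as
## the MOTIF feature (any fixed bijection works for tree models)
.MOTIF_CATALOG <- data.frame(
  name = c("threetwotwo", "twoonefour", "fivetwo", "twofive",
           "six", "threethree", "twofour", "five", "four", "three"),
  id = c(5L, 7L, 2L, 3L, 0L, 1L, 4L, 6L, 8L, 9L),
  direction = c(-1L, -1L, -1L, -1L, -1L, -1L, -1L, -1L, 1L, 1L),
  pattern = I(list(c(3L, 2L, 2L), c(2L, 1L, 4L), c(5L, 2L), c(2L, 5L),
                   6L, c(3L, 3L), c(2L, 4L), 5L, 4L, 3L)),
  stringsAsFactors = FALSE
)

#' The slippery-sequence motif catalog
#'
#' Ten motif classes: eight backward (-1) classes (six, threethree, fivetwo,
#' twofive, twofour, threetwotwo, five, twoonefour) and two forward (+1)
#' classes (four, three).  Rows are ordered by matching precedence; `id` is
#' the fixed 0-9 integer used as the MOTIF feature.
#'
#' @return data.frame with columns `name`, `id`, `direction`, `pattern`
#'   (list of run lengths, 5'->3') and `rank` (1 = highest precedence).
#' @export
motifCatalog <- function() {
  cat <- .MOTIF_CATALOG
  cat$rank <- seq_len(nrow(cat))
  cat
}

## does run pattern `pat` match the 3' end of window `w` (character vector
## of single bases)?  N never matches.
.match_pattern <- function(w, pat) {
  n <- length(w)
  need <- sum(pat)
  if (n < need) return(FALSE)
  pos <- n  # consume from the 3' end
  for (ri in rev(seq_along(pat))) {
    len <- pat[ri]
    base <- w[pos]
    if (base == "N") return(FALSE)
    run <- w[(pos - len + 1L):pos]
    if (any(run != base)) return(FALSE)
    ## base 5' of this run must differ, except for the 5'-most run
    ## (maximal-run semantics) or at the window edge
    prev <- if (pos - len >= 1L) w[pos - len] else NA_character_
    if (ri > 1L) {
      if (is.na(prev) || prev == base || prev == "N") return(FALSE)
    }
    pos <- pos - len
  }
  TRUE
}

#' Match a slippery motif at a codon boundary
#'
#' Tests the window of (up to) 7 nt immediately 5' of an A-site codon
#' boundary against the ten motif classes and returns the highest-precedence
#' match.
#'
#' @param window Nucleotide string (<= 7 nt is typical; longer input is
#'   truncated to its last 7 bases).  `N` at a required position blocks a
#'   match.
#' @param directions Restrict to motif classes of these shift directions.
#' @return One row of [motifCatalog()], or `NULL` when nothing matches.
#' @examples
#' matchMotif("GGGGGAA")$name   # "fivetwo"
#' matchMotif("CCCGGAA")$name   # "threetwotwo"
#' matchMotif("AAAAAA")$name    # "six"
#' @export
matchMotif <- function(window, directions = c(-1L, 1L)) {
  w <- strsplit(toupper(window), "")[[1]]
  if (length(w) > 7L) w <- w[(length(w) - 6L):length(w)]
  cat <- motifCatalog()
  for (i in seq_len(nrow(cat))) {
    if (!(cat$direction[i] %in% directions)) next
    if (.match_pattern(w, cat$pattern[[i]])) return(cat[i, ])
  }
  NULL
}

#' Scan an overlap region for candidate slippery sites
#'
#' Tests every codon boundary of geneA's (+0) frame inside the region's
#' window.  Backward-motif candidates are emitted in -1-geometry regions;
#' forward-motif candidates are emitted in +1-geometry regions, and only
#' when the shifted (+1 frame) A-site codon is more abundant genome-wide
#' than the waiting +0 codon (the A1 > A0 gate).
#'
#' @param region One row of [findOverlapRegions()] output.
#' @param genome A [GenomeRecord-class].
#' @param usage Codon usage table from [codonUsage()]; required for the
#'   forward gate (may be `NULL` for backward-geometry regions).
#' @return data.frame of candidates: `aSitePos` (oriented position of the
#'   first base of the empty A-site codon), `motif`, `motifId`,
#'   `direction`, `strand`, plus the region's `geneA`/`geneB`.
#' @export
scanRegion <- function(region, genome, usage = NULL) {
  stopifnot(nrow(region) == 1L)
  seqc <- orientSeq(genome, region$strand)
  dir <- region$direction
  ## codon boundaries in geneA's frame within the window
  first <- region$startA +
    3L * ceiling((region$windowStart - region$startA) / 3)
  ps <- seq(from = first, to = region$windowEnd - 2L, by = 3L)
  ps <- ps[ps >= max(2L, region$windowStart)]
  out <- list()
  for (p in ps) {
    win <- substr(seqc, max(1L, p - 7L), p - 1L)
    m <- matchMotif(win, directions = dir)
    if (is.null(m)) next
    if (dir == 1L) {
      if (is.null(usage)) stop("codon usage required for forward regions")
      a0 <- substr(seqc, p, p + 2L)
      a1 <- substr(seqc, p + 1L, p + 3L)
      if (nchar(a1) < 3L || grepl("N", a0) || grepl("N", a1)) next
      if (!(usage[[a1]] > usage[[a0]])) next
    }
    out[[length(out) + 1L]] <- data.frame(
      geneA = region$geneA, geneB = region$geneB,
      strand = region$strand, aSitePos = p,
      motif = m$name, motifId = m$id, direction = dir
    )
  }
  if (!length(out)) {
    return(data.frame(geneA = integer(), geneB = integer(),
                      strand = integer(), aSitePos = integer(),
                      motif = character(), motifId = integer(),
                      direction = integer()))
  }
  do.call(rbind, out)
}

#' Label candidates against an annotated shift position
#'
#' Candidates within `radius` bases of the annotated fragment boundary of a
#' joined gene receive the join's direction as their label; all other
#' candidates (including every candidate of a non-joined pair) are labeled
#' 0.
#'
#' @param candidates data.frame from [scanRegion()].
#' @param annotatedPos Oriented position of the annotated shift (fragment 1
#'   end), or `NA`/`NULL` for non-joined pairs.
#' @param annotatedDir The join's shift direction (-1/+1).
#' @param radius Maximum distance (bp) for a positive label.
#' @return The candidates with a `label` column in {-1, 0, +1}.
#' @export
labelCandidates <- function(candidates, annotatedPos = NULL,
                            annotatedDir = NA_integer_, radius = 10L) {
  lab <- rep(0L, nrow(candidates))
  if (!is.null(annotatedPos) && length(annotatedPos) && !is.na(annotatedPos)) {
    hit <- abs(candidates$aSitePos - annotatedPos) <= radius &
      candidates$direction == annotatedDir
    lab[hit] <- as.integer(annotatedDir)
  }
  candidates$label <- lab
  candidates
}
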