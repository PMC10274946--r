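## Shine-Dalgarno ribosome-binding-site scoring upstream of the P-site
## codon, by two methods:
##
##  * a Prodigal-style 28-bin integer score (bins 0-27), reconstructed from
##    the published tier description: SD motif tiers from the bare GG
##    dinucleotide up to the full anti-SD complement AGGAGG, crossed with
##    spacer ranges, ranked so that stronger motifs at better spacings get
##    higher bins and bin 27 is AGGAGG at the optimal 5-10 nt spacing;
##  * a RAST-style frequency score: the best log2(frequency/background)
##    over a table of 191 SD-like motifs x 10 spacer classes, clipped to
##    [0, 6.3].  The shipped frequency table is a synthetic anti-SD
##    neighborhood model (see rbsFrequencyTable()), not RAST's internal
##    data, which is not publicly distributed.
##
## The spacer is measured from the motif's 3' end to the first base of the
## P-site codon; spacers of 3-15 nt are searched, i.e. a 20-nt upstream
## window.  Both scorers are pure functions of that window.

.SPACER_RANGES <- data.frame(
  smin = c(5L, 3L, 11L, 13L),
  smax = c(10L, 4L, 12L, 15L),
  weight = c(4L, 3L, 2L, 1L)   # spacer suitability, 4 = best
)

.rbs_tier_motifs <- function() {
  list(
    `1` = "GG",
    `2` = c("GGTGG", "GGCGG", "GGGGG"),
    `3` = c("GGA", "GAG", "AGG"),
    `4` = c("AGGA", "GGAG", "GAGG"),
    `5` = c("AGGAG", "GGAGG"),
    ## one-mismatch hexamers AGGxGG (x != A) and AGxAGG (x != G)
    `6` = c("AGGTGG", "AGGCGG", "AGGGGG", "AGTAGG", "AGCAGG", "AGAAGG"),
    `7` = "AGGAGG"
  )
}

#' The Prodigal-style 28-bin RBS table
#'
#' Each row maps an SD motif string and a spacer range (motif 3' end to
#' P-site codon start, in nt) to an integer bin 0-27.  Bins rank the
#' (motif tier, spacer suitability) grid: bin = 4*(tier-1) + spacer weight
#' - 1, so extending a motif to a stronger tier at the same spacer never
#' lowers the bin, and bin 27 is AGGAGG at a 5-10 nt spacer.  The weakest
#' cell (GG at 13-15 nt) is bin 0, indistinguishable from "no motif".
#'
#' @return data.frame with columns `motif`, `spacer_min`, `spacer_max`,
#'   `bin`.
#' @export
rbsBinTable <- function() {
  tiers <- .rbs_tier_motifs()
  rows <- list()
  for (t in seq_along(tiers)) {
    for (m in tiers[[t]]) {
      for (r in seq_len(nrow(.SPACER_RANGES))) {
        bin <- 4L * (t - 1L) + .SPACER_RANGES$weight[r] - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          motif = m, spacer_min = .SPACER_RANGES$smin[r],
          spacer_max = .SPACER_RANGES$smax[r], bin = bin
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$bin, out$motif, out$spacer_min), , drop = FALSE]
}

.hamming_neighbors <- function(word, maxd) {
  bases <- c("A", "C", "G", "T")
  w <- strsplit(word, "")[[1]]
  res <- new.env(parent = emptyenv())
  rec <- function(cur, i, d) {
    if (d > maxd) return()
    if (i > length(cur)) {
      assign(paste(cur, collapse = ""), TRUE, envir = res)
      return()
    }
    for (b in bases) {
      cur2 <- cur; cur2[i] <- b
      rec(cur2, i + 1L, d + (b != w[i]))
    }
  }
  rec(w, 1L, 0L)
  sort(ls(res))
}

.RAST_SPACER_CLASSES <- data.frame(
  class = c("3-4", "5", "6", "7", "8", "9", "10", "11", "12", "13-15"),
  smin = c(3L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L),
  smax = c(4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 15L),
  weight = c(0.85, 1, 1, 1, 1, 1, 1, 0.9, 0.8, 0.6)
)

.RAST_BACKGROUND <- 1e-4

#' The synthetic 191-motif RBS frequency table
#'
#' A RAST-style table of observed frequencies for 191 SD-like motifs at 10
#' spacer-size classes.  The motif set is the anti-SD neighborhood of
#' AGGAGG: the 154 hexamers within Hamming distance 2 of AGGAGG, the 32
#' pentamers within Hamming distance 1 of AGGAG or GGAGG, and the 5
#' tetramer substrings of AAGGAGGT.  Frequencies follow a documented model
#' (frequency = background * 2^(base score * spacer weight), base score
#' 6.3/4.8/3.3 for hexamers with 0/1/2 mismatches, 5.0/3.5 for pentamers
#' with 0/1, 2.5 for tetramers), so that the derived score
#' log2(frequency/background) spans (0, 6.3].  This is a synthetic
#' stand-in with the same shape and range as the original external table.
#'
#' @return data.frame with columns `motif`, `spacer_class`, `freq`.
#' @export
rbsFrequencyTable <- function() {
  mism <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  hex <- .hamming_neighbors("AGGAGG", 2L)
  pent <- sort(unique(c(.hamming_neighbors("AGGAG", 1L),
                        .hamming_neighbors("GGAGG", 1L))))
  tet <- c("AAGG", "AGGA", "GGAG", "GAGG", "AGGT")
  base <- c(
    stats::setNames(6.3 - 1.5 * vapply(hex, mism, 0, b = "AGGAGG"), hex),
    stats::setNames(5.0 - 1.5 * pmin(vapply(pent, mism, 0, b = "AGGAG"),
                                     vapply(pent, mism, 0, b = "GGAGG")), pent),
    stats::setNames(rep(2.5, length(tet)), tet)
  )
  motifs <- names(base)
  stopifnot(length(motifs) == 191L)
  out <- expand.grid(motif = motifs,
                     spacer_class = .RAST_SPACER_CLASSES$class,
                     stringsAsFactors = FALSE)
  w <- .RAST_SPACER_CLASSES$weight[match(out$spacer_class,
                                         .RAST_SPACER_CLASSES$class)]
  out$freq <- .RAST_BACKGROUND * 2^(base[out$motif] * w)
  rownames(out) <- NULL
  out[order(out$motif, match(out$spacer_class, .RAST_SPACER_CLASSES$class)), ]
}

.pkg_cache <- new.env(parent = emptyenv())

.rbs_bins_cached <- function() {
  if (is.null(.pkg_cache$bins)) .pkg_cache$bins <- rbsBinTable()
  .pkg_cache$bins
}

.rbs_freq_cached <- function() {
  if (is.null(.pkg_cache$freq)) .pkg_cache$freq <- rbsFrequencyTable()
  .pkg_cache$freq
}

#' Write the RBS tables as TSV package data
#'
#' Serializes [rbsBinTable()] and [rbsFrequencyTable()] to tab-separated
#' files (the interchange format shipped under `inst/extdata/`).
#'
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
writeRbsTables <- function(dir = ".") {
  p1 <- file.path(dir, "rbs_prodigal_bins.tsv")
  p2 <- file.path(dir, "rbs_sd_frequencies_synthetic.tsv")
  utils::write.table(rbsBinTable(), p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(rbsFrequencyTable(), p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}

## scan for (motif, spacer) occurrences upstream of pSiteStart in an
## oriented sequence; calls FUN(motif, spacer) for the score and returns max
.best_upstream <- function(seqc, pSiteStart, motifs, score_fn,
                           spacer_range = c(3L, 15L)) {
  best <- -Inf
  L <- nchar(seqc)
  for (m in motifs) {
    ml <- nchar(m)
    for (s in spacer_range[1]:spacer_range[2]) {
      en <- pSiteStart - s - 1L
      st <- en - ml + 1L
      if (st < 1L || en < 1L) next
      if (substr(seqc, st, en) == m) {
        v <- score_fn(m, s)
        if (!is.na(v) && v > best) best <- v
      }
    }
  }
  best
}

#' Prodigal-style RBS bin score
#'
#' Finds the best-scoring (SD motif, spacer) combination in the upstream
#' window of the P-site codon under the 28-bin table and returns its bin;
#' 0 when nothing matches.  Windows truncated by the contig edge are scored
#' on the available bases.
#'
#' @param seqc Oriented (coding strand, 5'->3') sequence as a character
#'   string.
#' @param pSiteStart Position (1-based, oriented) of the first base of the
#'   P-site codon.
#' @return Integer bin in 0-27.
#' @export
scoreRbsProdigal <- function(seqc, pSiteStart) {
  tab <- .rbs_bins_cached()
  motifs <- unique(tab$motif)
  v <- .best_upstream(seqc, pSiteStart, motifs, function(m, s) {
    hit <- tab$motif == m & tab$spacer_min <= s & tab$spacer_max >= s
    if (!any(hit)) return(NA_real_)
    max(tab$bin[hit])
  })
  if (is.finite(v)) as.integer(v) else 0L
}

#' RAST-style RBS frequency score
#'
#' Best `log2(frequency / background)` over the (motif, spacer-class) pairs
#' of the shipped frequency table present in the upstream window, clipped
#' to [0, 6.3]; 0 when no tabulated motif is present.
#'
#' @inheritParams scoreRbsProdigal
#' @return Numeric score in [0, 6.3].
#' @export
scoreRbsRast <- function(seqc, pSiteStart) {
  tab <- .rbs_freq_cached()
  cls <- .RAST_SPACER_CLASSES
  motifs <- unique(tab$motif)
  v <- .best_upstream(seqc, pSiteStart, motifs, function(m, s) {
    ci <- which(cls$smin <= s & cls$smax >= s)
    if (!length(ci)) return(NA_real_)
    hit <- tab$motif == m & tab$spacer_class == cls$class[ci[1]]
    if (!any(hit)) return(NA_real_)
    log2(max(tab$freq[hit]) / .RAST_BACKGROUND)
  })
  if (is.finite(v)) max(0, min(6.3, v)) else 0
}
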