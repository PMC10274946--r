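## Minimum-free-energy estimation of downstream RNA secondary structure
## over fixed windows, via a pluggable backend contract, plus the
## length-and-GC normalization that maps raw MFE onto [0, 1].
##
## Backend contract: deterministic; mfe <= 0; fold(reverse complement)
## need not equal fold(window).  The built-in "baseline_nested" backend is
## a Nussinov-style dynamic program with stacking-aware pair weights
## (G:C -3, A:U -2, G:U -1, minimum hairpin loop 3, energies summed over
## pairs); it serves both the hairpin (LF) and pseudoknot (HK) feature
## slots by default.  An adapter for ViennaRNA's RNAfold is used when that
## program is on the PATH and the "vienna" backend is requested.

.FOLD_BACKENDS <- c("baseline_nested", "vienna")

#' Fold a sequence window
#'
#' @param window Nucleotide string (ACGT/U; N is unpairable).
#' @param backend `"baseline_nested"` (built-in weighted Nussinov DP) or
#'   `"vienna"` (RNAfold CLI adapter; requires RNAfold on the PATH).
#' @return List with `mfe` (<= 0), `structure` (dot-bracket string or `NA`)
#'   and `backend`.
#' @examples
#' fold("GGGGAAAACCCC")$mfe
#' @export
fold <- function(window, backend = "baseline_nested") {
  if (!nzchar(window)) stop("empty window")
  window <- chartr("u", "t", chartr("U", "T", toupper(window)))
  if (!backend %in% .FOLD_BACKENDS) stop("unknown backend '", backend, "'")
  if (backend == "baseline_nested") {
    list(mfe = .nussinov_mfe(window), structure = NA_character_,
         backend = backend)
  } else {
    .fold_vienna(window)
  }
}

#' @rdname fold
#' @return `viennaAvailable()`: TRUE when the RNAfold executable is found.
#' @export
viennaAvailable <- function() nzchar(Sys.which("RNAfold"))

.fold_vienna <- function(window) {
  if (!viennaAvailable()) stop("RNAfold not found on PATH")
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS"), input = window, stdout = TRUE)
  )
  ## last line: "STRUCTURE ( MFE)"
  mfe_line <- utils::tail(out, 1)
  mfe <- as.numeric(gsub("[()]", "", regmatches(
    mfe_line, regexpr("\\(\\s*-?[0-9.]+\\s*\\)$", mfe_line))))
  struct <- sub("\\s*\\(\\s*-?[0-9.]+\\s*\\)$", "", mfe_line)
  list(mfe = min(0, mfe), structure = struct, backend = "vienna")
}

## GC fraction of a window (N counts in the denominator)
.gc_fraction <- function(window) {
  ch <- strsplit(toupper(window), "")[[1]]
  if (!length(ch)) return(0)
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Length- and GC-normalized MFE
#'
#' `clamp(|mfe| / length / GC, 0, 1)`; 0 when GC = 0.  Raw MFE scales with
#' both window length and GC content, so the normalization makes windows of
#' different lengths and compositions comparable on a fixed [0, 1] scale.
#'
#' @param mfe Raw minimum free energy (<= 0).
#' @param window The folded window (supplies length and GC content).
#' @return Numeric in [0, 1].
#' @export
normalizedMfe <- function(mfe, window) {
  n <- nchar(window)
  gc <- .gc_fraction(window)
  if (n == 0 || gc == 0) return(0)
  max(0, min(1, abs(mfe) / n / gc))
}

#' Normalized MFE of a downstream window
#'
#' Folds the window of `windowLen` bases starting immediately after the
#' three A-site bases of the slippery sequence (an offset of 3 from the
#' motif) and returns the normalized MFE.  Windows truncated by the contig
#' edge are folded at their actual length and normalized by it; a window
#' entirely off the contig scores 0 with a warning.
#'
#' @param seqc Oriented sequence (character string).
#' @param aSiteEnd Position of the last base of the A-site codon.
#' @param windowLen Window length in bp (50 or 100 by convention).
#' @param backend Folding backend name (see [fold()]).
#' @return Numeric in [0, 1].
#' @export
windowedMfe <- function(seqc, aSiteEnd, windowLen = 50L,
                        backend = "baseline_nested") {
  st <- aSiteEnd + 1L
  en <- min(nchar(seqc), aSiteEnd + windowLen)
  if (st > nchar(seqc)) {
    warning("fold window entirely off contig; scoring 0")
    return(0)
  }
  win <- substr(seqc, st, en)
  normalizedMfe(fold(win, backend = backend)$mfe, win)
}
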