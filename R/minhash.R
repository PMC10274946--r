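## MinHash genome sketching, Mash distance estimation and single-linkage
## clustering into ~95%-identity groups for leakage-controlled
## leave-one-group-out validation.

.MINHASH_SEED <- 42  # fixed, documented hash seed: sketches are reproducible

#' Sketch a genome
#'
#' Bottom-`size` MinHash sketch over canonical k-mers (the lexicographic
#' minimum of each k-mer and its reverse complement under 2-bit encoding),
#' hashed with a fixed 64-bit mixer (splitmix64, truncated to 53 bits).
#' A genome and its reverse complement produce identical sketches.
#'
#' @param genome A [GenomeRecord-class], or a nucleotide string.
#' @param k K-mer size (default 16).
#' @param size Sketch size (default 400).
#' @param name Identifier used when `genome` is a plain string.
#' @return A [MinHashSketch-class].
#' @export
sketchGenome <- function(genome, k = 16L, size = 400L, name = "genome") {
  if (is(genome, "GenomeRecord")) {
    seqc <- as.character(genome@sequence)
    name <- genome@name
  } else {
    seqc <- toupper(as.character(genome))
  }
  if (nchar(seqc) < k) stop("genome shorter than k = ", k)
  h <- .minhash_bottom(seqc, as.integer(k), as.integer(size), .MINHASH_SEED)
  new("MinHashSketch", name = name, k = as.integer(k),
      size = as.integer(size), hashes = h)
}

#' Mash distance between two sketches
#'
#' Estimates the Jaccard index j from the merged bottom sketch and returns
#' the Mash distance d = -(1/k) * ln(2j / (1 + j)); 0 for identical
#' sketches and capped at 1 when no hashes are shared.
#'
#' @param s1,s2 [MinHashSketch-class] objects with equal `k` and `size`.
#' @return Numeric distance in [0, 1].
#' @export
mashDistance <- function(s1, s2) {
  if (s1@k != s2@k) stop("sketches have different k")
  if (s1@size != s2@size) stop("sketches have different size")
  merged <- sort(unique(c(s1@hashes, s2@hashes)))
  s <- min(s1@size, length(merged))
  merged <- merged[seq_len(s)]
  shared <- sum(merged %in% s1@hashes & merged %in% s2@hashes)
  j <- shared / s
  if (j <= 0) return(1)
  if (j >= 1) return(0)
  min(1, -log(2 * j / (1 + j)) / s1@k)
}

#' Cluster genomes at a Mash-distance threshold
#'
#' Single-linkage clustering of the pairwise Mash-distance graph: genomes
#' joined by any chain of distances <= `threshold` share a group.  At the
#' default threshold 0.05 groups approximate 95% sequence identity.
#'
#' @param genomes List of [GenomeRecord-class] objects (or sketches).
#' @param threshold Linkage distance cutoff.
#' @param k,size Sketch parameters (used when genomes are not yet
#'   sketched).
#' @return Integer vector of group ids, named by genome; invariant under
#'   input order up to relabeling (groups are numbered by first
#'   appearance).
#' @export
clusterGenomes <- function(genomes, threshold = 0.05, k = 16L, size = 400L) {
  sketches <- lapply(genomes, function(g) {
    if (is(g, "MinHashSketch")) g else sketchGenome(g, k = k, size = size)
  })
  n <- length(sketches)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (mashDistance(sketches[[i]], sketches[[j]]) <= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  ids <- match(roots, unique(roots))
  names(ids) <- vapply(sketches, function(s) s@name, "")
  ids
}
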