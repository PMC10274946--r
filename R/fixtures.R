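## Synthetic GenBank genomes with planted programmed-frameshift signals.
##
## The generator emulates the signal model the method assumes: a slippery
## motif whose 3' end abuts an empty A-site codon, an AGGAGG-like
## Shine-Dalgarno element upstream of the P-site, a GC-rich inverted-repeat
## hairpin a few bases 3' of the A-site, codon-usage skew that exercises
## the A1 > A0 gate both ways, and a +0 in-frame stop a configurable N nt
## downstream.  Planted genes are annotated as joined CDS features with
## separation 0 (backward) or 1 (forward), so every stage of the pipeline
## can be tested end-to-end without external data.
##
## Planted cassettes are assembled from fixed parts chosen to be stop-free
## in the frames where stops are forbidden (AGGAGG, C-rich fillers and the
## hairpin contain no stop triplet in any frame); remaining free bases are
## sampled and then repaired until the frame constraints hold, so the
## generator is deterministic per seed and its output always satisfies the
## candidate-geometry invariants.

.MOTIF_INSTANCE <- c(
  six = "AAAAAA", threethree = "TTTAAA", fivetwo = "GGGGGAA",
  twofive = "GGAAAAA", twofour = "CCGGGG", threetwotwo = "CCCGGAA",
  five = "GGGGG", twoonefour = "AAGAAAA", four = "GGGG", three = "AAA"
)

.HAIRPIN_ARM <- "GGCAGCGCC"  # no runs >= 3, no stop triplet in any frame
.HAIRPIN_LOOP <- "GCAA"

.sense_codons <- function() setdiff(.all_codons(), STOP_CODONS)

## Dirichlet-style perturbed codon-usage weights over the 61 sense codons
.skewed_usage_weights <- function(alpha = 3) {
  w <- stats::rgamma(61, shape = alpha)
  stats::setNames(w / sum(w), .sense_codons())
}

.sample_sense <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

.random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## resample free bases until no stop codon sits at any constrained boundary
.repair <- function(chars, fixed, boundaries, gc) {
  for (iter in 1:500) {
    bad <- NA_integer_
    for (q in boundaries) {
      if (paste(chars[q:(q + 2L)], collapse = "") %in% STOP_CODONS) {
        bad <- q; break
      }
    }
    if (is.na(bad)) return(chars)
    free <- bad:(bad + 2L)
    free <- free[!fixed[free]]
    if (!length(free)) stop("infeasible cassette: fixed stop codon")
    chars[free] <- .random_bases(length(free), gc)
  }
  stop("cassette repair did not converge")
}

## assemble one planted frameshift gene; returns list(seq, e1, s2, p, glen)
## with positions relative to the gene start (1-based; gene starts on an
## A-frame codon boundary)
.build_prf_gene <- function(motif, direction, N, sdSpacer, usage, gc,
                            sdOn = TRUE, partACodons = 30L,
                            tailBCodons = 8L) {
  stopifnot(motif %in% names(.MOTIF_INSTANCE),
            N %% 3L == 0L, N >= 6L, sdSpacer >= 6L)
  inst <- .MOTIF_INSTANCE[[motif]]
  ml <- nchar(inst)
  p <- 1L + 3L * partACodons              # A-site codon start (A-frame)
  s2 <- if (direction == -1L) p + 2L else p + 1L
  e1 <- if (direction == -1L) p + 1L else p - 1L

  ## choose the A-site codon (and, forward, the base completing A1):
  ## maximize the shifted codon's advantage so the realized genome-wide
  ## usage keeps A1 > A0 with margin
  if (direction == 1L) {
    best <- NULL
    for (a1 in names(sort(usage, decreasing = TRUE))[1:12]) {
      for (x in c("A", "C", "G", "T")) {
        a0 <- paste0(x, substr(a1, 1, 2))
        if (a0 %in% STOP_CODONS) next
        ratio <- usage[[a1]] / max(usage[[a0]], 1e-9)
        if (is.null(best) || ratio > best$ratio) {
          best <- list(a0 = a0, b1 = substr(a1, 3, 3), a1 = a1,
                       ratio = ratio)
        }
      }
    }
    a0 <- best$a0; b1 <- best$b1; a1boost <- best$a1
  } else {
    a0 <- .sample_sense(1L, usage)
    b1 <- NA_character_
    a1boost <- NULL
  }

  hp <- paste0(.HAIRPIN_ARM, .HAIRPIN_LOOP,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(.HAIRPIN_ARM))))
  hpStart <- p + N + 3L
  hpEnd <- hpStart + nchar(hp) - 1L
  t0 <- s2 + 3L * ceiling((hpEnd + 1L - s2) / 3)   # next B boundary
  stopB <- t0 + 3L * tailBCodons
  glen <- stopB + 2L

  chars <- rep("A", glen)
  fixed <- rep(FALSE, glen)
  put <- function(at, str) {
    v <- strsplit(str, "")[[1]]
    chars[at:(at + length(v) - 1L)] <<- v
    fixed[at:(at + length(v) - 1L)] <<- TRUE
  }

  ## part A: start codon + sense codons, then the fixed cassette pieces
  put(1L, "ATG")
  partAcod <- .sample_sense(partACodons - 1L, usage)
  if (!is.null(a1boost)) {
    ## reinforce the shifted codon's genome-wide abundance so the
    ## realized (counted) usage keeps the forward gate satisfied
    partAcod[sample(seq_along(partAcod), min(6L, length(partAcod)))] <- a1boost
  }
  chars[4:(p - 1L)] <- strsplit(paste(partAcod, collapse = ""), "")[[1]]
  if (sdOn) {
    sdStart <- p - sdSpacer - 9L
    put(sdStart, "AGGAGG")
  }
  ## filler between SD/part A and the motif: C-rich, with a run-breaking
  ## base just 5' of the motif so the planted class matches exactly
  preLen <- 9L - ml
  if (preLen > 0L) {
    b1brk <- if (substr(inst, 1, 1) == "C") "G" else "C"
    pre <- rep("C", preLen)
    if (preLen >= 2L) pre[preLen - 1L] <- "A"
    pre[preLen] <- b1brk
    put(p - 9L, paste(pre, collapse = ""))
  } else {
    put(p - 9L, "CA")  # 7-mer motifs: safe junction codon
  }
  put(p - ml, inst)
  put(p, a0)
  ## downstream: B-frame sense codons from s2, then fixed overwrites
  dsStart <- p + 3L
  if (direction == 1L) { put(p + 3L, b1); dsStart <- p + 4L }
  nfill <- glen - dsStart + 1L
  chars[dsStart:glen] <- .random_bases(nfill, gc)
  bFirst <- s2 + 3L * ceiling((dsStart - s2) / 3)
  for (q in seq(bFirst, stopB - 3L, by = 3L)) {
    cod <- .sample_sense(1L, usage)
    idx <- q:(q + 2L)
    chars[idx[!fixed[idx]]] <- strsplit(cod, "")[[1]][!fixed[idx]]
  }
  put(p + N, "TAA")
  put(hpStart, hp)
  put(stopB, sample(STOP_CODONS, 1L))

  ## frame constraints: +0 stop-free up to the planted stop, shifted frame
  ## stop-free up to the planted gene end
  bndA <- seq(4L, p + N - 3L, by = 3L)
  bndA <- bndA[bndA != p]                 # a0 is fixed sense anyway
  bndB <- seq(s2, stopB - 3L, by = 3L)
  chars <- .repair(chars, fixed, c(bndA, bndB), gc)
  list(seq = paste(chars, collapse = ""), e1 = e1, s2 = s2, p = p,
       glen = glen, a0 = a0)
}

## a plain gene: ATG + sense codons + stop
.build_plain_gene <- function(nCodons, usage) {
  paste0("ATG", paste(.sample_sense(nCodons, usage), collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Generate a synthetic genome with an optional planted frameshift
#'
#' Builds a GenBank-style genome: background sequence at a target GC,
#' plain genes with skewed codon usage, optionally one planted
#' frameshifted gene (annotated as a joined CDS with separation 0 or 1)
#' and optionally extra overlapping same-strand gene pairs that supply
#' negative candidate sites.  Deterministic per `seed`.
#'
#' @param seed Integer seed.
#' @param nGenes Number of plain genes.
#' @param gc Target background GC fraction.
#' @param usage Optional named weights over the 61 sense codons; drawn
#'   from a Dirichlet-style perturbation when `NULL`.
#' @param prf `NULL` for no planted shift, or a list with elements
#'   `motif` (catalog name), `direction` (-1/+1, must match the motif),
#'   `N` (nt to the +0 stop; multiple of 3), `sdSpacer` (>= 6),
#'   `strand` (+1/-1) and optionally `sdOn` (plant the AGGAGG element;
#'   default TRUE).
#' @param extraOverlapPairs Number of engineered overlapping gene pairs.
#' @param name Genome name.
#' @return List with `genome` (a [GenomeRecord-class]) and `truth`, a
#'   data.frame with the planted site (motif, direction, strand,
#'   `aSiteOriented`, `boundaryOriented` in oriented coordinates, and
#'   `aSiteGenome`), empty when nothing was planted.
#' @export
makePRFGenome <- function(seed, nGenes = 5L, gc = 0.55, usage = NULL,
                          prf = list(motif = "threethree", direction = -1L,
                                     N = 15L, sdSpacer = 6L, strand = 1L),
                          extraOverlapPairs = 1L, name = NULL) {
  set.seed(seed)
  if (is.null(usage)) usage <- .skewed_usage_weights()
  if (is.null(name)) name <- sprintf("synth%06d", seed %% 1000000L)

  pieces <- character()   # sequence chunks
  feats <- list()
  truth <- NULL
  pos <- 0L
  addPiece <- function(s) { pieces[[length(pieces) + 1L]] <<- s; pos <<- pos + nchar(s) }
  addPiece(paste(.random_bases(sample(60:120, 1L), gc), collapse = ""))

  geneSlots <- sample(rep(c("plain", "prf", "overlap"),
                          c(nGenes, as.integer(!is.null(prf)),
                            extraOverlapPairs)))
  for (slot in geneSlots) {
    if (slot == "plain") {
      g <- .build_plain_gene(sample(60:140, 1L), usage)
      strand <- sample(c(1L, 1L, 1L, -1L), 1L)
      s <- if (strand == 1L) g else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
      feats[[length(feats) + 1L]] <- list(start = pos + 1L,
                                          end = pos + nchar(g),
                                          strand = strand,
                                          product = "hypothetical protein")
      addPiece(s)
    } else if (slot == "prf") {
      pg <- .build_prf_gene(prf$motif, prf$direction, prf$N,
                            prf$sdSpacer %||% 6L, usage, gc,
                            sdOn = prf$sdOn %||% TRUE)
      strand <- prf$strand %||% 1L
      gstart <- pos + 1L
      glen <- pg$glen
      if (strand == 1L) {
        addPiece(pg$seq)
        fr <- list(start = c(gstart, gstart + pg$s2 - 1L),
                   end = c(gstart + pg$e1 - 1L, gstart + glen - 1L))
        aSiteOr <- gstart + pg$p - 1L
        boundOr <- gstart + pg$e1 - 1L
        aSiteGen <- aSiteOr
      } else {
        addPiece(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(pg$seq))))
        ## relative position r maps to genome gstart + glen - r
        fr <- list(start = c(gstart + glen - pg$e1, gstart),
                   end = c(gstart + glen - 1L, gstart + glen - pg$s2))
        aSiteGen <- gstart + glen - pg$p
        aSiteOr <- NA_integer_  # filled below once genome length is known
        boundOr <- NA_integer_
      }
      feats[[length(feats) + 1L]] <- list(start = fr$start, end = fr$end,
                                          strand = strand,
                                          product = "tail assembly chaperone")
      truth <- data.frame(
        motif = prf$motif, direction = as.integer(prf$direction),
        strand = strand, aSiteOriented = aSiteOr,
        boundaryOriented = boundOr, aSiteGenome = aSiteGen,
        relE1 = pg$e1, gstart = gstart, glen = glen
      )
    } else {  # engineered overlapping pair (negative-site factory)
      nx <- sample(50:90, 1L)
      gX <- .build_plain_gene(nx, usage)
      lenX <- nchar(gX)
      ov <- sample(c(7L, 8L, 10L, 11L, 13L, 14L), 1L)  # frame-shifting overlaps
      startX <- pos + 1L
      startY <- startX + lenX - ov
      if ((startY - startX) %% 3L == 0L) startY <- startY + 1L
      nyTail <- 3L * sample(25:45, 1L)
      endY <- startY + 3L * ((nyTail + ov) %/% 3L) + 2L
      addPiece(gX)
      extra <- endY - (startX + lenX - 1L)
      if (extra > 0L) {
        tail_chars <- .random_bases(extra, gc)
        ## keep geneY's frame stop-free over its free part, stop at its end
        off <- startX + lenX            # genome coord of tail_chars[1]
        q0 <- startY + 3L * ceiling((off - startY) / 3)
        for (q in seq(q0, endY - 3L, by = 3L)) {
          idx <- (q - off + 1L):(q - off + 3L)
          idx <- idx[idx >= 1L & idx <= extra]
          for (t in 1:50) {
            if (!(paste(tail_chars[pmax(1L, (q - off + 1L)):(q - off + 3L)],
                        collapse = "") %in% STOP_CODONS)) break
            tail_chars[idx] <- .random_bases(length(idx), gc)
          }
        }
        tail_chars[(endY - off - 1L):(endY - off + 1L)] <-
          strsplit(sample(STOP_CODONS, 1L), "")[[1]]
        addPiece(paste(tail_chars, collapse = ""))
      }
      feats[[length(feats) + 1L]] <- list(start = startX,
                                          end = startX + lenX - 1L,
                                          strand = 1L,
                                          product = "hypothetical protein")
      feats[[length(feats) + 1L]] <- list(start = startY, end = endY,
                                          strand = 1L,
                                          product = "hypothetical protein")
    }
    addPiece(paste(.random_bases(sample(60:120, 1L), gc), collapse = ""))
  }

  genome <- GenomeRecord(name, paste(pieces, collapse = ""),
                         circular = FALSE, features = feats)
  L <- length(genome@sequence)
  if (is.null(truth)) {
    truth <- data.frame(motif = character(), direction = integer(),
                        strand = integer(), aSiteOriented = integer(),
                        boundaryOriented = integer(),
                        aSiteGenome = integer())
  } else {
    mi <- which(truth$strand == -1L)
    if (length(mi)) {
      truth$aSiteOriented[mi] <- L - truth$aSiteGenome[mi] + 1L
      truth$boundaryOriented[mi] <-
        L - (truth$gstart[mi] + truth$glen[mi] - truth$relE1[mi]) + 1L
    }
    truth$relE1 <- truth$gstart <- truth$glen <- NULL
  }
  list(genome = genome, truth = truth)
}

#' Simulate a corpus of related genome groups
#'
#' Generates `nBackward` genomes with one planted backward (-1) shift,
#' `nForward` with one planted forward (+1) shift and `nNull` without any,
#' assigned to `nGroups` groups.  Genomes within a group share a codon
#' usage table, GC content, a preferred motif pool and an N distribution,
#' so that a model trained without a group has genuinely less information
#' about it than a model trained without only one genome — the desk-scale
#' analogue of phage cluster structure.
#'
#' @param seed Integer seed.
#' @param nBackward,nForward,nNull Genome counts by planted-signal type.
#' @param nGroups Number of groups.
#' @return List with `genomes` (list of [GenomeRecord-class]), `truth`
#'   (per-genome planted-site tables, named), and `groups` (integer group
#'   label per genome).
#' @export
simulateCorpus <- function(seed, nBackward = 40L, nForward = 10L,
                           nNull = 10L, nGroups = 5L) {
  set.seed(seed)
  n <- nBackward + nForward + nNull
  kinds <- c(rep(-1L, nBackward), rep(1L, nForward), rep(0L, nNull))
  groups <- rep(seq_len(nGroups), length.out = n)
  ## shuffle kinds so every group holds a mixture of all three
  kinds <- sample(kinds)
  seeds <- sample.int(2^30, n)
  ## every pool shares the canonical heptamer class so no group's motif
  ## vocabulary is wholly novel to a model trained without it
  back_pools <- list(c("threethree", "six"), c("threethree", "fivetwo", "twofive"),
                     c("threethree", "twofour", "threetwotwo"),
                     c("threethree", "five", "twoonefour"),
                     c("threethree", "fivetwo"))
  fwd_pool <- c("three", "four")
  gparam <- lapply(seq_len(nGroups), function(g) {
    list(gc = 0.45 + 0.05 * (g - 1),
         usage = .skewed_usage_weights(alpha = 2.5),
         pool = back_pools[[(g - 1L) %% length(back_pools) + 1L]],
         N = c(9L, 15L, 21L, 27L, 33L)[g],
         ## SD-less shift sites occur only in one group, so leaving that
         ## group out withholds the evidence for them and separates the
         ## validation levels
         sdProb = if (g == nGroups) 0.45 else 1)
  })
  genomes <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    gp <- gparam[[g]]
    prf <- if (kinds[i] == 0L) NULL else if (kinds[i] == -1L) {
      list(motif = sample(gp$pool, 1L), direction = -1L,
           N = gp$N + sample(c(0L, 3L), 1L), sdSpacer = 6L,
           strand = sample(c(1L, 1L, 1L, -1L), 1L),
           sdOn = stats::runif(1) <= gp$sdProb)
    } else {
      list(motif = sample(fwd_pool, 1L), direction = 1L,
           N = gp$N + sample(c(0L, 3L), 1L), sdSpacer = 6L, strand = 1L,
           sdOn = stats::runif(1) <= gp$sdProb)
    }
    fx <- makePRFGenome(seeds[i], nGenes = 4L, gc = gp$gc,
                        usage = gp$usage, prf = prf,
                        extraOverlapPairs = 2L,
                        name = sprintf("g%02d_s%02d", g, i))
    genomes[[i]] <- fx$genome
    truths[[i]] <- fx$truth
  }
  names(truths) <- vapply(genomes, genomeName, "")
  list(genomes = genomes, truth = truths, groups = groups)
}
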