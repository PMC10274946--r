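## Shared helpers: small GenBank texts and sequence utilities built in code.

## a minimal two-gene GenBank text: one plain CDS (1..100) and one joined
## CDS join(200..300,301..400) on a 400 nt genome
gb_two_gene_text <- function() {
  set.seed(4242)
  sq <- paste(sample(c("a", "c", "g", "t"), 400, TRUE), collapse = "")
  c("LOCUS       example             400 bp    DNA     linear",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..100",
    '                     /product="example gene"',
    "     CDS             join(200..300,301..400)",
    '                     /product="tail assembly chaperone"',
    "ORIGIN",
    vapply(seq(1, 400, 60), function(p) {
      chunk <- substr(sq, p, min(p + 59, 400))
      groups <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      sprintf("%9d %s", p, paste(groups, collapse = " "))
    }, ""),
    "//")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## a random GenomeRecord with a mix of plain, joined and reverse-strand
## features (for round-trip property tests)
random_record <- function(seed) {
  set.seed(seed)
  L <- sample(500:900, 1)
  sq <- random_dna(L)
  nf <- sample(0:4, 1)
  feats <- list()
  if (nf > 0) {
    for (i in seq_len(nf)) {
      st <- sample(seq(1, L - 120), 1)
      strand <- sample(c(1L, -1L), 1)
      if (runif(1) < 0.4) {  # joined, separation 0
        mid <- st + sample(30:60, 1)
        en <- min(L, mid + sample(30:50, 1))
        starts <- c(st, mid + 1L); ends <- c(mid, en)
        if (strand == -1L) { starts <- rev(starts); ends <- rev(ends) }
        feats[[i]] <- list(start = starts, end = ends, strand = strand,
                           product = sprintf("joined product %d", i))
      } else {
        en <- min(L, st + sample(60:100, 1))
        feats[[i]] <- list(start = st, end = en, strand = strand,
                           product = sprintf("plain product %d", i))
      }
    }
  }
  GenomeRecord(sprintf("rand%04d", seed), sq, circular = runif(1) < 0.3,
               features = feats)
}

records_identical <- function(a, b) {
  fa <- cdsFeatures(a); fb <- cdsFeatures(b)
  identical(genomeName(a), genomeName(b)) &&
    identical(as.character(genomeSeq(a)), as.character(genomeSeq(b))) &&
    identical(isCircular(a), isCircular(b)) &&
    nrow(fa) == nrow(fb) &&
    all(vapply(seq_len(nrow(fa)), function(i) {
      identical(IRanges::start(fa$locations[[i]]),
                IRanges::start(fb$locations[[i]])) &&
        identical(IRanges::end(fa$locations[[i]]),
                  IRanges::end(fb$locations[[i]])) &&
        fa$strand[i] == fb$strand[i] &&
        fa$product[i] == fb$product[i] &&
        fa$is_joined[i] == fb$is_joined[i]
    }, TRUE))
}

## genome with two CDS at chosen coordinates over a supplied sequence
pair_genome <- function(sq, startA, endA, startB, endB,
                        strandA = 1L, strandB = 1L) {
  GenomeRecord("pair", sq, features = list(
    list(start = startA, end = endA, strand = strandA, product = "A"),
    list(start = startB, end = endB, strand = strandB, product = "B")
  ))
}

## independent regex-based motif oracle: builds a regex per catalog row
## (anchored at the window 3' end) and returns the first match in catalog
## (precedence) order
regex_motif_oracle <- function(window, directions = c(-1L, 1L)) {
  cat <- motifCatalog()
  w <- toupper(window)
  if (nchar(w) > 7) w <- substr(w, nchar(w) - 6, nchar(w))
  for (i in seq_len(nrow(cat))) {
    if (!(cat$direction[i] %in% directions)) next
    pat <- cat$pattern[[i]]
    k <- length(pat)
    refs <- paste0("x", seq_len(k))
    parts <- character(k)
    for (j in seq_len(k)) {
      parts[j] <- sprintf("(?P<%s>[ACGT])\\%d{%d}", refs[j], j, pat[j] - 1L)
    }
    ## adjacent runs must differ: use lookahead on the backreference
    rx <- parts[1]
    if (k > 1) {
      for (j in 2:k) {
        rx <- paste0(rx, sprintf("(?!\\%d)", j - 1L), parts[j])
      }
    }
    rx <- paste0(rx, "$")
    m <- regexpr(rx, w, perl = TRUE)
    if (m[1] != -1) return(cat$name[i])
  }
  NA_character_
}

## genome with a single joined feature whose fragments are `sep` bases
## apart (frames arranged to imply a backward shift when possible)
join_genome <- function(sep, strand = 1L, L = 600L) {
  set.seed(900 + sep)
  sq <- random_dna(L)
  e1 <- 250L
  ## keep the two fragments in different frames (a same-frame join could
  ## never be a frameshift, whatever its separation)
  if ((e1 + 1L + sep - 100L) %% 3L == 0L) e1 <- e1 + 1L
  starts <- c(100L, e1 + 1L + sep)
  ends <- c(e1, e1 + sep + 150L)
  if (strand == -1L) {
    ## strand complementation of the whole record
    sq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    ns <- L - ends + 1L
    ne <- L - starts + 1L
    starts <- ns; ends <- ne
  }
  GenomeRecord("j", sq, features = list(
    list(start = starts, end = ends, strand = strand, product = "tac")))
}

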