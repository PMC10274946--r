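## Independent oracles shared across test files.

## exact canonical-k-mer Jaccard, as an independent oracle
exact_jaccard <- function(s1, s2, k = 16L) {
  canon <- function(s) {
    n <- nchar(s)
    km <- substring(s, 1:(n - k + 1), k:n)
    rc <- vapply(km, function(x) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    }, "")
    unique(pmin(km, rc))
  }
  a <- canon(s1); b <- canon(s2)
  length(intersect(a, b)) / length(union(a, b))
}

## the enumeration oracle: generate every nested structure explicitly and
## score it with the baseline energy rule (per maximal helix: +4
## initiation + the weights of all stacked (inner) pairs), then take the
## minimum.  Independent of the dynamic program it checks.

pair_w <- function(a, b) {
  k <- paste0(a, b)
  if (k %in% c("GC", "CG")) -3 else if (k %in% c("AT", "TA")) -2
  else if (k %in% c("GT", "TG")) -1 else NA_real_
}

enumerate_structures <- function(chars, i, j) {
  if (i >= j) return(list(matrix(numeric(0), ncol = 2)))
  out <- list()
  ## i unpaired
  for (s in enumerate_structures(chars, i + 1, j)) out[[length(out) + 1]] <- s
  ## i paired with k (min hairpin loop 3)
  if (j < i + 4) return(out)
  for (k in (i + 4):j) {
    if (is.na(pair_w(chars[i], chars[k]))) next
    left <- enumerate_structures(chars, i + 1, k - 1)
    right <- enumerate_structures(chars, k + 1, j)
    for (a in left) for (b in right) {
      out[[length(out) + 1]] <- rbind(c(i, k), a, b)
    }
  }
  out
}

score_structure <- function(chars, pairs) {
  if (nrow(pairs) == 0) return(0)
  key <- paste(pairs[, 1], pairs[, 2])
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; k <- pairs[r, 2]
    inner <- paste(i + 1, k - 1) %in% key
    outer <- paste(i - 1, k + 1) %in% key
    if (!outer) total <- total + 4            # helix initiation
    if (inner) total <- total + pair_w(chars[i + 1], chars[k - 1])
  }
  total
}

oracle_mfe <- function(sq) {
  chars <- strsplit(sq, "")[[1]]
  best <- 0
  for (s in enumerate_structures(chars, 1L, length(chars))) {
    v <- score_structure(chars, s)
    if (v < best) best <- v
  }
  best
}
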