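## GenBank flat-file reading and writing.
##
## Only the NCBI dialect features needed for frameshift analysis are
## handled: LOCUS line, FEATURES table with CDS entries (including
## join(...)/complement(...) compound locations and the /product qualifier)
## and the ORIGIN sequence block.  All coordinates are 1-based inclusive.

#' Read GenBank flat files
#'
#' Parses one or more GenBank records (LOCUS/FEATURES/ORIGIN sections) into
#' [GenomeRecord-class] objects.  Only CDS features are retained; other
#' feature types are skipped.  Compound `join(a..b,c..d)` locations become
#' multi-location features; `complement(...)` sets strand -1, and for
#' reverse-strand joined features fragments are stored in biological 5'->3'
#' order.  Sequences are uppercased, U is mapped to T, and any other
#' non-ACGT character becomes N.  Fuzzy location bounds (`<`/`>`) are parsed
#' as exact.
#'
#' @param x Path to a GenBank file, or GenBank text (a single string with
#'   newlines, or a character vector of lines).
#' @return A list of [GenomeRecord-class] objects, one per LOCUS block.
#' @examples
#' txt <- c(
#'   "LOCUS       toy                 60 bp    DNA     linear",
#'   "FEATURES             Location/Qualifiers",
#'   "     CDS             1..30",
#'   "                     /product=\"demo\"",
#'   "ORIGIN",
#'   paste("        1", "atgaaaccca tgtttggctt aatgcccaaa ggctttaaat",
#'         "aacccgggtt tatgaaataa"),
#'   "//")
#' readGenBank(txt)
#' @export
readGenBank <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    lines <- strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- as.character(x)
  }
  recs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^LOCUS", lines[i])) { i <- i + 1L; next }
    j <- i
    while (j <= n && !grepl("^//\\s*$", lines[j])) j <- j + 1L
    recs[[length(recs) + 1L]] <- .parse_gb_record(lines[i:min(j, n)], i)
    i <- j + 1L
  }
  if (!length(recs)) stop("no LOCUS record found in input")
  recs
}

.parse_gb_record <- function(lines, offset) {
  locus <- lines[1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  name <- if (length(toks) >= 2) toks[2] else "unnamed"
  circular <- any(grepl("circular", locus, ignore.case = TRUE))

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("missing ORIGIN section in record '", name, "'")
  ori <- ori[1]

  ## sequence
  seq_lines <- lines[seq(ori + 1L, length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sq <- chartr("U", "T", sq)
  sq <- gsub("[^ACGT]", "N", sq)
  if (!nzchar(sq)) stop("empty ORIGIN sequence in record '", name, "'")

  ## feature table: lines between FEATURES and ORIGIN
  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart) && fstart[1] + 1L <= ori - 1L) {
    flines <- lines[seq(fstart[1] + 1L, ori - 1L)]
    k <- 1L
    while (k <= length(flines)) {
      ln <- flines[k]
      if (grepl("^ {0,5}\\S", ln) && !grepl("^ {21}", ln)) {
        type <- trimws(substr(ln, 1, 21))
        locstr <- trimws(substr(ln, 22, nchar(ln)))
        ## location may continue on following lines that are not qualifiers
        while (k + 1L <= length(flines) &&
               grepl("^ {21}", flines[k + 1L]) &&
               !grepl("^\\s*/", trimws(flines[k + 1L]))) {
          k <- k + 1L
          locstr <- paste0(locstr, trimws(flines[k]))
        }
        quals <- character()
        while (k + 1L <= length(flines) && grepl("^ {21}", flines[k + 1L])) {
          k <- k + 1L
          quals <- c(quals, trimws(flines[k]))
        }
        if (identical(type, "CDS")) {
          loc <- .parse_location(locstr, line = offset)
          prod <- .extract_product(quals)
          feats[[length(feats) + 1L]] <-
            list(start = loc$start, end = loc$end, strand = loc$strand,
                 product = prod)
        }
      }
      k <- k + 1L
    }
  }

  gl <- nchar(sq)
  for (f in feats) {
    if (any(f$start < 1L) || any(f$end > gl) || any(f$start > f$end)) {
      stop("feature location out of bounds in record '", name, "'")
    }
  }
  GenomeRecord(name, sq, circular = circular, features = feats)
}

.extract_product <- function(quals) {
  if (!length(quals)) return("")
  txt <- paste(quals, collapse = "\n")
  m <- regmatches(txt, regexpr('/product="[^"]*"', txt))
  if (!length(m)) return("")
  gsub("\n\\s*", " ", sub('/product="([^"]*)"', "\\1", m))
}

## Parse a GenBank location string into start/end vectors and a strand.
## Handles a..b, single positions, join(...), complement(...) and
## complement(join(...)); fuzzy markers < and > are stripped.
.parse_location <- function(s, line = NA) {
  s <- gsub("[<>\\s]", "", s)
  strand <- 1L
  if (grepl("^complement\\(", s)) {
    strand <- -1L
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^join\\(", s)) {
    s <- sub("^join\\((.*)\\)$", "\\1", s)
  }
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  st <- en <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (grepl("^complement\\(", p)) {
      strand <- -1L
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
      st[i] <- ab[1]; en[i] <- ab[2]
    } else if (grepl("^\\d+$", p)) {
      st[i] <- en[i] <- as.integer(p)
    } else {
      stop("malformed coordinates '", p, "' near line ", line)
    }
  }
  ## biological 5'->3' fragment order: ascending for +, descending for -
  o <- order(st, decreasing = (strand == -1L))
  list(start = st[o], end = en[o], strand = strand)
}

#' Write GenBank flat files
#'
#' Serializes [GenomeRecord-class] objects back to GenBank flat-file text.
#' Joined features use the `join` keyword; reverse-strand features are
#' wrapped in `complement(...)`.  `readGenBank(writeGenBank(x))` round-trips
#' name, sequence, coordinates, strand and join structure.
#'
#' @param records A `GenomeRecord` or list of them.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return Invisibly (when writing to file) or visibly (otherwise) a
#'   character vector of lines.
#' @export
writeGenBank <- function(records, path = NULL) {
  if (is(records, "GenomeRecord")) records <- list(records)
  out <- character()
  for (rec in records) {
    L <- length(rec@sequence)
    ft <- rec@features
    ## bounds re-checked before any output is produced
    if (nrow(ft)) {
      en <- unlist(lapply(ft$locations, IRanges::end))
      st <- unlist(lapply(ft$locations, IRanges::start))
      if (any(st < 1L) || any(en > L)) stop("feature location out of bounds")
    }
    out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     %s",
                          rec@name, L,
                          if (rec@circular) "circular" else "linear"))
    out <- c(out, "FEATURES             Location/Qualifiers")
    if (nrow(ft)) {
      for (i in seq_len(nrow(ft))) {
        r <- ft$locations[[i]]
        st <- IRanges::start(r); en <- IRanges::end(r)
        if (ft$strand[i] == -1L) {  # file order is ascending coordinates
          o <- order(st); st <- st[o]; en <- en[o]
        }
        locstr <- paste(sprintf("%d..%d", st, en), collapse = ",")
        if (length(st) > 1L) locstr <- sprintf("join(%s)", locstr)
        if (ft$strand[i] == -1L) locstr <- sprintf("complement(%s)", locstr)
        out <- c(out, sprintf("     CDS             %s", locstr))
        if (nzchar(ft$product[i])) {
          out <- c(out, sprintf('                     /product="%s"', ft$product[i]))
        }
      }
    }
    out <- c(out, "ORIGIN")
    sq <- tolower(as.character(rec@sequence))
    pos <- seq(1L, nchar(sq), by = 60L)
    for (p in pos) {
      chunk <- substr(sq, p, min(p + 59L, nchar(sq)))
      groups <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
    }
    out <- c(out, "//")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    invisible(out)
  } else out
}
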