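#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges IRangesList
#' @importFrom Biostrings DNAString reverseComplement
#' @useDynLib prfscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GenomeRecord: an annotated genome
#'
#' Container for one parsed genome: its name, nucleotide sequence, circular
#' flag and the ordered list of CDS features.  Feature locations are stored
#' as an [IRanges::IRangesList] (one element per feature, length > 1 for
#' compound `join(...)` locations), with one strand per feature.  All
#' coordinates are 1-based inclusive, the native GenBank and IRanges
#' convention, and are used unchanged throughout the package.
#'
#' @slot name Genome identifier (LOCUS name).
#' @slot sequence A [Biostrings::DNAString]; uppercased, U mapped to T and
#'   other ambiguity codes mapped to N on read.
#' @slot circular Logical; whether the molecule is circular.
#' @slot features A [S4Vectors::DataFrame] with columns `locations`
#'   (IRangesList), `strand` (integer, +1/-1), `product` (character) and
#'   `is_joined` (logical, TRUE iff more than one location).
#'
#' @seealso [readGenBank()], [writeGenBank()], [cdsFeatures()]
#' @export
setClass("GenomeRecord",
  representation(
    name = "character",
    sequence = "DNAString",
    circular = "logical",
    features = "DataFrame"
  )
)

setValidity("GenomeRecord", function(object) {
  msg <- character()
  L <- length(object@sequence)
  if (L < 1L) msg <- c(msg, "sequence must be non-empty")
  ft <- object@features
  need <- c("locations", "strand", "product", "is_joined")
  if (!all(need %in% colnames(ft))) {
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(ft) > 0L) {
    locs <- ft$locations
    nloc <- lengths(locs)
    if (any(nloc < 1L)) msg <- c(msg, "every feature needs >= 1 location")
    st <- unlist(lapply(locs, IRanges::start))
    en <- unlist(lapply(locs, IRanges::end))
    if (length(st) && (any(st < 1L) || any(en > L) || any(st > en))) {
      msg <- c(msg, "feature locations out of genome bounds")
    }
    if (!all(ft$strand %in% c(1L, -1L))) msg <- c(msg, "strand must be +1 or -1")
    if (!identical(as.logical(nloc > 1L), ft$is_joined)) {
      msg <- c(msg, "is_joined must mirror multi-location status")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeRecord
#'
#' @param name Genome identifier.
#' @param sequence Character string or `DNAString` over A/C/G/T/N.
#' @param circular Logical circular-molecule flag.
#' @param features `DataFrame` of CDS features, or `NULL` for none.  May also
#'   be a plain list of per-feature lists with elements `start`, `end`
#'   (parallel vectors), `strand`, `product`.
#' @return A [GenomeRecord-class] object.
#' @examples
#' g <- GenomeRecord("toy", "ATGAAATAAATGCCCTAA")
#' @export
GenomeRecord <- function(name, sequence, circular = FALSE, features = NULL) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (is.null(features)) {
    features <- S4Vectors::DataFrame(
      locations = IRanges::IRangesList(),
      strand = integer(), product = character(), is_joined = logical()
    )
  } else if (is.list(features) && !is(features, "DataFrame")) {
    locs <- IRanges::IRangesList(lapply(features, function(f) {
      IRanges::IRanges(start = as.integer(f$start), end = as.integer(f$end))
    }))
    features <- S4Vectors::DataFrame(
      locations = locs,
      strand = vapply(features, function(f) as.integer(f$strand %||% 1L), 1L),
      product = vapply(features, function(f) as.character(f$product %||% ""), ""),
      is_joined = lengths(locs) > 1L
    )
  }
  new("GenomeRecord", name = as.character(name), sequence = sequence,
      circular = isTRUE(circular), features = features)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn GenomeRecord-class Genome identifier.
#' @param object,x A `GenomeRecord`.
#' @export
genomeName <- function(x) x@name

#' @describeIn GenomeRecord-class Genome sequence as a `DNAString`.
#' @export
genomeSeq <- function(x) x@sequence

#' @describeIn GenomeRecord-class Circular-molecule flag.
#' @export
isCircular <- function(x) x@circular

#' @describeIn GenomeRecord-class `DataFrame` of CDS features.
#' @export
cdsFeatures <- function(x) x@features

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord:", object@name,
      sprintf("(%d bp, %s)", length(object@sequence),
              if (object@circular) "circular" else "linear"), "\n")
  nf <- nrow(object@features)
  cat(" ", nf, "CDS feature(s);", sum(object@features$is_joined), "joined\n")
})

#' MinHashSketch: a bottom-k MinHash sketch of a genome
#'
#' Holds the `size` smallest 64-bit-style hash values over the canonical
#' k-mers of a genome (canonical k-mer = lexicographic minimum of the k-mer
#' and its reverse complement under 2-bit encoding).  Hashes are stored as
#' doubles holding exact 53-bit integers.
#'
#' @slot name Genome identifier.
#' @slot k K-mer size.
#' @slot size Maximum sketch size.
#' @slot hashes Sorted ascending numeric vector of distinct hash values.
#' @seealso [sketchGenome()], [mashDistance()], [clusterGenomes()]
#' @export
setClass("MinHashSketch",
  representation(name = "character", k = "integer", size = "integer",
                 hashes = "numeric")
)

setValidity("MinHashSketch", function(object) {
  if (length(object@hashes) > object@size) return("more hashes than sketch size")
  if (is.unsorted(object@hashes, strictly = TRUE)) {
    return("hashes must be sorted, distinct")
  }
  TRUE
})

setMethod("show", "MinHashSketch", function(object) {
  cat(sprintf("MinHashSketch: %s (k=%d, %d/%d hashes)\n",
              object@name, object@k, length(object@hashes), object@size))
})

#' PRFModel: a trained frameshift-site classifier
#'
#' Wraps a gradient-boosted tree model for the three-class problem
#' (-1 backward shift, 0 no shift, +1 forward shift) together with the
#' feature-column order, the slippery-motif id table and the training
#' configuration, so that a persisted model cannot silently drift out of
#' sync with the feature schema.
#'
#' @slot booster Raw serialized xgboost booster.
#' @slot featureNames Ordered feature column names.
#' @slot classLevels Numeric class labels in internal order.
#' @slot motifTable The motif catalog (name/id mapping) in force at training.
#' @slot config The [prfConfig()] list used for training.
#' @slot version Schema version string.
#' @seealso [trainPRFModel()], [predictGenome()], [saveModel()], [loadModel()]
#' @export
setClass("PRFModel",
  representation(booster = "raw", featureNames = "character",
                 classLevels = "numeric", motifTable = "data.frame",
                 config = "list", version = "character")
)

setMethod("show", "PRFModel", function(object) {
  cat("PRFModel (gradient-boosted trees):",
      length(object@featureNames), "features, classes",
      paste(object@classLevels, collapse = "/"), "\n")
})
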