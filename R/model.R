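## Training, prediction and leave-one-group-out validation of the
## three-class gradient-boosted frameshift classifier.
##
## The classifier is xgboost with histogram trees, configured to mirror a
## histogram gradient-boosting classifier at library defaults except for
## the L2 regularization (1.0) and with no early stopping, so that
## training and prediction are deterministic: 100 rounds, learning rate
## 0.1, loss-guided growth with 31 leaves, single thread.

.MODEL_VERSION <- "prfscan-model-1"

.xgb_params <- function(l2 = 1.0) {
  list(objective = "multi:softprob", num_class = 3L,
       eta = 0.1, max_depth = 0L, max_leaves = 31L,
       grow_policy = "lossguide", tree_method = "hist",
       lambda = l2, nthread = 1L)
}

.feature_matrix <- function(features) {
  cols <- featureColumns()
  miss <- setdiff(cols, names(features))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(features[, cols])
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite feature value in row ", bad[1, 1], ", column ",
         cols[bad[1, 2]])
  }
  storage.mode(m) <- "double"
  m
}

#' Train the frameshift classifier
#'
#' Fits the three-class model ({-1, 0, +1}) on a labeled feature table.
#' Deterministic: identical inputs yield byte-identical predictions.
#'
#' @param features Feature table from [featurize()]/[prepareGenome()]
#'   containing the eleven feature columns.
#' @param labels Integer labels in {-1, 0, +1}; defaults to
#'   `features$label`.
#' @param config A [prfConfig()] list (stored with the model).
#' @param nrounds Boosting rounds.
#' @param l2 L2 regularization weight.
#' @return A [PRFModel-class].
#' @export
trainPRFModel <- function(features, labels = features$label,
                          config = prfConfig(), nrounds = 100L, l2 = 1.0) {
  m <- .feature_matrix(features)
  if (length(labels) != nrow(m)) stop("labels do not match feature rows")
  classes <- c(-1, 0, 1)
  if (!all(labels %in% classes)) stop("labels must be -1, 0 or +1")
  if (length(unique(labels)) < 2L) {
    stop("training requires at least two classes in the labels")
  }
  y <- match(labels, classes) - 1L
  dtr <- xgboost::xgb.DMatrix(m, label = y)
  bst <- xgboost::xgb.train(params = .xgb_params(l2), data = dtr,
                            nrounds = nrounds, verbose = 0)
  new("PRFModel", booster = xgboost::xgb.save.raw(bst),
      featureNames = featureColumns(), classLevels = classes,
      motifTable = motifCatalog()[, c("name", "id", "direction")],
      config = config, version = .MODEL_VERSION)
}

#' Class probabilities for a feature table
#'
#' @param object A [PRFModel-class].
#' @param features Feature table with the eleven feature columns.
#' @return Matrix (rows = candidates) with columns named by class
#'   (-1, 0, 1).
#' @export
predictProb <- function(object, features) {
  m <- .feature_matrix(features)
  bst <- xgboost::xgb.load.raw(object@booster)
  p <- stats::predict(bst, xgboost::xgb.DMatrix(m))
  if (!is.matrix(p)) p <- matrix(p, ncol = 3L, byrow = TRUE)
  colnames(p) <- as.character(object@classLevels)
  p
}

## best-site rule: per overlap (geneA, geneB), keep the candidate with the
## highest non-zero-class probability whose argmax class is not 0
.calls_from_features <- function(features, probs, genomeLength) {
  cls_idx <- max.col(probs, ties.method = "first")
  classes <- as.numeric(colnames(probs))
  pred_class <- classes[cls_idx]
  score <- pmax(probs[, "-1"], probs[, "1"])
  keep <- which(pred_class != 0)
  if (!length(keep)) return(.empty_calls())
  f <- features[keep, , drop = FALSE]
  f$direction_hat <- pred_class[keep]
  f$score <- score[keep]
  out <- list()
  for (key in unique(paste(f$geneA, f$geneB))) {
    rows <- f[paste(f$geneA, f$geneB) == key, , drop = FALSE]
    best <- rows[which.max(rows$score), , drop = FALSE]
    out[[length(out) + 1L]] <- best
  }
  f <- do.call(rbind, out)
  p <- f$aSitePos
  e1 <- ifelse(f$direction_hat == -1, p + 1L, p - 1L)
  data.frame(
    genome = f$genome, geneA = f$geneA, geneB = f$geneB,
    strand = f$strand, direction = f$direction_hat, motif = f$motif,
    aSitePos = p,
    aSiteGenome = ifelse(f$strand == 1L, p, genomeLength - p + 1L),
    boundary = e1, score = f$score, N = f$N
  )
}

.empty_calls <- function() {
  data.frame(genome = character(), geneA = integer(), geneB = integer(),
             strand = integer(), direction = numeric(), motif = character(),
             aSitePos = integer(), aSiteGenome = integer(),
             boundary = integer(), score = numeric(), N = numeric())
}

#' Predict frameshift sites in a genome
#'
#' Runs the full pipeline on one genome: split joins, find overlap
#' regions, scan for motif candidates, featurize, classify, and report at
#' most one call per overlap region (the highest-scoring candidate whose
#' predicted class is not 0).
#'
#' @param genome A [GenomeRecord-class].
#' @param model A trained [PRFModel-class].
#' @param config A [prfConfig()] list.
#' @return data.frame of calls: `genome`, `geneA`, `geneB`, `strand`,
#'   predicted `direction`, `motif`, `aSitePos` (oriented), `aSiteGenome`
#'   (genome coordinate of the A-site codon start), `boundary` (oriented
#'   implied fragment-1 end), `score` and `N`.
#' @export
predictGenome <- function(genome, model, config = prfConfig()) {
  prep <- prepareGenome(genome, config)
  if (!nrow(prep$features)) return(.empty_calls())
  probs <- predictProb(model, prep$features)
  .calls_from_features(prep$features, probs, length(genome@sequence))
}

#' Leave-one-group-out validation
#'
#' For each group: train on all other groups' genomes, predict on the
#' held-out genomes, merge.  A prediction counts as a true positive when
#' it lies on an annotated joined-gene pair within `config$labelRadius`
#' bases of the annotated shift; other predictions are false positives;
#' annotated shifts with no matching prediction are false negatives;
#' overlap regions with neither annotation nor prediction are true
#' negatives.
#'
#' @param genomes List of [GenomeRecord-class] objects.
#' @param groups Vector of group labels, one per genome (e.g. cluster ids
#'   from [clusterGenomes()], or genome names for GENOME-level
#'   validation).
#' @param config A [prfConfig()] list.
#' @param level Label stored in the result (e.g. "MASH95", "GENOME").
#' @param preps Optional precomputed [prepareGenome()] results (one per
#'   genome), to reuse featurization across levels.
#' @return List with `calls` (merged predictions), `confusion` (named
#'   TP/FP/TN/FN counts), `recall`, `precision` and `level`.
#' @export
validateCorpus <- function(genomes, groups, config = prfConfig(),
                           level = "GROUP", preps = NULL) {
  stopifnot(length(genomes) == length(groups))
  ug <- unique(groups)
  if (length(ug) < 2L) stop("need at least two groups to hold one out")
  if (is.null(preps)) preps <- lapply(genomes, prepareGenome, config = config)
  all_calls <- list()
  for (g in ug) {
    tr <- which(groups != g)
    te <- which(groups == g)
    trainFeats <- do.call(rbind, lapply(preps[tr], `[[`, "features"))
    model <- trainPRFModel(trainFeats, config = config)
    for (i in te) {
      f <- preps[[i]]$features
      if (!nrow(f)) next
      probs <- predictProb(model, f)
      calls <- .calls_from_features(f, probs,
                                    length(genomes[[i]]@sequence))
      if (nrow(calls)) {
        calls$genomeIdx <- i
        all_calls[[length(all_calls) + 1L]] <- calls
      }
    }
  }
  calls <- if (length(all_calls)) do.call(rbind, all_calls) else
    cbind(.empty_calls(), data.frame(genomeIdx = integer()))
  conf <- .confusion_counts(calls, preps, config$labelRadius)
  list(calls = calls, confusion = conf,
       recall = unname(conf["TP"] / max(1, conf["TP"] + conf["FN"])),
       precision = unname(conf["TP"] / max(1, conf["TP"] + conf["FP"])),
       level = level)
}

.confusion_counts <- function(calls, preps, radius = 10L) {
  TP <- FP <- TN <- FN <- 0L
  for (i in seq_along(preps)) {
    truth <- preps[[i]]$truth
    regions <- preps[[i]]$regions
    gc <- calls[!is.na(calls$genomeIdx) & calls$genomeIdx == i, , drop = FALSE]
    matched <- rep(FALSE, nrow(truth))
    for (r in seq_len(nrow(gc))) {
      ti <- which(truth$geneA == gc$geneA[r] & truth$geneB == gc$geneB[r] &
                  abs(truth$boundary - gc$aSitePos[r]) <= radius)
      if (length(ti)) { TP <- TP + 1L; matched[ti[1]] <- TRUE }
      else FP <- FP + 1L
    }
    FN <- FN + sum(!matched)
    if (nrow(regions)) {
      neg <- !(paste(regions$geneA, regions$geneB) %in%
                 paste(truth$geneA, truth$geneB))
      called <- paste(regions$geneA, regions$geneB) %in%
        paste(gc$geneA, gc$geneB)
      TN <- TN + sum(neg & !called)
    }
  }
  c(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' Persist a model
#'
#' Saves the serialized booster together with the feature-column order,
#' motif id table, class levels, configuration and a schema version, so a
#' reloaded model cannot be applied to a drifted feature schema.
#'
#' @param model A [PRFModel-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(version = model@version, booster = model@booster,
               featureNames = model@featureNames,
               classLevels = model@classLevels,
               motifTable = model@motifTable, config = model@config),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @return `loadModel()`: the restored [PRFModel-class].
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, .MODEL_VERSION)) {
    stop("model file version '", x$version, "' not supported")
  }
  if (!identical(x$featureNames, featureColumns())) {
    stop("model feature schema does not match this package version")
  }
  new("PRFModel", booster = x$booster, featureNames = x$featureNames,
      classLevels = x$classLevels, motifTable = x$motifTable,
      config = x$config, version = x$version)
}
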