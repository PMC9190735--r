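# channels x timepoints x supertrials cube for one condition
stCube <- function(st, ci) {
  x <- st@data[ci, , , , drop = FALSE]
  dim(x) <- dim(x)[-1]
  aperm(x, c(2, 3, 1))
}

#' Construct an accuracy time course
#'
#' Wraps decoding accuracies (percent correct) into an
#' [AccuracyTimecourse-class]; mainly useful for assembling group data
#' from external sources or tests.
#'
#' @param values vector (one participant), participants x timepoints
#'   matrix, or 3-d array for temporal generalization.
#' @param timeMs time axis in ms.
#' @param scheme scheme label.
#' @param nRepetitions repetitions used to produce the values.
#' @return an [AccuracyTimecourse-class].
#' @export
accuracyTimecourse <- function(values, timeMs, scheme = "custom",
                               nRepetitions = 1L) {
  if (is.null(dim(values)))
    values <- matrix(values, nrow = 1)
  new("AccuracyTimecourse", values = values, timeMs = as.numeric(timeMs),
      scheme = scheme, nRepetitions = as.integer(nRepetitions))
}

#' Decode one super-trial partition
#'
#' Pairwise linear SVM decoding of a single [SuperTrialSet-class]:
#' for every condition pair and timepoint, the classifier is trained on
#' all but one super-trial per condition and tested on the held-out one
#' (leave-one-super-trial-out over all folds). Accuracies are averaged
#' over folds and condition pairs. This is one repetition of the full
#' scheme; [pairwiseDecode()] and [categoryDecode()] own the repetition
#' loop over fresh random partitions.
#'
#' @param st a [SuperTrialSet-class] with at least 2 conditions.
#' @param cost SVM cost parameter (fixed at 1 throughout the pipeline).
#' @return numeric vector of percent-correct per timepoint.
#' @export
decodeSuperTrials <- function(st, cost = 1) {
  stopifnot(is(st, "SuperTrialSet"))
  nc <- length(st@conditions)
  if (nc < 2L) stop("pairwise decoding needs at least 2 conditions")
  cubes <- lapply(seq_len(nc), function(ci) stCube(st, ci))
  as.numeric(cppAllPairsDecode(cubes, cost))
}

#' Time-resolved pairwise object decoding
#'
#' The object-level scheme: per repetition, trials are randomly
#' repartitioned into `nGroups` super-trials per object
#' ([makeObjectSupertrials()]), optionally noise-normalized, and all
#' object pairs are decoded with leave-one-super-trial-out
#' cross-validation at every timepoint. Accuracies are averaged over
#' folds, pairs and repetitions.
#'
#' @param epochs an [EpochArray-class] (one participant, one modality,
#'   one-back repeats removed).
#' @param nRepetitions number of random repartition repetitions
#'   (100 in the full scheme).
#' @param nGroups super-trials per condition.
#' @param cost SVM cost parameter.
#' @param normalizer optional [NoiseNormalizer-class] applied to the
#'   super-trials of every repetition.
#' @param seed integer seed, or NULL.
#' @return an [AccuracyTimecourse-class] (one participant row),
#'   scheme "object".
#' @export
pairwiseDecode <- function(epochs, nRepetitions = 100L, nGroups = 3L,
                           cost = 1, normalizer = NULL, seed = NULL) {
  stopifnot(is(epochs, "EpochArray"))
  nRepetitions <- as.integer(nRepetitions)
  acc <- 0
  for (r in seq_len(nRepetitions)) {
    st <- makeObjectSupertrials(epochs, nGroups,
                                seed = childSeed(seed, 11L, r))
    if (!is.null(normalizer))
      st <- applyNormalizer(st, normalizer)
    acc <- acc + decodeSuperTrials(st, cost)
  }
  accuracyTimecourse(acc / nRepetitions, epochs@timeMs, "object",
                     nRepetitions)
}

# single repetition of the category scheme for one dimension, working
# from the (cached) object averages
categoryRepAccuracy <- function(avg, labels, dimension, nGroups, cost,
                                normalizer, seed, timeMs) {
  st <- categorySupertrialsCore(avg, labels, dimension, nGroups, seed,
                                timeMs)
  if (!is.null(normalizer))
    st <- applyNormalizer(st, normalizer)
  as.numeric(cppPairDecode(stCube(st, 1L), stCube(st, 2L), cost))
}

#' Time-resolved category decoding
#'
#' The category-level scheme: trials are averaged per object, the object
#' averages within each level of a category dimension are randomly
#' partitioned into `nGroups` super-trials ([makeCategorySupertrials()]),
#' and the two levels are decoded with leave-one-super-trial-out
#' cross-validation, so training and testing never share an object.
#' The procedure runs over `nRepetitions` random partitions for each
#' dimension separately; the dimension-wise time courses are averaged
#' into a single category-information measure (or returned per dimension
#' with `average = FALSE`).
#'
#' @inheritParams pairwiseDecode
#' @param stimset the [StimulusSet-class] providing category labels.
#' @param dimensions category dimensions to decode (default: all).
#' @param average average the dimension-wise time courses (default TRUE).
#' @return an [AccuracyTimecourse-class] with scheme "category", or a
#'   named list of per-dimension time courses when `average = FALSE`.
#' @export
categoryDecode <- function(epochs, stimset, nRepetitions = 100L,
                           nGroups = 3L, cost = 1, normalizer = NULL,
                           seed = NULL,
                           dimensions = dimensionNames(stimset),
                           average = TRUE) {
  stopifnot(is(epochs, "EpochArray"), is(stimset, "StimulusSet"))
  nRepetitions <- as.integer(nRepetitions)
  avg <- objectAverages(epochs)
  labs <- categoryLabels(stimset)
  perDim <- lapply(seq_along(dimensions), function(di) {
    labels <- labs[avg$objects, dimensions[di]]
    acc <- 0
    for (r in seq_len(nRepetitions)) {
      acc <- acc + categoryRepAccuracy(
        avg, labels, dimensions[di], nGroups, cost, normalizer,
        seed = childSeed(seed, 13L, di, r), timeMs = epochs@timeMs)
    }
    accuracyTimecourse(acc / nRepetitions, epochs@timeMs,
                       paste0("category:", dimensions[di]), nRepetitions)
  })
  names(perDim) <- dimensions
  if (!average) return(perDim)
  avg <- Reduce(`+`, lapply(perDim, function(a) a@values)) /
    length(perDim)
  accuracyTimecourse(avg, epochs@timeMs, "category", nRepetitions)
}

#' Leave-one-object-out category decoding
#'
#' Variant category scheme: per category dimension, the classifier is
#' trained on the object-averaged patterns of all objects but one,
#' labeled by category level, and tested on the held-out object's
#' average; accuracies are averaged over held-out objects. Because the
#' tested object never enters training, above-chance accuracy reflects
#' category structure that generalizes across objects. The scheme is
#' deterministic (no random partitioning).
#'
#' @inheritParams categoryDecode
#' @param dimension the category dimension to decode.
#' @return an [AccuracyTimecourse-class], scheme
#'   "category-loo:<dimension>".
#' @export
leaveOneObjectOutDecode <- function(epochs, stimset, dimension,
                                    cost = 1, normalizer = NULL) {
  stopifnot(is(epochs, "EpochArray"), is(stimset, "StimulusSet"))
  if (!dimension %in% dimensionNames(stimset))
    stop(sprintf("dimension '%s' not present in the stimulus set",
                 dimension))
  avg <- objectAverages(epochs)
  labels <- categoryLabels(stimset)[avg$objects, dimension]
  if (min(table(labels)) < 2L)
    stop("need at least 2 objects per level")
  X <- aperm(avg$data, c(2, 3, 1))          # channels x time x objects
  if (!is.null(normalizer)) {
    W <- whiteningMatrix(normalizer)
    d <- dim(X)
    X <- array(W %*% matrix(X, nrow = d[1]), dim = d)
  }
  y <- ifelse(labels == levels(labels)[1], 1, -1)
  acc <- as.numeric(cppLoocvDecode(X, y, cost))
  accuracyTimecourse(acc, epochs@timeMs,
                     paste0("category-loo:", dimension), 1L)
}

checkSameAxis <- function(a, b) {
  if (!isTRUE(all.equal(a@timeMs, b@timeMs)))
    stop("the two modalities must share the same time axis")
}

# build the category super-trial pair (levels 1 and 2) for both
# modalities with the per-(dimension, repetition) seeds shared by the
# cross-modal and temporal-generalization schemes
crossmodalSupertrials <- function(avgA, avgB, labels, dimension, timeMs,
                                  nGroups, normalizerA, normalizerB,
                                  seedA, seedB) {
  stA <- categorySupertrialsCore(avgA, labels, dimension, nGroups,
                                 seedA, timeMs)
  stB <- categorySupertrialsCore(avgB, labels, dimension, nGroups,
                                 seedB, timeMs)
  if (!is.null(normalizerA)) stA <- applyNormalizer(stA, normalizerA)
  if (!is.null(normalizerB)) stB <- applyNormalizer(stB, normalizerB)
  list(A1 = stCube(stA, 1L), A2 = stCube(stA, 2L),
       B1 = stCube(stB, 1L), B2 = stCube(stB, 2L))
}

#' Cross-modal category decoding
#'
#' Trains the classifier on the category super-trials of one modality
#' and tests it on those of the other modality at the same timepoint
#' (no cross-validation folds: all super-trials of the training modality
#' train, all of the test modality test). Both train/test directions are
#' computed and averaged, per dimension and repetition. Above-chance
#' accuracy indicates a category code shared between the modalities.
#'
#' @param epochsA,epochsB [EpochArray-class] objects for the two
#'   modalities of the same participant, on identical time axes.
#' @inheritParams categoryDecode
#' @param normalizerA,normalizerB optional per-modality
#'   [NoiseNormalizer-class] objects.
#' @return an [AccuracyTimecourse-class], scheme "crossmodal".
#' @export
crossmodalDecode <- function(epochsA, epochsB, stimset,
                             nRepetitions = 100L, nGroups = 3L,
                             cost = 1, normalizerA = NULL,
                             normalizerB = NULL, seed = NULL,
                             dimensions = dimensionNames(stimset)) {
  stopifnot(is(epochsA, "EpochArray"), is(epochsB, "EpochArray"))
  checkSameAxis(epochsA, epochsB)
  nRepetitions <- as.integer(nRepetitions)
  avgA <- objectAverages(epochsA)
  avgB <- objectAverages(epochsB)
  if (!identical(avgA$objects, avgB$objects))
    stop("the two modalities must cover the same object conditions")
  labs <- categoryLabels(stimset)
  acc <- 0
  for (di in seq_along(dimensions)) {
    labels <- labs[avgA$objects, dimensions[di]]
    for (r in seq_len(nRepetitions)) {
      cs <- crossmodalSupertrials(
        avgA, avgB, labels, dimensions[di], epochsA@timeMs, nGroups,
        normalizerA, normalizerB,
        seedA = childSeed(seed, 17L, di, r),
        seedB = childSeed(seed, 17L, di, r, 2L))
      ab <- cppPairCrossDecode(cs$A1, cs$A2, cs$B1, cs$B2, cost)
      ba <- cppPairCrossDecode(cs$B1, cs$B2, cs$A1, cs$A2, cost)
      acc <- acc + (ab + ba) / 2
    }
  }
  accuracyTimecourse(
    as.numeric(acc) / (length(dimensions) * nRepetitions),
    epochsA@timeMs, "crossmodal", nRepetitions)
}

#' Cross-modal temporal generalization
#'
#' Like [crossmodalDecode()], but the classifier trained at each
#' timepoint of one modality is tested at every timepoint of the other,
#' yielding a train-time x test-time accuracy matrix (averaged over both
#' train/test directions, dimensions and repetitions). The matrix
#' diagonal reproduces the cross-modal time course for the same seed.
#'
#' @inheritParams crossmodalDecode
#' @return an [AccuracyTimecourse-class] whose values are a
#'   1 x train-time x test-time array, scheme "generalization".
#' @export
temporalGeneralization <- function(epochsA, epochsB, stimset,
                                   nRepetitions = 100L, nGroups = 3L,
                                   cost = 1, normalizerA = NULL,
                                   normalizerB = NULL, seed = NULL,
                                   dimensions = dimensionNames(stimset)) {
  stopifnot(is(epochsA, "EpochArray"), is(epochsB, "EpochArray"))
  checkSameAxis(epochsA, epochsB)
  nRepetitions <- as.integer(nRepetitions)
  avgA <- objectAverages(epochsA)
  avgB <- objectAverages(epochsB)
  if (!identical(avgA$objects, avgB$objects))
    stop("the two modalities must cover the same object conditions")
  labs <- categoryLabels(stimset)
  acc <- 0
  for (di in seq_along(dimensions)) {
    labels <- labs[avgA$objects, dimensions[di]]
    for (r in seq_len(nRepetitions)) {
      cs <- crossmodalSupertrials(
        avgA, avgB, labels, dimensions[di], epochsA@timeMs, nGroups,
        normalizerA, normalizerB,
        seedA = childSeed(seed, 17L, di, r),
        seedB = childSeed(seed, 17L, di, r, 2L))
      ab <- cppPairTimeGen(cs$A1, cs$A2, cs$B1, cs$B2, cost)
      ba <- cppPairTimeGen(cs$B1, cs$B2, cs$A1, cs$A2, cost)
      acc <- acc + (ab + ba) / 2
    }
  }
  acc <- acc / (length(dimensions) * nRepetitions)
  vals <- array(acc, dim = c(1L, nrow(acc), ncol(acc)))
  new("AccuracyTimecourse", values = vals, timeMs = epochsA@timeMs,
      scheme = "generalization", nRepetitions = nRepetitions)
}

#' Stack per-participant accuracy time courses
#'
#' @param accList list of [AccuracyTimecourse-class] objects on the same
#'   time axis and scheme, one (or more) participant rows each.
#' @return an [AccuracyTimecourse-class] with all participant rows.
#' @export
bindParticipants <- function(accList) {
  stopifnot(length(accList) >= 1L)
  t0 <- accList[[1]]@timeMs
  for (a in accList) {
    if (!isTRUE(all.equal(a@timeMs, t0)))
      stop("time axes differ across participants")
  }
  d0 <- dim(accList[[1]]@values)
  if (length(d0) == 2L) {
    vals <- do.call(rbind, lapply(accList, function(a) a@values))
  } else {
    n <- sum(vapply(accList, function(a) dim(a@values)[1], 1L))
    vals <- array(0, dim = c(n, d0[2], d0[3]))
    at <- 1L
    for (a in accList) {
      k <- dim(a@values)[1]
      vals[at:(at + k - 1L), , ] <- a@values
      at <- at + k
    }
  }
  new("AccuracyTimecourse", values = vals, timeMs = t0,
      scheme = accList[[1]]@scheme,
      nRepetitions = accList[[1]]@nRepetitions)
}
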