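#' @import methods
NULL

#' Experimental design parameters
#'
#' Container for the structural parameters of a two-modality epoched
#' recording session: stimulus-set size, category dimensions, runs per
#' modality, presentations per stimulus per run, one-back repetition rate,
#' epoch window, sampling rates and channel count.
#'
#' @slot nObjects number of object conditions.
#' @slot nDims number of orthogonal binary category dimensions.
#' @slot runsPerModality named integer vector, runs per modality.
#' @slot repsPerStimPerRun presentations of each stimulus per run
#'   (one-back repeats not counted).
#' @slot onebackFraction fraction of all trials that are one-back repeats,
#'   in \[0, 0.5).
#' @slot epochWindow numeric length-2, epoch start/end in ms relative to
#'   stimulus onset (start < 0 < end).
#' @slot fsRaw acquisition sampling rate, Hz.
#' @slot fsTarget analysis sampling rate after downsampling, Hz.
#' @slot nChannels number of recording channels.
#'
#' @seealso [designSpec()]
#' @exportClass DesignSpec
setClass("DesignSpec",
  representation(
    nObjects = "integer",
    nDims = "integer",
    runsPerModality = "integer",
    repsPerStimPerRun = "integer",
    onebackFraction = "numeric",
    epochWindow = "numeric",
    fsRaw = "numeric",
    fsTarget = "numeric",
    nChannels = "integer"
  )
)

setValidity("DesignSpec", function(object) {
  msg <- character()
  if (object@nObjects < 1L || object@nDims < 1L || object@nChannels < 1L ||
      object@repsPerStimPerRun < 1L || any(object@runsPerModality < 1L))
    msg <- c(msg, "all counts must be positive")
  if (is.null(names(object@runsPerModality)) ||
      any(!nzchar(names(object@runsPerModality))))
    msg <- c(msg, "runsPerModality must be a named vector")
  if (object@onebackFraction < 0 || object@onebackFraction >= 0.5)
    msg <- c(msg, "onebackFraction must lie in [0, 0.5)")
  if (length(object@epochWindow) != 2L ||
      !(object@epochWindow[1] < 0 && 0 < object@epochWindow[2]))
    msg <- c(msg, "epochWindow must satisfy start < 0 < end")
  if (object@fsTarget > object@fsRaw)
    msg <- c(msg, "fsTarget cannot exceed fsRaw")
  if (length(msg)) msg else TRUE
})

#' Balanced stimulus set
#'
#' A set of object conditions, each carrying one binary level on each of
#' several orthogonal category dimensions. Balance is enforced: every
#' dimension splits the objects exactly in half, and every combination of
#' levels is assigned to the same number of objects.
#'
#' @slot objectIds character vector of object condition identifiers.
#' @slot categoryLabels data.frame of factors (one column per dimension,
#'   one row per object, rownames = objectIds), each with exactly two levels.
#'
#' @seealso [buildStimulusSet()]
#' @exportClass StimulusSet
setClass("StimulusSet",
  representation(
    objectIds = "character",
    categoryLabels = "data.frame"
  )
)

setValidity("StimulusSet", function(object) {
  msg <- character()
  n <- length(object@objectIds)
  if (anyDuplicated(object@objectIds))
    msg <- c(msg, "objectIds must be unique")
  if (nrow(object@categoryLabels) != n)
    msg <- c(msg, "categoryLabels must have one row per object")
  if (!identical(rownames(object@categoryLabels), object@objectIds))
    msg <- c(msg, "categoryLabels rownames must equal objectIds")
  for (d in names(object@categoryLabels)) {
    f <- object@categoryLabels[[d]]
    if (!is.factor(f) || nlevels(f) != 2L) {
      msg <- c(msg, sprintf("dimension '%s' must be a two-level factor", d))
      next
    }
    if (any(is.na(f)))
      msg <- c(msg, sprintf("dimension '%s' has missing levels", d))
    tab <- table(f)
    if (length(unique(tab)) != 1L)
      msg <- c(msg, sprintf("dimension '%s' does not split objects 50/50", d))
  }
  nd <- ncol(object@categoryLabels)
  if (nd > 0L && n %% (2L^nd) == 0L) {
    combo <- interaction(object@categoryLabels, drop = FALSE)
    if (length(unique(table(combo))) != 1L)
      msg <- c(msg, "level combinations are not equally represented")
  }
  if (length(msg)) msg else TRUE
})

#' Generative signal model for synthetic epochs
#'
#' Describes the multivariate patterns planted into simulated epochs: a
#' channel pattern per object, a channel pattern per category level on each
#' dimension, onset latencies and a linear ramp for the temporal envelope,
#' per-modality channel mixing matrices (shared or orthogonal subspaces),
#' a channel noise covariance, and a global signal gain (snr).
#'
#' @slot objectPatterns channels x objects matrix (colnames = object ids).
#' @slot categoryPatterns named list, per dimension a channels x 2 matrix
#'   (colnames = the two level names).
#' @slot objectOnsetMs,categoryOnsetMs onset latencies in ms.
#' @slot rampMs linear onset ramp duration in ms (0 = step).
#' @slot modalityCodes named list of channels x channels mixing matrices.
#' @slot noiseCov channels x channels symmetric positive-definite matrix.
#' @slot snr scalar signal gain multiplying the planted patterns.
#'
#' @seealso [signalModel()], [simulateEpochs()]
#' @exportClass SignalModel
setClass("SignalModel",
  representation(
    objectPatterns = "matrix",
    categoryPatterns = "list",
    objectOnsetMs = "numeric",
    categoryOnsetMs = "numeric",
    rampMs = "numeric",
    modalityCodes = "list",
    noiseCov = "matrix",
    snr = "numeric"
  )
)

setValidity("SignalModel", function(object) {
  msg <- character()
  C <- nrow(object@objectPatterns)
  if (!isSymmetric(unname(object@noiseCov), tol = 1e-8))
    msg <- c(msg, "noiseCov must be symmetric")
  else {
    ev <- eigen(object@noiseCov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      msg <- c(msg, "noiseCov must be positive-definite")
  }
  if (nrow(object@noiseCov) != C)
    msg <- c(msg, "noiseCov dimension must match channel count")
  for (m in object@modalityCodes)
    if (!is.matrix(m) || any(dim(m) != C))
      msg <- c(msg, "modalityCodes must be channels x channels matrices")
  for (p in object@categoryPatterns)
    if (!is.matrix(p) || nrow(p) != C || ncol(p) != 2L)
      msg <- c(msg, "categoryPatterns must be channels x 2 matrices")
  if (object@snr < 0) msg <- c(msg, "snr must be non-negative")
  if (object@rampMs < 0) msg <- c(msg, "rampMs must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Epoched multichannel data
#'
#' A trials x channels x timepoints array with its time axis, sampling
#' rate, per-trial metadata and participant identifier.
#'
#' @slot data 3-d numeric array, trials x channels x timepoints.
#' @slot timeMs strictly increasing, uniformly spaced time axis in ms.
#' @slot fs sampling rate in Hz; spacing of timeMs is 1000/fs.
#' @slot trialMeta data.frame with columns run, modality, object_id,
#'   is_oneback_repeat, trial_index; one row per trial.
#' @slot participantId character scalar.
#'
#' @seealso [simulateEpochs()], [rejectArtifacts()], [downsampleEpochs()]
#' @exportClass EpochArray
setClass("EpochArray",
  representation(
    data = "array",
    timeMs = "numeric",
    fs = "numeric",
    trialMeta = "data.frame",
    participantId = "character"
  )
)

setValidity("EpochArray", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trials x channels x timepoints array")
  else {
    if (length(object@timeMs) != d[3])
      msg <- c(msg, "timeMs length must equal the time dimension")
    if (nrow(object@trialMeta) != d[1])
      msg <- c(msg, "trialMeta must have one row per trial")
  }
  if (length(object@timeMs) > 1L) {
    dt <- diff(object@timeMs)
    if (any(dt <= 0))
      msg <- c(msg, "time axis must be strictly increasing")
    else if (max(abs(dt - 1000 / object@fs)) > 1e-6)
      msg <- c(msg, "time axis spacing must equal 1000/fs ms")
  }
  need <- c("run", "modality", "object_id", "is_oneback_repeat", "trial_index")
  if (!all(need %in% names(object@trialMeta)))
    msg <- c(msg, paste("trialMeta must contain columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Super-trial (pseudo-trial) set
#'
#' Averaged pattern exemplars per condition: for every condition, a fixed
#' number of super-trials over channels x timepoints, with the provenance
#' (which raw trials or object averages entered each super-trial).
#'
#' @slot conditions condition labels (object ids, or the two levels of one
#'   category dimension).
#' @slot data 4-d array, condition x supertrial x channels x timepoints.
#' @slot timeMs time axis in ms.
#' @slot scheme "object" or "category".
#' @slot dimension category dimension name (NA for the object scheme).
#' @slot provenance list (per condition) of lists (per super-trial) of the
#'   source trial indices or object ids averaged into it.
#' @slot normalized logical; TRUE once a noise normalizer has been applied
#'   (guards against double application).
#'
#' @seealso [makeObjectSupertrials()], [makeCategorySupertrials()]
#' @exportClass SuperTrialSet
setClass("SuperTrialSet",
  representation(
    conditions = "character",
    data = "array",
    timeMs = "numeric",
    scheme = "character",
    dimension = "character",
    provenance = "list",
    normalized = "logical"
  )
)

setValidity("SuperTrialSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L)
    msg <- c(msg, "data must be condition x supertrial x channels x time")
  else {
    if (d[1] != length(object@conditions))
      msg <- c(msg, "first dimension must match conditions")
    if (d[4] != length(object@timeMs))
      msg <- c(msg, "fourth dimension must match timeMs")
  }
  if (length(object@provenance) != length(object@conditions))
    msg <- c(msg, "provenance must have one entry per condition")
  else if (length(d) == 4L) {
    for (i in seq_along(object@provenance)) {
      pv <- object@provenance[[i]]
      if (length(pv) != d[2]) {
        msg <- c(msg, "provenance must list sources for every super-trial")
        break
      }
      src <- unlist(pv)
      if (anyDuplicated(src))
        msg <- c(msg, sprintf(
          "condition '%s': a source contributes to more than one super-trial",
          object@conditions[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Multivariate noise normalizer
#'
#' A whitening transform estimated from within-condition residuals:
#' per-timepoint channel covariances with analytic (Ledoit-Wolf) shrinkage
#' toward a scaled identity, averaged over timepoints, inverted via the
#' symmetric matrix square root.
#'
#' @slot whiteningTransform channels x channels symmetric positive-definite
#'   matrix (the inverse square root of the shrunk covariance).
#' @slot shrinkageIntensity average shrinkage weight in \[0, 1\].
#' @slot source description of the residuals the transform was fit on.
#'
#' @seealso [fitNoiseNormalizer()], [applyNormalizer()]
#' @exportClass NoiseNormalizer
setClass("NoiseNormalizer",
  representation(
    whiteningTransform = "matrix",
    shrinkageIntensity = "numeric",
    source = "character"
  )
)

setValidity("NoiseNormalizer", function(object) {
  msg <- character()
  W <- object@whiteningTransform
  if (!isSymmetric(unname(W), tol = 1e-6))
    msg <- c(msg, "whiteningTransform must be symmetric")
  else {
    ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      msg <- c(msg, "whiteningTransform must be positive-definite")
  }
  if (object@shrinkageIntensity < 0 || object@shrinkageIntensity > 1)
    msg <- c(msg, "shrinkageIntensity must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Decoding accuracy time course
#'
#' Percent-correct decoding accuracy per participant and timepoint, or per
#' participant and train x test timepoint pair for temporal generalization.
#'
#' @slot values participants x timepoints matrix, or a participants x
#'   train-timepoints x test-timepoints array for generalization.
#' @slot timeMs time axis in ms (both axes for generalization).
#' @slot scheme label of the decoding scheme that produced the values.
#' @slot nRepetitions number of super-trial repartition repetitions used.
#'
#' @seealso [pairwiseDecode()], [categoryDecode()], [crossmodalDecode()]
#' @exportClass AccuracyTimecourse
setClass("AccuracyTimecourse",
  representation(
    values = "array",
    timeMs = "numeric",
    scheme = "character",
    nRepetitions = "integer"
  )
)

setValidity("AccuracyTimecourse", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (!(length(d) %in% c(2L, 3L)))
    msg <- c(msg, "values must be 2-d (time course) or 3-d (generalization)")
  else {
    nt <- length(object@timeMs)
    ok <- if (length(d) == 2L) d[2] == nt else d[2] == nt && d[3] == nt
    if (!ok) msg <- c(msg, "values dimensions must match timeMs")
  }
  v <- object@values
  if (any(!is.na(v) & (v < 0 | v > 100)))
    msg <- c(msg, "accuracies must lie in [0, 100] percent")
  if (length(msg)) msg else TRUE
})

#' Cluster-permutation inference result
#'
#' Output of the sign-flip cluster-size permutation test: the per-timepoint
#' significance mask, the candidate clusters with their sizes and
#' cluster-level p values, and the test parameters.
#'
#' @slot significantMask logical per timepoint.
#' @slot clusters data.frame with columns start_ms, end_ms, size, p,
#'   significant (all candidate clusters, significant or not).
#' @slot pointwiseP per-timepoint sign-flip p values (uncorrected).
#' @slot nPermutations,alpha,chance test parameters.
#' @slot timeMs time axis.
#' @slot statistic pointwise statistic used ("mean" or "t").
#'
#' @seealso [clusterPermutationTest()]
#' @exportClass ClusterInferenceResult
setClass("ClusterInferenceResult",
  representation(
    significantMask = "logical",
    clusters = "data.frame",
    pointwiseP = "numeric",
    nPermutations = "integer",
    alpha = "numeric",
    chance = "numeric",
    timeMs = "numeric",
    statistic = "character"
  )
)

setValidity("ClusterInferenceResult", function(object) {
  msg <- character()
  if (length(object@significantMask) != length(object@timeMs))
    msg <- c(msg, "significantMask length must equal timeMs")
  if (nrow(object@clusters) &&
      (any(object@clusters$p <= 0) || any(object@clusters$p > 1)))
    msg <- c(msg, "cluster p values must lie in (0, 1]")
  sig <- object@clusters[object@clusters$significant, , drop = FALSE]
  if (nrow(sig)) {
    dt <- if (length(object@timeMs) > 1L) diff(object@timeMs)[1] else 1
    covered <- unlist(lapply(seq_len(nrow(sig)), function(i)
      which(object@timeMs >= sig$start_ms[i] - dt / 2 &
            object@timeMs <= sig$end_ms[i] + dt / 2)))
    if (anyDuplicated(covered) ||
        !setequal(covered, which(object@significantMask)))
      msg <- c(msg, "significant timepoints must partition into clusters")
  } else if (any(object@significantMask)) {
    msg <- c(msg, "mask marks timepoints but no cluster is significant")
  }
  if (length(msg)) msg else TRUE
})

#' Bootstrap peak-latency comparison
#'
#' Result of the participant-bootstrap test for a difference in the peak
#' latency of two group-mean decoding time courses.
#'
#' @slot peakMsA,peakMsB peak latencies (ms) of the observed group means.
#' @slot bootDifferences per-bootstrap peak-latency differences (A - B), ms.
#' @slot pOneTailed fraction of bootstrap differences on the hypothesized
#'   side (strict inequality).
#' @slot nBootstrap number of bootstrap samples.
#' @slot alternative "greater" (A peaks later than B) or "less".
#' @slot degenerate TRUE when a time course was flat (peak tie-broken to
#'   the earliest timepoint) or all differences were exactly zero.
#'
#' @seealso [bootstrapPeakLatencyDifference()]
#' @exportClass PeakLatencyTest
setClass("PeakLatencyTest",
  representation(
    peakMsA = "numeric",
    peakMsB = "numeric",
    bootDifferences = "numeric",
    pOneTailed = "numeric",
    nBootstrap = "integer",
    alternative = "character",
    degenerate = "logical"
  )
)

setValidity("PeakLatencyTest", function(object) {
  msg <- character()
  if (length(object@bootDifferences) != object@nBootstrap)
    msg <- c(msg, "bootDifferences length must equal nBootstrap")
  if (object@pOneTailed < 0 || object@pOneTailed > 1)
    msg <- c(msg, "pOneTailed must lie in [0, 1]")
  if (!object@alternative %in% c("greater", "less"))
    msg <- c(msg, "alternative must be 'greater' or 'less'")
  if (length(msg)) msg else TRUE
})
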