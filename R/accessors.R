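#' Time axis of an object
#'
#' @param x an [EpochArray-class], [SuperTrialSet-class],
#'   [AccuracyTimecourse-class] or [ClusterInferenceResult-class].
#' @return numeric vector of timepoints in ms.
#' @name timePoints
NULL

#' @rdname timePoints
#' @export
setMethod("timePoints", "EpochArray", function(x) x@timeMs)
#' @rdname timePoints
#' @export
setMethod("timePoints", "SuperTrialSet", function(x) x@timeMs)
#' @rdname timePoints
#' @export
setMethod("timePoints", "AccuracyTimecourse", function(x) x@timeMs)
#' @rdname timePoints
#' @export
setMethod("timePoints", "ClusterInferenceResult", function(x) x@timeMs)

#' Sampling rate in Hz
#'
#' @param x an [EpochArray-class].
#' @return numeric scalar.
#' @name samplingRate
NULL

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochArray", function(x) x@fs)

#' Trial metadata table
#'
#' @param x an [EpochArray-class].
#' @return data.frame with columns run, modality, object_id,
#'   is_oneback_repeat, trial_index.
#' @name trialInfo
NULL

#' @rdname trialInfo
#' @export
setMethod("trialInfo", "EpochArray", function(x) x@trialMeta)

#' Raw epoch array
#'
#' @param x an [EpochArray-class].
#' @return trials x channels x timepoints numeric array.
#' @name epochData
NULL

#' @rdname epochData
#' @export
setMethod("epochData", "EpochArray", function(x) x@data)

#' Object condition identifiers
#'
#' @param x a [StimulusSet-class].
#' @return character vector.
#' @name objectIds
NULL

#' @rdname objectIds
#' @export
setMethod("objectIds", "StimulusSet", function(x) x@objectIds)

#' Category label table
#'
#' @param x a [StimulusSet-class].
#' @return data.frame of two-level factors, one column per dimension.
#' @name categoryLabels
NULL

#' @rdname categoryLabels
#' @export
setMethod("categoryLabels", "StimulusSet", function(x) x@categoryLabels)

#' Category dimension names
#'
#' @param x a [StimulusSet-class].
#' @return character vector of dimension names.
#' @name dimensionNames
NULL

#' @rdname dimensionNames
#' @export
setMethod("dimensionNames", "StimulusSet",
          function(x) names(x@categoryLabels))

#' Condition labels of a super-trial set
#'
#' @param x a [SuperTrialSet-class].
#' @return character vector.
#' @name conditionNames
NULL

#' @rdname conditionNames
#' @export
setMethod("conditionNames", "SuperTrialSet", function(x) x@conditions)

#' Super-trial data array
#'
#' @param x a [SuperTrialSet-class].
#' @return condition x supertrial x channels x timepoints array.
#' @name supertrialData
NULL

#' @rdname supertrialData
#' @export
setMethod("supertrialData", "SuperTrialSet", function(x) x@data)

#' Super-trial provenance
#'
#' The raw-trial indices (object scheme) or object ids (category scheme)
#' averaged into each super-trial.
#'
#' @param x a [SuperTrialSet-class].
#' @return list per condition of lists per super-trial.
#' @name provenance
NULL

#' @rdname provenance
#' @export
setMethod("provenance", "SuperTrialSet", function(x) x@provenance)

#' Whitening transform of a noise normalizer
#'
#' @param x a [NoiseNormalizer-class].
#' @return channels x channels matrix.
#' @name whiteningMatrix
NULL

#' @rdname whiteningMatrix
#' @export
setMethod("whiteningMatrix", "NoiseNormalizer",
          function(x) x@whiteningTransform)

#' Shrinkage intensity of a noise normalizer
#'
#' @param x a [NoiseNormalizer-class].
#' @return numeric scalar in \[0, 1\].
#' @name shrinkageIntensity
NULL

#' @rdname shrinkageIntensity
#' @export
setMethod("shrinkageIntensity", "NoiseNormalizer",
          function(x) x@shrinkageIntensity)

#' Accuracy values
#'
#' @param x an [AccuracyTimecourse-class].
#' @return participants x timepoints matrix (percent correct), or a 3-d
#'   array for temporal generalization.
#' @name accuracyValues
NULL

#' @rdname accuracyValues
#' @export
setMethod("accuracyValues", "AccuracyTimecourse", function(x) x@values)

#' Decoding scheme label
#'
#' @param x an [AccuracyTimecourse-class].
#' @return character scalar.
#' @name decodingScheme
NULL

#' @rdname decodingScheme
#' @export
setMethod("decodingScheme", "AccuracyTimecourse", function(x) x@scheme)

#' Per-timepoint significance mask
#'
#' @param x a [ClusterInferenceResult-class].
#' @return logical vector.
#' @name significantMask
NULL

#' @rdname significantMask
#' @export
setMethod("significantMask", "ClusterInferenceResult",
          function(x) x@significantMask)

#' Candidate cluster table
#'
#' @param x a [ClusterInferenceResult-class].
#' @return data.frame with columns start_ms, end_ms, size, p, significant.
#' @name clusterTable
NULL

#' @rdname clusterTable
#' @export
setMethod("clusterTable", "ClusterInferenceResult", function(x) x@clusters)

#' Uncorrected pointwise sign-flip p values
#'
#' @param x a [ClusterInferenceResult-class].
#' @return numeric vector, one p per timepoint.
#' @name pointwiseP
NULL

#' @rdname pointwiseP
#' @export
setMethod("pointwiseP", "ClusterInferenceResult", function(x) x@pointwiseP)

#' Observed peak latencies
#'
#' @param x a [PeakLatencyTest-class].
#' @return named numeric vector c(A = ..., B = ...) in ms.
#' @name peakLatencies
NULL

#' @rdname peakLatencies
#' @export
setMethod("peakLatencies", "PeakLatencyTest",
          function(x) c(A = x@peakMsA, B = x@peakMsB))

#' Bootstrap peak-latency differences
#'
#' @param x a [PeakLatencyTest-class].
#' @return numeric vector of per-bootstrap differences (A - B), ms.
#' @name bootDifferences
NULL

#' @rdname bootDifferences
#' @export
setMethod("bootDifferences", "PeakLatencyTest",
          function(x) x@bootDifferences)
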