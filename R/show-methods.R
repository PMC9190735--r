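setMethod("show", "DesignSpec", function(object) {
  cat("DesignSpec\n")
  cat("  objects:", object@nObjects, "across", object@nDims,
      "binary category dimensions\n")
  rp <- object@runsPerModality
  cat("  runs:", paste(sprintf("%s=%d", names(rp), rp), collapse = ", "),
      sprintf("(%d presentations/stimulus/run, one-back %.0f%%)\n",
              object@repsPerStimPerRun, 100 * object@onebackFraction))
  cat(sprintf("  epoch: [%g, %g] ms, %g Hz -> %g Hz, %d channels\n",
              object@epochWindow[1], object@epochWindow[2],
              object@fsRaw, object@fsTarget, object@nChannels))
})

setMethod("show", "StimulusSet", function(object) {
  cat("StimulusSet with", length(object@objectIds), "objects,",
      ncol(object@categoryLabels), "dimensions:",
      paste(names(object@categoryLabels), collapse = ", "), "\n")
})

setMethod("show", "SignalModel", function(object) {
  cat("SignalModel\n")
  cat(sprintf("  %d channels, %d objects, %d category dimensions\n",
              nrow(object@objectPatterns), ncol(object@objectPatterns),
              length(object@categoryPatterns)))
  cat(sprintf("  onsets: object %g ms, category %g ms (ramp %g ms)\n",
              object@objectOnsetMs, object@categoryOnsetMs, object@rampMs))
  cat(sprintf("  snr %g, modalities: %s\n", object@snr,
              paste(names(object@modalityCodes), collapse = ", ")))
})

setMethod("show", "EpochArray", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochArray '%s': %d trials x %d channels x %d timepoints @ %g Hz\n",
    object@participantId, d[1], d[2], d[3], object@fs))
  cat(sprintf("  window [%g, %g] ms; modalities: %s\n",
              min(object@timeMs), max(object@timeMs),
              paste(unique(object@trialMeta$modality), collapse = ", ")))
})

setMethod("show", "SuperTrialSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "SuperTrialSet (%s scheme%s): %d conditions x %d super-trials x %d channels x %d timepoints%s\n",
    object@scheme,
    if (!is.na(object@dimension)) paste0(", dimension '",
                                         object@dimension, "'") else "",
    d[1], d[2], d[3], d[4],
    if (object@normalized) ", noise-normalized" else ""))
})

setMethod("show", "NoiseNormalizer", function(object) {
  cat(sprintf(
    "NoiseNormalizer: %d channels, shrinkage intensity %.3f\n  fit on %s\n",
    nrow(object@whiteningTransform), object@shrinkageIntensity,
    object@source))
})

setMethod("show", "AccuracyTimecourse", function(object) {
  d <- dim(object@values)
  if (length(d) == 2L) {
    cat(sprintf(
      "AccuracyTimecourse '%s': %d participant(s) x %d timepoints (%d repetitions)\n",
      object@scheme, d[1], d[2], object@nRepetitions))
    cat(sprintf("  grand mean %.2f%%, range [%.1f, %.1f]%%\n",
                mean(object@values), min(object@values), max(object@values)))
  } else {
    cat(sprintf(
      "AccuracyTimecourse '%s' (temporal generalization): %d participant(s) x %d x %d timepoints\n",
      object@scheme, d[1], d[2], d[3]))
    cat(sprintf("  grand mean %.2f%%\n", mean(object@values)))
  }
})

setMethod("show", "ClusterInferenceResult", function(object) {
  sig <- object@clusters[object@clusters$significant, , drop = FALSE]
  cat(sprintf(
    "ClusterInferenceResult (%s statistic, %d permutations, alpha %.3g)\n",
    object@statistic, object@nPermutations, object@alpha))
  if (nrow(sig) == 0L) {
    cat("  no significant timepoints\n")
  } else {
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  cluster %d: %g to %g ms (size %d, p = %.4g)\n",
                  i, sig$start_ms[i], sig$end_ms[i], sig$size[i], sig$p[i]))
  }
})

setMethod("show", "PeakLatencyTest", function(object) {
  cat(sprintf(
    "PeakLatencyTest: peak A = %g ms, peak B = %g ms (%d bootstraps)\n",
    object@peakMsA, object@peakMsB, object@nBootstrap))
  cat(sprintf("  one-tailed p (A %s B) = %.4g%s\n",
              if (object@alternative == "greater") "later than" else
                "earlier than",
              object@pOneTailed,
              if (object@degenerate) " [degenerate: flat or tied input]"
              else ""))
})
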