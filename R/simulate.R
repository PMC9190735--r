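#' Simulate epoched multichannel data with planted representational
#' dynamics
#'
#' Generates one epoch per trial of `trials`: the object's channel pattern
#' switches on at the object onset and the summed category-level patterns
#' at the category onset (each with a linear ramp), the combined pattern is
#' projected through the trial's modality code, scaled by the model's snr,
#' and additive Gaussian noise with the model's channel covariance (white
#' across time) is added.
#'
#' @param trials trial table from [generateTrialSequence()] (or any
#'   data.frame with columns run, modality, object_id, is_oneback_repeat,
#'   trial_index).
#' @param stimset the [StimulusSet-class] the trials refer to.
#' @param model a [SignalModel-class].
#' @param design a [DesignSpec-class]; supplies the epoch window.
#' @param seed integer seed for the noise draw, or NULL.
#' @param participantId identifier stored in the result.
#' @param fs sampling rate of the simulated epochs (defaults to the
#'   design's acquisition rate; pass `design@fsTarget` to simulate
#'   directly on the analysis time axis).
#' @return an [EpochArray-class].
#' @examples
#' design <- designSpec(nObjects = 8, runsPerModality = c(auditory = 1),
#'                      repsPerStimPerRun = 2, nChannels = 8, fsRaw = 200)
#' ss <- buildStimulusSet(8, 3, seed = 1)
#' mod <- signalModel(ss, design, seed = 1)
#' tt <- generateTrialSequence(design, "auditory", seed = 1)
#' ep <- simulateEpochs(tt, ss, mod, design, seed = 1)
#' ep
#' @export
simulateEpochs <- function(trials, stimset, model, design, seed = NULL,
                           participantId = "sim01", fs = design@fsRaw) {
  stopifnot(is(stimset, "StimulusSet"), is(model, "SignalModel"),
            is(design, "DesignSpec"))
  C <- nrow(model@objectPatterns)
  if (C != design@nChannels)
    stop("channel count of model and design disagree")
  if (nrow(model@noiseCov) != C)
    stop("noise covariance does not match the channel count")
  ids <- unique(trials$object_id)
  if (!all(ids %in% colnames(model@objectPatterns)))
    stop("model object patterns do not cover all objects in the trials")
  dims <- dimensionNames(stimset)
  if (!all(dims %in% names(model@categoryPatterns)))
    stop("model category patterns do not cover all dimensions")
  mods <- unique(trials$modality)
  if (!all(mods %in% names(model@modalityCodes)))
    stop("model modality codes do not cover all modalities in the trials")

  timeMs <- seq(design@epochWindow[1], design@epochWindow[2],
                by = 1000 / fs)
  Tn <- length(timeMs)
  n <- nrow(trials)
  envObj <- onsetEnvelope(timeMs, model@objectOnsetMs, model@rampMs)
  envCat <- onsetEnvelope(timeMs, model@categoryOnsetMs, model@rampMs)
  labels <- categoryLabels(stimset)

  # deterministic signal per (object, modality), channels x time
  signalFor <- function(obj, modality) {
    pObj <- model@objectPatterns[, obj]
    pCat <- rowSums(vapply(dims, function(d) {
      lev <- as.character(labels[obj, d])
      model@categoryPatterns[[d]][, lev]
    }, numeric(C)))
    M <- model@modalityCodes[[modality]]
    model@snr * ((M %*% pObj) %*% t(envObj) + (M %*% pCat) %*% t(envCat))
  }
  sigCache <- new.env(parent = emptyenv())
  dat <- array(0, dim = c(n, C, Tn))
  L <- chol(model@noiseCov)
  withSeed(seed, {
    for (i in seq_len(n)) {
      key <- paste(trials$object_id[i], trials$modality[i], sep = "\r")
      sig <- sigCache[[key]]
      if (is.null(sig)) {
        sig <- signalFor(trials$object_id[i], trials$modality[i])
        sigCache[[key]] <- sig
      }
      noise <- crossprod(L, matrix(stats::rnorm(C * Tn), C, Tn))
      dat[i, , ] <- sig + noise
    }
  })
  new("EpochArray", data = dat, timeMs = timeMs, fs = fs,
      trialMeta = trials, participantId = participantId)
}

#' Subset trials of an EpochArray
#'
#' @param x an [EpochArray-class].
#' @param i trial indices (integer or logical).
#' @param j,...,drop ignored.
#' @return an [EpochArray-class] with the selected trials.
#' @export
setMethod("[", "EpochArray", function(x, i, j, ..., drop = FALSE) {
  meta <- x@trialMeta[i, , drop = FALSE]
  rownames(meta) <- NULL
  new("EpochArray", data = x@data[i, , , drop = FALSE],
      timeMs = x@timeMs, fs = x@fs, trialMeta = meta,
      participantId = x@participantId)
})

#' Drop one-back repetition trials
#'
#' One-back repeats serve the orthogonal attention task only and are
#' excluded before any analysis stage (before artifact rejection).
#'
#' @param epochs an [EpochArray-class].
#' @return an [EpochArray-class] containing only unflagged trials.
#' @export
dropOneBack <- function(epochs) {
  stopifnot(is(epochs, "EpochArray"))
  epochs[!epochs@trialMeta$is_oneback_repeat]
}

#' Simulate null group accuracy time courses
#'
#' Draws participant accuracy time courses around chance with temporally
#' autocorrelated (AR(1)) noise and no true effect, for calibrating the
#' family-wise error rate of the cluster permutation test.
#'
#' @param nParticipants number of participants.
#' @param timeMs time axis, or an integer count of timepoints.
#' @param sd stationary standard deviation of the accuracy noise
#'   (percentage points).
#' @param ar lag-1 autocorrelation of the noise across timepoints.
#' @param chance chance level in percent.
#' @param seed integer seed, or NULL.
#' @return an [AccuracyTimecourse-class] with scheme "null".
#' @export
simulateNullAccuracies <- function(nParticipants, timeMs, sd = 2,
                                   ar = 0.7, chance = 50, seed = NULL) {
  if (length(timeMs) == 1L) timeMs <- seq_len(timeMs) * 5
  Tn <- length(timeMs)
  stopifnot(abs(ar) < 1, sd >= 0)
  vals <- withSeed(seed, {
    innov <- matrix(stats::rnorm(nParticipants * Tn), nParticipants, Tn)
    x <- matrix(0, nParticipants, Tn)
    x[, 1] <- innov[, 1]
    if (Tn > 1L)
      for (t in 2:Tn)
        x[, t] <- ar * x[, t - 1] + sqrt(1 - ar^2) * innov[, t]
    chance + sd * x
  })
  vals <- pmin(pmax(vals, 0), 100)
  new("AccuracyTimecourse", values = vals, timeMs = timeMs,
      scheme = "null", nRepetitions = 0L)
}
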