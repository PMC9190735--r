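#' Construct an experimental design specification
#'
#' Defaults describe a two-modality session: 48 object conditions crossed
#' with 3 orthogonal binary category dimensions, 8 auditory and 6 visual
#' runs, 5 presentations of each stimulus per run plus 20% one-back
#' repetition trials (300 trials per run), epochs from -200 to 800 ms
#' around stimulus onset recorded at 1000 Hz from 63 channels and analyzed
#' at 200 Hz.
#'
#' @param nObjects number of object conditions; must be divisible by
#'   `2^nDims`.
#' @param nDims number of orthogonal binary category dimensions.
#' @param runsPerModality named integer vector of runs per modality.
#' @param repsPerStimPerRun presentations of each stimulus per run,
#'   excluding one-back repeats.
#' @param onebackFraction fraction of all trials that are one-back
#'   repetitions, in \[0, 0.5).
#' @param epochWindow epoch start/end in ms relative to stimulus onset.
#' @param fsRaw acquisition sampling rate (Hz).
#' @param fsTarget analysis sampling rate after downsampling (Hz).
#' @param nChannels number of recording channels.
#' @return a validated [DesignSpec-class].
#' @examples
#' design <- designSpec()
#' design
#' @export
designSpec <- function(nObjects = 48L,
                       nDims = 3L,
                       runsPerModality = c(auditory = 8L, visual = 6L),
                       repsPerStimPerRun = 5L,
                       onebackFraction = 0.20,
                       epochWindow = c(-200, 800),
                       fsRaw = 1000,
                       fsTarget = 200,
                       nChannels = 63L) {
  new("DesignSpec",
      nObjects = as.integer(nObjects),
      nDims = as.integer(nDims),
      runsPerModality = stats::setNames(as.integer(runsPerModality),
                                        names(runsPerModality)),
      repsPerStimPerRun = as.integer(repsPerStimPerRun),
      onebackFraction = onebackFraction,
      epochWindow = as.numeric(epochWindow),
      fsRaw = fsRaw,
      fsTarget = fsTarget,
      nChannels = as.integer(nChannels))
}

# Canonical object condition identifiers shared by the design generators.
makeObjectIds <- function(n) sprintf("obj%02d", seq_len(n))

defaultDimensionNames <- function(nDims) {
  base <- c("size", "movement", "naturalness")
  if (nDims <= length(base)) base[seq_len(nDims)]
  else c(base, sprintf("dim%d", seq(length(base) + 1L, nDims)))
}

defaultLevelNames <- function(dims) {
  known <- list(size = c("big", "small"),
                movement = c("moving", "nonmoving"),
                naturalness = c("natural", "manmade"))
  lapply(stats::setNames(dims, dims), function(d)
    known[[d]] %||% paste0(d, c("A", "B")))
}

#' Build a balanced stimulus set
#'
#' Assigns each object condition one level on each of `nDims` orthogonal
#' binary category dimensions such that every dimension splits the set
#' exactly in half and each combination of levels is carried by
#' `nObjects / 2^nDims` objects. The assignment of objects to level
#' combinations is randomized (deterministically for a given seed).
#'
#' @param nObjects number of objects; must be divisible by `2^nDims`.
#' @param nDims number of binary category dimensions.
#' @param seed integer seed for the random assignment, or NULL.
#' @param dimensions optional character vector of dimension names.
#' @return a validated [StimulusSet-class].
#' @examples
#' ss <- buildStimulusSet(48, 3, seed = 1)
#' table(categoryLabels(ss)$size)
#' @export
buildStimulusSet <- function(nObjects = 48L, nDims = 3L, seed = NULL,
                             dimensions = defaultDimensionNames(nDims)) {
  nObjects <- as.integer(nObjects)
  nDims <- as.integer(nDims)
  if (nDims < 1L) stop("nDims must be at least 1")
  if (length(dimensions) != nDims) stop("need one name per dimension")
  if (nObjects %% (2L^nDims) != 0L)
    stop(sprintf(
      "design error: nObjects (%d) must be divisible by 2^nDims (%d)",
      nObjects, 2L^nDims))
  levelNames <- defaultLevelNames(dimensions)
  perCombo <- nObjects %/% (2L^nDims)
  combos <- expand.grid(lapply(levelNames, function(l) l),
                        stringsAsFactors = FALSE)
  labels <- combos[rep(seq_len(nrow(combos)), each = perCombo), ,
                   drop = FALSE]
  ord <- withSeed(seed, sample.int(nObjects))
  labels <- labels[ord, , drop = FALSE]
  ids <- makeObjectIds(nObjects)
  rownames(labels) <- ids
  for (d in dimensions)
    labels[[d]] <- factor(labels[[d]], levels = levelNames[[d]])
  new("StimulusSet", objectIds = ids, categoryLabels = labels)
}
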