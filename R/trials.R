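# Rearrange a vector until no element equals its predecessor, by swaps
# that strictly reduce the number of adjacent duplicates.
arrangeNoAdjacent <- function(v) {
  n <- length(v)
  nbad <- function(w) sum(w[-1] == w[-n])
  cur <- nbad(v)
  guard <- 0L
  while (cur > 0L) {
    guard <- guard + 1L
    if (guard > 10000L)
      stop("could not arrange a sequence without immediate repeats")
    i <- which(v[-1] == v[-n])[1L] + 1L
    improved <- FALSE
    for (j in sample.int(n)) {
      if (j == i || v[j] == v[i]) next
      w <- v
      w[c(i, j)] <- w[c(j, i)]
      b <- nbad(w)
      if (b < cur) {
        v <- w
        cur <- b
        improved <- TRUE
        break
      }
    }
    if (!improved)
      stop("could not arrange a sequence without immediate repeats")
  }
  v
}

#' Generate an ordered trial sequence for one modality
#'
#' Builds, run by run, a pseudorandom stimulus sequence in which every
#' object appears exactly `repsPerStimPerRun` times (unflagged), no
#' stimulus accidentally follows itself, and one-back repetition trials
#' (an immediate, flagged repeat of the preceding stimulus) are inserted
#' at random positions until they make up `onebackFraction` of all trials.
#' No two one-back repeats are consecutive. With the default design each
#' run holds 240 unflagged presentations plus 60 repeats, i.e. 300 trials.
#'
#' @param design a [DesignSpec-class].
#' @param modality one of `names(design@runsPerModality)`.
#' @param seed integer seed, or NULL.
#' @return a data.frame (the trial table) with columns `run`, `modality`,
#'   `object_id`, `is_oneback_repeat`, `trial_index`.
#' @examples
#' tt <- generateTrialSequence(designSpec(), "auditory", seed = 1)
#' table(tt$run)[1]            # 300 trials in run 1
#' mean(tt$is_oneback_repeat)  # 0.20
#' @export
generateTrialSequence <- function(design, modality, seed = NULL) {
  stopifnot(is(design, "DesignSpec"))
  if (!modality %in% names(design@runsPerModality))
    stop(sprintf("unknown modality '%s'", modality))
  ids <- makeObjectIds(design@nObjects)
  nRuns <- design@runsPerModality[[modality]]
  nUnflagged <- design@nObjects * design@repsPerStimPerRun
  f <- design@onebackFraction
  nRepeat <- as.integer(round(f * nUnflagged / (1 - f)))
  if (nRepeat > nUnflagged)
    stop("infeasible one-back fraction for this run length")
  withSeed(seed, {
    runs <- lapply(seq_len(nRuns), function(r) {
      base <- arrangeNoAdjacent(
        sample(rep(ids, design@repsPerStimPerRun)))
      flagAfter <- logical(nUnflagged)
      if (nRepeat > 0L)
        flagAfter[sample.int(nUnflagged, nRepeat)] <- TRUE
      obj <- character(0)
      flag <- logical(0)
      # expand: each unflagged trial, optionally followed by its repeat
      reps <- ifelse(flagAfter, 2L, 1L)
      obj <- rep(base, reps)
      flag <- unlist(lapply(seq_len(nUnflagged), function(i)
        if (flagAfter[i]) c(FALSE, TRUE) else FALSE))
      data.frame(run = r, modality = modality, object_id = obj,
                 is_oneback_repeat = flag, stringsAsFactors = FALSE)
    })
    tt <- do.call(rbind, runs)
    tt$trial_index <- seq_len(nrow(tt))
    rownames(tt) <- NULL
    tt
  })
}
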