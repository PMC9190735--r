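#' Export a trial table as tab-separated text
#'
#' Columns: run, modality, object_id, is_oneback_repeat, trial_index.
#'
#' @param trials trial table data.frame (see [generateTrialSequence()]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportTrialTable <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an accuracy time course as tab-separated text
#'
#' Time courses are written one row per participant, one column per
#' timepoint (header = time in ms). Temporal-generalization results are
#' written in long format with columns train_ms, test_ms, participant,
#' accuracy.
#'
#' @param acc an [AccuracyTimecourse-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportAccuracy <- function(acc, path) {
  stopifnot(is(acc, "AccuracyTimecourse"))
  v <- acc@values
  if (length(dim(v)) == 2L) {
    df <- as.data.frame(v)
    names(df) <- sprintf("t%g", acc@timeMs)
    df <- cbind(participant = seq_len(nrow(v)), df)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    d <- dim(v)
    df <- data.frame(
      train_ms = rep(acc@timeMs, times = d[3] * d[1]),
      test_ms = rep(rep(acc@timeMs, each = d[2]), times = d[1]),
      participant = rep(seq_len(d[1]), each = d[2] * d[3]),
      accuracy = as.vector(aperm(v, c(2, 3, 1))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an accuracy time course written by [exportAccuracy()]
#'
#' @param path file path.
#' @param scheme scheme label to attach.
#' @param nRepetitions repetitions label to attach.
#' @return an [AccuracyTimecourse-class].
#' @export
readAccuracy <- function(path, scheme = "custom", nRepetitions = 1L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  if (all(c("train_ms", "test_ms", "participant", "accuracy") %in%
          names(df))) {
    timeMs <- sort(unique(df$train_ms))
    parts <- sort(unique(df$participant))
    v <- array(0, dim = c(length(parts), length(timeMs), length(timeMs)))
    df <- df[order(df$participant, df$test_ms, df$train_ms), ]
    v[] <- aperm(array(df$accuracy,
                       dim = c(length(timeMs), length(timeMs),
                               length(parts))), c(3, 1, 2))
    return(new("AccuracyTimecourse", values = v, timeMs = timeMs,
               scheme = scheme, nRepetitions = as.integer(nRepetitions)))
  }
  timeMs <- as.numeric(sub("^t", "", names(df)[-1]))
  v <- as.matrix(df[, -1, drop = FALSE])
  dimnames(v) <- NULL
  accuracyTimecourse(v, timeMs, scheme, nRepetitions)
}

#' Export cluster-inference results as tab-separated text
#'
#' One candidate cluster per row (start_ms, end_ms, size, p,
#' significant).
#'
#' @param res a [ClusterInferenceResult-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportClusterTable <- function(res, path) {
  stopifnot(is(res, "ClusterInferenceResult"))
  utils::write.table(res@clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Save / load an epoch container
#'
#' Serializes an [EpochArray-class] (data array, time axis, sampling
#' rate, trial metadata, participant id) to an R-native binary container
#' (RDS). The trial metadata remain exportable as text via
#' [exportTrialTable()].
#'
#' @param epochs an [EpochArray-class].
#' @param path file path.
#' @return `saveEpochs`: the path, invisibly. `loadEpochs`: the
#'   [EpochArray-class].
#' @export
saveEpochs <- function(epochs, path) {
  stopifnot(is(epochs, "EpochArray"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname saveEpochs
#' @export
loadEpochs <- function(path) {
  x <- readRDS(path)
  stopifnot(is(x, "EpochArray"))
  x
}
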