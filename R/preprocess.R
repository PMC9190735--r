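#' Reject trials with excessive deviations
#'
#' Automated jump-artifact rejection. For every trial and channel the
#' epoch-summed absolute deviation from the across-trial channel mean is
#' computed, z-scored per channel across trials, and the maximum over
#' channels taken as the trial's artifact score. Trials whose score
#' exceeds `zThreshold` (default 20 standardized deviations) are removed.
#' A warning is emitted when more than 10% of trials are removed.
#'
#' @param epochs an [EpochArray-class] with at least two trials.
#' @param zThreshold rejection threshold in standardized deviations;
#'   `Inf` disables rejection.
#' @return a list with elements `epochs` (the cleaned [EpochArray-class]),
#'   `removed` (indices of rejected trials), `fraction` (proportion
#'   removed) and `scores` (per-trial artifact scores).
#' @export
rejectArtifacts <- function(epochs, zThreshold = 20) {
  stopifnot(is(epochs, "EpochArray"))
  d <- dim(epochs@data)
  n <- d[1]
  if (n < 2L) stop("artifact rejection needs at least 2 trials")
  chanMean <- apply(epochs@data, c(2, 3), mean)        # channels x time
  dev <- matrix(0, n, d[2])                            # trials x channels
  for (i in seq_len(n))
    dev[i, ] <- rowSums(abs(matrix(epochs@data[i, , ], d[2], d[3]) -
                              chanMean))
  mu <- colMeans(dev)
  sdv <- apply(dev, 2, stats::sd)
  z <- sweep(sweep(dev, 2, mu, "-"), 2, pmax(sdv, .Machine$double.eps),
             "/")
  scores <- apply(z, 1, max)
  removed <- which(scores > zThreshold)
  if (length(removed) == n)
    stop("all trials were rejected as artifacts")
  fraction <- length(removed) / n
  if (fraction > 0.10)
    warning(sprintf("artifact rejection removed %.1f%% of trials (> 10%%)",
                    100 * fraction))
  keep <- setdiff(seq_len(n), removed)
  list(epochs = epochs[keep], removed = removed, fraction = fraction,
       scores = scores)
}

# Linear operator mapping a length-nIn series to its anti-aliased,
# q-fold decimated version: reflection-padded zero-phase Butterworth
# (order 4, cutoff 0.8 x target Nyquist), then every q-th sample.
decimOperator <- function(nIn, q) {
  bf <- signal::butter(4, 0.8 / q)
  p <- min(nIn - 1L, 3L * max(10L, q))
  filt1 <- function(x) {
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[nIn] - x[(nIn - 1):(nIn - p)])
    signal::filtfilt(bf, xp)[(p + 1):(p + nIn)]
  }
  D <- vapply(seq_len(nIn), function(j) {
    e <- numeric(nIn)
    e[j] <- 1
    filt1(e)
  }, numeric(nIn))
  D[seq(1, nIn, by = q), , drop = FALSE]
}

#' Downsample epochs with anti-alias filtering
#'
#' Integer decimation to `fsTarget`: a zero-phase (forward-backward)
#' Butterworth low-pass at 80% of the target Nyquist frequency is applied
#' along time (with reflection padding to suppress edge transients),
#' then every q-th sample is kept, q = fs / fsTarget. The time axis keeps
#' the same window at the coarser spacing.
#'
#' @param epochs an [EpochArray-class].
#' @param fsTarget target sampling rate in Hz; must divide the current
#'   rate and not exceed it.
#' @return an [EpochArray-class] sampled at `fsTarget`.
#' @export
downsampleEpochs <- function(epochs, fsTarget) {
  stopifnot(is(epochs, "EpochArray"))
  fs <- epochs@fs
  if (fsTarget > fs) stop("fsTarget cannot exceed the current rate")
  if (fsTarget == fs) return(epochs)
  q <- fs / fsTarget
  if (abs(q - round(q)) > 1e-8)
    stop("fsTarget must divide the sampling rate (integer decimation)")
  q <- as.integer(round(q))
  d <- dim(epochs@data)
  nIn <- d[3]
  D <- decimOperator(nIn, q)
  flat <- matrix(aperm(epochs@data, c(3, 1, 2)), nrow = nIn)
  out <- D %*% flat                                    # nOut x (trials*chan)
  nOut <- nrow(D)
  newDat <- aperm(array(out, dim = c(nOut, d[1], d[2])), c(2, 3, 1))
  new("EpochArray", data = newDat,
      timeMs = epochs@timeMs[seq(1, nIn, by = q)],
      fs = fsTarget, trialMeta = epochs@trialMeta,
      participantId = epochs@participantId)
}
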