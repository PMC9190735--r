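# maximum run length of TRUE per row of a logical matrix
maxRunPerRow <- function(M) {
  apply(M, 1, function(r) {
    if (!any(r)) return(0L)
    rl <- rle(r)
    max(rl$lengths[rl$values])
  })
}

#' Sign-flip cluster-size permutation test
#'
#' Group-level nonparametric inference for accuracy time courses against
#' chance. Participant time courses are centered on the chance level and
#' a one-sided pointwise group statistic (mean, or one-sample t) is
#' computed per timepoint. The null distribution is built by randomly
#' multiplying each participant's centered time course by +1 or -1
#' (`nPermutations` times, the identity assignment included); timepoints
#' whose statistic exceeds the pointwise (1 - alpha) null quantile form
#' contiguous candidate clusters scored by their size (number of
#' timepoints), and cluster p values are computed against the null
#' distribution of the maximum cluster size, controlling the family-wise
#' error over timepoints.
#'
#' @param acc an [AccuracyTimecourse-class] (participants x timepoints)
#'   with at least 2 participants, or a plain matrix.
#' @param chance chance level in percent (50 for balanced pairs).
#' @param nPermutations number of random sign assignments (ignored with
#'   `exhaustive = TRUE`).
#' @param alpha threshold used both for cluster forming (pointwise) and
#'   for cluster significance, one-sided.
#' @param statistic pointwise statistic, "mean" (default) or "t".
#' @param seed integer seed, or NULL.
#' @param exhaustive enumerate all `2^n` sign assignments instead of
#'   sampling (exact test; feasible for small groups).
#' @return a [ClusterInferenceResult-class].
#' @export
clusterPermutationTest <- function(acc, chance = 50,
                                   nPermutations = 10000L,
                                   alpha = 0.05,
                                   statistic = c("mean", "t"),
                                   seed = NULL, exhaustive = FALSE) {
  statistic <- match.arg(statistic)
  if (is(acc, "AccuracyTimecourse")) {
    timeMs <- acc@timeMs
    X <- acc@values
    if (length(dim(X)) != 2L)
      stop("cluster inference expects a participants x timepoints matrix")
  } else {
    X <- as.matrix(acc)
    timeMs <- seq_len(ncol(X))
  }
  n <- nrow(X)
  Tn <- ncol(X)
  if (n < 2L) stop("need at least 2 participants")
  X <- X - chance
  if (!exhaustive && nPermutations < 1 / alpha)
    warning("nPermutations below 1/alpha: insufficient resolution")

  if (exhaustive) {
    if (n > 20L) stop("exhaustive enumeration is limited to n <= 20")
    nPerm <- 2L^n
    flips <- (-1)^(outer(seq_len(nPerm) - 1L, seq_len(n) - 1L,
                         function(i, j) bitwAnd(i %/% 2L^j, 1L)))
    # put the identity assignment (all +1) first
    idRow <- which(rowSums(flips) == n)[1]
    flips <- flips[c(idRow, setdiff(seq_len(nPerm), idRow)), ,
                   drop = FALSE]
  } else {
    nPerm <- as.integer(nPermutations)
    flips <- withSeed(seed, matrix(
      sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n))
    flips[1, ] <- 1                     # identity assignment included
  }

  M <- flips %*% X / n                  # perm x T matrix of means
  if (statistic == "t") {
    ss <- colSums(X^2)                  # invariant under sign flips
    sdM <- sqrt(sweep(-n * M^2, 2, ss, "+") / (n - 1))
    M <- M / pmax(sdM, .Machine$double.eps) * sqrt(n)
  }
  obs <- M[1, ]
  pointwise <- colMeans(M >= matrix(obs, nPerm, Tn, byrow = TRUE))
  crit <- apply(M, 2, stats::quantile, probs = 1 - alpha, type = 1)
  supra <- M > matrix(crit, nPerm, Tn, byrow = TRUE)
  nullMax <- maxRunPerRow(supra)
  obsSupra <- supra[1, ]

  clusters <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                         size = integer(0), p = numeric(0),
                         significant = logical(0))
  if (any(obsSupra)) {
    rl <- rle(obsSupra)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- which(rl$values)
    clusters <- data.frame(
      start_ms = timeMs[starts[keep]],
      end_ms = timeMs[ends[keep]],
      size = rl$lengths[keep],
      p = vapply(rl$lengths[keep],
                 function(s) mean(nullMax >= s), numeric(1)))
    clusters$significant <- clusters$p < alpha
  }
  mask <- logical(Tn)
  sig <- clusters[clusters$significant, , drop = FALSE]
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig)))
      mask[timeMs >= sig$start_ms[i] & timeMs <= sig$end_ms[i]] <- TRUE
  }
  new("ClusterInferenceResult",
      significantMask = mask, clusters = clusters,
      pointwiseP = pointwise, nPermutations = as.integer(nPerm),
      alpha = alpha, chance = chance, timeMs = timeMs,
      statistic = statistic)
}

#' Bootstrap test for a peak-latency difference
#'
#' Tests whether the group-mean decoding time course of condition A
#' reaches its maximum reliably later (or earlier) than that of
#' condition B. Participants are resampled with replacement
#' `nBootstrap` times (the same resample applied to both conditions),
#' the group-mean time courses recomputed, and the latency of the
#' maximum recorded (ties broken to the earliest timepoint). The
#' one-tailed p value is the fraction of bootstrap samples whose
#' difference (A - B) lies strictly on the hypothesized side.
#'
#' @param accA,accB [AccuracyTimecourse-class] objects with the same
#'   participants (row order) and time axis.
#' @param nBootstrap number of bootstrap samples.
#' @param seed integer seed, or NULL.
#' @param alternative "greater" tests whether A peaks later than B
#'   (counts differences > 0); "less" the reverse.
#' @return a [PeakLatencyTest-class].
#' @export
bootstrapPeakLatencyDifference <- function(accA, accB,
                                           nBootstrap = 1000L,
                                           seed = NULL,
                                           alternative = c("greater",
                                                           "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is(accA, "AccuracyTimecourse"),
            is(accB, "AccuracyTimecourse"))
  if (!isTRUE(all.equal(accA@timeMs, accB@timeMs)))
    stop("time axes of the two conditions differ")
  XA <- accA@values
  XB <- accB@values
  if (nrow(XA) != nrow(XB))
    stop("the two conditions must have the same participants")
  n <- nrow(XA)
  timeMs <- accA@timeMs
  nBootstrap <- as.integer(nBootstrap)

  peakOf <- function(m) timeMs[which.max(m)]   # earliest max on ties
  flat <- function(m) max(m) - min(m) < .Machine$double.eps^0.5
  mA <- colMeans(XA)
  mB <- colMeans(XB)
  degenerate <- flat(mA) || flat(mB)

  diffs <- withSeed(seed, {
    vapply(seq_len(nBootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      peakOf(colMeans(XA[idx, , drop = FALSE])) -
        peakOf(colMeans(XB[idx, , drop = FALSE]))
    }, numeric(1))
  })
  qualifying <- if (alternative == "greater") diffs > 0 else diffs < 0
  if (all(diffs == 0)) degenerate <- TRUE
  new("PeakLatencyTest",
      peakMsA = peakOf(mA), peakMsB = peakOf(mB),
      bootDifferences = diffs,
      pOneTailed = sum(qualifying) / nBootstrap,
      nBootstrap = nBootstrap,
      alternative = alternative,
      degenerate = degenerate)
}
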