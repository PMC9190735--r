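# Ledoit-Wolf analytic shrinkage of a channel covariance toward a scaled
# identity, from the n x C residual matrix X (rows already centered).
# Returns list(sigma, lambda).
lwShrink <- function(X) {
  n <- nrow(X)
  C <- ncol(X)
  S <- crossprod(X) / n
  m <- sum(diag(S)) / C
  d2 <- sum((S - diag(m, C))^2)
  b2bar <- sum(rowSums(X^2)^2) / n^2 - sum(S^2) / n
  b2 <- min(max(b2bar, 0), d2)
  lambda <- if (d2 > 0) b2 / d2 else 1
  list(sigma = lambda * diag(m, C) + (1 - lambda) * S, lambda = lambda)
}

#' Fit a multivariate noise normalizer
#'
#' Estimates the channel noise covariance from within-condition residuals:
#' at every timepoint, trials are centered on their condition mean and the
#' channel covariance is estimated with analytic (Ledoit-Wolf) shrinkage
#' toward a scaled identity; the per-timepoint estimates are averaged over
#' the epoch, and the whitening transform is the inverse symmetric square
#' root of the result. Applying the transform down-weights channels (and
#' channel combinations) with high noise covariance.
#'
#' @param epochs an [EpochArray-class] of single trials.
#' @param conditionLabels grouping used to form residuals; defaults to the
#'   trials' object_id.
#' @return a [NoiseNormalizer-class].
#' @export
fitNoiseNormalizer <- function(epochs, conditionLabels = NULL) {
  stopifnot(is(epochs, "EpochArray"))
  d <- dim(epochs@data)
  labels <- conditionLabels %||% epochs@trialMeta$object_id
  if (length(labels) != d[1])
    stop("conditionLabels must have one entry per trial")
  tab <- table(labels)
  if (any(tab < 2L))
    stop("every condition needs at least 2 trials to form residuals")
  chanVar <- apply(epochs@data, 2, function(x) stats::var(as.vector(x)))
  if (any(chanVar <= 0))
    stop(sprintf("zero-variance channel(s): %s",
                 paste(which(chanVar <= 0), collapse = ", ")))
  groups <- split(seq_len(d[1]), labels)
  sigAcc <- matrix(0, d[2], d[2])
  lamAcc <- 0
  for (t in seq_len(d[3])) {
    X <- epochs@data[, , t, drop = TRUE]
    if (!is.matrix(X)) X <- matrix(X, d[1], d[2])
    for (g in groups) {
      X[g, ] <- sweep(X[g, , drop = FALSE], 2,
                      colMeans(X[g, , drop = FALSE]))
    }
    sh <- lwShrink(X)
    sigAcc <- sigAcc + sh$sigma
    lamAcc <- lamAcc + sh$lambda
  }
  sigma <- sigAcc / d[3]
  W <- invMatSqrt(sigma)
  new("NoiseNormalizer",
      whiteningTransform = (W + t(W)) / 2,
      shrinkageIntensity = lamAcc / d[3],
      source = sprintf(
        "within-condition residuals of %d trials (%d conditions, %d timepoints)",
        d[1], length(groups), d[3]))
}

#' Apply a noise normalizer
#'
#' Left-multiplies every channel vector (each super-trial or trial at each
#' timepoint) by the whitening transform. Shapes, time axes and labels
#' are preserved. A [SuperTrialSet-class] carries a `normalized` flag that
#' guards against accidental double application (whitening twice is not
#' idempotent).
#'
#' @param x a [SuperTrialSet-class] or [EpochArray-class].
#' @param normalizer a [NoiseNormalizer-class] with a matching channel
#'   count.
#' @return object of the same class with whitened channel patterns.
#' @name applyNormalizer
NULL

#' @rdname applyNormalizer
#' @export
setMethod("applyNormalizer", c("SuperTrialSet", "NoiseNormalizer"),
  function(x, normalizer) {
    if (x@normalized)
      stop("super-trials are already noise-normalized")
    W <- normalizer@whiteningTransform
    d <- dim(x@data)
    if (d[3] != nrow(W))
      stop("channel counts of data and normalizer disagree")
    # fold (cond, group) and time into columns: W acts on channel dim
    flat <- matrix(aperm(x@data, c(3, 1, 2, 4)), nrow = d[3])
    res <- aperm(array(W %*% flat, dim = d[c(3, 1, 2, 4)]),
                 c(2, 3, 1, 4))
    initialize(x, data = res, normalized = TRUE)
  })

#' @rdname applyNormalizer
#' @export
setMethod("applyNormalizer", c("EpochArray", "NoiseNormalizer"),
  function(x, normalizer) {
    W <- normalizer@whiteningTransform
    d <- dim(x@data)
    if (d[2] != nrow(W))
      stop("channel counts of data and normalizer disagree")
    flat <- matrix(aperm(x@data, c(2, 1, 3)), nrow = d[2])
    res <- aperm(array(W %*% flat, dim = d[c(2, 1, 3)]), c(2, 1, 3))
    initialize(x, data = res)
  })
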