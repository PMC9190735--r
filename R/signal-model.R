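#' Build per-modality channel mixing matrices
#'
#' With `coding = "shared"` every modality uses the identity, so planted
#' patterns are expressed identically in both modalities (a modality-
#' independent code). With `coding = "orthogonal"` each modality projects
#' the patterns onto its own half of a random orthonormal channel basis,
#' so the realized sensor patterns of the two modalities are mutually
#' orthogonal and cross-modal decoding carries no signal.
#'
#' @param nChannels number of channels.
#' @param modalities character vector of modality names.
#' @param coding "orthogonal" or "shared".
#' @param seed integer seed, or NULL.
#' @return named list of channels x channels matrices.
#' @export
buildModalityCodes <- function(nChannels,
                               modalities = c("auditory", "visual"),
                               coding = c("orthogonal", "shared"),
                               seed = NULL) {
  coding <- match.arg(coding)
  nMod <- length(modalities)
  if (coding == "shared" || nMod == 1L) {
    return(stats::setNames(
      rep(list(diag(nChannels)), nMod), modalities))
  }
  h <- nChannels %/% nMod
  if (h < 1L) stop("not enough channels for orthogonal modality codes")
  Q <- withSeed(seed,
                qr.Q(qr(matrix(stats::rnorm(nChannels^2), nChannels))))
  codes <- lapply(seq_len(nMod), function(m) {
    cols <- ((m - 1L) * h + 1L):(m * h)
    Qm <- Q[, cols, drop = FALSE]
    Qm %*% t(Qm)
  })
  stats::setNames(codes, modalities)
}

#' Construct a generative signal model
#'
#' Draws one multivariate channel pattern per object and one per category
#' level on each dimension (independent unit-norm Gaussian vectors), and
#' packages them with onset latencies, a linear onset ramp, per-modality
#' channel codes, a stationary channel noise covariance
#' (\eqn{\Sigma_{ij} = \sigma^2 \rho^{|i-j|}}) and a global signal gain.
#' A simulated trial of object *o* in modality *m* is
#' \deqn{snr \cdot M_m [p_o e_{obj}(t) + \sum_d c_{d,l_d(o)} e_{cat}(t)] +
#'   \epsilon(t), \quad \epsilon(t) \sim N(0, \Sigma),}
#' with envelopes \eqn{e(t)} ramping from 0 to 1 over `rampMs` after the
#' respective onset. Default onsets place the object code at 75 ms and the
#' category code at 305 ms after stimulus onset.
#'
#' @param stimset a [StimulusSet-class].
#' @param design a [DesignSpec-class] (channel count and modalities).
#' @param objectOnsetMs,categoryOnsetMs onset latencies in ms.
#' @param rampMs linear ramp duration in ms (0 = step onset).
#' @param snr global signal gain multiplying the planted patterns
#'   (noise has unit scale by default; snr = 0 simulates pure noise).
#' @param modalityCoding "orthogonal" (modality-specific sensor codes,
#'   the default) or "shared" (one modality-independent code).
#' @param noiseRho channel-to-channel correlation decay of the noise.
#' @param noiseSd marginal noise standard deviation per channel.
#' @param seed integer seed for pattern generation, or NULL.
#' @return a validated [SignalModel-class].
#' @export
signalModel <- function(stimset, design,
                        objectOnsetMs = 75,
                        categoryOnsetMs = 305,
                        rampMs = 20,
                        snr = 1,
                        modalityCoding = c("orthogonal", "shared"),
                        noiseRho = 0.3,
                        noiseSd = 1,
                        seed = NULL) {
  stopifnot(is(stimset, "StimulusSet"), is(design, "DesignSpec"))
  modalityCoding <- match.arg(modalityCoding)
  C <- design@nChannels
  ids <- objectIds(stimset)
  dims <- dimensionNames(stimset)
  win <- design@epochWindow
  if (objectOnsetMs < win[1] || objectOnsetMs > win[2] ||
      categoryOnsetMs < win[1] || categoryOnsetMs > win[2])
    stop("onsets must lie within the epoch window")
  unitCols <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")
  withSeed(seed, {
    objP <- unitCols(matrix(stats::rnorm(C * length(ids)), C,
                            dimnames = list(NULL, ids)))
    catP <- lapply(stats::setNames(dims, dims), function(d) {
      lv <- levels(categoryLabels(stimset)[[d]])
      unitCols(matrix(stats::rnorm(C * 2L), C,
                      dimnames = list(NULL, lv)))
    })
    codes <- buildModalityCodes(C, names(design@runsPerModality),
                                modalityCoding,
                                seed = childSeed(seed, 7L))
    noiseCov <- noiseSd^2 * noiseRho^abs(outer(1:C, 1:C, "-"))
    new("SignalModel",
        objectPatterns = objP,
        categoryPatterns = catP,
        objectOnsetMs = objectOnsetMs,
        categoryOnsetMs = categoryOnsetMs,
        rampMs = rampMs,
        modalityCodes = codes,
        noiseCov = noiseCov,
        snr = snr)
  })
}
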