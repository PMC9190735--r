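# Desk-scale designs and simulated sessions shared across tests.

tinyDesign <- function(nObjects = 8L, nChannels = 12L, reps = 3L,
                       runs = c(auditory = 1L, visual = 1L),
                       fsRaw = 200, fsTarget = 200,
                       onebackFraction = 0.2) {
  designSpec(nObjects = nObjects, nDims = 3L, runsPerModality = runs,
             repsPerStimPerRun = reps, onebackFraction = onebackFraction,
             epochWindow = c(-200, 800), fsRaw = fsRaw,
             fsTarget = fsTarget, nChannels = nChannels)
}

# A simulated participant: epochs for both modalities, one-back dropped.
makeSession <- function(seed = 1, snr = 5, coding = "orthogonal",
                        design = tinyDesign(), noiseSd = 1,
                        objectOnsetMs = 75, categoryOnsetMs = 305,
                        model = NULL) {
  stimset <- buildStimulusSet(design@nObjects, design@nDims, seed = seed)
  if (is.null(model))
    model <- signalModel(stimset, design, snr = snr,
                         modalityCoding = coding, noiseSd = noiseSd,
                         objectOnsetMs = objectOnsetMs,
                         categoryOnsetMs = categoryOnsetMs,
                         seed = seed + 1L)
  eps <- lapply(names(design@runsPerModality), function(m) {
    tt <- generateTrialSequence(design, m, seed = seed + 2L + match(
      m, names(design@runsPerModality)))
    dropOneBack(simulateEpochs(tt, stimset, model, design,
                               seed = seed + 10L + match(
                                 m, names(design@runsPerModality))))
  })
  names(eps) <- names(design@runsPerModality)
  list(design = design, stimset = stimset, model = model, epochs = eps)
}

# Build a SuperTrialSet directly from a condition x group x channel x
# time array (constant provenance), for classifier-level tests.
stFromArray <- function(arr, timeMs = seq_len(dim(arr)[4])) {
  conds <- sprintf("c%d", seq_len(dim(arr)[1]))
  prov <- lapply(seq_len(dim(arr)[1]), function(i)
    lapply(seq_len(dim(arr)[2]), function(g) sprintf("src%d.%d", i, g)))
  names(prov) <- conds
  new("SuperTrialSet", conditions = conds, data = arr,
      timeMs = as.numeric(timeMs), scheme = "object",
      dimension = NA_character_, provenance = prov, normalized = FALSE)
}

# Brute-force maximum-margin oracle for two classes of two training
# points each: closest points between the two segments (dense grid over
# the convex combinations), midpoint hyperplane, sign classification.
# Valid as the c = 1 SVM solution when the classes are far apart (all
# dual coefficients stay below the cost bound).
marginOracleAccuracy <- function(A, B, testA, testB) {
  s <- seq(0, 1, length.out = 401)
  P <- outer(1 - s, A[1, ]) + outer(s, A[2, ])      # points on segment A
  Q <- outer(1 - s, B[1, ]) + outer(s, B[2, ])
  d2 <- outer(rowSums(P^2), rep(1, nrow(Q))) +
    outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * P %*% t(Q)
  ij <- arrayInd(which.min(d2), dim(d2))
  p <- P[ij[1], ]; q <- Q[ij[2], ]
  w <- p - q                                        # points toward A
  m <- (p + q) / 2
  correct <- sum(drop((testA - matrix(m, nrow(testA), ncol(testA),
                                      byrow = TRUE)) %*% w) > 0) +
    sum(drop((testB - matrix(m, nrow(testB), ncol(testB),
                             byrow = TRUE)) %*% w) < 0)
  100 * correct / (nrow(testA) + nrow(testB))
}

# accuracy curve with a smooth bump peaking at peakMs
bumpCurve <- function(timeMs, peakMs, height = 10, width = 80,
                      chance = 50) {
  chance + height * exp(-0.5 * ((timeMs - peakMs) / width)^2)
}
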