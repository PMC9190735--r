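# epochs with known channel noise covariance and per-condition means
covEpochs <- function(n, Sigma, seed = 1, Tn = 20, nCond = 4) {
  C <- nrow(Sigma)
  L <- chol(Sigma)
  withr::with_seed(seed, {
    mu <- matrix(rnorm(nCond * C), nCond, C)
    cond <- rep(seq_len(nCond), length.out = n)
    dat <- array(0, dim = c(n, C, Tn))
    for (i in seq_len(n))
      dat[i, , ] <- mu[cond[i], ] +
        crossprod(L, matrix(rnorm(C * Tn), C, Tn))
    meta <- data.frame(run = 1L, modality = "auditory",
                       object_id = sprintf("obj%02d", cond),
                       is_oneback_repeat = FALSE,
                       trial_index = seq_len(n))
    new("EpochArray", data = dat, timeMs = seq(0, by = 5,
                                               length.out = Tn),
        fs = 200, trialMeta = meta, participantId = "p1")
  })
}

test_that("identity noise gives a near-identity whitening transform", {
  ep <- covEpochs(400, diag(6), seed = 2)
  nn <- fitNoiseNormalizer(ep)
  W <- whiteningMatrix(nn)
  expect_lt(max(abs(W - diag(6))), 0.1)
  # exact invariant: W is the inverse square root of the fitted covariance
  Sigma <- solve(W %*% W)
  expect_equal(mean(diag(W %*% Sigma %*% W)), 1, tolerance = 1e-10)
})

test_that("whitened residual covariance approaches identity with more trials", {
  Sigma <- 0.5^abs(outer(1:6, 1:6, "-")) * 2
  froDist <- vapply(c(60, 600), function(n) {
    ep <- covEpochs(n, Sigma, seed = 3)
    nn <- fitNoiseNormalizer(ep)
    W <- whiteningMatrix(nn)
    wh <- applyNormalizer(ep, nn)
    # residuals of the whitened data
    res <- NULL
    for (g in split(seq_len(n), trialInfo(ep)$object_id)) {
      x <- apply(wh@data[g, , , drop = FALSE], 2, as.vector)
      res <- rbind(res, scale(x, scale = FALSE))
    }
    sqrt(sum((stats::cov(res) - diag(6))^2))
  }, numeric(1))
  expect_lt(froDist[2], froDist[1])
  expect_lt(froDist[2], 0.3)
})

test_that("whitening is approximately equivariant to channel rescaling", {
  Sigma <- 0.4^abs(outer(1:5, 1:5, "-"))
  ep <- covEpochs(500, Sigma, seed = 4)
  nn <- fitNoiseNormalizer(ep)
  w1 <- applyNormalizer(ep, nn)
  ep10 <- ep
  ep10@data[, 2, ] <- ep10@data[, 2, ] * 10
  nn10 <- fitNoiseNormalizer(ep10)
  w2 <- applyNormalizer(ep10, nn10)
  # with little shrinkage, scaling a channel is undone by the whitener
  expect_lt(shrinkageIntensity(nn10), 0.2)
  expect_gt(cor(as.vector(w2@data), as.vector(w1@data)), 0.98)
  rel <- max(abs(w2@data - w1@data)) / max(abs(w1@data))
  expect_lt(rel, 0.3)
})

test_that("applying a normalizer preserves structure and linearity", {
  ses <- makeSession(seed = 5, design = tinyDesign(nObjects = 8, reps = 3,
                                                   runs = c(auditory = 1L)))
  ep <- ses$epochs$auditory
  st <- makeObjectSupertrials(ep, 3, seed = 1)
  idN <- new("NoiseNormalizer", whiteningTransform = diag(12),
             shrinkageIntensity = 0, source = "identity")
  stId <- applyNormalizer(st, idN)
  expect_equal(supertrialData(stId), supertrialData(st))
  expect_identical(timePoints(stId), timePoints(st))
  expect_identical(conditionNames(stId), conditionNames(st))
  # double application is guarded
  expect_error(applyNormalizer(stId, idN), "already")
  # linearity
  nn <- fitNoiseNormalizer(ep)
  st2 <- st
  st2@data <- st2@data * 3
  expect_equal(supertrialData(applyNormalizer(st2, nn)),
               3 * supertrialData(applyNormalizer(st, nn)))
})

test_that("normalizer fitting validates its inputs", {
  ses <- makeSession(seed = 6, design = tinyDesign(nObjects = 8, reps = 1,
                                                   runs = c(auditory = 1L),
                                                   onebackFraction = 0))
  expect_error(fitNoiseNormalizer(ses$epochs$auditory), "at least 2")
  ep <- covEpochs(40, diag(4), seed = 7)
  ep@data[, 3, ] <- 0
  expect_error(fitNoiseNormalizer(ep), "zero-variance")
})
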