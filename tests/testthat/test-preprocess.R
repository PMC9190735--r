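makeNoiseEpochs <- function(n, C = 3, Tn = 10, seed = 1, fs = 200) {
  withr::with_seed(seed, {
    dat <- array(rnorm(n * C * Tn), dim = c(n, C, Tn))
    meta <- data.frame(run = 1L, modality = "auditory",
                       object_id = rep(sprintf("obj%02d", 1:4),
                                       length.out = n),
                       is_oneback_repeat = FALSE, trial_index = seq_len(n))
    new("EpochArray", data = dat, timeMs = seq(0, by = 1000 / fs,
                                               length.out = Tn),
        fs = fs, trialMeta = meta, participantId = "p1")
  })
}

test_that("homogeneous noise yields no artifact rejections", {
  ep <- makeNoiseEpochs(600)
  res <- rejectArtifacts(ep, 20)
  expect_length(res$removed, 0)
  expect_equal(res$fraction, 0)
  expect_identical(epochData(res$epochs), epochData(ep))
})

test_that("a spiking trial is detected by direct score computation", {
  ep <- makeNoiseEpochs(600)
  ep@data[123, 2, ] <- ep@data[123, 2, ] + 100   # 100x the noise scale
  # oracle: recompute the score metric directly for the spiked trial
  d <- dim(ep@data)
  chanMean <- apply(ep@data, c(2, 3), mean)
  dev <- t(vapply(seq_len(d[1]), function(i)
    rowSums(abs(matrix(ep@data[i, , ], d[2], d[3]) - chanMean)),
    numeric(d[2])))
  z <- scale(dev)
  expect_gt(max(z[123, ]), 20)
  expect_true(all(apply(z[-123, ], 1, max) < 20))
  res <- rejectArtifacts(ep, 20)
  expect_identical(res$removed, 123L)
  expect_equal(nrow(trialInfo(res$epochs)), 599L)
})

test_that("artifact rejection edge cases behave as documented", {
  ep <- makeNoiseEpochs(200)
  expect_length(rejectArtifacts(ep, Inf)$removed, 0)       # identity
  expect_warning(rejectArtifacts(ep, 0.5),
                 "artifact rejection removed")              # heavy removal
  expect_error(rejectArtifacts(ep, -10), "all trials")     # removes all
  expect_error(rejectArtifacts(ep[1], 20), "at least 2")
})

test_that("downsampling decimates the axis and preserves content", {
  design <- tinyDesign(nObjects = 8, nChannels = 3, fsRaw = 1000,
                       fsTarget = 200, reps = 1, onebackFraction = 0,
                       runs = c(auditory = 1L))
  ss <- buildStimulusSet(8, 3, seed = 1)
  mod <- signalModel(ss, design, snr = 0, seed = 1)
  tt <- generateTrialSequence(design, "auditory", seed = 1)[1:4, ]
  ep <- simulateEpochs(tt, ss, mod, design, seed = 2)
  # replace content with known signals
  t <- timePoints(ep)
  ep@data[1, 1, ] <- 3.7                              # constant
  ep@data[1, 2, ] <- sin(2 * pi * 3 * t / 1000)       # in passband
  ep@data[1, 3, ] <- sin(2 * pi * 450 * t / 1000)     # above target Nyquist
  ds <- downsampleEpochs(ep, 200)
  td <- timePoints(ds)
  expect_equal(unique(round(diff(td), 10)), 5)
  expect_equal(range(td), range(t))
  expect_equal(samplingRate(ds), 200)
  expect_lt(max(abs(ds@data[1, 1, ] - 3.7)), 1e-2)
  expect_lt(max(abs(ds@data[1, 2, ] -
                      sin(2 * pi * 3 * td / 1000))), 1e-2)
  expect_lt(max(abs(ds@data[1, 3, ])), 1e-3)          # aliasing removed
})

test_that("downsampling validates rates and identity holds", {
  ep <- makeNoiseEpochs(5, fs = 200)
  expect_identical(downsampleEpochs(ep, 200), ep)
  expect_error(downsampleEpochs(ep, 400), "exceed")
  expect_error(downsampleEpochs(ep, 150), "integer")
})

test_that("one-back trials are dropped before analysis", {
  ses <- makeSession(seed = 3, design = tinyDesign())
  ep <- ses$epochs$auditory
  expect_false(any(trialInfo(ep)$is_oneback_repeat))
  expect_equal(nrow(trialInfo(ep)), 8L * 3L)
})
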