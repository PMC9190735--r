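test_that("decoding matches a brute-force maximum-margin oracle", {
  # 2 channels, 2 conditions, 3 super-trials, widely separated classes so
  # the soft-margin solution coincides with the hard margin
  withr::with_seed(11, {
    for (rep in 1:20) {
      arr <- array(0, dim = c(2, 3, 2, 2))     # cond x group x chan x time
      arr[1, , , ] <- rnorm(12, mean = +4)
      arr[2, , , ] <- rnorm(12, mean = -4)
      st <- stFromArray(arr)
      got <- decodeSuperTrials(st, cost = 1)
      for (tp in 1:2) {
        expected <- mean(vapply(1:3, function(f) {
          tr <- setdiff(1:3, f)
          marginOracleAccuracy(arr[1, tr, , tp], arr[2, tr, , tp],
                               matrix(arr[1, f, , tp], nrow = 1),
                               matrix(arr[2, f, , tp], nrow = 1))
        }, numeric(1)))
        expect_equal(got[tp], expected)
      }
    }
  })
})

test_that("decoding agrees with libsvm on random super-trial data", {
  skip_if_not_installed("e1071")
  withr::with_seed(21, {
    diffs <- c()
    for (rep in 1:25) {
      arr <- array(rnorm(2 * 3 * 4 * 3), dim = c(2, 3, 4, 3))
      arr[1, , , ] <- arr[1, , , ] + 1.5
      st <- stFromArray(arr)
      got <- decodeSuperTrials(st, cost = 1)
      for (tp in 1:3) {
        ref <- mean(vapply(1:3, function(f) {
          tr <- setdiff(1:3, f)
          X <- rbind(arr[1, tr, , tp], arr[2, tr, , tp])
          y <- factor(c(1, 1, -1, -1))
          fit <- e1071::svm(X, y, kernel = "linear", cost = 1,
                            scale = FALSE)
          Xt <- rbind(arr[1, f, , tp], arr[2, f, , tp])
          pred <- predict(fit, Xt)
          100 * mean(pred == factor(c(1, -1), levels = levels(y)))
        }, numeric(1)))
        diffs <- c(diffs, abs(got[tp] - ref))
      }
    }
    # disagreement only possible for test points on the decision boundary
    expect_lt(mean(diffs), 1)
    expect_lt(stats::median(diffs), 1e-8)
  })
})

test_that("noiseless separable patterns decode perfectly after onset", {
  design <- tinyDesign(nObjects = 8, nChannels = 10, reps = 3,
                       runs = c(auditory = 1L))
  ses <- makeSession(seed = 3, snr = 5, noiseSd = 1e-7, design = design)
  acc <- pairwiseDecode(ses$epochs$auditory, nRepetitions = 2, seed = 1)
  t <- timePoints(acc)
  v <- drop(accuracyValues(acc))
  expect_true(all(v[t >= 100] == 100))
  # and chance-level scatter before any signal exists
  expect_lt(mean(v[t < 75]), 65)
})

test_that("label and channel permutations leave accuracy unchanged", {
  withr::with_seed(31, {
    arr <- array(rnorm(2 * 3 * 5 * 4), dim = c(2, 3, 5, 4))
    arr[1, , , ] <- arr[1, , , ] + 1
    st <- stFromArray(arr)
    base <- decodeSuperTrials(st, cost = 1)
    # swap the two class labels
    stSwap <- stFromArray(arr[2:1, , , , drop = FALSE])
    expect_equal(decodeSuperTrials(stSwap, cost = 1), base)
    # permute channels consistently
    perm <- sample(5)
    stPerm <- stFromArray(arr[, , perm, , drop = FALSE])
    expect_equal(decodeSuperTrials(stPerm, cost = 1), base)
  })
})

test_that("shuffled condition labels decode at chance", {
  design <- tinyDesign(nObjects = 8, nChannels = 8, reps = 12,
                       runs = c(auditory = 1L))
  ses <- makeSession(seed = 13, snr = 1, design = design)
  ep <- ses$epochs$auditory
  ep@trialMeta$object_id <- withr::with_seed(
    5, sample(ep@trialMeta$object_id))
  acc <- pairwiseDecode(ep, nRepetitions = 4, seed = 2)
  expect_lt(abs(mean(accuracyValues(acc)) - 50), 3)
})

test_that("category decoding isolates the planted dimension", {
  design <- tinyDesign(nObjects = 48, nChannels = 12, reps = 2,
                       runs = c(auditory = 1L))
  stimset <- buildStimulusSet(48, 3, seed = 2)
  model <- signalModel(stimset, design, snr = 4, modalityCoding = "shared",
                       categoryOnsetMs = 305, seed = 3)
  # keep the category code of one dimension only
  for (d in c("movement", "naturalness"))
    model@categoryPatterns[[d]][] <- 0
  tt <- generateTrialSequence(design, "auditory", seed = 4)
  ep <- dropOneBack(simulateEpochs(tt, stimset, model, design, seed = 5))
  perDim <- categoryDecode(ep, stimset, nRepetitions = 10, seed = 6,
                           average = FALSE)
  post <- function(a) mean(accuracyValues(a)[, timePoints(a) >= 400])
  expect_gt(post(perDim$size), 90)
  expect_lt(abs(post(perDim$movement) - 50), 8)
  expect_lt(abs(post(perDim$naturalness) - 50), 8)
  # the 3-dimension average is lifted by a third of the per-dimension excess
  avg <- categoryDecode(ep, stimset, nRepetitions = 10, seed = 6)
  excess <- vapply(perDim, function(a) post(a) - 50, numeric(1))
  expect_equal(post(avg) - 50, mean(excess), tolerance = 1e-10)
})

test_that("object-only signal gives chance-level category decoding", {
  design <- tinyDesign(nObjects = 48, nChannels = 12, reps = 2,
                       runs = c(auditory = 1L))
  stimset <- buildStimulusSet(48, 3, seed = 7)
  model <- signalModel(stimset, design, snr = 5, seed = 8)
  for (d in dimensionNames(stimset))
    model@categoryPatterns[[d]][] <- 0
  tt <- generateTrialSequence(design, "auditory", seed = 9)
  ep <- dropOneBack(simulateEpochs(tt, stimset, model, design, seed = 10))
  acc <- categoryDecode(ep, stimset, nRepetitions = 10, seed = 11)
  expect_lt(abs(mean(accuracyValues(acc)) - 50), 5)
  # while object decoding on the same data is far above chance
  obj <- pairwiseDecode(ep, nRepetitions = 2, nGroups = 2, seed = 12)
  expect_gt(mean(accuracyValues(obj)[, timePoints(obj) > 150]), 90)
})

test_that("leave-one-object-out decoding generalizes category structure", {
  design <- tinyDesign(nObjects = 16, nChannels = 12, reps = 3,
                       runs = c(auditory = 1L))
  stimset <- buildStimulusSet(16, 3, seed = 2)
  model <- signalModel(stimset, design, snr = 6, categoryOnsetMs = 305,
                       seed = 3)
  tt <- generateTrialSequence(design, "auditory", seed = 4)
  ep <- dropOneBack(simulateEpochs(tt, stimset, model, design, seed = 5))
  acc <- leaveOneObjectOutDecode(ep, stimset, "size")
  t <- timePoints(acc)
  expect_gt(mean(accuracyValues(acc)[, t >= 400]), 90)
  # object-idiosyncratic signal only: no generalization across objects
  model2 <- model
  for (d in dimensionNames(stimset))
    model2@categoryPatterns[[d]][] <- 0
  ep2 <- dropOneBack(simulateEpochs(tt, stimset, model2, design, seed = 6))
  acc2 <- leaveOneObjectOutDecode(ep2, stimset, "size")
  expect_lt(abs(mean(accuracyValues(acc2)) - 50), 8)
})

test_that("temporal generalization diagonal equals the cross-modal curve", {
  design <- tinyDesign(nObjects = 8, nChannels = 8, reps = 3)
  ses <- makeSession(seed = 17, snr = 3, coding = "shared",
                     design = design)
  cm <- crossmodalDecode(ses$epochs$auditory, ses$epochs$visual,
                         ses$stimset, nRepetitions = 2, seed = 9)
  tg <- temporalGeneralization(ses$epochs$auditory, ses$epochs$visual,
                               ses$stimset, nRepetitions = 2, seed = 9)
  expect_equal(diag(drop(accuracyValues(tg))),
               drop(accuracyValues(cm)))
})

test_that("a copied modality reduces cross-modal to train-on-test decoding", {
  design <- tinyDesign(nObjects = 8, nChannels = 8, reps = 3,
                       runs = c(auditory = 1L, visual = 1L))
  ses <- makeSession(seed = 19, snr = 4, coding = "shared",
                     design = design)
  epA <- ses$epochs$auditory
  acc <- crossmodalDecode(epA, epA, ses$stimset, nRepetitions = 2,
                          seed = 3)
  t <- timePoints(acc)
  expect_gt(mean(accuracyValues(acc)[, t >= 400]), 95)
})

test_that("repetition count affects variance, not expectation", {
  design <- tinyDesign(nObjects = 8, nChannels = 8, reps = 4,
                       runs = c(auditory = 1L))
  ses <- makeSession(seed = 23, snr = 1, design = design)
  ep <- ses$epochs$auditory
  m2 <- vapply(1:6, function(s)
    mean(accuracyValues(pairwiseDecode(ep, nRepetitions = 2, seed = s))),
    numeric(1))
  m6 <- vapply(1:6, function(s)
    mean(accuracyValues(pairwiseDecode(ep, nRepetitions = 6,
                                       seed = 100 + s))), numeric(1))
  expect_lt(abs(mean(m2) - mean(m6)), 1.5)
})

test_that("decoding validates its inputs", {
  design <- tinyDesign(nObjects = 8, reps = 3)
  ses <- makeSession(seed = 29, design = design)
  shortened <- ses$epochs$visual
  shortened@data <- shortened@data[, , 1:50, drop = FALSE]
  shortened@timeMs <- shortened@timeMs[1:50]
  expect_error(crossmodalDecode(ses$epochs$auditory, shortened,
                                ses$stimset, nRepetitions = 1, seed = 1),
               "time axis")
  arr <- array(rnorm(8), dim = c(1, 2, 2, 2))
  expect_error(decodeSuperTrials(stFromArray(arr)), "at least 2")
})
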