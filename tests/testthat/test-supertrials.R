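test_that("object super-trials partition trials into near-equal groups", {
  ses <- makeSession(seed = 1, design = tinyDesign(reps = 2,
                                                   runs = c(auditory = 3L)))
  ep <- ses$epochs$auditory                       # 6 trials per object
  st <- makeObjectSupertrials(ep, 3, seed = 2)
  expect_equal(dim(supertrialData(st))[1:2], c(8L, 3L))
  sizes <- unlist(lapply(provenance(st), function(p) lengths(p)))
  expect_true(all(sizes == 2L))
  # averaging identity: supertrial equals the mean of its sources
  pv <- provenance(st)[["obj01"]][[2]]
  expected <- apply(epochData(ep)[pv, , , drop = FALSE], c(2, 3), mean)
  expect_equal(supertrialData(st)[1, 2, , ], expected)
})

test_that("partition property holds across 100 seeds", {
  ses <- makeSession(seed = 4, design = tinyDesign(nObjects = 8, reps = 4,
                                                   runs = c(auditory = 1L)))
  ep <- ses$epochs$auditory
  for (seed in 1:100) {
    st <- makeObjectSupertrials(ep, 3, seed = seed)
    for (cond in conditionNames(st)) {
      src <- sort(unname(unlist(provenance(st)[[cond]])))
      expect_equal(src, which(trialInfo(ep)$object_id == cond))
    }
  }
})

test_that("super-trial averaging reduces noise variance", {
  # i.i.d. noise: variance of an average of k trials is 1/k-th
  ses <- makeSession(seed = 7, snr = 0,
                     design = tinyDesign(nObjects = 8, reps = 6,
                                         runs = c(auditory = 1L)))
  ep <- ses$epochs$auditory                       # 6 trials per object
  st <- makeObjectSupertrials(ep, 3, seed = 1)
  vSingle <- var(as.vector(epochData(ep)))
  vSuper <- var(as.vector(supertrialData(st)))
  expect_lt(vSuper, vSingle * 0.75)               # expect about half
})

test_that("category super-trials group object averages within levels", {
  design <- tinyDesign(nObjects = 48, nChannels = 6, reps = 1,
                       runs = c(auditory = 1L), onebackFraction = 0)
  ses <- makeSession(seed = 3, snr = 0, design = design)
  ep <- ses$epochs$auditory
  st <- makeCategorySupertrials(ep, ses$stimset, "size", 3, seed = 5)
  expect_equal(conditionNames(st),
               levels(categoryLabels(ses$stimset)$size))
  sizes <- lapply(provenance(st), lengths)
  expect_true(all(unlist(sizes) == 8L))           # 24 objects over 3 groups
  # object-independence: no object id in two super-trials
  allSrc <- unlist(provenance(st))
  expect_false(anyDuplicated(allSrc) > 0)
  expect_setequal(allSrc, objectIds(ses$stimset))
})

test_that("category super-trials equal the mean of their object averages", {
  design <- tinyDesign(nObjects = 8, nChannels = 4, reps = 2,
                       runs = c(auditory = 1L))
  ses <- makeSession(seed = 9, design = design)
  ep <- ses$epochs$auditory
  st <- makeCategorySupertrials(ep, ses$stimset, "movement", 2, seed = 1)
  avg <- mvpatime:::objectAverages(ep)
  pv <- provenance(st)[[1]][[1]]
  idx <- match(pv, avg$objects)
  expected <- apply(avg$data[idx, , , drop = FALSE], c(2, 3), mean)
  expect_equal(supertrialData(st)[1, 1, , ], expected)
})

test_that("super-trial formation validates trial counts", {
  design <- tinyDesign(nObjects = 8, reps = 2, runs = c(auditory = 1L),
                       onebackFraction = 0)
  ses <- makeSession(seed = 2, design = design)
  expect_error(makeObjectSupertrials(ses$epochs$auditory, 3, seed = 1),
               "obj01")
  expect_error(makeCategorySupertrials(ses$epochs$auditory, ses$stimset,
                                       "size", 5, seed = 1),
               "fewer objects")
  expect_error(makeCategorySupertrials(ses$epochs$auditory, ses$stimset,
                                       "color", 3, seed = 1),
               "not present")
})
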