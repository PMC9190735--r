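test_that("exhaustive sign-flip p values match independent enumeration", {
  withr::with_seed(41, {
    X <- matrix(rnorm(10 * 8, mean = 0.6), 10, 8)
    acc <- accuracyTimecourse(50 + X, seq(0, 35, by = 5))
    res <- clusterPermutationTest(acc, chance = 50, exhaustive = TRUE)
    expect_equal(res@nPermutations, 1024L)
    # oracle: explicit loop over all sign assignments
    for (tp in c(1, 4, 8)) {
      x <- X[, tp]
      obs <- mean(x)
      cnt <- 0L
      for (k in 0:1023) {
        s <- 1 - 2 * as.integer(intToBits(k))[1:10]
        if (mean(s * x) >= obs) cnt <- cnt + 1L
      }
      expect_equal(pointwiseP(res)[tp], cnt / 1024)
    }
  })
})

test_that("random sign flips converge to the exhaustive null", {
  withr::with_seed(43, {
    X <- 50 + matrix(rnorm(10 * 12, mean = 0.4), 10, 12)
  })
  acc <- accuracyTimecourse(X, seq(0, 55, by = 5))
  exact <- clusterPermutationTest(acc, exhaustive = TRUE)
  mc <- clusterPermutationTest(acc, nPermutations = 10000, seed = 7)
  expect_lt(max(abs(pointwiseP(exact) - pointwiseP(mc))), 0.02)
})

test_that("degenerate inputs give the expected cluster outcomes", {
  t <- seq(0, 95, by = 5)
  # all participants exactly at chance: nothing can be significant
  flat <- accuracyTimecourse(matrix(50, 8, 20), t)
  res <- clusterPermutationTest(flat, nPermutations = 500, seed = 1)
  expect_false(any(significantMask(res)))
  # constant +10 effect across the whole epoch: one full-epoch cluster
  up <- accuracyTimecourse(matrix(60, 12, 20), t)
  res2 <- clusterPermutationTest(up, nPermutations = 2000, seed = 2)
  ct <- clusterTable(res2)
  expect_equal(nrow(ct[ct$significant, ]), 1L)
  expect_equal(ct$size[1], 20L)
  expect_equal(c(ct$start_ms[1], ct$end_ms[1]), c(0, 95))
  expect_true(all(significantMask(res2)))
})

test_that("upscaling a genuine effect never shrinks the significant mask", {
  withr::with_seed(47, {
    eff <- c(rep(0, 8), rep(1.2, 8), rep(0, 4))
    X <- 50 + matrix(rnorm(12 * 20, sd = 1.5), 12, 20) +
      matrix(eff, 12, 20, byrow = TRUE)
  })
  acc1 <- accuracyTimecourse(X, seq(0, 95, by = 5))
  acc2 <- accuracyTimecourse(50 + (X - 50) * 1.5, seq(0, 95, by = 5))
  m1 <- significantMask(clusterPermutationTest(acc1, seed = 5,
                                               nPermutations = 2000))
  m2 <- significantMask(clusterPermutationTest(acc2, seed = 5,
                                               nPermutations = 2000))
  expect_true(all(m2[m1]))
  expect_true(any(m1))
})

test_that("participant order is irrelevant under exhaustive flips", {
  withr::with_seed(53, {
    X <- 50 + matrix(rnorm(8 * 15, mean = 0.5), 8, 15)
  })
  t <- seq(0, 70, by = 5)
  r1 <- clusterPermutationTest(accuracyTimecourse(X, t),
                               exhaustive = TRUE)
  r2 <- clusterPermutationTest(accuracyTimecourse(X[8:1, ], t),
                               exhaustive = TRUE)
  expect_equal(pointwiseP(r1), pointwiseP(r2))
  expect_equal(clusterTable(r1), clusterTable(r2))
})

test_that("the t statistic variant handles the same cases", {
  withr::with_seed(59, {
    X <- 50 + matrix(rnorm(10 * 20), 10, 20)
    X[, 5:10] <- X[, 5:10] + 2
  })
  res <- clusterPermutationTest(accuracyTimecourse(X, seq(0, 95, 5)),
                                statistic = "t", nPermutations = 2000,
                                seed = 3)
  expect_s4_class(res, "ClusterInferenceResult")
  expect_true(any(significantMask(res)[5:10]))
})

test_that("cluster test warns or errors on inadequate inputs", {
  acc <- accuracyTimecourse(matrix(50, 1, 10), seq(0, 45, 5))
  expect_error(clusterPermutationTest(acc), "at least 2")
  acc2 <- accuracyTimecourse(matrix(50 + rnorm(40), 4, 10),
                             seq(0, 45, 5))
  expect_warning(clusterPermutationTest(acc2, nPermutations = 10,
                                        seed = 1), "resolution")
})

test_that("bootstrap peak test recovers a planted latency order", {
  t <- seq(-200, 800, by = 5)
  withr::with_seed(61, {
    A <- t(replicate(24, bumpCurve(t, 150) + rnorm(length(t), sd = 1)))
    B <- t(replicate(24, bumpCurve(t, 400) + rnorm(length(t), sd = 1)))
  })
  accA <- accuracyTimecourse(A, t)
  accB <- accuracyTimecourse(B, t)
  # A peaks at 150, B at 400: A is reliably earlier
  later <- bootstrapPeakLatencyDifference(accA, accB, seed = 2,
                                          alternative = "greater")
  earlier <- bootstrapPeakLatencyDifference(accA, accB, seed = 2,
                                            alternative = "less")
  expect_lt(later@pOneTailed, 0.05)
  expect_gt(earlier@pOneTailed, 0.95)
  expect_equal(unname(peakLatencies(later)["A"]), 150, tolerance = 15)
  expect_equal(unname(peakLatencies(later)["B"]), 400, tolerance = 15)
})

test_that("bootstrap peak test is deterministic and flags degeneracy", {
  t <- seq(0, 200, by = 5)
  withr::with_seed(67, {
    A <- t(replicate(10, bumpCurve(t, 100) + rnorm(length(t))))
  })
  accA <- accuracyTimecourse(A, t)
  r1 <- bootstrapPeakLatencyDifference(accA, accA, seed = 9)
  r2 <- bootstrapPeakLatencyDifference(accA, accA, seed = 9)
  expect_identical(bootDifferences(r1), bootDifferences(r2))
  # identical conditions: all differences zero, p forced to 0, flagged
  expect_true(all(bootDifferences(r1) == 0))
  expect_equal(r1@pOneTailed, 0)
  expect_true(r1@degenerate)
  # flat curves tie-break to the earliest timepoint and are flagged
  flat <- accuracyTimecourse(matrix(50, 10, length(t)), t)
  rf <- bootstrapPeakLatencyDifference(flat, accA, seed = 1)
  expect_equal(rf@peakMsA, 0)
  expect_true(rf@degenerate)
})
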