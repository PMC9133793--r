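test_that("pooled t and Cohen's d reproduce the printed behavioral battery", {
  ## worked examples
  wi <- pooledTD(110.17, 7.87, 24, 90.63, 9.39, 24)
  expect_equal(wi$d, 2.26, tolerance = 0.005)
  wa <- pooledTD(101.50, 8.29, 24, 78.83, 9.95, 24)
  expect_equal(wa$t, 8.58, tolerance = 0.01)

  ## full-row regression over the bundled battery
  tab <- behavioralReferenceTable()
  expect_equal(nrow(tab), 11L)
  for (i in seq_len(nrow(tab))) {
    res <- pooledTD(tab$mean_control[i], tab$sd_control[i],
                    tab$n_per_group[i], tab$mean_dyslexia[i],
                    tab$sd_dyslexia[i], tab$n_per_group[i])
    expect_lt(abs(res$t - tab$t_printed[i]), 0.02)
    expect_lt(abs(res$d - tab$d_printed[i]), 0.01)
  }

  ## trivial and error cases
  eq <- pooledTD(5, 1, 10, 5, 1, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$d, 0)
  expect_equal(eq$p, 1)
  expect_error(pooledTD(1, 1, 1, 2, 1, 10), ">= 2")
  expect_error(pooledTD(1, 0, 10, 2, 1, 10), "positive")
})

test_that("the sign-permutation cluster test handles exact nulls and the p floor", {
  tms <- seq(0, 190, by = 10)
  ## all-zero deviation: no suprathreshold clusters
  zero <- matrix(0.5, 6, length(tms))
  res0 <- signPermutationClusterTest(zero, tms,
                                     clusterTestConfig(nPermutations = 500))
  expect_equal(nrow(clusterTable(res0)), 0L)
  expect_false(any(significantMask(res0)))

  ## observed mass exceeding every permuted maximum: p = 1/nPermutations
  big <- matrix(0.5, 30, length(tms))
  big[, 5:14] <- 0.8
  big <- big + matrix(rnorm(length(big), 0, 1e-3), nrow(big))
  cfg <- clusterTestConfig(nPermutations = 1000, seed = 4)
  resF <- signPermutationClusterTest(big, tms, cfg)
  ct <- clusterTable(resF)
  expect_equal(min(ct$corrected_p), 1 / 1000)
  expect_true(any(significantMask(resF)))

  ## determinism and p-value bounds
  noisy <- smoothSeries(8, length(tms), 0.05, seed = 9)
  r1 <- signPermutationClusterTest(noisy, tms, cfg)
  r2 <- signPermutationClusterTest(noisy, tms, cfg)
  expect_identical(clusterTable(r1), clusterTable(r2))
  if (nrow(clusterTable(r1))) {
    expect_true(all(clusterTable(r1)$corrected_p >= 1 / 1000))
    expect_true(all(clusterTable(r1)$corrected_p <= 1))
  }
  expect_error(signPermutationClusterTest(noisy, tms,
    clusterTestConfig(analysisWindow = c(900, 1000))), "empty analysis")
  expect_error(signPermutationClusterTest(noisy[1, , drop = FALSE], tms,
                                          cfg), "2 subjects")
})

test_that("Monte-Carlo cluster p matches exhaustive sign enumeration", {
  ## fixture chosen so no pointwise p sits near the cluster-forming
  ## threshold (mask identical under enumeration and sampling)
  set.seed(34)
  n <- 10L; nt <- 8L
  D <- matrix(rnorm(n * nt, 0, 0.05), n, nt)
  D[, 4:5] <- D[, 4:5] + 0.03
  pEnum <- enumClusterOracle(D, alphaDef = 0.05)
  cfg <- clusterTestConfig(nPermutations = 4000, nullValue = 0,
                           analysisWindow = c(0, nt - 1), seed = 5)
  res <- signPermutationClusterTest(D, seq(0, nt - 1), cfg)
  expect_gt(nrow(clusterTable(res)), 0L)
  expect_gt(length(pEnum), 0L)
  pm <- min(clusterTable(res)$corrected_p)
  pe <- min(pEnum)
  se <- sqrt(pe * (1 - pe) / 4000)
  expect_lt(abs(pm - pe), 3 * se + 1e-6)
})

test_that("adding a constant shifts the one-sample map and cancels between groups", {
  tms <- seq(0, 140, by = 10)
  A <- smoothSeries(10, length(tms), 0.04, seed = 31)
  cfg <- clusterTestConfig(nPermutations = 400, nullValue = 0.5, seed = 6)
  base <- signPermutationClusterTest(A, tms, cfg)
  shifted <- signPermutationClusterTest(A + 0.1, tms, cfg)
  expect_equal(shifted@statisticMap, base@statisticMap + 0.1,
               tolerance = 1e-12)

  B <- smoothSeries(10, length(tms), 0.04, seed = 32)
  cfg2 <- clusterTestConfig(nPermutations = 400, alternative = "two.sided",
                            nullValue = 0, seed = 7)
  t1 <- twoSampleClusterTest(A, B, tms, cfg2)
  t2 <- twoSampleClusterTest(A + 0.2, B + 0.2, tms, cfg2)
  expect_equal(t1@statisticMap, t2@statisticMap, tolerance = 1e-12)
  expect_identical(clusterTable(t1)$corrected_p,
                   clusterTable(t2)$corrected_p)
})

test_that("two-sample tests: duplicated groups, paired variant, input guards", {
  tms <- seq(0, 140, by = 10)
  A <- smoothSeries(8, length(tms), 0.05, seed = 41)
  cfg <- clusterTestConfig(nPermutations = 300, alternative = "two.sided",
                           nullValue = 0, seed = 8)
  dup <- twoSampleClusterTest(A, A, tms, cfg)
  expect_true(all(dup@statisticMap == 0))
  expect_equal(nrow(clusterTable(dup)), 0L)

  ## paired sign-flip variant equals the one-sample test on differences
  B <- smoothSeries(8, length(tms), 0.05, seed = 42)
  pv <- twoSampleClusterTest(A, B, tms, cfg,
                             method = "signflip-differences")
  cfg1 <- cfg
  cfg1$nullValue <- 0
  ov <- signPermutationClusterTest(A - B, tms, cfg1)
  expect_identical(pv@statisticMap, ov@statisticMap)
  expect_identical(clusterTable(pv), clusterTable(ov))

  expect_error(twoSampleClusterTest(A[1:3, ], B, tms, cfg,
                                    method = "signflip-differences"),
               "equally sized")
})

test_that("onset and peak latencies follow the mask and the group mean", {
  tms <- seq(0, 500, by = 10)
  n <- 14L
  bump <- 0.2 * exp(-((tms - 280) / 80)^2)
  bump[tms < 120] <- 0
  S <- 0.5 + rep(1, n) %o% bump +
    smoothSeries(n, length(tms), 0.02, seed = 51, base = 0)
  cfg <- clusterTestConfig(nPermutations = 1000, seed = 9)
  res <- signPermutationClusterTest(S, tms, cfg)
  lat <- onsetPeakLatency(res)
  expect_true(lat$onsetDefined)
  expect_lte(abs(lat$peak_ms - 280), 30)
  expect_lte(lat$onset_ms, 180)
  expect_gte(lat$onset_ms, 100)

  ## no significant cluster: onset undefined, peak still reported
  null <- smoothSeries(6, length(tms), 0.002, seed = 52)
  resN <- signPermutationClusterTest(null, tms,
                                     clusterTestConfig(nPermutations = 300,
                                                       seed = 10))
  latN <- onsetPeakLatency(resN)
  expect_false(latN$onsetDefined)
  expect_true(is.na(latN$onset_ms))
  expect_false(is.na(latN$peak_ms))
})

test_that("bootstrap latency comparisons are exact for identity and recover shifts", {
  tms <- seq(0, 400, by = 4)
  set.seed(61)
  n <- 12L
  A <- t(sapply(seq_len(n), function(i) {
    noise <- stats::filter(rnorm(length(tms), 0, 0.05), rep(1 / 15, 15),
                           circular = TRUE)
    0.5 + 0.18 / (1 + exp(-(tms - 150 - rnorm(1, 0, 6)) / 12)) +
      as.numeric(noise)
  }))
  cfg <- clusterTestConfig(nPermutations = 400,
                           analysisWindow = c(0, 400))

  idres <- bootstrapLatencyTest(A, A, tms, kind = "onset", paired = TRUE,
                                nBoot = 60, config = cfg, seed = 11)
  expect_equal(idres@pTwoSided, 1)
  expect_true(all(idres@bootstrapDifferences == 0))
  expect_false(idres@unreliable)

  ## +48 ms literal time shift (12 grid steps at 4 ms)
  shift <- 12L
  B <- cbind(matrix(A[, 1], n, shift), A[, seq_len(ncol(A) - shift)])
  sres <- bootstrapLatencyTest(A, B, tms, kind = "onset", paired = TRUE,
                               nBoot = 120, config = cfg, seed = 12)
  expect_equal(sres@observedDifference, -48)
  expect_lte(abs(median(sres@bootstrapDifferences) + 48), 4)
  expect_lt(sres@pTwoSided, 0.05)

  pres <- bootstrapLatencyTest(A, B, tms, kind = "peak", paired = TRUE,
                               nBoot = 60, config = cfg, seed = 13)
  expect_true(is.finite(pres@pTwoSided))
})

test_that("the bootstrap latency test keeps its size on null-difference cohorts", {
  tms <- seq(0, 390, by = 10)
  bump <- 0.15 / (1 + exp(-(tms - 150) / 15))
  cfg <- clusterTestConfig(nPermutations = 150, analysisWindow = c(0, 390))
  mkCohort <- function(seed) {
    set.seed(seed)
    0.5 + rep(1, 8) %o% bump +
      t(sapply(1:8, function(i)
        as.numeric(stats::filter(rnorm(length(tms), 0, 0.04),
                                 rep(1 / 4, 4), circular = TRUE))))
  }
  rej <- vapply(1:100, function(s) {
    A <- mkCohort(400000 + s)
    B <- mkCohort(500000 + s)
    res <- bootstrapLatencyTest(A, B, tms, kind = "onset", nBoot = 60,
                                config = cfg, seed = 600000 + s)
    isTRUE(res@pTwoSided < 0.05)
  }, logical(1))
  expect_lte(mean(rej), 0.07)
})
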