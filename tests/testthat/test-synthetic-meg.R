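test_that("sensor layout partitions types with the 102/204 default split", {
  lay <- sensorLayout()
  expect_length(sensorTypes(lay), 306L)
  expect_equal(sum(sensorTypes(lay) == "mag"), 102L)
  expect_equal(sum(sensorTypes(lay) == "grad"), 204L)
  expect_equal(lay@units[["mag"]], "fT")
  expect_equal(lay@units[["grad"]], "fT/cm")
})

test_that("ground truth honors profiles, kernels, and validity", {
  tms <- seq(-100, 400, by = 5)
  tr <- groundTruth(times = tms, nSensors = 12, profile = "control",
                    seed = 2)
  expect_equal(sum(tr@commonTopography^2), 1, tolerance = 1e-10)
  expect_equal(sum(tr@devianceTopography^2), 1, tolerance = 1e-10)
  expect_equal(sum(tr@commonTopography * tr@devianceTopography), 0,
               tolerance = 1e-10)
  expect_true(all(tr@devianceKernel[tms <= 100] == 0))
  expect_equal(tms[which.max(tr@devianceKernel)], 280)
  expect_true(all(tr@commonKernel[tms < 0] == 0))
  expect_equal(tr@attenuationProfile, c(1, 0.6, 0.4, 0.2, 0.1, 0.05))
  flat <- groundTruth(times = tms, nSensors = 12, profile = "dyslexia")
  expect_equal(unique(flat@attenuationProfile[-1]), 0.6)
  expect_equal(groundTruth(times = tms, nSensors = 12,
                           profile = "null")@attenuationProfile, rep(1, 6))
  ev <- eigen(tr@noiseCovariance, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(max(ev) / min(ev), 100, tolerance = 0.01)
  expect_error(groundTruth(times = tms, nSensors = 12, profile = "custom"),
               "attenuation")
  expect_error(groundTruth(times = tms, nSensors = 12,
                           attenuation = c(0.5, 1, 1, 1, 1, 1)),
               "position 1")
})

test_that("noiseless simulation is the deterministic two-component model", {
  d <- smokeDesign(seed = 4, nTrains = 30L)
  tms <- seq(-50, 300, by = 10)
  tr <- groundTruth(times = tms, nSensors = 8, profile = "control",
                    noiseScale = 0, trialJitterSD = 0, seed = 3)
  ep <- simulateEpochs(d, tr, sensorLayout(8), seed = 5)
  x <- epochsArray(ep)
  pos <- trialInfo(ep)$position_in_train
  expected1 <- tr@commonAmplitude * outer(tr@commonTopography,
                                          tr@commonKernel) +
    tr@devianceAmplitude * outer(tr@devianceTopography, tr@devianceKernel)
  for (i in which(pos == 1L))
    expect_equal(x[i, , ], expected1, tolerance = 1e-12)
  ## attenuation multiplies only the deviance component
  i4 <- which(pos == 4L)[1L]
  proj <- colSums(x[i4, , ] * tr@devianceTopography)
  expect_equal(proj, 0.2 * tr@devianceAmplitude * tr@devianceKernel,
               tolerance = 1e-10)
})

test_that("projection onto the deviance pattern recovers the repetition profile", {
  d <- smokeDesign(seed = 6, nTrains = 60L)
  tms <- seq(-50, 350, by = 10)
  tr <- groundTruth(times = tms, nSensors = 16, profile = "control",
                    trialJitterSD = 0, noiseScale = 5, seed = 7)
  ep <- simulateEpochs(d, tr, sensorLayout(16), seed = 8)
  x <- epochsArray(ep)
  pos <- trialInfo(ep)$position_in_train
  pk <- which.max(tr@devianceKernel)
  proj <- apply(x[, , pk], 1L, function(v) sum(v * tr@devianceTopography))
  m <- tapply(proj, pos, mean)
  A <- tr@devianceAmplitude  # kernel is 1 at its peak
  ## 1sts-vs-4ths mean difference exceeds 1sts-vs-2nds by the constructed
  ## factor (0.8 A vs 0.4 A)
  expect_equal(m[["1"]] - m[["4"]], 0.8 * A, tolerance = 0.15 * A)
  expect_equal(m[["1"]] - m[["2"]], 0.4 * A, tolerance = 0.15 * A)
  expect_equal((m[["1"]] - m[["4"]]) / (m[["1"]] - m[["2"]]), 2,
               tolerance = 0.25)
})

test_that("emitted noise matches the requested covariance and purity", {
  ## noise-only epochs: sensor covariance converges to noiseScale^2 * Sigma
  dd <- smokeDesign(seed = 2, nTrains = 501L)  # ~2500 trials
  tms <- seq(-20, 20, by = 10)
  tr <- groundTruth(times = tms, nSensors = 8, profile = "null",
                    commonAmplitude = 0, devianceAmplitude = 0,
                    noiseScale = 2, seed = 1)
  ep <- simulateEpochs(dd, tr, sensorLayout(8), seed = 2)
  x <- epochsArray(ep)
  obs <- matrix(aperm(x, c(1, 3, 2)), prod(dim(x)[c(1, 3)]), 8)
  S <- crossprod(obs) / (nrow(obs) - 1)
  target <- 4 * tr@noiseCovariance
  relErr <- norm(S - target, "F") / norm(target, "F")
  expect_lt(relErr, 0.05)
  ## prestimulus purity with kernels on: mean over trials ~ 0 before 0 ms
  tr2 <- groundTruth(times = seq(-100, 100, by = 10), nSensors = 8,
                     profile = "control", seed = 3)
  ep2 <- simulateEpochs(smokeDesign(seed = 3, nTrains = 120L), tr2,
                        sensorLayout(8), seed = 4)
  pre <- epochsArray(ep2)[, , epochTimes(ep2) < 0]
  se <- tr2@noiseScale / sqrt(dim(pre)[1L])
  expect_lt(max(abs(apply(pre, c(2, 3), mean))), 5 * se)
})

test_that("simulation is bitwise deterministic in the seed", {
  d <- smokeDesign(seed = 9, nTrains = 15L)
  tms <- seq(-50, 100, by = 10)
  tr <- groundTruth(times = tms, nSensors = 6, seed = 5)
  a <- simulateEpochs(d, tr, sensorLayout(6), seed = 42)
  b <- simulateEpochs(d, tr, sensorLayout(6), seed = 42)
  expect_identical(epochsArray(a), epochsArray(b))
  c2 <- simulateEpochs(d, tr, sensorLayout(6), seed = 43)
  expect_false(identical(epochsArray(a), epochsArray(c2)))
})

test_that("artifact injection returns the corrupted list and warns when weak", {
  d <- smokeDesign(seed = 10, nTrains = 60L)
  tms <- seq(-50, 150, by = 10)
  tr <- groundTruth(times = tms, nSensors = 8, seed = 6)
  ep <- simulateEpochs(d, tr, sensorLayout(8), seed = 7)

  none <- injectArtifacts(ep, 0, seed = 1)
  expect_identical(epochsArray(none$epochs), epochsArray(ep))
  expect_length(none$corrupted, 0L)

  out <- injectArtifacts(ep, 0.05, seed = 1)
  expect_length(out$corrupted, round(0.05 * nrow(trialInfo(ep))))
  changed <- which(apply(epochsArray(out$epochs) != epochsArray(ep), 1, any))
  expect_identical(changed, out$corrupted)

  expect_warning(injectArtifacts(ep, 0.05,
                                 amplitude = c(mag = 100, grad = 100),
                                 seed = 2),
                 "survive rejection")
  expect_error(injectArtifacts(ep, 1.2), "fraction")
})
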