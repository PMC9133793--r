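## Synthetic sensor-level epochs with ground-truth deviance and
## repetition-attenuation structure.

#' Construct a sensor layout
#'
#' @param nSensors total sensor count (default 306).
#' @param magFraction fraction of magnetometers (default 1/3, i.e. the
#'   102/204 magnetometer/gradiometer split of a 306-channel system).
#' @return A [SensorLayout-class]; magnetometers come first.
#' @export
sensorLayout <- function(nSensors = 306L, magFraction = 1 / 3) {
  nSensors <- as.integer(nSensors)
  nMag <- max(1L, round(nSensors * magFraction))
  if (nMag >= nSensors) nMag <- nSensors - 1L
  new("SensorLayout",
      sensorType = c(rep("mag", nMag), rep("grad", nSensors - nMag)),
      units = c(mag = "fT", grad = "fT/cm"))
}

## Smooth gamma-like bump: 0 before onset, rises to 1 at the peak, decays.
gammaBump <- function(times, onsetMs, peakMs, shape = 3) {
  u <- (times - onsetMs) / (peakMs - onsetMs)
  k <- ifelse(u > 0, u^shape * exp(shape * (1 - u)), 0)
  k[times <= onsetMs] <- 0
  k
}

## Named repetition-attenuation profiles (multiplier on the deviance
## component by position-in-train; position 1 is the deviant, always 1).
attenuationProfiles <- list(
  control  = c(1, 0.6, 0.4, 0.2, 0.1, 0.05),
  dyslexia = c(1, 0.6, 0.6, 0.6, 0.6, 0.6),
  null     = c(1, 1, 1, 1, 1, 1)
)

#' Ground truth for the epoch simulator
#'
#' Builds the generative model for synthetic epochs: two unit-norm,
#' mutually orthogonal sensor patterns (a common auditory response and a
#' deviance-specific component), smooth gamma-shaped temporal kernels (the
#' deviance kernel rising at ~100 ms and peaking at ~280 ms), a
#' position-in-train attenuation profile for the deviance component, and a
#' spatially correlated noise covariance (random orthogonal mixing of
#' exponentially decaying eigenvalues, condition number ~100, so that
#' multivariate noise normalization is consequential).
#'
#' Profiles: `"control"` attenuates the deviance component cumulatively
#' over repetitions (multipliers 1, 0.6, 0.4, 0.2, 0.1, 0.05 for positions
#' 1-6), `"dyslexia"` attenuates immediately but flatly (1 then 0.6 for all
#' repetitions), `"null"` applies no attenuation anywhere, leaving no
#' decodable deviant-vs-standard difference.
#'
#' Default amplitudes and noise scale are calibrated so that a default
#' synthetic participant decodes deviants from standards with post-onset
#' peak accuracies in the 60-80% band (see the package vignette).
#'
#' @param times epoch time grid in ms (default -200..550 at 1,000 Hz).
#' @param nSensors sensor count.
#' @param profile attenuation profile name, or "custom" with
#'   `attenuation` supplied.
#' @param attenuation optional numeric multipliers per position (first
#'   element must be 1).
#' @param commonAmplitude,devianceAmplitude component amplitudes (nominal
#'   fT scale).
#' @param devianceOnsetMs,deviancePeakMs deviance-kernel landmarks.
#' @param commonOnsetMs,commonPeakMs common-kernel landmarks.
#' @param trialJitterSD SD of multiplicative per-trial amplitude jitter on
#'   the deviance component.
#' @param noiseScale noise standard-deviation scale (nominal fT).
#' @param conditionNumber eigenvalue spread of the noise covariance.
#' @param kernelShape shape of the gamma-like temporal kernels (smaller =
#'   faster initial rise; default 2).
#' @param seed RNG seed for topographies and the noise-covariance mixing.
#' @return A [GroundTruth-class].
#' @export
groundTruth <- function(times = seq(-200, 550, by = 1), nSensors = 306L,
                        profile = c("control", "dyslexia", "null", "custom"),
                        attenuation = NULL,
                        commonAmplitude = 45, devianceAmplitude = 30,
                        devianceOnsetMs = 100, deviancePeakMs = 280,
                        commonOnsetMs = 40, commonPeakMs = 130,
                        trialJitterSD = 0.2, noiseScale = 60,
                        conditionNumber = 100, kernelShape = 2,
                        seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(attenuation)) {
    if (profile == "custom")
      stop("profile 'custom' requires an 'attenuation' vector")
    attenuation <- attenuationProfiles[[profile]]
  } else if (profile != "custom") {
    profile <- "custom"
  }
  if (abs(attenuation[1L] - 1) > 1e-12)
    stop("attenuation multiplier for position 1 (the deviant) must be 1")
  nSensors <- as.integer(nSensors)
  withSeed(seed, {
    ct <- rnorm(nSensors)
    ct <- ct / sqrt(sum(ct^2))
    dt <- rnorm(nSensors)
    dt <- dt - sum(dt * ct) * ct  # orthogonal to the common pattern
    dt <- dt / sqrt(sum(dt^2))
    ## noise covariance: Q diag(lambda) Q', eigenvalues exp-decaying with
    ## the requested condition number, normalized to mean 1
    Q <- qr.Q(qr(matrix(rnorm(nSensors^2), nSensors)))
    lambda <- exp(seq(0, -log(conditionNumber),
                      length.out = nSensors))
    lambda <- lambda / mean(lambda)
    Sigma <- Q %*% (lambda * t(Q))
    Sigma <- (Sigma + t(Sigma)) / 2
    new("GroundTruth",
        times = times,
        commonTopography = ct, devianceTopography = dt,
        commonKernel = gammaBump(times, commonOnsetMs, commonPeakMs,
                                 shape = kernelShape),
        devianceKernel = gammaBump(times, devianceOnsetMs, deviancePeakMs,
                                   shape = kernelShape),
        commonAmplitude = commonAmplitude,
        devianceAmplitude = devianceAmplitude,
        attenuationProfile = attenuation,
        profileName = profile,
        trialJitterSD = trialJitterSD,
        noiseCovariance = Sigma,
        noiseScale = noiseScale)
  })
}

#' Simulate epoched sensor data for a train design
#'
#' Each trial is
#' `commonAmplitude * commonTopography x commonKernel +
#'  m(position) * devianceAmplitude * (1 + jitter) *
#'  devianceTopography x devianceKernel + spatially correlated noise`,
#' where `m(position)` is the attenuation multiplier (1 for deviants) and
#' the noise is Gaussian with covariance `noiseScale^2 * noiseCovariance`,
#' independent across time points. Deterministic given `seed`.
#'
#' @param design a [TrainDesign-class].
#' @param truth a [GroundTruth-class].
#' @param layout a [SensorLayout-class] matching `truth`'s sensor count.
#' @param seed RNG seed.
#' @return An [EpochsData-class] in "raw" normalization state.
#' @export
simulateEpochs <- function(design, truth, layout = NULL, seed = 1L) {
  stopifnot(is(design, "TrainDesign"), is(truth, "GroundTruth"))
  ns <- length(truth@commonTopography)
  if (is.null(layout)) layout <- sensorLayout(ns)
  if (length(layout@sensorType) != ns)
    stop("sensor layout does not match the ground truth sensor count")
  trials <- design@trials
  n <- nrow(trials)
  if (n == 0L) stop("design has no trials")
  nt <- length(truth@times)
  pos <- trials$position_in_train
  if (max(pos) > length(truth@attenuationProfile))
    stop("attenuation profile does not cover all positions in the design")
  m <- truth@attenuationProfile[pos]

  commonMat <- truth@commonAmplitude *
    outer(truth@commonTopography, truth@commonKernel)
  devMat <- truth@devianceAmplitude *
    outer(truth@devianceTopography, truth@devianceKernel)
  R <- chol(truth@noiseCovariance)

  withSeed(seed, {
    jitter <- rnorm(n, 0, truth@trialJitterSD)
    x <- array(0, dim = c(n, ns, nt))
    for (i in seq_len(n)) {
      noise <- truth@noiseScale *
        crossprod(R, matrix(rnorm(ns * nt), ns, nt))
      x[i, , ] <- commonMat + m[i] * (1 + jitter[i]) * devMat + noise
    }
    dtms <- if (nt > 1L) diff(truth@times[1:2]) else 1
    new("EpochsData", data = x, times = truth@times, sfreq = 1000 / dtms,
        layout = layout, trials = trials, normalizationState = "raw")
  })
}

#' Inject high-amplitude artifact trials
#'
#' Adds a short high-amplitude pulse to one random sensor of a random
#' subset of trials, so that downstream peak-to-peak artifact rejection can
#' be tested against a known corrupted set. The pulse amplitude is
#' specified per sensor type; a warning is issued when it does not exceed
#' the rejection threshold for that type (such trials may survive
#' rejection).
#'
#' @param epochs an [EpochsData-class] (raw state).
#' @param fraction proportion of trials to corrupt, in `[0, 1)`.
#' @param amplitude named numeric, pulse amplitude per sensor type; the
#'   default is twice the standard rejection thresholds.
#' @param criteria a [rejectionCriteria()] used only for the
#'   below-threshold warning.
#' @param seed RNG seed.
#' @return A list with `epochs` (corrupted copy) and `corrupted` (sorted
#'   trial indices that received a pulse).
#' @export
injectArtifacts <- function(epochs, fraction,
                            amplitude = c(mag = 20000, grad = 5000),
                            criteria = rejectionCriteria(), seed = 1L) {
  stopifnot(is(epochs, "EpochsData"))
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  n <- dim(epochs@data)[1L]
  nCorrupt <- round(fraction * n)
  if (nCorrupt == 0L)
    return(list(epochs = epochs, corrupted = integer(0)))
  thr <- c(mag = criteria$magPtpMax, grad = criteria$gradPtpMax)
  low <- names(amplitude)[amplitude <= thr[names(amplitude)]]
  if (length(low))
    warning("artifact amplitude at or below the rejection threshold for: ",
            paste(low, collapse = ", "), " (trials may survive rejection)")
  nt <- length(epochs@times)
  pulseLen <- max(3L, min(nt, round(nt / 25)))
  withSeed(seed, {
    corrupted <- sort(sample.int(n, nCorrupt))
    for (i in corrupted) {
      s <- sample.int(dim(epochs@data)[2L], 1L)
      t0 <- sample.int(nt - pulseLen + 1L, 1L)
      amp <- amplitude[[epochs@layout@sensorType[s]]]
      pulse <- amp * gammaBump(seq_len(pulseLen), 0, pulseLen / 2, shape = 2)
      epochs@data[i, s, t0:(t0 + pulseLen - 1L)] <-
        epochs@data[i, s, t0:(t0 + pulseLen - 1L)] + pulse
    }
    list(epochs = epochs, corrupted = corrupted)
  })
}
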