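## Central S4 containers. Configuration objects are validated plain lists
## (see designSpec(), decodeConfig(), clusterTestConfig(), ...) so that they
## serialize naturally to JSON provenance records.

#' Psychometric (logistic) fit of a labeling function
#'
#' Four-parameter logistic fit of a /ba/-/da/ labeling proportion against
#' continuum step, used to locate a participant's categorical boundary.
#' The midpoint is the inflection point of the sigmoid; asymptotes are
#' constrained to proportions.
#'
#' @slot midpoint numeric(1), boundary location in continuum-step units.
#' @slot slope numeric(1), logistic slope per continuum step (positive for
#'   responses increasing toward /da/).
#' @slot asymptotes numeric(2), lower and upper asymptote in `[0, 1]`.
#' @slot converged logical(1), whether the least-squares fit converged on
#'   non-degenerate data.
#' @slot residualSS numeric(1), residual sum of squares (NA when not
#'   converged).
#' @exportClass PsychometricFit
setClass("PsychometricFit",
  representation(
    midpoint = "numeric",
    slope = "numeric",
    asymptotes = "numeric",
    converged = "logical",
    residualSS = "numeric"
  )
)

setValidity("PsychometricFit", function(object) {
  msg <- character()
  if (length(object@converged) != 1L)
    msg <- c(msg, "'converged' must be a single flag")
  if (isTRUE(object@converged) && !is.finite(object@midpoint))
    msg <- c(msg, "midpoint must be finite when converged")
  if (length(object@asymptotes) == 2L &&
      all(is.finite(object@asymptotes)) &&
      (any(object@asymptotes < -1e-8) || any(object@asymptotes > 1 + 1e-8)))
    msg <- c(msg, "asymptotes must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Equidistant five-stimulus set on a perceptual continuum
#'
#' Stimuli A-E as integer continuum steps, centered (subject to clamping at
#' the continuum edge) on the psychometric boundary.
#'
#' @slot steps integer(5), strictly increasing, equidistant continuum steps
#'   for stimuli A-E; stimulus C is `steps[3]`.
#' @slot spacing integer(1), step distance between neighboring stimuli.
#' @slot clamped logical(1), TRUE when the boundary had to be moved so the
#'   equidistant set fits inside the continuum.
#' @exportClass StimulusSet
setClass("StimulusSet",
  representation(steps = "integer", spacing = "integer", clamped = "logical")
)

setValidity("StimulusSet", function(object) {
  msg <- character()
  if (length(object@steps) != 5L)
    msg <- c(msg, "exactly 5 stimulus steps (A-E) required")
  else {
    d <- diff(object@steps)
    if (any(d <= 0L)) msg <- c(msg, "steps must be strictly increasing")
    if (length(unique(d)) != 1L) msg <- c(msg, "steps must be equidistant")
    if (length(object@spacing) == 1L && !all(d == object@spacing))
      msg <- c(msg, "step differences must equal 'spacing'")
  }
  if (length(msg)) msg else TRUE
})

#' Roving-oddball train design
#'
#' The ordered sequence of stimulus trains and its per-trial expansion.
#' Train lengths are 4, 5 or 6; consecutive trains always carry different
#' stimuli, so the first token of every train is a deviant and positions
#' 2..length are standards.
#'
#' @slot trains data.frame with columns `train_index`, `stimulus`, `length`.
#' @slot trials data.frame with columns `trial_index`, `train_index`,
#'   `stimulus`, `position_in_train`, `is_deviant`.
#' @slot spec list, the [designSpec()] the design was generated from
#'   (includes timing metadata: stimulus onset asynchrony and syllable
#'   duration in ms).
#' @exportClass TrainDesign
setClass("TrainDesign",
  representation(trains = "data.frame", trials = "data.frame", spec = "list")
)

setValidity("TrainDesign", function(object) {
  msg <- character()
  tr <- object@trains
  tl <- object@trials
  need_tr <- c("train_index", "stimulus", "length")
  need_tl <- c("trial_index", "train_index", "stimulus", "position_in_train",
               "is_deviant")
  if (!all(need_tr %in% names(tr))) {
    msg <- c(msg, "trains table lacks required columns")
  } else if (!all(need_tl %in% names(tl))) {
    msg <- c(msg, "trials table lacks required columns")
  } else {
    if (!all(tr$length %in% 4:6))
      msg <- c(msg, "train lengths must be in {4, 5, 6}")
    if (nrow(tr) > 1L &&
        any(tr$stimulus[-1L] == tr$stimulus[-nrow(tr)]))
      msg <- c(msg, "consecutive trains must carry different stimuli")
    if (nrow(tl) != sum(tr$length))
      msg <- c(msg, "trial rows must expand to the sum of train lengths")
    if (!all(tl$is_deviant == (tl$position_in_train == 1L)))
      msg <- c(msg, "is_deviant must mark exactly position 1")
    len <- tr$length[match(tl$train_index, tr$train_index)]
    if (any(tl$position_in_train < 1L | tl$position_in_train > len))
      msg <- c(msg, "position_in_train out of range for its train")
  }
  if (length(msg)) msg else TRUE
})

#' MEG sensor layout
#'
#' Sensor types and units for a (simulated) whole-head system; the default
#' mirrors a 306-channel system with 102 magnetometers (fT) and 204 planar
#' gradiometers (fT/cm).
#'
#' @slot sensorType character vector, one of "mag"/"grad" per sensor.
#' @slot units named character, unit label per sensor type.
#' @exportClass SensorLayout
setClass("SensorLayout",
  representation(sensorType = "character", units = "character")
)

setValidity("SensorLayout", function(object) {
  msg <- character()
  if (length(object@sensorType) < 2L)
    msg <- c(msg, "at least 2 sensors required")
  if (!all(object@sensorType %in% c("mag", "grad")))
    msg <- c(msg, "sensor types must be 'mag' or 'grad'")
  if (!all(unique(object@sensorType) %in% names(object@units)))
    msg <- c(msg, "every sensor type needs a unit entry")
  if (length(msg)) msg else TRUE
})

#' Ground truth for the epoch simulator
#'
#' A low-rank (two-component) spatiotemporal effect model: a common auditory
#' response shared by all trials plus a deviance-specific component whose
#' amplitude is attenuated with the position of the trial in its train.
#' Named attenuation profiles encode the study conditions: "control"
#' (attenuation accrues with repetition), "dyslexia" (immediate but flat
#' attenuation for every repetition), "null" (no attenuation anywhere, hence
#' no decodable condition difference).
#'
#' @slot times numeric, epoch time grid in ms.
#' @slot commonTopography,devianceTopography unit-norm sensor patterns.
#' @slot commonKernel,devianceKernel numeric time courses on `times`,
#'   zero over the prestimulus window; the deviance kernel rises at about
#'   100 ms and peaks at about 280 ms by default.
#' @slot commonAmplitude,devianceAmplitude numeric(1) signal amplitudes
#'   (same nominal units as the noise, fT-scale).
#' @slot attenuationProfile numeric, multiplier in `[0, 1]` per
#'   position-in-train (index 1 = deviant, always 1).
#' @slot profileName character(1), "control", "dyslexia", "null" or "custom".
#' @slot trialJitterSD numeric(1), SD of the multiplicative per-trial
#'   amplitude jitter on the deviance component.
#' @slot noiseCovariance symmetric positive-definite sensor covariance of
#'   the additive noise (unit scale; multiplied by `noiseScale^2`).
#' @slot noiseScale numeric(1), noise standard-deviation scale.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    times = "numeric",
    commonTopography = "numeric",
    devianceTopography = "numeric",
    commonKernel = "numeric",
    devianceKernel = "numeric",
    commonAmplitude = "numeric",
    devianceAmplitude = "numeric",
    attenuationProfile = "numeric",
    profileName = "character",
    trialJitterSD = "numeric",
    noiseCovariance = "matrix",
    noiseScale = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  nt <- length(object@times)
  ns <- length(object@commonTopography)
  if (length(object@devianceTopography) != ns)
    msg <- c(msg, "topographies must have equal length")
  if (length(object@commonKernel) != nt ||
      length(object@devianceKernel) != nt)
    msg <- c(msg, "kernels must be defined on the epoch time grid")
  pre <- object@times < 0
  if (any(abs(object@commonKernel[pre]) > 1e-12) ||
      any(abs(object@devianceKernel[pre]) > 1e-12))
    msg <- c(msg, "kernels must be zero over the prestimulus window")
  if (any(object@attenuationProfile < 0 | object@attenuationProfile > 1))
    msg <- c(msg, "attenuation multipliers must lie in [0, 1]")
  S <- object@noiseCovariance
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    msg <- c(msg, "noise covariance must be symmetric")
  } else if (nrow(S) != ns) {
    msg <- c(msg, "noise covariance dimension must match sensor count")
  } else {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      msg <- c(msg, "noise covariance must be positive-definite")
  }
  if (length(msg)) msg else TRUE
})

#' Epoched sensor data
#'
#' The single interchange container of the pipeline: a trials x sensors x
#' time array with its time axis, sampling rate, sensor layout and per-trial
#' metadata. `normalizationState` tracks whether baseline z-normalization
#' has been applied, which makes pipeline misordering detectable.
#'
#' @slot data numeric array, trials x sensors x time.
#' @slot times numeric, ms grid (strictly increasing, uniform).
#' @slot sfreq numeric(1), sampling rate in Hz.
#' @slot layout [SensorLayout-class].
#' @slot trials data.frame of per-trial metadata (at least `trial_index`,
#'   `stimulus`, `position_in_train`, `train_index`).
#' @slot normalizationState character(1), "raw" or "z-normalized".
#' @exportClass EpochsData
setClass("EpochsData",
  representation(
    data = "array",
    times = "numeric",
    sfreq = "numeric",
    layout = "SensorLayout",
    trials = "data.frame",
    normalizationState = "character"
  )
)

setValidity("EpochsData", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) {
    msg <- c(msg, "data must be a 3-d array (trials x sensors x time)")
  } else {
    if (d[1L] != nrow(object@trials))
      msg <- c(msg, "trial metadata rows must match array dim 1")
    if (d[2L] != length(object@layout@sensorType))
      msg <- c(msg, "sensor layout must match array dim 2")
    if (d[3L] != length(object@times))
      msg <- c(msg, "time grid must match array dim 3")
  }
  dt <- diff(object@times)
  if (length(dt) && (any(dt <= 0) ||
      max(dt) - min(dt) > 1e-6 * max(abs(dt))))
    msg <- c(msg, "times must be strictly increasing and uniform")
  if (!object@normalizationState %in% c("raw", "z-normalized"))
    msg <- c(msg, "normalizationState must be 'raw' or 'z-normalized'")
  if (length(msg)) msg else TRUE
})

#' Multivariate noise normalizer
#'
#' Shrinkage-regularized noise covariance and its inverse square root
#' (whitener), estimated with the "epoch" method: per time point and
#' condition covariances of trial deviations from the condition mean,
#' averaged over time points and then conditions.
#'
#' @slot covariance shrunk sensor covariance.
#' @slot shrinkageGamma numeric(1) in `[0, 1]`, shrinkage intensity toward
#'   the diagonal target.
#' @slot whitener matrix, symmetric inverse square root of `covariance`.
#' @exportClass NoiseNormalizer
setClass("NoiseNormalizer",
  representation(covariance = "matrix", shrinkageGamma = "numeric",
                 whitener = "matrix")
)

setValidity("NoiseNormalizer", function(object) {
  W <- object@whitener
  S <- object@covariance
  if (!all(dim(W) == dim(S)))
    return("whitener and covariance dimensions differ")
  I <- W %*% S %*% t(W)
  if (max(abs(I - diag(nrow(I)))) > 1e-6)
    return("whitener %*% covariance %*% t(whitener) must be identity")
  if (object@shrinkageGamma < 0 || object@shrinkageGamma > 1)
    return("shrinkage gamma must lie in [0, 1]")
  TRUE
})

#' Time-resolved decoding result
#'
#' Cross-validated classification accuracy per time point for one condition
#' pair, averaged over folds and repetitions; 0.5 is chance.
#'
#' @slot accuracy numeric per time point, in `[0, 1]`.
#' @slot times numeric, ms grid (full stored epoch; inference later
#'   restricts to the post-stimulus analysis window).
#' @slot conditionPair character(2), labels of the decoded conditions.
#' @slot nTrialsUsed integer(2), trials entering the analysis per condition.
#' @slot config list, echo of the [decodeConfig()] used.
#' @exportClass DecodingResult
setClass("DecodingResult",
  representation(
    accuracy = "numeric",
    times = "numeric",
    conditionPair = "character",
    nTrialsUsed = "integer",
    config = "list"
  )
)

setValidity("DecodingResult", function(object) {
  msg <- character()
  if (length(object@accuracy) != length(object@times))
    msg <- c(msg, "accuracy must align with the time grid")
  if (any(object@accuracy < 0 | object@accuracy > 1))
    msg <- c(msg, "accuracy must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Temporal generalization result
#'
#' Accuracy of classifiers trained at each time point and tested at every
#' time point, on a decimated grid shared by training and testing.
#'
#' @slot matrix numeric train-time x test-time accuracy matrix.
#' @slot times numeric, the shared (decimated) ms grid.
#' @slot conditionPair character(2).
#' @slot config list, config echo.
#' @exportClass TGResult
setClass("TGResult",
  representation(matrix = "matrix", times = "numeric",
                 conditionPair = "character", config = "list")
)

setValidity("TGResult", function(object) {
  d <- dim(object@matrix)
  if (d[1L] != d[2L] || d[1L] != length(object@times))
    return("generalization matrix must be square on the shared time grid")
  TRUE
})

#' Cluster-corrected permutation test result
#'
#' Pointwise statistic map (group mean deviation from the null value),
#' pointwise permutation p-values, suprathreshold clusters with mass and
#' corrected p, the significance mask, and the null distribution of maximal
#' cluster masses.
#'
#' @slot statisticMap numeric per time point.
#' @slot times numeric, ms grid of the analysis window.
#' @slot pointwiseP numeric per time point.
#' @slot clusters data.frame with columns `start_ms`, `end_ms`, `mass`,
#'   `corrected_p`.
#' @slot significantMask logical per time point.
#' @slot nullMaxMass numeric, empirical distribution of the maximal cluster
#'   mass (the observed sample is counted as one entry).
#' @slot config list, config echo.
#' @exportClass ClusterTestResult
setClass("ClusterTestResult",
  representation(
    statisticMap = "numeric",
    times = "numeric",
    pointwiseP = "numeric",
    clusters = "data.frame",
    significantMask = "logical",
    nullMaxMass = "numeric",
    config = "list"
  )
)

setValidity("ClusterTestResult", function(object) {
  msg <- character()
  nt <- length(object@times)
  if (length(object@statisticMap) != nt ||
      length(object@pointwiseP) != nt ||
      length(object@significantMask) != nt)
    msg <- c(msg, "maps must align with the time grid")
  if (nrow(object@clusters) > 0) {
    np <- length(object@nullMaxMass)
    p <- object@clusters$corrected_p
    if (any(p < 1 / np - 1e-12 | p > 1 + 1e-12))
      msg <- c(msg, "corrected p must lie in [1/n_permutations, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Bootstrap latency comparison result
#'
#' Onset or peak decoding latencies per group/condition and the bootstrap
#' distribution of their difference.
#'
#' @slot kind character(1), "onset" or "peak".
#' @slot latencyA,latencyB numeric(1) observed latencies in ms (NA when no
#'   significant cluster defines an onset).
#' @slot observedDifference numeric(1), `latencyA - latencyB` in ms.
#' @slot bootstrapDifferences numeric, defined bootstrap draws of the
#'   latency difference.
#' @slot pTwoSided numeric(1).
#' @slot nUndefined integer(1), bootstrap draws dropped because a latency
#'   was undefined.
#' @slot unreliable logical(1), TRUE when more than half the draws were
#'   undefined.
#' @exportClass LatencyResult
setClass("LatencyResult",
  representation(
    kind = "character",
    latencyA = "numeric",
    latencyB = "numeric",
    observedDifference = "numeric",
    bootstrapDifferences = "numeric",
    pTwoSided = "numeric",
    nUndefined = "integer",
    unreliable = "logical"
  )
)
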