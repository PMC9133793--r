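## Accessors and show methods. Slot access from user code should go through
## these.

#' @name accessors
#' @title Accessors for oddwave containers
#'
#' @description Small accessor family: `epochsArray()` returns the trials x
#' sensors x time array, `epochTimes()` the ms grid, `trialInfo()` the
#' per-trial metadata, `sensorTypes()` the per-sensor type labels,
#' `normalizationState()` the container state, `accuracies()` the accuracy
#' series (or matrix for temporal generalization), `clusterTable()` the
#' cluster summary and `significantMask()` the corrected significance mask.
#'
#' @param x an oddwave S4 object.
#' @return The extracted component; see Description.
NULL

#' @rdname accessors
#' @export
setGeneric("epochsArray", function(x) standardGeneric("epochsArray"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))
#' @rdname accessors
#' @export
setGeneric("sensorTypes", function(x) standardGeneric("sensorTypes"))
#' @rdname accessors
#' @export
setGeneric("normalizationState",
           function(x) standardGeneric("normalizationState"))
#' @rdname accessors
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname accessors
#' @export
setGeneric("significantMask", function(x) standardGeneric("significantMask"))
#' @rdname accessors
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))
#' @rdname accessors
#' @export
setGeneric("trainTable", function(x) standardGeneric("trainTable"))
#' @rdname accessors
#' @export
setGeneric("stimulusSteps", function(x) standardGeneric("stimulusSteps"))
#' @rdname accessors
#' @export
setGeneric("whitener", function(x) standardGeneric("whitener"))

#' @rdname accessors
setMethod("epochsArray", "EpochsData", function(x) x@data)
#' @rdname accessors
setMethod("epochTimes", "EpochsData", function(x) x@times)
#' @rdname accessors
setMethod("epochTimes", "DecodingResult", function(x) x@times)
#' @rdname accessors
setMethod("epochTimes", "TGResult", function(x) x@times)
#' @rdname accessors
setMethod("epochTimes", "ClusterTestResult", function(x) x@times)
#' @rdname accessors
setMethod("trialInfo", "EpochsData", function(x) x@trials)
#' @rdname accessors
setMethod("sensorTypes", "EpochsData", function(x) x@layout@sensorType)
#' @rdname accessors
setMethod("sensorTypes", "SensorLayout", function(x) x@sensorType)
#' @rdname accessors
setMethod("normalizationState", "EpochsData",
          function(x) x@normalizationState)
#' @rdname accessors
setMethod("accuracies", "DecodingResult", function(x) x@accuracy)
#' @rdname accessors
setMethod("accuracies", "TGResult", function(x) x@matrix)
#' @rdname accessors
setMethod("clusterTable", "ClusterTestResult", function(x) x@clusters)
#' @rdname accessors
setMethod("significantMask", "ClusterTestResult",
          function(x) x@significantMask)
#' @rdname accessors
setMethod("trialTable", "TrainDesign", function(x) x@trials)
#' @rdname accessors
setMethod("trainTable", "TrainDesign", function(x) x@trains)
#' @rdname accessors
setMethod("stimulusSteps", "StimulusSet", function(x) x@steps)
#' @rdname accessors
setMethod("whitener", "NoiseNormalizer", function(x) x@whitener)

setMethod("show", "PsychometricFit", function(object) {
  cat("PsychometricFit:",
      if (object@converged) "converged" else "NOT converged", "\n")
  if (object@converged) {
    cat(sprintf("  midpoint %.3f steps, slope %.3f /step, asymptotes [%.3f, %.3f]\n",
                object@midpoint, object@slope,
                object@asymptotes[1L], object@asymptotes[2L]))
  }
})

setMethod("show", "StimulusSet", function(object) {
  cat("StimulusSet: A-E at steps", paste(object@steps, collapse = ", "),
      sprintf("(spacing %d%s)\n", object@spacing,
              if (object@clamped) ", clamped" else ""))
})

setMethod("show", "TrainDesign", function(object) {
  cat(sprintf("TrainDesign: %d trains, %d trials, %d stimuli\n",
              nrow(object@trains), nrow(object@trials),
              length(unique(object@trains$stimulus))))
  pc <- positionCounts(object)
  cat("  trials per position:",
      paste(sprintf("%s:%d", names(pc), pc), collapse = " "), "\n")
})

setMethod("show", "SensorLayout", function(object) {
  tab <- table(object@sensorType)
  cat("SensorLayout:", length(object@sensorType), "sensors (",
      paste(sprintf("%d %s [%s]", tab, names(tab),
                    object@units[names(tab)]), collapse = ", "), ")\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: profile '%s', %d sensors, %d time points\n",
              object@profileName, length(object@commonTopography),
              length(object@times)))
  cat(sprintf("  deviance amplitude %.3g, noise scale %.3g, jitter SD %.3g\n",
              object@devianceAmplitude, object@noiseScale,
              object@trialJitterSD))
  cat("  attenuation by position:",
      paste(sprintf("%d:%.2f", seq_along(object@attenuationProfile),
                    object@attenuationProfile), collapse = " "), "\n")
})

setMethod("show", "EpochsData", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochsData: %d trials x %d sensors x %d samples (%s)\n",
              d[1L], d[2L], d[3L], object@normalizationState))
  cat(sprintf("  %.0f-%.0f ms at %g Hz\n", min(object@times),
              max(object@times), object@sfreq))
})

setMethod("show", "NoiseNormalizer", function(object) {
  cat(sprintf("NoiseNormalizer: %d sensors, shrinkage gamma %.3f\n",
              nrow(object@covariance), object@shrinkageGamma))
})

setMethod("show", "DecodingResult", function(object) {
  post <- object@times >= 0
  cat(sprintf("DecodingResult: %s vs %s, %d time points\n",
              object@conditionPair[1L], object@conditionPair[2L],
              length(object@times)))
  cat(sprintf("  peak accuracy %.1f%% at %.0f ms (post-stimulus)\n",
              100 * max(object@accuracy[post]),
              object@times[post][which.max(object@accuracy[post])]))
})

setMethod("show", "TGResult", function(object) {
  cat(sprintf("TGResult: %s vs %s, %d x %d generalization matrix\n",
              object@conditionPair[1L], object@conditionPair[2L],
              nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf("ClusterTestResult: %d time points, %d cluster(s)\n",
              length(object@times), nrow(object@clusters)))
  if (nrow(object@clusters)) {
    sig <- object@clusters$corrected_p < object@config$clusterAlpha
    for (i in seq_len(nrow(object@clusters))) {
      cat(sprintf("  %s%.0f-%.0f ms, mass %.3g, p = %.4g\n",
                  if (sig[i]) "* " else "  ",
                  object@clusters$start_ms[i], object@clusters$end_ms[i],
                  object@clusters$mass[i], object@clusters$corrected_p[i]))
    }
  }
})

setMethod("show", "LatencyResult", function(object) {
  cat(sprintf("LatencyResult (%s): A %.0f ms, B %.0f ms, diff %.0f ms, p = %.3g%s\n",
              object@kind, object@latencyA, object@latencyB,
              object@observedDifference, object@pTwoSided,
              if (object@unreliable) " [unreliable]" else ""))
})
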