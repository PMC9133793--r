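## Orchestration of the full synthetic study: cohort simulation, decoding
## across contrasts, group inference, repetition contrasts, subsetting
## controls, latency comparisons and the stimulus-specific grid.

#' Study configuration
#'
#' Bundles everything [runFullStudy()] needs. The defaults mirror the
#' full-scale study structure (24 subjects per group, 600-train design,
#' 306 sensors, 1 ms resolution, 100 decoding repetitions, 5,000
#' permutations); reduced configurations for quick runs simply override
#' the sizes.
#'
#' @param nPerGroup subjects per group (default 24).
#' @param groupProfiles named character, simulator attenuation profile per
#'   group (default control/dyslexia).
#' @param design a [designSpec()].
#' @param times epoch grid in ms.
#' @param nSensors sensor count for simulation.
#' @param contrasts decoding contrasts run per subject (see
#'   [contrastLabels()]).
#' @param decode a [decodeConfig()].
#' @param cluster a [clusterTestConfig()] (used with a one-sided greater
#'   alternative and null 0.5 for accuracies; two-sided null 0 between
#'   groups).
#' @param latency list with `nBoot`, `kinds` and `contrasts` for the
#'   bootstrap latency comparisons.
#' @param subsetControl run the trial-count control: re-decode the per-level
#'   contrasts with the standards subsetted to each subject's usable
#'   6th-trial count (default TRUE).
#' @param repetitionContrasts run the ordered repetition-accrual contrasts
#'   (1v3 > 1v2, 1v4 > 1v2, 1v4 > 1v3) per group (default TRUE).
#' @param latencyComparisons run the bootstrap latency tests (default TRUE).
#' @param stimulusSpecific run the 5 x 5 stimulus-specific decoding grid
#'   (4th-position standards of each stimulus vs each possible successor;
#'   default TRUE).
#' @param artifactFraction fraction of simulated trials corrupted by
#'   injected artifacts before preprocessing (default 0.02).
#' @param truthArgs named list of overrides passed to [groundTruth()]
#'   (amplitudes, noise scale, kernels, ...).
#' @param seed master seed; all per-subject and per-analysis seeds are
#'   drawn from it up front, so reports are fully reproducible.
#' @return A validated list of class `study_config`.
#' @export
studyConfig <- function(nPerGroup = 24L,
                        groupProfiles = c(control = "control",
                                          dyslexia = "dyslexia"),
                        design = designSpec(),
                        times = seq(-200, 550, by = 1),
                        nSensors = 306L,
                        contrasts = c("deviant-vs-standards", "1v2", "1v3",
                                      "1v4", "1v5", "1v6"),
                        decode = decodeConfig(),
                        cluster = clusterTestConfig(),
                        latency = list(nBoot = 1000L,
                                       kinds = c("onset", "peak"),
                                       contrasts = c("1v2", "1v3", "1v4")),
                        subsetControl = TRUE,
                        repetitionContrasts = TRUE,
                        latencyComparisons = TRUE,
                        stimulusSpecific = TRUE,
                        artifactFraction = 0.02,
                        truthArgs = list(),
                        seed = 1L) {
  if (as.integer(nPerGroup) < 2L) stop("nPerGroup must be >= 2")
  if (!length(contrasts)) stop("at least one contrast is required")
  if (is.null(names(groupProfiles)))
    stop("groupProfiles must be named by group")
  structure(list(nPerGroup = as.integer(nPerGroup),
                 groupProfiles = groupProfiles, design = design,
                 times = times, nSensors = as.integer(nSensors),
                 contrasts = contrasts, decode = decode, cluster = cluster,
                 latency = latency, subsetControl = isTRUE(subsetControl),
                 repetitionContrasts = isTRUE(repetitionContrasts),
                 latencyComparisons = isTRUE(latencyComparisons),
                 stimulusSpecific = isTRUE(stimulusSpecific),
                 artifactFraction = artifactFraction,
                 truthArgs = truthArgs, seed = as.integer(seed)),
            class = "study_config")
}

## Sequential seed dispenser: a fixed-size pool drawn once from the master
## seed, handed out in program order. Keeps every stage independently
## seeded while leaving the whole study reproducible from one integer.
seedDispenser <- function(masterSeed, poolSize = 200000L) {
  pool <- withSeed(masterSeed,
                   sample.int(.Machine$integer.max - 1L, poolSize))
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > poolSize) stop("seed pool exhausted")
    pool[i]
  }
}

## Successor metadata for the stimulus-specific grid: for each trial, which
## stimulus headed the previous train and how long that train was.
annotatePrevTrain <- function(trials, trains) {
  ord <- order(trains$train_index)
  prevStim <- c(NA, trains$stimulus[ord][-nrow(trains)])
  prevLen <- c(NA, trains$length[ord][-nrow(trains)])
  idx <- match(trials$train_index, trains$train_index[ord])
  trials$prev_stimulus <- prevStim[idx]
  trials$prev_length <- prevLen[idx]
  trials
}

## Labels for one cell of the stimulus-specific grid: 4th-position trials
## of standard stimulus `std` vs their possible successor `succ` (the 5th
## of the same train when succ == std, else deviant 1sts of `succ` directly
## following a length-4 train of `std`).
stimulusSpecificLabels <- function(trials, std, succ) {
  pos <- trials$position_in_train
  isStd <- pos == 4L & trials$stimulus == std
  isSucc <- if (succ == std) {
    pos == 5L & trials$stimulus == std
  } else {
    pos == 1L & trials$stimulus == succ &
      trials$prev_stimulus == std & trials$prev_length == 4L
  }
  lab <- rep(NA_character_, nrow(trials))
  lab[isStd] <- "standard4th"
  lab[isSucc & !isStd] <- "successor"
  factor(lab, levels = c("successor", "standard4th"))
}

#' Ordered repetition-accrual contrasts
#'
#' For the per-subject 1v2, 1v3 and 1v4 accuracy series of one group, runs
#' the three one-sided one-sample sign-permutation cluster tests on the
#' accuracy-difference series (1v3 - 1v2 > 0, 1v4 - 1v2 > 0,
#' 1v4 - 1v3 > 0), asking whether decoding grows more accurate as the
#' standard accrues repetitions.
#'
#' @param seriesByContrast named list with subjects x time matrices for
#'   `"1v2"`, `"1v3"` and `"1v4"` (same subjects, same grid).
#' @param times ms grid.
#' @param config a [clusterTestConfig()]; the null value is forced to 0 and
#'   the alternative to one-sided greater.
#' @return List with `tests` (named [ClusterTestResult-class] objects) and
#'   `summary` (data.frame of cluster counts, minimal corrected p and
#'   significance per ordered contrast).
#' @export
compareRepetitionLevels <- function(seriesByContrast, times,
                                    config = clusterTestConfig()) {
  need <- c("1v2", "1v3", "1v4")
  if (!all(need %in% names(seriesByContrast)))
    stop("series for contrasts 1v2, 1v3 and 1v4 are required")
  dims <- vapply(seriesByContrast[need], dim, integer(2))
  if (length(unique(dims[1L, ])) != 1L)
    stop("the three series must share subjects")
  cfg <- config
  cfg$nullValue <- 0
  cfg$alternative <- "greater"
  pairs <- list("1v3>1v2" = c("1v3", "1v2"),
                "1v4>1v2" = c("1v4", "1v2"),
                "1v4>1v3" = c("1v4", "1v3"))
  tests <- lapply(pairs, function(p) {
    signPermutationClusterTest(
      seriesByContrast[[p[1L]]] - seriesByContrast[[p[2L]]], times, cfg)
  })
  summary <- do.call(rbind, lapply(names(tests), function(nm) {
    res <- tests[[nm]]
    data.frame(contrast = nm, n_clusters = nrow(res@clusters),
               min_p = if (nrow(res@clusters))
                 min(res@clusters$corrected_p) else NA_real_,
               significant = any(res@clusters$corrected_p <
                                   cfg$clusterAlpha),
               stringsAsFactors = FALSE)
  }))
  list(tests = tests, summary = summary)
}

#' Run the full synthetic study
#'
#' Executes the whole pipeline per group and subject: design generation,
#' epoch simulation under the group's attenuation profile, artifact
#' injection and preprocessing, decoding of every configured contrast
#' (plus the trial-count control with standards subsetted to the usable
#' 6th-trial count), and the group-level inference battery: within-group
#' significance, between-group comparisons, ordered repetition contrasts,
#' bootstrap latency comparisons, and the stimulus-specific 5 x 5 grid.
#' Everything is seeded from the master seed, so two runs with identical
#' configuration produce identical reports.
#'
#' @param config a [studyConfig()].
#' @return A list of class `study_report`; see the vignette for the layout.
#' @export
runFullStudy <- function(config) {
  stopifnot(inherits(config, "study_config"))
  nextSeed <- seedDispenser(config$seed)
  design <- generateDesign(config$design)
  groups <- names(config$groupProfiles)
  layout <- sensorLayout(config$nSensors)
  times <- config$times
  perLevel <- intersect(config$contrasts, c("1v2", "1v3", "1v4", "1v5"))
  stimuli <- sort(unique(design@trains$stimulus))

  accuracy <- list(); accuracySubset <- list()
  usableCounts <- list(); rejectionCounts <- list()
  stimGridAcc <- list(); stimGridSeries <- list()

  for (grp in groups) {
    profile <- config$groupProfiles[[grp]]
    accuracy[[grp]] <- lapply(setNames(config$contrasts, config$contrasts),
                              function(.) NULL)
    accuracySubset[[grp]] <- lapply(setNames(perLevel, perLevel),
                                    function(.) NULL)
    usableCounts[[grp]] <- NULL
    if (config$stimulusSpecific)
      stimGridSeries[[grp]] <- array(
        list(), dim = c(length(stimuli), length(stimuli)),
        dimnames = list(standard = stimuli, successor = stimuli))

    for (s in seq_len(config$nPerGroup)) {
      truth <- do.call(groundTruth, c(
        list(times = times, nSensors = config$nSensors, profile = profile,
             seed = nextSeed()),
        config$truthArgs))
      epochs <- simulateEpochs(design, truth, layout, seed = nextSeed())
      artSeed <- nextSeed()
      if (config$artifactFraction > 0) {
        epochs <- injectArtifacts(epochs, config$artifactFraction,
                                  seed = artSeed)$epochs
      }
      pp <- preprocess(epochs)
      epochs <- pp$epochs
      epochs@trials <- annotatePrevTrain(epochs@trials, design@trains)
      pos <- epochs@trials$position_in_train
      usableCounts[[grp]] <- rbind(
        usableCounts[[grp]],
        table(factor(pos, levels = 1:6)))
      n6 <- sum(pos == 6L)

      for (ct in config$contrasts) {
        dcfg <- config$decode
        dcfg$seed <- nextSeed()
        labels <- contrastLabels(epochs@trials, ct)
        res <- decodeTimecourse(epochs, labels, dcfg)
        accuracy[[grp]][[ct]] <- rbind(accuracy[[grp]][[ct]],
                                       accuracies(res))
      }
      if (config$subsetControl && n6 >= config$decode$nFolds) {
        for (ct in perLevel) {
          kth <- as.integer(substring(ct, 3L))
          labels <- contrastLabels(epochs@trials, ct)
          stdIdx <- which(pos == kth)
          keep <- subsetTrials(stdIdx, min(n6, length(stdIdx)),
                               seed = nextSeed())
          labels[setdiff(stdIdx, keep)] <- NA
          dcfg <- config$decode
          dcfg$seed <- nextSeed()
          res <- decodeTimecourse(epochs, labels, dcfg)
          accuracySubset[[grp]][[ct]] <-
            rbind(accuracySubset[[grp]][[ct]], accuracies(res))
        }
      }
      if (config$stimulusSpecific) {
        for (std in stimuli) for (succ in stimuli) {
          labels <- stimulusSpecificLabels(epochs@trials, std, succ)
          nPer <- table(labels)
          acc <- rep(NA_real_, length(times))
          if (all(nPer >= config$decode$nFolds)) {
            dcfg <- config$decode
            dcfg$seed <- nextSeed()
            acc <- accuracies(decodeTimecourse(epochs, labels, dcfg))
          }
          stimGridSeries[[grp]][[std, succ]] <-
            rbind(stimGridSeries[[grp]][[std, succ]], acc)
        }
      }
    }
  }

  ## --- group-level inference -------------------------------------------
  oneSampleCfg <- config$cluster
  oneSampleCfg$alternative <- "greater"
  oneSampleCfg$nullValue <- 0.5
  betweenCfg <- config$cluster
  betweenCfg$alternative <- "two.sided"
  betweenCfg$nullValue <- 0

  groupTests <- list(); betweenTests <- list(); subsetTests <- list()
  for (grp in groups) {
    groupTests[[grp]] <- list()
    for (ct in config$contrasts) {
      cfg <- oneSampleCfg
      cfg$seed <- nextSeed()
      groupTests[[grp]][[ct]] <-
        signPermutationClusterTest(accuracy[[grp]][[ct]], times, cfg)
    }
  }
  if (length(groups) == 2L) {
    for (ct in config$contrasts) {
      cfg <- betweenCfg
      cfg$seed <- nextSeed()
      betweenTests[[ct]] <- twoSampleClusterTest(
        accuracy[[groups[1L]]][[ct]], accuracy[[groups[2L]]][[ct]],
        times, cfg)
    }
  }
  if (config$subsetControl) {
    for (grp in groups) {
      subsetTests[[grp]] <- list()
      for (ct in perLevel) {
        if (is.null(accuracySubset[[grp]][[ct]])) next
        cfg <- oneSampleCfg
        cfg$nullValue <- 0
        cfg$seed <- nextSeed()
        ## full minus subset: positive clusters mean the reduced trial
        ## count lowered accuracy
        subsetTests[[grp]][[ct]] <- signPermutationClusterTest(
          accuracy[[grp]][[ct]] - accuracySubset[[grp]][[ct]], times, cfg)
      }
    }
  }

  repetitionTests <- list()
  if (config$repetitionContrasts &&
      all(c("1v2", "1v3", "1v4") %in% config$contrasts)) {
    for (grp in groups) {
      cfg <- config$cluster
      cfg$seed <- nextSeed()
      repetitionTests[[grp]] <- compareRepetitionLevels(
        accuracy[[grp]][c("1v2", "1v3", "1v4")], times, cfg)
    }
  }

  latencyBetween <- list()
  if (config$latencyComparisons && length(groups) == 2L) {
    for (ct in intersect(config$latency$contrasts, config$contrasts)) {
      latencyBetween[[ct]] <- list()
      for (kind in config$latency$kinds) {
        cfg <- oneSampleCfg
        latencyBetween[[ct]][[kind]] <- bootstrapLatencyTest(
          accuracy[[groups[1L]]][[ct]], accuracy[[groups[2L]]][[ct]],
          times, kind = kind, paired = FALSE,
          nBoot = config$latency$nBoot, config = cfg, seed = nextSeed())
      }
    }
  }

  stimulusGrid <- NULL
  if (config$stimulusSpecific) {
    stimulusGrid <- list()
    for (grp in groups) {
      nStim <- length(stimuli)
      peakAcc <- matrix(NA_real_, nStim, nStim,
                        dimnames = list(standard = stimuli,
                                        successor = stimuli))
      sig <- matrix(NA, nStim, nStim,
                    dimnames = dimnames(peakAcc))
      meanWindowAcc <- peakAcc
      post <- times >= 0
      for (std in stimuli) for (succ in stimuli) {
        mat <- stimGridSeries[[grp]][[std, succ]]
        ok <- !apply(is.na(mat), 1L, any)
        if (sum(ok) >= 2L) {
          m <- colMeans(mat[ok, , drop = FALSE])
          peakAcc[std, succ] <- max(m[post])
          meanWindowAcc[std, succ] <- mean(m[post])
          cfg <- oneSampleCfg
          cfg$seed <- nextSeed()
          res <- signPermutationClusterTest(mat[ok, , drop = FALSE],
                                            times, cfg)
          sig[std, succ] <- any(res@clusters$corrected_p <
                                  cfg$clusterAlpha)
        }
      }
      stimulusGrid[[grp]] <- list(peakAccuracy = peakAcc,
                                  meanWindowAccuracy = meanWindowAcc,
                                  significant = sig,
                                  series = stimGridSeries[[grp]])
    }
  }

  structure(list(
    config = config, times = times, design = design,
    usableCounts = usableCounts,
    accuracy = accuracy, accuracySubset = accuracySubset,
    groupTests = groupTests, betweenTests = betweenTests,
    subsetTests = subsetTests, repetitionTests = repetitionTests,
    latencyBetween = latencyBetween, stimulusGrid = stimulusGrid),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  groups <- names(x$config$groupProfiles)
  cat("Synthetic roving-oddball study report\n")
  cat(sprintf("  groups: %s (%d subjects each)\n",
              paste(groups, collapse = ", "), x$config$nPerGroup))
  cat(sprintf("  contrasts: %s\n",
              paste(x$config$contrasts, collapse = ", ")))
  post <- x$times >= 0
  for (grp in groups) {
    for (ct in names(x$accuracy[[grp]])) {
      m <- colMeans(x$accuracy[[grp]][[ct]])
      res <- x$groupTests[[grp]][[ct]]
      sig <- any(res@clusters$corrected_p < res@config$clusterAlpha)
      cat(sprintf("  %s %-22s peak %.1f%% @ %4.0f ms  %s\n", grp, ct,
                  100 * max(m[post]), x$times[post][which.max(m[post])],
                  if (sig) sprintf("sig (min p = %.4g)",
                                   min(res@clusters$corrected_p))
                  else "n.s."))
    }
  }
  if (length(x$repetitionTests)) {
    for (grp in groups) {
      cat("  repetition accrual,", grp, ":\n")
      s <- x$repetitionTests[[grp]]$summary
      for (i in seq_len(nrow(s)))
        cat(sprintf("    %-8s %s\n", s$contrast[i],
                    if (s$significant[i])
                      sprintf("significant (p = %.4g)", s$min_p[i])
                    else "n.s."))
    }
  }
  invisible(x)
}
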