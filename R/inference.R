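## Nonparametric inference: sign-permutation cluster tests, two-sample
## group tests, bootstrap latency comparisons, and pooled t / Cohen's d.

#' Cluster-test configuration
#'
#' @param nPermutations permutation samples; the observed arrangement is
#'   counted as one of them, so corrected p-values are floored at
#'   `1 / nPermutations` (default 5,000, floor 0.0002).
#' @param clusterAlpha corrected significance level (default 0.05).
#' @param clusterDefiningAlpha pointwise threshold forming clusters
#'   (default 0.05).
#' @param alternative `"greater"` (one-sided, e.g. accuracy above chance)
#'   or `"two.sided"` (e.g. group differences).
#' @param nullValue null value subtracted from each series (0.5 for
#'   accuracies, 0 for accuracy differences).
#' @param analysisWindow `(start, end)` ms window tested (default (0, 550);
#'   the prestimulus period is excluded because with rapid stimulation it
#'   coincides with the tail of the preceding trial's epoch).
#' @param seed RNG seed for the permutation draw.
#' @return A validated list of class `cluster_config`.
#' @export
clusterTestConfig <- function(nPermutations = 5000L, clusterAlpha = 0.05,
                              clusterDefiningAlpha = 0.05,
                              alternative = c("greater", "two.sided"),
                              nullValue = 0.5,
                              analysisWindow = c(0, 550), seed = 1L) {
  alternative <- match.arg(alternative)
  if (clusterAlpha <= 0 || clusterAlpha >= 1 ||
      clusterDefiningAlpha <= 0 || clusterDefiningAlpha >= 1)
    stop("alphas must lie in (0, 1)")
  if (as.integer(nPermutations) < 1L)
    stop("nPermutations must be >= 1")
  structure(list(nPermutations = as.integer(nPermutations),
                 clusterAlpha = clusterAlpha,
                 clusterDefiningAlpha = clusterDefiningAlpha,
                 alternative = alternative, nullValue = nullValue,
                 analysisWindow = analysisWindow, seed = as.integer(seed)),
            class = "cluster_config")
}

## Pointwise permutation p-values for every permutation map (rows) against
## the column-wise empirical distribution: p = #{values >= this} / R.
permPointwiseP <- function(stats) {
  R <- nrow(stats)
  apply(stats, 2L, function(col) (R - rank(col, ties.method = "min") + 1L) / R)
}

## Shared clustering/correction stage given the observed map (row 1 of
## `stats`) and the full permutation stat matrix. Cluster extraction for
## all permutation maps runs in one pass over a guard-separated
## row-major flattening of the suprathreshold mask.
clusterCorrect <- function(stats, times, config) {
  twoSided <- config$alternative == "two.sided"
  R <- nrow(stats)
  nt <- ncol(stats)
  P <- permPointwiseP(if (twoSided) abs(stats) else stats)
  alphaDef <- config$clusterDefiningAlpha
  maskMat <- P < alphaDef + 1e-12  # threshold "p = alpha" includes ties at alpha
  grpMat <- if (twoSided) maskMat * sign(stats) else maskMat + 0
  v <- as.vector(t(cbind(grpMat, 0)))        # guard column between rows
  sv <- as.vector(t(cbind(stats, 0)))
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0
  starts <- starts[keep]; ends <- ends[keep]
  cs <- c(0, cumsum(sv))
  mass <- cs[ends + 1L] - cs[starts]
  rowid <- (starts - 1L) %/% (nt + 1L) + 1L
  sz <- if (twoSided) abs(mass) else mass
  nullMax <- numeric(R)
  if (length(sz)) {
    mx <- tapply(sz, rowid, max)
    nullMax[as.integer(names(mx))] <- mx
  }
  ## row 1 occupies flattened positions 1..nt, so its run bounds are
  ## already time indices
  obs <- which(rowid == 1L)
  obsClusters <- data.frame(start = starts[obs], end = ends[obs],
                            mass = mass[obs])
  if (nrow(obsClusters)) {
    obsSize <- if (twoSided) abs(obsClusters$mass) else obsClusters$mass
    corrected <- vapply(obsSize, function(m) mean(nullMax >= m), numeric(1))
    clusters <- data.frame(start_ms = times[obsClusters$start],
                           end_ms = times[obsClusters$end],
                           mass = obsClusters$mass,
                           corrected_p = corrected)
  } else {
    clusters <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                           mass = numeric(0), corrected_p = numeric(0))
  }
  sigMask <- logical(length(times))
  sig <- which(clusters$corrected_p < config$clusterAlpha)
  for (i in sig)
    sigMask[which(times >= clusters$start_ms[i] &
                  times <= clusters$end_ms[i])] <- TRUE
  new("ClusterTestResult",
      statisticMap = stats[1L, ], times = times, pointwiseP = P[1L, ],
      clusters = clusters, significantMask = sigMask, nullMaxMass = nullMax,
      config = unclass(config))
}

restrictWindow <- function(series, times, window) {
  keep <- which(times >= window[1L] & times <= window[2L])
  if (!length(keep)) stop("empty analysis window")
  list(series = series[, keep, drop = FALSE], times = times[keep])
}

#' One-sample sign-permutation cluster test
#'
#' Tests whether the across-subject mean of per-subject time series
#' deviates from a null value, controlling familywise error over time
#' points with cluster-based inference. Permutation samples flip each
#' subject's whole series around the null value with independent random
#' signs and re-average; the observed arrangement is counted as one sample,
#' so p-values are floored at `1 / nPermutations` (0.0002 at the 5,000
#' default). Clusters are maximal contiguous runs of pointwise
#' `p < clusterDefiningAlpha`; the cluster mass is the sum of the averaged
#' statistic within the run, and the corrected p is the proportion of
#' permutation maximal cluster masses at least as large.
#'
#' @param series numeric matrix, subjects x time (e.g. decoding-accuracy
#'   series); at least 2 subjects.
#' @param times ms grid matching the columns.
#' @param config a [clusterTestConfig()].
#' @return A [ClusterTestResult-class].
#' @export
signPermutationClusterTest <- function(series, times,
                                       config = clusterTestConfig()) {
  stopifnot(is.matrix(series), ncol(series) == length(times))
  if (nrow(series) < 2L) stop("at least 2 subjects are required")
  w <- restrictWindow(series, times, config$analysisWindow)
  D <- w$series - config$nullValue
  n <- nrow(D)
  R <- config$nPermutations
  withSeed(config$seed, {
    signs <- matrix(sample(c(-1, 1), (R - 1L) * n, replace = TRUE),
                    R - 1L, n)
    signs <- rbind(rep(1, n), signs)  # row 1 = observed arrangement
    stats <- (signs %*% D) / n
    clusterCorrect(stats, w$times, config)
  })
}

#' Two-sample cluster-corrected permutation test
#'
#' Tests for a difference between two groups of subject time series. The
#' observed statistic is the difference of group means per time point. The
#' default null scheme (`"label-permutation"`) randomly reassigns subjects
#' to groups with sizes preserved; `"signflip-differences"` is the paired
#' variant, sign-flipping the per-subject difference series (requires equal
#' sizes with matched ordering). Clustering and correction as in
#' [signPermutationClusterTest()].
#'
#' @param seriesA,seriesB subjects x time matrices on a common grid.
#' @param times ms grid.
#' @param config a [clusterTestConfig()]; `nullValue` should be 0 and the
#'   default alternative for group comparisons is two-sided.
#' @param method null-generation scheme.
#' @return A [ClusterTestResult-class].
#' @export
twoSampleClusterTest <- function(seriesA, seriesB, times,
                                 config = clusterTestConfig(
                                   alternative = "two.sided", nullValue = 0),
                                 method = c("label-permutation",
                                            "signflip-differences")) {
  method <- match.arg(method)
  stopifnot(ncol(seriesA) == length(times), ncol(seriesB) == length(times))
  if (nrow(seriesA) < 2L || nrow(seriesB) < 2L)
    stop("at least 2 subjects per group are required")
  if (method == "signflip-differences") {
    if (nrow(seriesA) != nrow(seriesB))
      stop("paired sign-flip requires equally sized, matched groups")
    cfg <- config
    cfg$nullValue <- 0
    return(signPermutationClusterTest(seriesA - seriesB, times, cfg))
  }
  wA <- restrictWindow(seriesA, times, config$analysisWindow)
  wB <- restrictWindow(seriesB, times, config$analysisWindow)
  pooled <- rbind(wA$series, wB$series)
  nA <- nrow(wA$series); nTot <- nrow(pooled)
  R <- config$nPermutations
  withSeed(config$seed, {
    stats <- matrix(0, R, ncol(pooled))
    stats[1L, ] <- colMeans(pooled[seq_len(nA), , drop = FALSE]) -
      colMeans(pooled[-seq_len(nA), , drop = FALSE])
    for (r in seq_len(R - 1L) + 1L) {
      idx <- sample.int(nTot, nA)
      stats[r, ] <- colMeans(pooled[idx, , drop = FALSE]) -
        colMeans(pooled[-idx, , drop = FALSE])
    }
    clusterCorrect(stats, wA$times, config)
  })
}

#' Onset and peak latency from a cluster test
#'
#' Onset is the first time point of the earliest significant cluster (NA
#' with an undefined flag when none is significant); peak is the argmax of
#' the group-mean series within the analysis window (always defined).
#'
#' @param clusterResult a [ClusterTestResult-class].
#' @return List with `onset_ms`, `peak_ms` and `onsetDefined`.
#' @export
onsetPeakLatency <- function(clusterResult) {
  stopifnot(is(clusterResult, "ClusterTestResult"))
  sig <- clusterResult@clusters[
    clusterResult@clusters$corrected_p < clusterResult@config$clusterAlpha, ,
    drop = FALSE]
  onset <- if (nrow(sig)) min(sig$start_ms) else NA_real_
  peak <- clusterResult@times[which.max(clusterResult@statisticMap)]
  list(onset_ms = onset, peak_ms = peak, onsetDefined = nrow(sig) > 0L)
}

#' Bootstrap test for latency differences
#'
#' Resamples subjects with replacement (jointly for paired comparisons of
#' the same subjects' two condition series, independently for two-group
#' comparisons), recomputes the group sign-permutation cluster test and the
#' onset or peak latency per draw, and forms the bootstrap distribution of
#' latency differences (A minus B). The two-sided p-value is
#' `2 * min(P(diff <= 0), P(diff >= 0))` over defined draws, capped at 1.
#' Draws where an onset is undefined are dropped; the result is flagged
#' unreliable when more than half the draws are undefined.
#'
#' @param seriesA,seriesB subjects x time matrices on a common grid.
#' @param times ms grid.
#' @param kind `"onset"` or `"peak"`.
#' @param paired resample the same subject indices for both sets (requires
#'   equal sizes with matched ordering).
#' @param nBoot bootstrap draws (default 1,000).
#' @param config inner [clusterTestConfig()] used for significance and the
#'   analysis window.
#' @param seed RNG seed (controls resampling and the inner tests).
#' @return A [LatencyResult-class].
#' @export
bootstrapLatencyTest <- function(seriesA, seriesB, times,
                                 kind = c("onset", "peak"), paired = FALSE,
                                 nBoot = 1000L,
                                 config = clusterTestConfig(), seed = 1L) {
  kind <- match.arg(kind)
  nBoot <- as.integer(nBoot)
  stopifnot(ncol(seriesA) == length(times), ncol(seriesB) == length(times))
  if (paired && nrow(seriesA) != nrow(seriesB))
    stop("paired resampling requires equally sized, matched sets")
  latencyOf <- function(series, innerSeed) {
    cfg <- config
    cfg$seed <- innerSeed
    lat <- onsetPeakLatency(signPermutationClusterTest(series, times, cfg))
    if (kind == "onset") {
      if (lat$onsetDefined) lat$onset_ms else NA_real_
    } else {
      lat$peak_ms
    }
  }
  withSeed(seed, {
    ## one inner-permutation seed per draw, shared between the two sets
    ## (common random numbers; makes identical inputs give exactly zero
    ## differences)
    innerSeeds <- sample.int(.Machine$integer.max - 1L, nBoot + 1L)
    nA <- nrow(seriesA); nB <- nrow(seriesB)
    latA <- latencyOf(seriesA, innerSeeds[1L])
    latB <- latencyOf(seriesB, innerSeeds[1L])
    diffs <- numeric(nBoot)
    nUndef <- 0L
    for (bIdx in seq_len(nBoot)) {
      ia <- sample.int(nA, nA, replace = TRUE)
      ib <- if (paired) ia else sample.int(nB, nB, replace = TRUE)
      la <- latencyOf(seriesA[ia, , drop = FALSE], innerSeeds[bIdx + 1L])
      lb <- latencyOf(seriesB[ib, , drop = FALSE], innerSeeds[bIdx + 1L])
      d <- la - lb
      if (is.na(d)) {
        nUndef <- nUndef + 1L
        diffs[bIdx] <- NA_real_
      } else {
        diffs[bIdx] <- d
      }
    }
    defined <- diffs[!is.na(diffs)]
    p <- if (length(defined)) {
      min(1, 2 * min(mean(defined <= 0), mean(defined >= 0)))
    } else {
      NA_real_
    }
    new("LatencyResult", kind = kind,
        latencyA = latA, latencyB = latB,
        observedDifference = latA - latB,
        bootstrapDifferences = defined, pTwoSided = p,
        nUndefined = nUndef, unreliable = nUndef > nBoot / 2)
  })
}

#' Pooled two-sample t statistic and Cohen's d
#'
#' Computes the pooled-variance two-sample t, its two-sided p, and Cohen's
#' d with the pooled standard deviation, from group summary statistics.
#'
#' @param meanA,meanB group means.
#' @param sdA,sdB group standard deviations (> 0).
#' @param nA,nB group sizes (>= 2).
#' @return List with `t`, `p`, `d` and `df`.
#' @examples
#' pooledTD(110.17, 7.87, 24, 90.63, 9.39, 24)  # d approximately 2.26
#' @export
pooledTD <- function(meanA, sdA, nA, meanB, sdB, nB) {
  if (nA < 2 || nB < 2) stop("group sizes must be >= 2")
  if (sdA <= 0 || sdB <= 0) stop("standard deviations must be positive")
  sp <- sqrt(((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2))
  tval <- (meanA - meanB) / (sp * sqrt(1 / nA + 1 / nB))
  df <- nA + nB - 2
  list(t = tval, p = 2 * pt(-abs(tval), df), d = (meanA - meanB) / sp,
       df = df)
}

#' Worked-example behavioral battery (two reading groups, n = 24 each)
#'
#' Summary statistics (age-based standard scores, mean and SD per group)
#' for a standardized reading and cognitive battery comparing a typical
#' reader group with a dyslexia group of 24 adults each, together with the
#' printed two-sample t and Cohen's d for each subtest. Used as worked
#' examples and a regression suite for [pooledTD()].
#'
#' @return data.frame with columns `test`, `subtest`, `mean_control`,
#'   `sd_control`, `mean_dyslexia`, `sd_dyslexia`, `n_per_group`,
#'   `t_printed`, `d_printed`.
#' @export
behavioralReferenceTable <- function() {
  tab <- data.frame(
    test = c("KBIT-2", "WRMT-III", "WRMT-III", "WRMT-III", "TOWRE-2",
             "TOWRE-2", "GORT-5", "CTOPP-2", "CTOPP-2", "CTOPP-2",
             "WAIS-IV"),
    subtest = c("Matrices", "Word identification", "Word attack",
                "Listening comprehension", "Sight word efficiency",
                "Phonemic decoding efficiency", "Oral reading index",
                "Elision", "Blending words", "Non-word repetition",
                "Digit span total"),
    mean_control = c(114.75, 110.17, 101.50, 107.83, 108.63, 104.29,
                     105.75, 9.63, 11.79, 8.79, 10.79),
    sd_control = c(13.28, 7.87, 8.29, 6.75, 12.37, 6.80, 8.76, 1.91,
                   2.30, 2.23, 2.62),
    mean_dyslexia = c(107.00, 90.63, 78.83, 102.17, 89.71, 84.00, 85.08,
                      7.92, 10.75, 6.38, 8.79),
    sd_dyslexia = c(15.25, 9.39, 9.95, 11.03, 9.42, 8.50, 11.65, 2.55,
                    2.74, 1.58, 2.40),
    t_printed = c(1.88, 7.82, 8.58, 2.15, 5.96, 9.13, 6.94, 2.63, 1.43,
                  4.33, 2.76),
    d_printed = c(0.54, 2.26, 2.48, 0.62, 1.72, 2.64, 2.01, 0.76, 0.41,
                  1.25, 0.80),
    stringsAsFactors = FALSE)
  tab$n_per_group <- 24L
  tab
}
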