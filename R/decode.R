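## Time-resolved pairwise decoding with multivariate noise normalization,
## pseudo-trial cross-validation and temporal generalization.

#' Decoding configuration
#'
#' @param nFolds cross-validation folds (default 5).
#' @param nRepetitions repeats of the whole fold/average/decode procedure;
#'   accuracies are averaged over folds and repetitions (default 100).
#' @param cost linear SVM soft-margin constant (default 1).
#' @param shrinkage `"auto"` for analytic (Ledoit-Wolf-style) shrinkage of
#'   the noise covariance toward its diagonal, or a fixed gamma in `[0, 1]`.
#' @param tgDownsample decimation factor for temporal generalization
#'   (default 4).
#' @param seed RNG seed for fold assignment.
#' @return A validated list of class `decode_config`.
#' @export
decodeConfig <- function(nFolds = 5L, nRepetitions = 100L, cost = 1,
                         shrinkage = "auto", tgDownsample = 4L, seed = 1L) {
  nFolds <- as.integer(nFolds)
  nRepetitions <- as.integer(nRepetitions)
  if (nFolds < 2L) stop("nFolds must be >= 2")
  if (nRepetitions < 1L) stop("nRepetitions must be >= 1")
  if (as.integer(tgDownsample) < 1L) stop("tgDownsample must be >= 1")
  if (!(identical(shrinkage, "auto") ||
        (is.numeric(shrinkage) && shrinkage >= 0 && shrinkage <= 1)))
    stop("shrinkage must be \"auto\" or a gamma in [0, 1]")
  structure(list(nFolds = nFolds, nRepetitions = nRepetitions, cost = cost,
                 shrinkage = shrinkage, tgDownsample = as.integer(tgDownsample),
                 seed = as.integer(seed)),
            class = "decode_config")
}

#' Estimate a multivariate noise normalizer ("epoch" method)
#'
#' Computes, per time point and condition, the across-trial sensor
#' covariance of deviations from the condition mean; averages over time
#' points and then conditions; shrinks the result toward its diagonal with
#' an analytically chosen intensity (Ledoit-Wolf-style, estimated from the
#' pooled centered observations) or a fixed gamma; and returns the
#' symmetric inverse square root as the whitener.
#'
#' @param x numeric array, trials x sensors x time (training trials only,
#'   to keep train/test hygiene).
#' @param labels condition label per trial (2 or more conditions, each with
#'   at least 2 trials).
#' @param shrinkage `"auto"` or a fixed gamma in `[0, 1]`.
#' @return A [NoiseNormalizer-class].
#' @export
estimateNoiseNormalizer <- function(x, labels, shrinkage = "auto") {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  labels <- as.factor(labels)
  conds <- levels(droplevels(labels))
  ns <- d[2L]; nt <- d[3L]
  S <- matrix(0, ns, ns)
  WW <- matrix(0, ns, ns)   # sum of cross-products of centered obs
  W2 <- matrix(0, ns, ns)   # sum of squared cross-products
  N <- 0L
  for (cond in conds) {
    idx <- which(labels == cond)
    nc <- length(idx)
    if (nc < 2L)
      stop("condition '", cond, "' has fewer than 2 trials")
    xc <- x[idx, , , drop = FALSE]
    mu <- colMeans(xc)                      # sensors x time
    xc <- xc - rep(mu, each = nc)
    ## observations: trial deviations at each time point
    M <- matrix(aperm(xc, c(1L, 3L, 2L)), nc * nt, ns)
    S <- S + crossprod(M) / ((nc - 1L) * nt)
    WW <- WW + crossprod(M)
    W2 <- W2 + crossprod(M^2)
    N <- N + nc * nt
  }
  S <- S / length(conds)
  if (identical(shrinkage, "auto")) {
    ## analytic shrinkage toward the diagonal: gamma = sum of estimated
    ## variances of the off-diagonal sample covariances over their squares
    varS <- N / (N - 1)^3 * (W2 - WW^2 / N)
    sij <- WW / (N - 1)
    off <- !diag(ns)
    denom <- sum(sij[off]^2)
    gamma <- if (denom > 0) sum(varS[off]) / denom else 1
    gamma <- min(max(gamma, 0), 1)
  } else {
    gamma <- shrinkage
  }
  Sstar <- (1 - gamma) * S + gamma * diag(diag(S), ns)
  es <- eigen(Sstar, symmetric = TRUE)
  ev <- pmax(es$values, max(es$values) * 1e-12)
  Wm <- es$vectors %*% (t(es$vectors) / sqrt(ev))
  new("NoiseNormalizer", covariance = Sstar, shrinkageGamma = gamma,
      whitener = Wm)
}

## Normalize a label vector into a 2-level factor; NA drops the trial.
decodeLabels <- function(labels, n) {
  if (length(labels) != n)
    stop("labels must align with trials")
  f <- droplevels(as.factor(labels))
  if (nlevels(f) != 2L)
    stop("exactly 2 conditions are required (got ", nlevels(f), ")")
  f
}

## Shared engine for time-resolved decoding and temporal generalization.
## Randomness (stratified fold assignment per repetition) is consumed in a
## fixed order, so a time-resolved run and a generalization run with the
## same seed use identical folds and classifiers.
decodeEngine <- function(epochs, labels, config, generalize = FALSE) {
  stopifnot(is(epochs, "EpochsData"), inherits(config, "decode_config"))
  if (epochs@normalizationState != "z-normalized")
    stop("epochs must be baseline z-normalized before decoding")
  d <- dim(epochs@data)
  f <- decodeLabels(labels, d[1L])
  keep <- which(!is.na(f))
  x <- epochs@data[keep, , , drop = FALSE]
  f <- droplevels(f[keep])
  lv <- levels(f)
  idxA <- which(f == lv[1L]); idxB <- which(f == lv[2L])
  k <- config$nFolds
  if (length(idxA) < k || length(idxB) < k)
    stop("each condition needs at least nFolds trials (",
         length(idxA), " vs ", length(idxB), " available)")
  ns <- d[2L]; nt <- dim(x)[3L]
  acc <- if (generalize) matrix(0, nt, nt) else numeric(nt)

  withSeed(config$seed, {
    for (rep in seq_len(config$nRepetitions)) {
      foldOf <- integer(length(f))
      foldOf[idxA] <- sample(rep_len(seq_len(k), length(idxA)))
      foldOf[idxB] <- sample(rep_len(seq_len(k), length(idxB)))
      ## per-fold, per-condition trial means (pseudo-trials), unwhitened;
      ## whitening is linear so it commutes with the averaging
      P <- array(0, dim = c(k, 2L, ns, nt))
      for (g in seq_len(k)) {
        P[g, 1L, , ] <- colMeans(x[idxA[foldOf[idxA] == g], , ,
                                   drop = FALSE])
        P[g, 2L, , ] <- colMeans(x[idxB[foldOf[idxB] == g], , ,
                                   drop = FALSE])
      }
      for (g in seq_len(k)) {
        trainIdx <- which(foldOf != g)
        nn <- estimateNoiseNormalizer(x[trainIdx, , , drop = FALSE],
                                      f[trainIdx], config$shrinkage)
        Wn <- nn@whitener
        train <- array(0, dim = c(2L * (k - 1L), ns, nt))
        yTrain <- numeric(2L * (k - 1L))
        r <- 0L
        for (g2 in setdiff(seq_len(k), g)) {
          for (cc in 1:2) {
            r <- r + 1L
            train[r, , ] <- Wn %*% matrix(P[g2, cc, , ], ns, nt)
            yTrain[r] <- c(1, -1)[cc]
          }
        }
        fit <- linearSvmTimecourse(train, yTrain, cost = config$cost)
        testA <- Wn %*% matrix(P[g, 1L, , ], ns, nt)
        testB <- Wn %*% matrix(P[g, 2L, , ], ns, nt)
        if (generalize) {
          ## decision of the classifier trained at column time, applied to
          ## the test pattern at row time
          dA <- crossprod(testA, fit$W) + rep(fit$b, each = nt)
          dB <- crossprod(testB, fit$W) + rep(fit$b, each = nt)
          acc <- acc + (t(dA > 0) + t(dB < 0)) / 2
        } else {
          dA <- colSums(testA * fit$W) + fit$b
          dB <- colSums(testB * fit$W) + fit$b
          acc <- acc + ((dA > 0) + (dB < 0)) / 2
        }
      }
    }
  })
  acc <- acc / (config$nRepetitions * k)
  list(acc = acc, pair = lv,
       nUsed = c(length(idxA), length(idxB)), times = epochs@times)
}

#' Time-resolved decoding of two conditions
#'
#' For every repetition, trials of each condition are randomly assigned to
#' `nFolds` stratified folds; a noise normalizer is estimated from the
#' training folds only and applied to training and test data; trials of the
#' same condition within each fold are averaged into one pseudo-trial; and
#' a linear SVM is trained at each time point on the `2 * (nFolds - 1)`
#' training pseudo-trials and tested on the 2 held-out pseudo-trials, with
#' folds rotating. Accuracy is averaged over folds and repetitions; 0.5 is
#' chance. Deterministic given the config seed.
#'
#' @param epochs a z-normalized [EpochsData-class].
#' @param labels per-trial condition labels (2-level factor or logical;
#'   `NA` excludes a trial).
#' @param config a [decodeConfig()].
#' @return A [DecodingResult-class].
#' @export
decodeTimecourse <- function(epochs, labels, config = decodeConfig()) {
  out <- decodeEngine(epochs, labels, config, generalize = FALSE)
  new("DecodingResult", accuracy = as.numeric(out$acc), times = out$times,
      conditionPair = out$pair, nTrialsUsed = as.integer(out$nUsed),
      config = unclass(config))
}

#' Decimate an epoch container in time
#'
#' Keeps every `factor`-th sample. Meant to be applied after low-pass
#' filtering (a 15 Hz low-pass leaves no content near the decimated
#' Nyquist).
#'
#' @param epochs an [EpochsData-class].
#' @param factor integer decimation factor.
#' @return The decimated [EpochsData-class].
#' @export
decimateEpochs <- function(epochs, factor) {
  stopifnot(is(epochs, "EpochsData"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("decimation factor must be >= 1")
  if (factor == 1L) return(epochs)
  idx <- seq.int(1L, length(epochs@times), by = factor)
  epochs@data <- epochs@data[, , idx, drop = FALSE]
  epochs@times <- epochs@times[idx]
  epochs@sfreq <- epochs@sfreq / factor
  epochs
}

#' Temporal generalization
#'
#' Trains the same per-time-point classifiers as [decodeTimecourse()] on a
#' grid decimated by `config$tgDownsample`, but tests each classifier at
#' every time point, yielding a train-time x test-time accuracy matrix.
#' With the same seed, the matrix diagonal equals the time-resolved
#' accuracy computed on the decimated grid (shared computation path).
#'
#' @inheritParams decodeTimecourse
#' @return A [TGResult-class]; `accuracies()` returns the matrix with
#'   training time in rows and testing time in columns.
#' @export
temporalGeneralization <- function(epochs, labels, config = decodeConfig()) {
  dec <- decimateEpochs(epochs, config$tgDownsample)
  out <- decodeEngine(dec, labels, config, generalize = TRUE)
  new("TGResult", matrix = out$acc, times = out$times,
      conditionPair = out$pair, config = unclass(config))
}

#' Random trial subsetting
#'
#' Uniform subsample without replacement, used to match trial counts
#' across analyses (e.g., reducing 2nd-5th standard trials to the usable
#' 6th-trial count). Deterministic given the seed.
#'
#' @param indices available trial indices.
#' @param targetCount number to keep (must not exceed availability).
#' @param seed RNG seed.
#' @return Sorted integer subset of `indices`; the identity when
#'   `targetCount == length(indices)`.
#' @export
subsetTrials <- function(indices, targetCount, seed = 1L) {
  targetCount <- as.integer(targetCount)
  if (targetCount > length(indices))
    stop("target count (", targetCount, ") exceeds available trials (",
         length(indices), ")")
  if (targetCount == length(indices)) return(sort(indices))
  withSeed(seed, sort(indices[sample.int(length(indices), targetCount)]))
}

#' Build condition labels for a standard decoding contrast
#'
#' Supported contrasts: `"deviant-vs-standards"` (position 1 vs everything
#' else) and `"1vK"` for K in 2..6 (position 1 vs position K). Trials
#' outside the contrast are `NA` (excluded).
#'
#' @param trials a per-trial metadata table with `position_in_train`.
#' @param contrast contrast name.
#' @return Factor of labels per trial with the deviant level first.
#' @export
contrastLabels <- function(trials, contrast) {
  pos <- trials$position_in_train
  if (contrast == "deviant-vs-standards") {
    factor(ifelse(pos == 1L, "deviant", "standard"),
           levels = c("deviant", "standard"))
  } else if (grepl("^1v[2-6]$", contrast)) {
    kth <- as.integer(substring(contrast, 3L))
    lab <- ifelse(pos == 1L, "1st",
                  ifelse(pos == kth, paste0(kth, "th"), NA))
    factor(lab, levels = c("1st", paste0(kth, "th")))
  } else {
    stop("unknown contrast: ", contrast)
  }
}
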