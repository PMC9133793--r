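## Trial rejection, zero-phase low-pass filtering and baseline
## z-normalization. Pipeline order is reject -> filter -> normalize; the
## container's normalization state makes misordering detectable.

#' Trial-rejection criteria
#'
#' @param magPtpMax peak-to-peak rejection threshold for magnetometers
#'   (default 10,000 fT).
#' @param gradPtpMax peak-to-peak rejection threshold for gradiometers
#'   (default 2,500 fT/cm).
#' @param rejectZeroSignal reject trials whose samples are all exactly zero
#'   across all sensors (default TRUE).
#' @return A validated list of class `rejection_criteria`.
#' @export
rejectionCriteria <- function(magPtpMax = 10000, gradPtpMax = 2500,
                              rejectZeroSignal = TRUE) {
  if (magPtpMax <= 0 || gradPtpMax <= 0)
    stop("rejection thresholds must be positive")
  structure(list(magPtpMax = magPtpMax, gradPtpMax = gradPtpMax,
                 rejectZeroSignal = isTRUE(rejectZeroSignal)),
            class = "rejection_criteria")
}

#' Preprocessing configuration
#'
#' @param lowpassHz low-pass cutoff in Hz (default 15).
#' @param baselineWindow `(start, end)` of the prestimulus baseline in ms
#'   (default (-200, 0); samples at `start <= t < end` are used).
#' @param epochWindow `(start, end)` of the epoch in ms.
#' @param transitionHz low-pass transition bandwidth in Hz (default 5; sets
#'   the FIR order).
#' @return A validated list of class `preproc_config`.
#' @export
preprocConfig <- function(lowpassHz = 15, baselineWindow = c(-200, 0),
                          epochWindow = c(-200, 550), transitionHz = 5) {
  if (baselineWindow[1L] < epochWindow[1L] ||
      baselineWindow[2L] > epochWindow[2L])
    stop("baseline window must lie inside the epoch window")
  structure(list(lowpassHz = lowpassHz, baselineWindow = baselineWindow,
                 epochWindow = epochWindow, transitionHz = transitionHz),
            class = "preproc_config")
}

## Row maxima/minima of a matrix via max.col (C-level, fast).
rowRange <- function(M) {
  hi <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  lo <- -(-M)[cbind(seq_len(nrow(M)), max.col(-M, ties.method = "first"))]
  cbind(lo, hi)
}

#' Reject artifact trials
#'
#' Removes trials with zero signal (all samples of all sensors exactly
#' zero) or in which any sensor exceeds its peak-to-peak amplitude
#' threshold (computed over the full epoch window, per sensor). Surviving
#' trials are passed through bit-identically, in their original order.
#'
#' @param epochs an [EpochsData-class] in raw state (rejection precedes
#'   normalization).
#' @param criteria a [rejectionCriteria()].
#' @return A list with `epochs` (survivors) and `log`, a data.frame of
#'   `trial_index` and `reason` ("zero_signal", "mag_ptp", "grad_ptp",
#'   possibly comma-joined).
#' @export
rejectArtifacts <- function(epochs, criteria = rejectionCriteria()) {
  stopifnot(is(epochs, "EpochsData"), inherits(criteria, "rejection_criteria"))
  if (epochs@normalizationState != "raw")
    stop("artifact rejection must run on raw (un-normalized) epochs")
  d <- dim(epochs@data)
  n <- d[1L]; ns <- d[2L]; nt <- d[3L]
  M <- matrix(epochs@data, n * ns, nt)  # rows ordered trial-major
  rng <- rowRange(M)
  ptp <- matrix(rng[, 2L] - rng[, 1L], n, ns)
  thr <- ifelse(epochs@layout@sensorType == "mag",
                criteria$magPtpMax, criteria$gradPtpMax)
  overType <- vapply(seq_len(n), function(i) {
    bad <- ptp[i, ] > thr
    if (!any(bad)) return("")
    paste(sort(unique(paste0(epochs@layout@sensorType[bad], "_ptp"))),
          collapse = ",")
  }, character(1))
  zero <- rowSums(matrix(abs(M), n, ns * nt)) == 0
  reason <- ifelse(criteria$rejectZeroSignal & zero, "zero_signal", overType)
  bad <- reason != ""
  if (all(bad)) stop("all trials rejected; downstream analysis undefined")
  log <- data.frame(trial_index = epochs@trials$trial_index[bad],
                    reason = reason[bad], stringsAsFactors = FALSE)
  epochs@data <- epochs@data[!bad, , , drop = FALSE]
  epochs@trials <- epochs@trials[!bad, , drop = FALSE]
  rownames(epochs@trials) <- NULL
  validObject(epochs)
  list(epochs = epochs, log = log)
}

## Zero-phase FIR application to the columns of a time x channels matrix by
## FFT convolution with reflection padding; h must be odd-length symmetric.
zeroPhaseFirFilter <- function(M, h, chunk = 1024L) {
  nt <- nrow(M)
  H <- (length(h) - 1L) %/% 2L
  if (H >= nt)
    stop("filter length exceeds the epoch; shorten the transition band")
  padTop <- if (H > 0L) rev(seq.int(2L, H + 1L)) else integer(0)
  padBot <- if (H > 0L) rev(seq.int(nt - H, nt - 1L)) else integer(0)
  L <- nt + 2L * H
  N <- stats::nextn(L + length(h) - 1L)
  Hf <- stats::fft(c(h, numeric(N - length(h))))
  out <- M
  for (j0 in seq.int(1L, ncol(M), by = chunk)) {
    j <- j0:min(j0 + chunk - 1L, ncol(M))
    P <- rbind(M[padTop, j, drop = FALSE], M[, j, drop = FALSE],
               M[padBot, j, drop = FALSE],
               matrix(0, N - L, length(j)))
    Y <- stats::mvfft(stats::mvfft(P) * Hf, inverse = TRUE) / N
    out[, j] <- Re(Y[(2L * H + 1L):(2L * H + nt), , drop = FALSE])
  }
  out
}

#' Zero-phase low-pass filter
#'
#' Applies a Hamming-windowed linear-phase FIR low-pass (designed with
#' [signal::fir1()]; order set by the transition bandwidth) to every trial
#' and sensor, with centered (delay-compensated) FFT convolution and
#' reflection padding at the epoch edges, i.e. zero phase shift. DC gain is
#' 1, so baselines are preserved and no latency bias is introduced.
#'
#' @param epochs an [EpochsData-class].
#' @param config a [preprocConfig()]; the cutoff must be below Nyquist.
#' @return The filtered [EpochsData-class].
#' @export
lowpassFilter <- function(epochs, config = preprocConfig()) {
  stopifnot(is(epochs, "EpochsData"), inherits(config, "preproc_config"))
  fs <- epochs@sfreq
  if (config$lowpassHz >= fs / 2)
    stop("low-pass cutoff must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  d <- dim(epochs@data)
  nt <- d[3L]
  order <- 2L * max(1L, ceiling(3.3 * fs / config$transitionHz / 2))
  order <- min(order, 2L * (nt - 2L))
  h <- as.numeric(signal::fir1(order, config$lowpassHz / (fs / 2),
                               type = "low"))
  h <- h / sum(h)  # exact unit gain at DC
  ## columns = (trial, sensor) series
  M <- t(matrix(epochs@data, d[1L] * d[2L], nt))
  epochs@data <- array(t(zeroPhaseFirFilter(M, as.numeric(h))), dim = d)
  epochs
}

#' Baseline z-normalization
#'
#' Per trial and per sensor, subtracts the mean and divides by the standard
#' deviation of the prestimulus baseline window, then marks the container
#' as z-normalized. Applying it twice is an error (the normalization state
#' guards pipeline order).
#'
#' @param epochs an [EpochsData-class] in raw state.
#' @param config a [preprocConfig()]; the baseline window must contain at
#'   least 2 samples.
#' @return The normalized [EpochsData-class].
#' @export
baselineZNormalize <- function(epochs, config = preprocConfig()) {
  stopifnot(is(epochs, "EpochsData"), inherits(config, "preproc_config"))
  if (epochs@normalizationState == "z-normalized")
    stop("epochs are already z-normalized")
  idx <- which(epochs@times >= config$baselineWindow[1L] &
               epochs@times < config$baselineWindow[2L])
  if (length(idx) < 2L)
    stop("baseline window must contain at least 2 samples")
  d <- dim(epochs@data)
  B <- matrix(epochs@data[, , idx, drop = FALSE], d[1L] * d[2L],
              length(idx))
  mu <- rowMeans(B)
  sdv <- sqrt(rowSums((B - mu)^2) / (length(idx) - 1L))
  if (any(sdv == 0)) {
    k <- which(sdv == 0)[1L]
    trial <- (k - 1L) %% d[1L] + 1L
    sensor <- (k - 1L) %/% d[1L] + 1L
    stop(sprintf("zero baseline SD for trial %d, sensor %d; %s",
                 epochs@trials$trial_index[trial], sensor,
                 "reject such trials before normalizing"))
  }
  epochs@data <- (epochs@data - array(mu, d)) / array(sdv, d)
  epochs@normalizationState <- "z-normalized"
  epochs
}

#' Run the full preprocessing chain
#'
#' Applies, in order: artifact rejection, zero-phase low-pass filtering,
#' baseline z-normalization.
#'
#' @param epochs an [EpochsData-class] in raw state.
#' @param criteria a [rejectionCriteria()].
#' @param config a [preprocConfig()].
#' @return A list with `epochs` (preprocessed) and `log` (rejection log).
#' @export
preprocess <- function(epochs, criteria = rejectionCriteria(),
                       config = preprocConfig()) {
  rej <- rejectArtifacts(epochs, criteria)
  out <- lowpassFilter(rej$epochs, config)
  out <- baselineZNormalize(out, config)
  list(epochs = out, log = rej$log)
}
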