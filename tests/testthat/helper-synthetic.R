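## Shared fixtures, built in code.

## Small roving-oddball design for simulation tests.
smokeDesign <- function(seed = 1L, nTrains = 60L) {
  k <- nTrains / 3L
  generateDesign(designSpec(
    nTrains = nTrains,
    lengthCounts = setNames(as.integer(c(k, k, k)), c("4", "5", "6")),
    seed = seed))
}

## Epoch container filled with (optionally spatially correlated) Gaussian
## noise, already flagged z-normalized so it can go straight to decoding.
noiseEpochs <- function(n, ns, nt, seed, Sigma = NULL,
                        labels = NULL, state = "z-normalized") {
  set.seed(seed)
  if (is.null(Sigma)) {
    x <- array(rnorm(n * ns * nt), c(n, ns, nt))
  } else {
    R <- chol(Sigma)
    x <- array(0, c(n, ns, nt))
    for (i in seq_len(n))
      x[i, , ] <- crossprod(R, matrix(rnorm(ns * nt), ns, nt))
  }
  new("EpochsData", data = x, times = seq(0, nt - 1), sfreq = 1000,
      layout = sensorLayout(ns),
      trials = data.frame(trial_index = seq_len(n), stimulus = "A",
                          position_in_train = 1L, train_index = seq_len(n)),
      normalizationState = state)
}

## Subject x time matrices of smoothed null noise around a baseline.
smoothSeries <- function(n, nt, sd, seed, base = 0.5) {
  set.seed(seed)
  base + t(sapply(seq_len(n), function(i)
    as.numeric(stats::filter(rnorm(nt, 0, sd), rep(1 / 5, 5),
                             circular = TRUE))))
}

## Independent oracle for the one-sample sign-permutation cluster test:
## exhaustive enumeration of all 2^n sign patterns, plain loops throughout.
## Returns the corrected p of each cluster of the observed (all +1) map.
enumClusterOracle <- function(D, alphaDef = 0.05, alternative = "greater") {
  n <- nrow(D)
  nt <- ncol(D)
  nPat <- 2^n
  stats <- matrix(0, nPat, nt)
  for (p in seq_len(nPat)) {
    bits <- as.integer(intToBits(p - 1L))[seq_len(n)]
    signs <- ifelse(bits == 1L, -1, 1)  # pattern 0 = identity
    stats[p, ] <- colMeans(signs * D)
  }
  ## pointwise p by counting
  pw <- matrix(0, nPat, nt)
  for (t in seq_len(nt)) {
    v <- if (alternative == "greater") stats[, t] else abs(stats[, t])
    for (p in seq_len(nPat)) pw[p, t] <- sum(v >= v[p]) / nPat
  }
  maxMass <- numeric(nPat)
  obs <- NULL
  for (p in seq_len(nPat)) {
    mask <- pw[p, ] < alphaDef + 1e-12
    if (alternative == "two.sided")
      grp <- mask * sign(stats[p, ])
    else
      grp <- as.integer(mask)
    masses <- c(); starts <- c(); ends <- c()
    t <- 1L
    while (t <= nt) {
      if (grp[t] != 0) {
        t0 <- t
        while (t < nt && grp[t + 1L] == grp[t0]) t <- t + 1L
        masses <- c(masses, sum(stats[p, t0:t]))
        starts <- c(starts, t0); ends <- c(ends, t)
      }
      t <- t + 1L
    }
    sz <- if (alternative == "two.sided") abs(masses) else masses
    maxMass[p] <- if (length(sz)) max(sz) else 0
    if (p == 1L) obs <- list(starts = starts, ends = ends, masses = masses)
  }
  if (is.null(obs) || !length(obs$masses)) return(numeric(0))
  sz <- if (alternative == "two.sided") abs(obs$masses) else obs$masses
  vapply(sz, function(m) mean(maxMass >= m), numeric(1))
}
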