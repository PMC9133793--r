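## Roving-oddball design generation: psychometric stimulus selection and
## transition-balanced train sequences.

## Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Fit a logistic psychometric function
#'
#' Least-squares fit of a four-parameter logistic
#' \eqn{r(x) = lo + (hi - lo) / (1 + e^{-s (x - m)})}
#' to per-step labeling proportions, with asymptotes constrained to
#' `[0, 1]`. The midpoint `m` is the inflection point and estimates the
#' categorical-perception boundary.
#'
#' Degenerate data (all proportions equal) or a non-converging optimizer
#' yield a flagged non-converged result rather than an error.
#'
#' @param stepIds integer-like vector of continuum steps (>= 4 distinct).
#' @param responseRatio proportions in `[0, 1]`, one per step.
#' @return A [PsychometricFit-class].
#' @examples
#' x <- 1:10
#' r <- 1 / (1 + exp(-1.2 * (x - 5.8)))
#' fitPsychometric(x, r)
#' @export
fitPsychometric <- function(stepIds, responseRatio) {
  x <- as.numeric(stepIds)
  r <- as.numeric(responseRatio)
  if (length(unique(x)) < 4L)
    stop("at least 4 distinct continuum steps are required")
  if (length(r) != length(x))
    stop("one response ratio per step is required")
  if (any(r < -1e-9 | r > 1 + 1e-9))
    stop("response ratios must lie in [0, 1]")

  failed <- new("PsychometricFit", midpoint = NA_real_, slope = NA_real_,
                asymptotes = c(NA_real_, NA_real_), converged = FALSE,
                residualSS = NA_real_)
  if (diff(range(r)) < 1e-12) return(failed)

  ## data-driven starting values; slope sign from the overall trend
  trend <- sign(sum((x - mean(x)) * (r - mean(r))))
  if (trend == 0) trend <- 1
  mid0 <- sum(x * abs(diff(c(r[1L], r)))) / max(sum(abs(diff(c(r[1L], r)))), 1e-12)
  if (!is.finite(mid0)) mid0 <- mean(x)
  start <- list(lo = max(min(r), 0), hi = min(max(r), 1),
                slope = trend * 4 / max(diff(range(x)) / 2, 1e-6),
                mid = mid0)
  span <- diff(range(x))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ lo + (hi - lo) / (1 + exp(-slope * (x - mid))),
      start = start,
      lower = c(lo = 0, hi = 0, slope = -500, mid = min(x) - span),
      upper = c(lo = 1, hi = 1, slope = 500, mid = max(x) + span),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(failed)
  cf <- coef(fit)
  if (!all(is.finite(cf)) || abs(cf[["slope"]]) < 1e-8) return(failed)
  new("PsychometricFit",
      midpoint = unname(cf[["mid"]]), slope = unname(cf[["slope"]]),
      asymptotes = unname(c(cf[["lo"]], cf[["hi"]])), converged = TRUE,
      residualSS = sum(residuals(fit)^2))
}

#' Select an equidistant five-stimulus set around the boundary
#'
#' The continuum step nearest the fitted inflection point becomes stimulus
#' C; A, B, D, E are placed at `-2*spacing`, `-spacing`, `+spacing`,
#' `+2*spacing` steps. When the midpoint sits too close to a continuum edge
#' for the set to fit, C is clamped into the feasible range and the result
#' is flagged.
#'
#' @param fit a converged [PsychometricFit-class], or `NULL` when supplying
#'   `midpoint` directly.
#' @param nContinuumSteps integer, number of continuum steps (default 10).
#' @param spacing integer, steps between neighboring stimuli (default 2).
#' @param midpoint optional numeric override used when `fit` is `NULL`.
#' @return A [StimulusSet-class].
#' @examples
#' selectStimulusSet(NULL, midpoint = 5.2)  # steps 1, 3, 5, 7, 9
#' selectStimulusSet(NULL, midpoint = 6.0)  # steps 2, 4, 6, 8, 10
#' @export
selectStimulusSet <- function(fit, nContinuumSteps = 10L, spacing = 2L,
                              midpoint = NULL) {
  spacing <- as.integer(spacing)
  nContinuumSteps <- as.integer(nContinuumSteps)
  if (spacing * 4L >= nContinuumSteps)
    stop("the equidistant set does not fit: need spacing * 4 < nContinuumSteps")
  if (is.null(midpoint)) {
    if (is.null(fit) || !isTRUE(fit@converged))
      stop("psychometric fit did not converge; a default midpoint must be ",
           "supplied via the 'midpoint' argument")
    midpoint <- fit@midpoint
  }
  C <- as.integer(floor(midpoint + 0.5))  # nearest step, .5 rounds up
  lo <- 1L + 2L * spacing
  hi <- nContinuumSteps - 2L * spacing
  clamped <- C < lo || C > hi
  C <- min(max(C, lo), hi)
  new("StimulusSet", steps = C + spacing * (-2:2), spacing = spacing,
      clamped = clamped)
}

#' Specify a roving-oddball design
#'
#' Bundles the design parameters: number of trains, how many trains of each
#' length, the stimulus inventory, whether ordered stimulus transitions are
#' balanced, and the timing metadata (stimulus onset asynchrony 575 ms,
#' syllable duration 310 ms) carried for provenance.
#'
#' @param nTrains integer, number of trains (default 600).
#' @param lengthCounts named integer vector, trains per length; names are
#'   the lengths (default 200 each of 4, 5, 6). Must sum to `nTrains`.
#' @param nStimuli integer >= 2 (default 5, labels A-E).
#' @param transitionBalance logical, balance ordered stimulus transitions to
#'   within +/- 1 (default TRUE).
#' @param seed integer RNG seed for the design draw.
#' @param soaMs,durationMs timing metadata in ms (not used computationally;
#'   the simulator emits pre-epoched trials).
#' @return A validated list of class `design_spec`.
#' @export
designSpec <- function(nTrains = 600L,
                       lengthCounts = c("4" = 200L, "5" = 200L, "6" = 200L),
                       nStimuli = 5L, transitionBalance = TRUE, seed = 1L,
                       soaMs = 575, durationMs = 310) {
  nTrains <- as.integer(nTrains)
  nStimuli <- as.integer(nStimuli)
  if (nStimuli < 2L) stop("nStimuli must be >= 2")
  if (is.null(names(lengthCounts)))
    stop("lengthCounts must be named by train length")
  if (!all(names(lengthCounts) %in% c("4", "5", "6")))
    stop("train lengths must be in {4, 5, 6}")
  if (sum(lengthCounts) != nTrains)
    stop("lengthCounts must sum to nTrains")
  structure(list(nTrains = nTrains,
                 lengthCounts = setNames(as.integer(lengthCounts),
                                         names(lengthCounts)),
                 nStimuli = nStimuli,
                 transitionBalance = isTRUE(transitionBalance),
                 seed = as.integer(seed), soaMs = soaMs,
                 durationMs = durationMs),
            class = "design_spec")
}

## Eulerian path through the transition multigraph by Hierholzer's
## algorithm; counts[u, v] holds the remaining multiplicity of u -> v.
eulerianPath <- function(counts, start) {
  k <- nrow(counts)
  stack <- integer(sum(counts) + 1L)
  stack[1L] <- start
  top <- 1L
  path <- integer(sum(counts) + 1L)
  np <- 0L
  while (top > 0L) {
    u <- stack[top]
    row <- counts[u, ]
    tot <- sum(row)
    if (tot > 0L) {
      v <- sample.int(k, 1L, prob = row)
      counts[u, v] <- counts[u, v] - 1L
      top <- top + 1L
      stack[top] <- v
    } else {
      np <- np + 1L
      path[np] <- u
      top <- top - 1L
    }
  }
  rev(path[seq_len(np)])
}

## Draw a transition multiset with all pair counts in {base, base + 1} whose
## multigraph admits an Eulerian path; returns counts matrix plus start node.
balancedTransitionCounts <- function(nTransitions, k, maxTries = 200L) {
  P <- k * (k - 1L)
  base <- nTransitions %/% P
  r <- nTransitions %% P
  pairs <- which(!diag(k), arr.ind = TRUE)  # all ordered pairs u != v
  for (try in seq_len(maxTries)) {
    counts <- matrix(0L, k, k)
    counts[pairs] <- base
    if (r > 0L) {
      extra <- pairs[sample.int(nrow(pairs), r), , drop = FALSE]
      counts[extra] <- counts[extra] + 1L
    }
    outd <- rowSums(counts)
    ind <- colSums(counts)
    diffs <- outd - ind
    plus <- which(diffs == 1L)
    minus <- which(diffs == -1L)
    balancedOk <- (all(diffs == 0L) ||
                   (length(plus) == 1L && length(minus) == 1L &&
                    sum(abs(diffs)) == 2L))
    if (!balancedOk) next
    ## connectivity over nodes that carry edges (trivially true once every
    ## pair has base >= 1)
    if (base == 0L) {
      active <- which(outd + ind > 0L)
      if (length(active)) {
        reach <- logical(k)
        frontier <- active[1L]
        reach[frontier] <- TRUE
        und <- (counts + t(counts)) > 0L
        while (length(frontier)) {
          nxt <- which(colSums(und[frontier, , drop = FALSE] > 0) > 0 & !reach)
          reach[nxt] <- TRUE
          frontier <- nxt
        }
        if (!all(reach[active])) next
      }
    }
    start <- if (length(plus)) plus[1L] else {
      act <- which(outd > 0L)
      act[sample.int(length(act), 1L)]
    }
    return(list(counts = counts, start = start))
  }
  stop("could not draw a transition multiset admitting an Eulerian path ",
       "(balanced-transition constraint infeasible after ", maxTries,
       " tries)")
}

#' Generate a roving-oddball train design
#'
#' Draws the pseudo-randomized sequence of stimulus trains: consecutive
#' trains always differ in stimulus, and with `transitionBalance` every
#' ordered stimulus pair occurs as a train-to-train transition with counts
#' balanced to within +/- 1 (with the 600-train default: 19 ordered pairs
#' occur 30 times and one occurs 29 times over the 599 transitions, and
#' every stimulus heads exactly 120 trains). The stimulus sequence is an
#' Eulerian path through the transition multigraph, drawn with a seeded
#' random edge order; train lengths are a seeded shuffle of the length
#' multiset. Deterministic given the seed carried by the design
#' specification.
#'
#' @param spec a [designSpec()].
#' @return A [TrainDesign-class]; `trialTable()` gives the per-trial
#'   expansion (3,000 rows with the defaults).
#' @examples
#' d <- generateDesign(designSpec(seed = 7))
#' positionCounts(d)
#' @export
generateDesign <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  k <- spec$nStimuli
  labels <- LETTERS[seq_len(k)]
  withSeed(spec$seed, {
    if (spec$nTrains == 1L) {
      stimSeq <- sample.int(k, 1L)
    } else if (spec$transitionBalance) {
      tc <- balancedTransitionCounts(spec$nTrains - 1L, k)
      stimSeq <- eulerianPath(tc$counts, tc$start)
    } else {
      stimSeq <- integer(spec$nTrains)
      stimSeq[1L] <- sample.int(k, 1L)
      for (i in seq_len(spec$nTrains - 1L) + 1L)
        stimSeq[i] <- sample(setdiff(seq_len(k), stimSeq[i - 1L]), 1L)
    }
    lens <- rep(as.integer(names(spec$lengthCounts)), spec$lengthCounts)
    lens <- lens[sample.int(length(lens))]
    trains <- data.frame(train_index = seq_len(spec$nTrains),
                         stimulus = labels[stimSeq],
                         length = lens,
                         stringsAsFactors = FALSE)
    trials <- data.frame(
      trial_index = seq_len(sum(lens)),
      train_index = rep(trains$train_index, lens),
      stimulus = rep(trains$stimulus, lens),
      position_in_train = sequence(lens),
      stringsAsFactors = FALSE)
    trials$is_deviant <- trials$position_in_train == 1L
    new("TrainDesign", trains = trains, trials = trials,
        spec = unclass(spec))
  })
}

#' Count trials per position-in-train
#'
#' @param design a [TrainDesign-class].
#' @return Named integer vector of trial counts per position label
#'   ("1" = deviants, "2".."6" = standards); the default design yields
#'   600/600/600/600/400/200.
#' @export
positionCounts <- function(design) {
  stopifnot(is(design, "TrainDesign"))
  pos <- design@trials$position_in_train
  tab <- table(factor(pos, levels = seq_len(max(pos))))
  setNames(as.integer(tab), names(tab))
}

#' Count ordered stimulus transitions between consecutive trains
#'
#' @param design a [TrainDesign-class].
#' @return Integer matrix `from x to` of transition counts (diagonal zero by
#'   construction).
#' @export
transitionCounts <- function(design) {
  stopifnot(is(design, "TrainDesign"))
  s <- design@trains$stimulus
  labels <- sort(unique(s))
  out <- matrix(0L, length(labels), length(labels),
                dimnames = list(from = labels, to = labels))
  if (length(s) > 1L) {
    tab <- table(factor(s[-length(s)], labels), factor(s[-1L], labels))
    out[] <- as.integer(tab)
  }
  out
}

#' Write / read a train design as a delimited trial table
#'
#' The per-trial table is written as TSV with a JSON sidecar
#' (`<file>.spec.json`) holding the generating spec.
#'
#' @param design a [TrainDesign-class].
#' @param file path of the TSV trial table.
#' @return `writeDesign()` returns `file` invisibly; `readDesign()` returns
#'   the reconstructed [TrainDesign-class].
#' @export
writeDesign <- function(design, file) {
  stopifnot(is(design, "TrainDesign"))
  write.table(design@trials, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(design@spec, paste0(file, ".spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeDesign
#' @export
readDesign <- function(file) {
  trials <- read.table(file, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  trials$is_deviant <- as.logical(trials$is_deviant)
  spec <- jsonlite::read_json(paste0(file, ".spec.json"),
                              simplifyVector = TRUE)
  first <- !duplicated(trials$train_index)
  lens <- as.integer(table(trials$train_index)[
    as.character(trials$train_index[first])])
  trains <- data.frame(train_index = trials$train_index[first],
                       stimulus = trials$stimulus[first],
                       length = lens, stringsAsFactors = FALSE)
  new("TrainDesign", trains = trains, trials = trials, spec = spec)
}
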