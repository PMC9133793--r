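## Linear soft-margin SVM, solved in the dual with an SMO sweep over all
## index pairs. The per-time-point training sets of the decoding pipeline
## are tiny (2 * (nFolds - 1) pseudo-trials), but there are hundreds of
## time points per fold; the solver therefore runs all time points'
## problems simultaneously, every SMO quantity being a vector over time.

#' Train linear SVMs at every time point
#'
#' Solves, independently per time point, the C-SVM dual
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j
#'       y_i y_j x_i^\top x_j, \quad 0 \le \alpha_i \le C, \;
#'       \sum_i \alpha_i y_i = 0}
#' by sequential minimal optimization over all index pairs, vectorized
#' across time points. Intended for the small-n, many-time-points training
#' problems of time-resolved decoding.
#'
#' @param x numeric array, trials x sensors x time (training patterns).
#' @param y labels, coercible to -1/+1 (2-level factor, logical, or +/-1).
#' @param cost soft-margin constant C (default 1).
#' @param maxSweeps maximum full passes over all pairs.
#' @param tol convergence tolerance on the largest alpha change per sweep.
#' @return List with `W` (sensors x time weight matrix), `b` (intercept per
#'   time point) and `alpha` (trials x time dual coefficients). The decision
#'   value for a pattern `v` at time `t` is `sum(W[, t] * v) + b[t]`.
#' @seealso [decodeTimecourse()] which uses this internally.
#' @export
linearSvmTimecourse <- function(x, y, cost = 1, maxSweeps = 100L,
                                tol = 1e-6) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  n <- d[1L]; ns <- d[2L]; nt <- d[3L]
  y <- svmLabels(y)
  stopifnot(length(y) == n, all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training set")

  ## Gram tensor as a list: K[[i]] is n x time, K[[i]][j, t] = <x_i, x_j>_t
  xm <- lapply(seq_len(n), function(i) matrix(x[i, , ], ns, nt))
  K <- lapply(seq_len(n), function(i) matrix(0, n, nt))
  for (i in seq_len(n)) {
    for (j in i:n) {
      kij <- colSums(xm[[i]] * xm[[j]])
      K[[i]][j, ] <- kij
      K[[j]][i, ] <- kij
    }
  }

  alpha <- matrix(0, n, nt)
  b <- numeric(nt)
  E <- matrix(rep(-y, nt), n, nt)  # E_k = f(x_k) - y_k, f = 0 initially
  eps <- 1e-12
  act <- seq_len(nt)  # columns (time points) still being optimized
  for (sweep in seq_len(maxSweeps)) {
    colDelta <- numeric(length(act))
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        eta <- K[[i]][i, act] + K[[j]][j, act] - 2 * K[[i]][j, act]
        ok <- eta > eps
        if (!any(ok)) next
        ajOld <- alpha[j, act]
        aiOld <- alpha[i, act]
        ajNew <- ajOld + y[j] * (E[i, act] - E[j, act]) / pmax(eta, eps)
        if (y[i] != y[j]) {
          L <- pmax(0, ajOld - aiOld)
          Hh <- pmin(cost, cost + ajOld - aiOld)
        } else {
          L <- pmax(0, aiOld + ajOld - cost)
          Hh <- pmin(cost, aiOld + ajOld)
        }
        ajNew <- pmin(pmax(ajNew, L), Hh)
        dj <- ifelse(ok, ajNew - ajOld, 0)
        changed <- abs(dj) > eps
        if (!any(changed)) next
        dj[!changed] <- 0
        di <- -y[i] * y[j] * dj
        aiNew <- aiOld + di
        ajNew <- ajOld + dj
        alpha[i, act] <- aiNew
        alpha[j, act] <- ajNew
        ## intercept update (standard SMO b1/b2 rule)
        bAct <- b[act]
        b1 <- bAct - E[i, act] - y[i] * di * K[[i]][i, act] -
          y[j] * dj * K[[i]][j, act]
        b2 <- bAct - E[j, act] - y[i] * di * K[[i]][j, act] -
          y[j] * dj * K[[j]][j, act]
        freeI <- aiNew > eps & aiNew < cost - eps
        freeJ <- ajNew > eps & ajNew < cost - eps
        bNew <- ifelse(freeI, b1, ifelse(freeJ, b2, (b1 + b2) / 2))
        db <- bNew - bAct
        b[act] <- bNew
        ## E_k += y_i di K_ik + y_j dj K_jk + db, all k
        E[, act] <- E[, act] + K[[i]][, act] * rep(y[i] * di, each = n) +
          K[[j]][, act] * rep(y[j] * dj, each = n) + rep(db, each = n)
        colDelta <- pmax(colDelta, abs(dj))
      }
    }
    conv <- colDelta < tol * cost
    if (all(conv)) break
    act <- act[!conv]
  }

  ## final intercept from the KKT conditions: with g_k = y_k - f0_k, free
  ## support vectors pin b = mean(g_free); otherwise b is the midpoint of
  ## the feasible interval [max g_lower, min g_upper]
  F0 <- E + y - rep(b, each = n)        # f without intercept
  G <- y - F0
  freeM <- alpha > eps & alpha < cost - eps
  atLo <- alpha <= eps
  atHi <- alpha >= cost - eps
  lowerM <- (atLo & y == 1) | (atHi & y == -1)
  upperM <- (atLo & y == -1) | (atHi & y == 1)
  nFree <- colSums(freeM)
  bFree <- colSums(G * freeM) / pmax(nFree, 1L)
  gl <- G; gl[!lowerM] <- -Inf
  gu <- G; gu[!upperM] <- Inf
  bBound <- (do.call(pmax, asplit(gl, 1L)) +
             do.call(pmin, asplit(gu, 1L))) / 2
  bBound[!is.finite(bBound)] <- 0
  b <- ifelse(nFree > 0L, bFree, bBound)

  W <- matrix(0, ns, nt)
  for (i in seq_len(n)) {
    coefi <- alpha[i, ] * y[i]
    if (any(coefi != 0))
      W <- W + xm[[i]] * rep(coefi, each = ns)
  }
  list(W = W, b = b, alpha = alpha)
}

## Coerce labels to -1/+1; the FIRST factor level (or TRUE) maps to +1.
svmLabels <- function(y) {
  if (is.factor(y)) {
    stopifnot(nlevels(droplevels(y)) == 2L)
    ifelse(y == levels(droplevels(y))[1L], 1, -1)
  } else if (is.logical(y)) {
    ifelse(y, 1, -1)
  } else {
    as.numeric(y)
  }
}
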