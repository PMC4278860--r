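#' Lag grid for lagged-correlation feature selection
#'
#' Signed lags from `-max_ms` to `+max_ms` in `step_ms` steps (41 values by
#' default). Convention: r at lag `l` correlates `feature(t + l)` with
#' `target(t)`, so a *negative* lag means the neural feature changes before
#' the kinematics (motor-like) and a positive lag after (sensory-like).
#'
#' @param max_ms Maximum absolute lag in ms (default 1000).
#' @param step_ms Lag step in ms (default 50).
#' @return A `lag_grid` with `lags_ms`.
#' @export
lag_grid <- function(max_ms = 1000, step_ms = 50) {
  if (max_ms %% step_ms != 0) stop("step_ms must divide max_ms")
  structure(list(lags_ms = seq(-max_ms, max_ms, by = step_ms)),
            class = "lag_grid")
}

#' Pearson correlation between a feature and a target over a lag grid
#'
#' For each lag `l`, computes the Pearson correlation between
#' `feature(t + l)` and `target(t)` over the overlapping interval only (no
#' padding). A constant trace within the overlap yields r = 0 with a warning.
#'
#' @param feature,target Equal-length numeric traces at `fs` Hz.
#' @param grid A [lag_grid()].
#' @param fs Sampling rate of the traces in Hz (default 100).
#' @return data.frame with `lag_ms` and `r` (one row per lag).
#' @export
lagged_correlation <- function(feature, target, grid = lag_grid(), fs = 100) {
  stopifnot(length(feature) == length(target))
  shifts <- lag_samples(grid, fs)
  if (length(feature) <= 2 * max(abs(shifts))) {
    stop("traces must be longer than twice the maximum lag")
  }
  r <- lagged_cor_matrix(matrix(feature, ncol = 1), target, shifts,
                         rep(TRUE, length(target)), warn_constant = TRUE)
  data.frame(lag_ms = grid$lags_ms, r = as.numeric(r))
}

lag_samples <- function(grid, fs) as.integer(round(grid$lags_ms / 1000 * fs))

# Target-side tables for masked lagged correlation: for each shift, the
# shifted target (zeroed outside valid pairs), the pair mask, and its
# marginal sums. These depend on the target and fold masks only, so the
# shuffle null builds them once and reuses them for every surrogate.
lag_tables <- function(y, shifts, valid) {
  Tn <- length(y); L <- length(shifts)
  u <- seq_len(Tn)
  Yl <- matrix(0, Tn, L)
  M <- matrix(0, Tn, L)
  for (l in seq_len(L)) {
    s <- shifts[l]
    t_idx <- u - s                      # target index paired with feature row u
    ok <- t_idx >= 1L & t_idx <= Tn
    ok[ok] <- valid[u[ok]] & valid[t_idx[ok]]
    Yl[ok, l] <- y[t_idx[ok]]
    M[ok, l] <- 1
  }
  list(Yl = Yl, M = M, n = colSums(M), Sy = colSums(Yl),
       Syy = colSums(Yl * Yl))
}

# Correlation of every column of X (samples x features) with y at each shift,
# restricted to rows where both ends of the pair lie in `valid`. Returns a
# features x lags matrix. One crossprod per quantity keeps this at BLAS speed.
lagged_cor_matrix <- function(X, y, shifts, valid, warn_constant = FALSE,
                              tab = NULL, X2 = NULL) {
  if (is.null(tab)) tab <- lag_tables(y, shifts, valid)
  if (is.null(X2)) X2 <- X * X
  n <- tab$n
  Sy <- tab$Sy
  Syy <- tab$Syy
  Sxy <- crossprod(X, tab$Yl)            # F x L
  Sx <- crossprod(X, tab$M)
  Sxx <- crossprod(X2, tab$M)
  num <- Sxy - sweep(Sx, 2L, Sy / n, "*")
  vx <- Sxx - sweep(Sx^2, 2L, 1 / n, "*")
  vy <- Syy - Sy^2 / n
  # a trace that is constant within the overlap has no defined correlation;
  # guard against catastrophic cancellation as well as exact zeros
  deg <- vx <= 1e-12 * pmax(Sxx, .Machine$double.xmin) |
    rep(vy <= 1e-12 * pmax(Syy, .Machine$double.xmin), each = nrow(vx))
  den <- sqrt(pmax(vx, 0) * rep(pmax(vy, 0), each = nrow(vx)))
  r <- num / den
  bad <- !is.finite(r) | deg
  if (any(bad)) {
    if (warn_constant) warning("constant trace in overlap; returning r = 0")
    r[bad] <- 0
  }
  r
}

#' Select the top-n features by lagged training correlation
#'
#' Scores every (channel, feature type) candidate at its best lag — the lag
#' maximizing `|r|` with the target over the grid — and returns the `n`
#' highest-|r| candidates, each included once at its best lag. Ranking uses
#' the correlation magnitude, since informative low-frequency band powers
#' correlate negatively with movement. Ties are broken deterministically by
#' (lower channel index, earlier feature-type order, smaller |lag|, earlier
#' lag).
#'
#' @param features A `feature_tensor` (see [extract_features()]).
#' @param target Numeric target trace, aligned with the feature samples.
#' @param n Number of features to select.
#' @param grid A [lag_grid()].
#' @param valid Optional logical mask of training samples (default: all).
#' @return data.frame (class `selected_features`) with columns `channel`,
#'   `feature_type`, `best_lag_ms`, `train_r`, ordered by decreasing `|train_r|`.
#' @export
select_features <- function(features, target, n, grid = lag_grid(),
                            valid = NULL) {
  stopifnot(inherits(features, "feature_tensor"))
  fm <- feature_matrix(features)
  if (n <= 0) stop("n must be positive")
  if (n > ncol(fm$X)) stop("n exceeds the ", ncol(fm$X), " available features")
  sel <- select_from_matrix(fm$X, fm$candidates, target, n, grid,
                            features$fs, valid)
  class(sel) <- c("selected_features", "data.frame")
  sel
}

select_from_matrix <- function(X, candidates, target, n, grid, fs,
                               valid = NULL, tab = NULL, X2 = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(target))
  shifts <- lag_samples(grid, fs)
  R <- lagged_cor_matrix(X, target, shifts, valid, tab = tab, X2 = X2)
  # per-candidate best lag; ties prefer smaller |lag|, then the earlier lag
  colorder <- order(abs(grid$lags_ms), grid$lags_ms)
  best_l <- colorder[max.col(abs(R)[, colorder, drop = FALSE],
                             ties.method = "first")]
  best_r <- R[cbind(seq_len(nrow(R)), best_l)]
  lag_ms <- grid$lags_ms[best_l]
  ord <- order(-abs(best_r), candidates$channel, candidates$type,
               abs(lag_ms), lag_ms)
  pick <- ord[seq_len(n)]
  data.frame(channel = candidates$channel_label[pick],
             channel_index = candidates$channel[pick],
             feature_type = candidates$feature_type[pick],
             column = pick,
             best_lag_ms = lag_ms[pick],
             train_r = best_r[pick],
             stringsAsFactors = FALSE)
}
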