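#' Ordinary least squares linear decoder
#'
#' Fits `y = b0 + X w + e` by ordinary least squares. The kinematic target is
#' modeled as a linear combination of the (z-scored) neural features with a
#' constant offset and Gaussian noise. A rank-deficient design falls back to
#' the minimum-norm solution with a warning.
#'
#' @param X samples x features numeric matrix.
#' @param y numeric response, `length(y) == nrow(X)`.
#' @return A `linear_decoder`: `weights`, `intercept`, `sigma2` (residual
#'   variance), `rank`, `df_residual`.
#' @export
fit_linear <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p + 1) stop("need more samples (", n, ") than features + 1 (", p + 1, ")")
  A <- cbind(`(intercept)` = 1, X)
  fit <- stats::lm.fit(A, y)
  cf <- fit$coefficients
  if (anyNA(cf)) {
    warning("rank-deficient design; using minimum-norm least squares")
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    cf <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    cf <- drop(cf)
    names(cf) <- colnames(A)
  }
  res <- y - drop(A %*% cf)
  dfres <- n - sum(!is.na(fit$coefficients))
  structure(list(weights = cf[-1], intercept = unname(cf[1]),
                 sigma2 = sum(res^2) / max(dfres, 1),
                 rank = fit$rank, df_residual = dfres),
            class = "linear_decoder")
}

#' Pearson product-moment correlation
#'
#' @param y_hat,y Equal-length numeric vectors (length >= 3, nonconstant).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(y_hat, y) {
  stopifnot(length(y_hat) == length(y), length(y) >= 3)
  if (stats::sd(y_hat) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation undefined for a constant input")
  }
  stats::cor(y_hat, y)
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r) * sqrt(n - 3)`, mapping a correlation computed from `n`
#' points to an approximately standard-normal score.
#'
#' @param r Correlation, `|r| < 1`.
#' @param n Number of points used to compute `r` (> 3).
#' @return Fisher z-score.
#' @export
fisher_z <- function(r, n) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher transform")
  if (any(n <= 3)) stop("n must exceed 3")
  atanh(r) * sqrt(n - 3)
}

# Contiguous fold boundaries: fold i tests block (bounds[i], bounds[i+1]].
fold_bounds <- function(Tn, folds) floor(seq(0, Tn, length.out = folds + 1))

# Build the lagged design matrix for the rows in `rows`, using feature columns
# `cols` of X at sample shifts `shifts`, z-scored with (mu, sdv). Rows are
# assumed pre-filtered so that all source indices are in range.
lagged_design <- function(X, rows, cols, shifts, mu, sdv) {
  D <- matrix(NA_real_, length(rows), length(cols))
  for (j in seq_along(cols)) {
    D[, j] <- (X[rows + shifts[j], cols[j]] - mu[j]) / sdv[j]
  }
  D
}

# Rows t (within `candidate`) whose every lag-source index t + s lies in the
# region marked TRUE in `member`.
rows_with_sources <- function(candidate, shifts, member) {
  Tn <- length(member)
  keep <- rep(TRUE, length(candidate))
  for (s in unique(shifts)) {
    src <- candidate + s
    keep <- keep & src >= 1L & src <= Tn & member[pmin(pmax(src, 1L), Tn)]
  }
  candidate[keep]
}

# Per-fold quantities that do not involve the neural features: masks, the
# training-fitted kinematic transforms, the target trace and the lag/mask
# tables for selection. Built once per (kin, target, folds, grid); the
# shuffle null reuses one plan for every surrogate.
build_cv_plan <- function(kin, fs, target, folds, grid) {
  Tn <- ncol(kin)
  bounds <- fold_bounds(Tn, folds)
  shifts <- lag_samples(grid, fs)
  plan_folds <- lapply(seq_len(folds), function(f) {
    test_idx <- seq.int(bounds[f] + 1L, bounds[f + 1L])
    train <- rep(TRUE, Tn); train[test_idx] <- FALSE
    norm_kin <- fit_normalizer(kin[, train, drop = FALSE])
    z_kin <- apply_normalizer(norm_kin, kin)
    pca <- fit_kin_pca(z_kin[, train, drop = FALSE])
    y <- target_trace(z_kin, pca, target)
    list(test_idx = test_idx, train = train, normalizer = norm_kin,
         pca = pca, y = y,
         tab = lag_tables(y, shifts, train))
  })
  list(bounds = bounds, folds = plan_folds, shifts = shifts, target = target,
       n_folds = folds)
}

# Core cross-validation engine shared by reach_decoder(), shuffle_null() and
# the saturation analysis. X is the flattened feature matrix; `n_inputs` may
# be a vector, in which case nested models are fitted from one ranking.
cv_decode <- function(X, candidates, kin, fs, target, n_inputs, folds, grid,
                      keep_predictions = FALSE, plan = NULL) {
  Tn <- nrow(X)
  stopifnot(ncol(kin) == Tn)
  n_max <- max(n_inputs)
  if (n_max > ncol(X)) {
    stop("n_inputs (", n_max, ") exceeds the ", ncol(X), " available features")
  }
  if (is.null(plan)) plan <- build_cv_plan(kin, fs, target, folds, grid)
  bounds <- plan$bounds
  X2 <- X * X
  out <- vector("list", folds)
  for (f in seq_len(folds)) {
    pf <- plan$folds[[f]]
    test_idx <- pf$test_idx
    train <- pf$train
    norm_kin <- pf$normalizer
    pca <- pf$pca
    y <- pf$y
    sel <- select_from_matrix(X, candidates, y, n_max, grid, fs,
                              valid = train, tab = pf$tab, X2 = X2)
    shifts_all <- as.integer(round(sel$best_lag_ms / 1000 * fs))
    per_n <- lapply(n_inputs, function(nn) {
      cols <- sel$column[seq_len(nn)]
      shifts <- shifts_all[seq_len(nn)]
      tr_rows <- rows_with_sources(which(train), shifts, train)
      mu <- vapply(seq_len(nn), function(j) mean(X[tr_rows + shifts[j], cols[j]]),
                   numeric(1))
      sdv <- vapply(seq_len(nn), function(j) stats::sd(X[tr_rows + shifts[j], cols[j]]),
                    numeric(1))
      sdv[sdv == 0] <- 1
      D_tr <- lagged_design(X, tr_rows, cols, shifts, mu, sdv)
      dec <- fit_linear(D_tr, y[tr_rows])
      te_member <- !train
      te_rows <- rows_with_sources(test_idx, shifts, te_member)
      D_te <- lagged_design(X, te_rows, cols, shifts, mu, sdv)
      pred <- dec$intercept + drop(D_te %*% dec$weights)
      r <- pearson_r(pred, y[te_rows])
      list(r = r, z = fisher_z(r, length(te_rows)), n_test = length(te_rows),
           decoder = dec,
           predictions = if (keep_predictions) {
             data.frame(index = te_rows, observed = y[te_rows], predicted = pred)
           })
    })
    out[[f]] <- list(test_range = range(test_idx), normalizer = norm_kin,
                     pca = pca, selection = sel, models = per_n)
  }
  r_mat <- sapply(out, function(f) vapply(f$models, `[[`, numeric(1), "r"))
  r_mat <- matrix(r_mat, nrow = length(n_inputs))
  z_mat <- sapply(out, function(f) vapply(f$models, `[[`, numeric(1), "z"))
  z_mat <- matrix(z_mat, nrow = length(n_inputs))
  list(folds = out, n_inputs = n_inputs, bounds = bounds,
       r = r_mat, z = z_mat,
       median_r = apply(r_mat, 1, stats::median),
       median_z = apply(z_mat, 1, stats::median))
}

# Target trace from normalized kinematics under a fitted PCA.
target_trace <- function(z_kin, pca, target) {
  dims <- c(height = 1L, depth = 2L, lateral = 3L)
  if (target %in% c("pc1", "pc2", "pc3")) {
    drop(project_kin_pca(pca, z_kin)[as.integer(substring(target, 3)), ])
  } else if (target %in% names(dims)) {
    z_kin[dims[[target]], ]
  } else {
    stop("unknown target: ", target)
  }
}

#' Cross-validated accuracy as a function of model size
#'
#' Fits nested decoders with increasing numbers of inputs from a single
#' per-fold feature ranking and returns the held-out accuracy of every
#' (model size, fold) pair — the raw material for saturation analysis
#' ([saturation_point()]) and factorial comparisons
#' ([anova_inputs_by_featuretype()]).
#'
#' @inheritParams reach_decoder
#' @param n_inputs Integer vector of model sizes (e.g. `1:10`).
#' @return data.frame with `n_inputs`, `fold`, `r`, `z`.
#' @export
input_count_sweep <- function(features, n_inputs = 1:10, target = "pc1",
                              folds = 5, grid = lag_grid()) {
  stopifnot(inherits(features, "feature_tensor"))
  fm <- feature_matrix(features)
  cv <- cv_decode(fm$X, fm$candidates, features$kinematics, features$fs,
                  target, n_inputs, folds, grid)
  data.frame(n_inputs = rep(n_inputs, times = folds),
             fold = rep(seq_len(folds), each = length(n_inputs)),
             r = as.numeric(cv$r), z = as.numeric(cv$z))
}

#' Fit a cross-validated linear reach decoder
#'
#' The package's central model. Given extracted neural features and the
#' aligned kinematics, evaluates a linear decoder of the chosen kinematic
#' target under fivefold cross-validation with contiguous test blocks: within
#' each fold the kinematic normalizer, the kinematic PCA, the
#' lagged-correlation feature selection and the OLS weights are all fitted on
#' the training block only, and Pearson's r between predicted and observed
#' target is computed on the held-out block. A deployable full-data model is
#' fitted alongside for `predict()`, `coef()` and `plot()`.
#'
#' Contiguous (rather than random-sample) folds are used because the 1-2 s
#' feature smoothing induces strong autocorrelation that random-sample
#' cross-validation would leak across the train/test boundary.
#'
#' @param features A `feature_tensor` from [extract_features()] (carries the
#'   trimmed, aligned kinematics).
#' @param target One of `"pc1"`, `"pc2"`, `"pc3"`, `"height"`, `"depth"`,
#'   `"lateral"`.
#' @param n_inputs Number of neural features in the model (default 9).
#' @param folds Number of cross-validation folds (default 5).
#' @param grid A [lag_grid()].
#' @return A `reach_decoder` object; see [summary.reach_decoder()].
#' @export
#' @examples
#' \donttest{
#' sess <- generate_session(synth_config(n_channels = 4, n_reaches = 8,
#'                                       seed = 7))
#' feats <- extract_features(sess)
#' fit <- reach_decoder(feats, target = "pc1", n_inputs = 3)
#' fit
#' }
reach_decoder <- function(features, target = "pc1", n_inputs = 9, folds = 5,
                          grid = lag_grid()) {
  stopifnot(inherits(features, "feature_tensor"))
  fm <- feature_matrix(features)
  kin <- features$kinematics
  cv <- cv_decode(fm$X, fm$candidates, kin, features$fs, target, n_inputs,
                  folds, grid, keep_predictions = TRUE)
  # full-data model for deployment
  norm_kin <- fit_normalizer(kin)
  z_kin <- apply_normalizer(norm_kin, kin)
  pca <- fit_kin_pca(z_kin)
  y <- target_trace(z_kin, pca, target)
  sel <- select_from_matrix(fm$X, fm$candidates, y, n_inputs, grid,
                            features$fs)
  shifts <- as.integer(round(sel$best_lag_ms / 1000 * features$fs))
  all_rows <- seq_len(nrow(fm$X))
  rows <- rows_with_sources(all_rows, shifts, rep(TRUE, nrow(fm$X)))
  mu <- vapply(seq_len(n_inputs), function(j) mean(fm$X[rows + shifts[j], sel$column[j]]),
               numeric(1))
  sdv <- vapply(seq_len(n_inputs), function(j) stats::sd(fm$X[rows + shifts[j], sel$column[j]]),
                numeric(1))
  sdv[sdv == 0] <- 1
  D <- lagged_design(fm$X, rows, sel$column, shifts, mu, sdv)
  dec <- fit_linear(D, y[rows])
  fit_vals <- dec$intercept + drop(D %*% dec$weights)
  structure(list(
    call = match.call(), target = target, n_inputs = n_inputs, folds = folds,
    grid = grid, fs = features$fs,
    cv = list(r = drop(cv$r), z = drop(cv$z),
              median_r = cv$median_r, median_z = cv$median_z,
              n_test = vapply(cv$folds, function(f) f$models[[1]]$n_test,
                              numeric(1)),
              bounds = cv$bounds,
              selections = lapply(cv$folds, `[[`, "selection"),
              fold_weights = lapply(cv$folds,
                                    function(f) f$models[[1]]$decoder$weights),
              fold_normalizers = lapply(cv$folds, `[[`, "normalizer"),
              fold_pcas = lapply(cv$folds, `[[`, "pca"),
              predictions = lapply(cv$folds,
                                   function(f) f$models[[1]]$predictions)),
    selection = sel, decoder = dec,
    feature_norm = list(mu = mu, sd = sdv), shifts = shifts,
    kin_normalizer = norm_kin, pca = pca,
    rows = rows, y = y, fitted = fit_vals, residuals = y[rows] - fit_vals
  ), class = "reach_decoder")
}

#' @export
print.reach_decoder <- function(x, ...) {
  cat("Cross-validated linear reach decoder\n")
  cat("  target: ", x$target, "   inputs: ", x$n_inputs,
      "   folds: ", x$folds, "\n", sep = "")
  cat("  per-fold test r:", paste(sprintf("%.3f", x$cv$r), collapse = " "), "\n")
  cat("  median r = ", sprintf("%.3f", x$cv$median_r),
      "  median Fisher z = ", sprintf("%.1f", x$cv$median_z), "\n", sep = "")
  invisible(x)
}

#' Summarize a fitted reach decoder
#'
#' @param object A [reach_decoder()] fit.
#' @param ... Unused.
#' @return The object, invisibly; prints per-fold accuracies and the
#'   full-data feature selection table.
#' @export
summary.reach_decoder <- function(object, ...) {
  print(object)
  cat("\nPer-fold accuracy:\n")
  print(data.frame(fold = seq_len(object$folds), r = round(object$cv$r, 4),
                   fisher_z = round(object$cv$z, 2),
                   n_test = object$cv$n_test), row.names = FALSE)
  cat("\nSelected features (full data), decreasing |train r|:\n")
  sel <- object$selection
  print(data.frame(channel = sel$channel, feature = sel$feature_type,
                   lag_ms = sel$best_lag_ms, r = round(sel$train_r, 3),
                   weight = round(object$decoder$weights, 3)),
        row.names = FALSE)
  invisible(object)
}

#' @export
coef.reach_decoder <- function(object, ...) {
  w <- object$decoder$weights
  names(w) <- paste(object$selection$channel, object$selection$feature_type,
                    object$selection$best_lag_ms, sep = ".")
  c(`(intercept)` = object$decoder$intercept, w)
}

#' Predict the kinematic target from new features
#'
#' Applies the stored full-data decoder (selected channels/bands at their
#' training lags, training feature normalization, training weights) to a new
#' feature tensor. Samples whose lagged sources fall outside the record are
#' returned as `NA`.
#'
#' @param object A [reach_decoder()] fit.
#' @param newdata A `feature_tensor` with the same channels and feature types.
#' @param ... Unused.
#' @return Numeric vector of predicted (normalized) target values, one per
#'   feature sample; `NA` at unresolvable edges.
#' @export
predict.reach_decoder <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    out <- rep(NA_real_, length(object$y))
    out[object$rows] <- object$fitted
    return(out)
  }
  stopifnot(inherits(newdata, "feature_tensor"))
  fm <- feature_matrix(newdata)
  key_new <- paste(fm$candidates$channel_label, fm$candidates$feature_type)
  key_sel <- paste(object$selection$channel, object$selection$feature_type)
  cols <- match(key_sel, key_new)
  if (anyNA(cols)) stop("newdata lacks selected feature(s): ",
                        paste(key_sel[is.na(cols)], collapse = ", "))
  Tn <- nrow(fm$X)
  rows <- rows_with_sources(seq_len(Tn), object$shifts, rep(TRUE, Tn))
  D <- lagged_design(fm$X, rows, cols, object$shifts,
                     object$feature_norm$mu, object$feature_norm$sd)
  out <- rep(NA_real_, Tn)
  out[rows] <- object$decoder$intercept + drop(D %*% object$decoder$weights)
  out
}

#' @export
fitted.reach_decoder <- function(object, ...) predict(object)

#' @export
residuals.reach_decoder <- function(object, ...) {
  out <- rep(NA_real_, length(object$y))
  out[object$rows] <- object$residuals
  out
}

#' Simulate target traces from the fitted decoder
#'
#' Draws `nsim` traces `fitted + N(0, sigma2)` from the Gaussian linear model,
#' mirroring `simulate.lm`.
#'
#' @param object A [reach_decoder()] fit.
#' @param nsim Number of simulated traces.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return data.frame with `nsim` columns, one row per modeled sample.
#' @export
simulate.reach_decoder <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(n, 0, sqrt(object$decoder$sigma2)),
                                 simplify = FALSE))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot observed and decoded kinematic target
#'
#' Overlays the observed (normalized) target with the cross-validated
#' held-out predictions of each fold.
#'
#' @param x A [reach_decoder()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.reach_decoder <- function(x, ...) {
  tt <- (seq_along(x$y) - 1) / x$fs
  graphics::plot(tt, x$y, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = paste("target:", x$target),
                 main = sprintf("held-out predictions (median r = %.2f)",
                                x$cv$median_r), ...)
  for (p in x$cv$predictions) {
    graphics::lines((p$index - 1) / x$fs, p$predicted, col = "firebrick")
  }
  graphics::abline(v = x$cv$bounds[-c(1, length(x$cv$bounds))] / x$fs,
                   lty = 3, col = "grey70")
  invisible(x)
}
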