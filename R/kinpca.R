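#' Fit a per-dimension z-score normalizer on training data
#'
#' Records the per-dimension mean and sample standard deviation of the
#' training block only; test data are always transformed with training
#' statistics, so the transform leaks nothing from held-out samples.
#'
#' @param train_kin dims x samples numeric matrix (rows = dimensions).
#' @return A `kin_normalizer` with `means` and `sds`.
#' @export
fit_normalizer <- function(train_kin) {
  if (is.vector(train_kin)) train_kin <- matrix(train_kin, nrow = 1)
  if (ncol(train_kin) < 2) stop("need at least 2 samples to fit a normalizer")
  means <- rowMeans(train_kin)
  sds <- apply(train_kin, 1, stats::sd)
  bad <- which(sds == 0)
  if (length(bad)) {
    stop("zero-variance dimension(s): ",
         paste(rownames(train_kin)[bad] %||% bad, collapse = ", "))
  }
  structure(list(means = means, sds = sds), class = "kin_normalizer")
}

#' Apply (or invert) a fitted normalizer
#' @param norm A [fit_normalizer()] result.
#' @param kin dims x samples matrix (or vector for 1-D).
#' @return Transformed matrix of the same shape.
#' @export
apply_normalizer <- function(norm, kin) {
  stopifnot(inherits(norm, "kin_normalizer"))
  if (is.vector(kin)) kin <- matrix(kin, nrow = 1)
  (kin - norm$means) / norm$sds
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(norm, kin) {
  stopifnot(inherits(norm, "kin_normalizer"))
  if (is.vector(kin)) kin <- matrix(kin, nrow = 1)
  kin * norm$sds + norm$means
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal component analysis of normalized 3-D kinematics
#'
#' Eigendecomposition of the sample (n-1) covariance of the normalized
#' training kinematics. PC1 is the direction of maximal variance — for
#' reaching data, the dominant movement axis. Because the sign of an
#' eigenvector is arbitrary, each component is flipped so its
#' largest-magnitude loading is positive, keeping loadings comparable across
#' cross-validation folds.
#'
#' @param train_kin_z dims x samples normalized matrix.
#' @return A `kin_pca`: `loadings` (rows = PCs, orthonormal),
#'   `explained_variance` (descending).
#' @export
fit_kin_pca <- function(train_kin_z) {
  stopifnot(is.matrix(train_kin_z), ncol(train_kin_z) > nrow(train_kin_z))
  cv <- stats::cov(t(train_kin_z))
  e <- eigen(cv, symmetric = TRUE)
  if (any(e$values < -1e-8)) stop("covariance not positive semidefinite")
  if (any(abs(e$values) < 1e-12)) {
    warning("rank-deficient kinematic covariance; zero-variance component(s)")
  }
  L <- t(e$vectors)  # rows = PCs
  for (i in seq_len(nrow(L))) {
    j <- which.max(abs(L[i, ]))
    if (L[i, j] < 0) L[i, ] <- -L[i, ]
  }
  rownames(L) <- paste0("pc", seq_len(nrow(L)))
  colnames(L) <- rownames(train_kin_z)
  structure(list(loadings = L, explained_variance = pmax(e$values, 0)),
            class = "kin_pca")
}

#' Project kinematics onto fitted principal components
#' @param pca A [fit_kin_pca()] result.
#' @param kin_z dims x samples normalized matrix.
#' @return PCs x samples score matrix.
#' @export
project_kin_pca <- function(pca, kin_z) {
  stopifnot(inherits(pca, "kin_pca"))
  pca$loadings %*% kin_z
}

#' @export
print.kin_pca <- function(x, ...) {
  cat("<kin_pca> explained variance:",
      paste(signif(x$explained_variance, 4), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}
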