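#' Chance decoding distribution by feature shuffling
#'
#' Decouples the neural features from the kinematics `n_shuffles` times and
#' reruns the *full* cross-validated decoding procedure — including feature
#' selection — on each surrogate, returning the distribution of median
#' held-out r. Two decoupling modes are provided: `"circular_shift"` (the
#' default) rotates each feature's time axis by an independent uniform shift
#' in `[5 s, T - 5 s]`, preserving the autocorrelation that the smoothing
#' windows impose; `"permute"` draws an independent random permutation of the
#' time axis per feature, which destroys autocorrelation and yields a more
#' permissive null.
#'
#' @param features A `feature_tensor` (see [extract_features()]).
#' @param n_inputs Number of model inputs per decoder.
#' @param n_shuffles Number of surrogates (default 1024).
#' @param mode `"circular_shift"` or `"permute"`.
#' @param target Kinematic target (as in [reach_decoder()]).
#' @param folds Cross-validation folds.
#' @param grid A [lag_grid()].
#' @param seed Optional RNG seed for reproducibility.
#' @return A `null_distribution`: `r` (n_shuffles median accuracies), `mode`,
#'   `seed`.
#' @export
shuffle_null <- function(features, n_inputs = 9, n_shuffles = 1024,
                         mode = c("circular_shift", "permute"),
                         target = "pc1", folds = 5, grid = lag_grid(),
                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(features, "feature_tensor"))
  if (n_shuffles < 100) warning("fewer than 100 shuffles: null tail is unstable")
  if (!is.null(seed)) set.seed(seed)
  fm <- feature_matrix(features)
  kin <- features$kinematics
  Tn <- nrow(fm$X)
  fs <- features$fs
  lo <- as.integer(5 * fs); hi <- Tn - as.integer(5 * fs)
  if (hi <= lo) stop("record too short for circular shifts (need > 10 s)")
  plan <- build_cv_plan(kin, fs, target, folds, grid)
  r <- numeric(n_shuffles)
  fold_r <- matrix(NA_real_, n_shuffles, folds)
  for (s in seq_len(n_shuffles)) {
    Xs <- fm$X
    for (j in seq_len(ncol(Xs))) {
      if (mode == "circular_shift") {
        k <- sample.int(hi - lo, 1L) + lo   # in (lo, hi], never 0
        Xs[, j] <- Xs[c((k + 1L):Tn, 1L:k), j]
      } else {
        Xs[, j] <- Xs[sample.int(Tn), j]
      }
    }
    cv <- cv_decode(Xs, fm$candidates, kin, fs, target, n_inputs, folds, grid,
                    plan = plan)
    r[s] <- cv$median_r
    fold_r[s, ] <- drop(cv$r)
  }
  structure(list(r = r, fold_r = fold_r, mode = mode, seed = seed,
                 n_inputs = n_inputs, target = target),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  q <- stats::quantile(x$r, c(0.025, 0.5, 0.975))
  cat("<null_distribution> ", length(x$r), " ", x$mode, " shuffles (",
      x$target, ", ", x$n_inputs, " inputs)\n", sep = "")
  cat(sprintf("  median r: %.3f   central 95%%: [%.3f, %.3f]   max: %.3f\n",
              q[2], q[1], q[3], max(x$r)))
  invisible(x)
}

#' Wilcoxon rank-sum test of decoding accuracy against chance
#'
#' Compares the per-fold accuracies with the shuffle-null accuracies by a
#' one-sided two-sample Wilcoxon rank-sum test and applies a Bonferroni
#' correction for `n_comparisons` simultaneous tests. When the null carries
#' per-fold surrogate accuracies these are used as the reference sample, so
#' that fold-level statistics are compared with fold-level statistics (the
#' test keeps its nominal size; comparing folds against medians-of-folds
#' would not).
#'
#' @param actual_r Per-fold accuracies (>= 3 values).
#' @param null A [shuffle_null()] result (or numeric vector of null r).
#' @param n_comparisons Bonferroni multiplier (default 1).
#' @param alpha Significance level after correction (default 0.05).
#' @return List with `p` (corrected, capped at 1), `p_uncorrected`,
#'   `significant`.
#' @export
wilcoxon_vs_chance <- function(actual_r, null, n_comparisons = 1,
                               alpha = 0.05) {
  null_r <- if (inherits(null, "null_distribution")) {
    if (!is.null(null$fold_r)) as.numeric(null$fold_r) else null$r
  } else {
    null
  }
  if (length(null_r) == 0) stop("empty null distribution")
  if (length(actual_r) < 3) stop("need at least 3 actual accuracies")
  p0 <- suppressWarnings(
    stats::wilcox.test(actual_r, null_r, alternative = "greater")$p.value)
  p <- min(1, p0 * n_comparisons)
  list(p = p, p_uncorrected = p0, significant = p < alpha)
}

#' Dunn-Sidak corrected per-test significance level
#'
#' `1 - (1 - alpha)^(1/m)`: the per-comparison level that keeps the
#' family-wise error at `alpha` over `m` independent comparisons. Always at
#' least as large as the Bonferroni level `alpha/m`.
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return Corrected per-test alpha.
#' @export
dunn_sidak_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("m must be >= 1")
  1 - (1 - alpha)^(1 / m)
}

#' Two-way ANOVA of Fisher-z accuracies by input count and feature type
#'
#' Fixed-effects two-way ANOVA of Fisher-transformed decoding accuracies with
#' the number of model inputs and the feature type as factors, followed by
#' Dunn-Sidak-corrected pairwise post-hoc t comparisons within each factor.
#'
#' @param z Numeric Fisher-z accuracies.
#' @param n_inputs Factor/vector: input-count level per value.
#' @param feature_type Factor/vector: feature-type level per value.
#' @param alpha Family-wise level for the post-hoc tests (default 0.05).
#' @return List with `anova` (the summary table), `p_n_inputs`,
#'   `p_feature_type` (main-effect p-values) and `posthoc` (pairwise table
#'   with `significant` flags at the Dunn-Sidak level).
#' @export
anova_inputs_by_featuretype <- function(z, n_inputs, feature_type,
                                        alpha = 0.05) {
  d <- data.frame(z = z, a = factor(n_inputs), b = factor(feature_type))
  if (nlevels(d$a) < 2 || nlevels(d$b) < 2) stop("need >= 2 levels per factor")
  cells <- table(d$a, d$b)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("empty cell(s): ", paste(rownames(cells)[bad[, 1]],
                                  colnames(cells)[bad[, 2]],
                                  sep = ":", collapse = ", "))
  }
  if (any(cells < 2)) stop("need >= 2 replicates per cell")
  fit <- stats::aov(z ~ a + b, data = d)
  tab <- summary(fit)[[1]]
  posthoc <- rbind(pairwise_t(d$z, d$a, "n_inputs"),
                   pairwise_t(d$z, d$b, "feature_type"))
  m <- nrow(posthoc)
  posthoc$alpha_corrected <- dunn_sidak_alpha(alpha, m)
  posthoc$significant <- posthoc$p < posthoc$alpha_corrected
  list(anova = tab,
       p_n_inputs = tab["a", "Pr(>F)"],
       p_feature_type = tab["b", "Pr(>F)"],
       posthoc = posthoc)
}

pairwise_t <- function(z, g, factor_name) {
  lev <- levels(g)
  cmb <- utils::combn(lev, 2)
  p <- apply(cmb, 2, function(pr) {
    stats::t.test(z[g == pr[1]], z[g == pr[2]])$p.value
  })
  data.frame(factor = factor_name, level_1 = cmb[1, ], level_2 = cmb[2, ],
             p = p, stringsAsFactors = FALSE)
}

#' Saturation point of decoding performance over model size
#'
#' Given accuracies grouped by number of model inputs, runs a Kruskal-Wallis
#' one-way analysis of variance across the groups; if it is significant, an
#' LSD-style (Conover) pairwise post-hoc on rank means determines the
#' smallest input count `n` such that no larger count performs significantly
#' better. If the groups are indistinguishable the smallest count is
#' returned.
#'
#' @param accuracy Numeric accuracies (r or Fisher z).
#' @param n_inputs Number of inputs associated with each accuracy.
#' @param alpha Significance level (default 0.05).
#' @return The saturating number of inputs (smallest group label if no group
#'   differences exist).
#' @export
saturation_point <- function(accuracy, n_inputs, alpha = 0.05) {
  g <- sort(unique(n_inputs))
  if (length(g) < 2) stop("need at least 2 input-count groups")
  sizes <- table(n_inputs)
  if (any(sizes < 3)) stop("need >= 3 accuracies per group")
  if (stats::var(accuracy) == 0) return(g[1])
  kw <- stats::kruskal.test(accuracy, factor(n_inputs))
  if (!is.finite(kw$p.value) || kw$p.value >= alpha) return(g[1])
  # Conover-Iman pairwise comparisons on rank means
  N <- length(accuracy)
  k <- length(g)
  rk <- rank(accuracy)
  mean_rk <- tapply(rk, factor(n_inputs), mean)
  n_g <- as.numeric(table(factor(n_inputs)))
  S2 <- (sum(rk^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- unname(kw$statistic)
  denom_scale <- S2 * (N - 1 - H) / (N - k)
  better_than <- function(i, j) {  # group j significantly better than i?
    se <- sqrt(denom_scale * (1 / n_g[i] + 1 / n_g[j]))
    tstat <- (mean_rk[j] - mean_rk[i]) / se
    pval <- stats::pt(tstat, df = N - k, lower.tail = FALSE)
    is.finite(pval) && pval < alpha / 2
  }
  for (i in seq_len(k)) {
    if (!any(vapply((i + 1):k, function(j) j <= k && better_than(i, j),
                    logical(1)))) {
      return(g[i])
    }
  }
  g[k]
}
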