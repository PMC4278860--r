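test_that("OLS recovers exact linear relations and rejects tiny designs", {
  x <- matrix(seq_len(20), ncol = 1)
  fit <- fit_linear(x, 2 * x[, 1] + 1)
  expect_equal(unname(fit$weights), 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_lt(fit$sigma2, 1e-10)
  expect_error(fit_linear(matrix(1:4, 2), c(1, 2)), "samples")
})

test_that("independent response yields near-zero weights", {
  set.seed(20)
  X <- matrix(rnorm(5e4), 1e4, 5)
  y <- rnorm(1e4)
  fit <- fit_linear(X, y)
  expect_true(all(abs(fit$weights) < 0.05))
  pred <- fit$intercept + drop(X %*% fit$weights)
  expect_lt(1 - fit$sigma2 / var(y), 0.01)      # train R^2 below 1%
})

test_that("OLS matches the normal-equations oracle; residuals are orthogonal", {
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  fit <- fit_linear(X, y)
  A <- cbind(1, X)
  beta <- solve(t(A) %*% A, t(A) %*% y)      # independent oracle
  expect_equal(unname(c(fit$intercept, fit$weights)), drop(beta),
               tolerance = 1e-10)
  e <- y - drop(A %*% beta)
  expect_lt(max(abs(t(A) %*% e)), 1e-8 * sqrt(sum(y^2)))
})

test_that("rank deficiency falls back to minimum-norm with a warning", {
  set.seed(22)
  X <- matrix(rnorm(40), 20, 2)
  X <- cbind(X, X[, 1] + X[, 2])
  expect_warning(fit <- fit_linear(X, rnorm(20)), "minimum-norm")
  expect_true(all(is.finite(fit$weights)))
})

test_that("pearson_r matches hand-computed values and rejects constants", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("fisher_z follows the closed form and is antisymmetric", {
  expect_equal(fisher_z(0, 50), 0)
  expect_equal(fisher_z(0.5, 103), 0.5 * log(3) * 10, tolerance = 1e-12)
  expect_equal(fisher_z(-0.3, 40), -fisher_z(0.3, 40))
  expect_error(fisher_z(1, 10), "< 1")
  expect_error(fisher_z(0.5, 3), "exceed 3")
})

test_that("contiguous folds partition the session", {
  b <- ecogreach:::fold_bounds(1234, 5)
  blocks <- lapply(1:5, function(f) seq.int(b[f] + 1L, b[f + 1L]))
  expect_equal(sort(unlist(blocks)), 1:1234)
  expect_equal(sum(lengths(blocks)), 1234)
  expect_true(all(abs(lengths(blocks) - 1234 / 5) < 1))
})

test_that("the cross-validated decoder recovers a synthetic encoding", {
  fit <- cached("small_fit", reach_decoder(small_features(), n_inputs = 2))
  expect_length(fit$cv$r, 5)
  expect_gt(fit$cv$median_r, 0.5)
  expect_equal(fit$selection$channel[1], "ch02")
  expect_equal(fit$selection$feature_type[1], "high_gamma_1")
  # print/summary/coef/predict methods behave
  expect_output(print(fit), "median r")
  expect_output(summary(fit), "Selected features")
  expect_length(coef(fit), 3)
  p <- predict(fit)
  expect_length(p, dim(small_features()$values)[3])
  expect_gt(cor(p[fit$rows], fit$y[fit$rows]), 0.5)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(length(fit$fitted), 2))
  r <- residuals(fit)
  expect_equal(p[fit$rows] + r[fit$rows], fit$y[fit$rows], tolerance = 1e-10)
})

test_that("fold models are functions of training data only", {
  feats <- small_features()
  fit <- cached("small_fit", reach_decoder(feats, n_inputs = 2))
  # corrupt the fold-1 test block (plus the lag reach on either side is NOT
  # needed: sources outside the block are excluded by construction)
  b <- fit$cv$bounds
  test1 <- seq.int(b[1] + 1L, b[2])
  feats2 <- feats
  set.seed(99)
  feats2$values[, , test1] <- rnorm(length(feats2$values[, , test1]))
  fit2 <- reach_decoder(feats2, n_inputs = 2)
  expect_equal(fit2$cv$selections[[1]], fit$cv$selections[[1]])
  expect_equal(fit2$cv$fold_weights[[1]], fit$cv$fold_weights[[1]])
  expect_equal(fit2$cv$fold_normalizers[[1]], fit$cv$fold_normalizers[[1]])
  expect_equal(fit2$cv$fold_pcas[[1]], fit$cv$fold_pcas[[1]])
  # but its held-out accuracy changes
  expect_false(isTRUE(all.equal(fit2$cv$r[1], fit$cv$r[1])))
})

test_that("near-noiseless strong encoding decodes almost perfectly", {
  cfg <- small_cfg(seed = 17, n_channels = 4, n_reaches = 12,
                   noise_pink_rms = 0.02, carrier_rms = 10,
                   reach_duration_s = c(3.5, 5.0),
                   informative = data.frame(
                     channel = c(2L, 3L),
                     feature_type = c("high_gamma_1", "high_gamma_2"),
                     gain = c(3, 2.5), lag_ms = c(0, 0),
                     stringsAsFactors = FALSE))
  feats <- extract_features(generate_session(cfg))
  fit <- reach_decoder(feats, n_inputs = 2)
  expect_true(all(fit$cv$r >= 0.85))
  expect_gt(fit$cv$median_r, 0.9)
})

test_that("input-count sweep returns one accuracy per fold and model size", {
  sw <- input_count_sweep(small_features(), n_inputs = 1:3, folds = 5)
  expect_equal(nrow(sw), 15)
  expect_equal(sort(unique(sw$n_inputs)), 1:3)
  expect_true(all(abs(sw$r) <= 1))
  # more informative inputs never catastrophically hurt the small session
  med <- tapply(sw$r, sw$n_inputs, median)
  expect_gt(max(med), 0.5)
})
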