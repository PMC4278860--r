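test_that("minimum-jerk profile satisfies its boundary conditions", {
  p <- min_jerk_profile(c(0, 1))
  expect_equal(p$s, c(0, 1))
  expect_equal(p$ds, c(0, 0))
  # monotone position, peak speed at midpoint
  tau <- seq(0, 1, by = 0.01)
  pr <- min_jerk_profile(tau)
  expect_true(all(diff(pr$s) >= 0))
  expect_equal(tau[which.max(pr$ds)], 0.5)
  expect_equal(max(pr$ds), 1.875, tolerance = 1e-12)
})

test_that("reach kinematics stay in the workspace with configured durations", {
  cfg <- small_cfg(seed = 3, n_reaches = 50, reach_duration_s = c(2.0, 5.0))
  set.seed(cfg$seed)
  k <- generate_reach_kinematics(cfg)
  ws <- cfg$workspace
  for (ax in 1:3) {
    expect_true(all(k$kin[ax, ] >= ws[ax, 1] - 1e-9))
    expect_true(all(k$kin[ax, ] <= ws[ax, 2] + 1e-9))
  }
  expect_equal(nrow(k$reaches), 50)
  expect_true(all(k$reaches$duration_s >= 2.0 & k$reaches$duration_s <= 5.0))
  # continuity: no jump exceeds the peak minimum-jerk speed over one sample
  max_dist <- sqrt(sum((ws[, 2] - ws[, 1])^2))
  vmax <- 1.875 * max_dist / min(cfg$reach_duration_s) * 2  # per leg
  expect_true(max(sqrt(rowSums(diff(t(k$kin))^2))) <= vmax / cfg$fs_kin)
  # hand is at rest (home) at every reach onset and back at its offset
  fs <- cfg$fs_kin
  home <- k$kin[, 1]
  for (i in seq_len(nrow(k$reaches))) {
    expect_equal(k$kin[, round(k$reaches$onset_s[i] * fs)], home)
    expect_equal(k$kin[, round(k$reaches$offset_s[i] * fs) + 1L], home)
  }
})

test_that("zero reaches give a constant trace and an empty reach table", {
  cfg <- small_cfg(seed = 1, n_reaches = 0, informative = no_encoding())
  set.seed(cfg$seed)
  k <- generate_reach_kinematics(cfg)
  expect_equal(nrow(k$reaches), 0)
  expect_true(all(k$kin == k$kin[, 1]))
})

test_that("degenerate configurations are rejected", {
  expect_error(small_cfg(workspace = rbind(c(0, 0), c(0, 1), c(0, 1))),
               "degenerate workspace")
  expect_error(small_cfg(reach_duration_s = c(0.5, 3)), "within")
  expect_error(small_cfg(rest_duration_s = c(0, 30)), "within")
  expect_error(small_cfg(informative = data.frame(
    channel = 99L, feature_type = "mu", gain = 1, lag_ms = 0)),
    "out of range")
  expect_error(small_cfg(informative = data.frame(
    channel = 2L, feature_type = "mu", gain = 1, lag_ms = 2000)),
    "lag_ms")
  expect_error(small_cfg(informative = data.frame(
    channel = 2L, feature_type = "mu", gain = Inf, lag_ms = 0)),
    "finite")
})

test_that("session generation is bit-identical under a fixed seed", {
  cfg <- small_cfg(seed = 42, n_reaches = 3)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$neural, s2$neural)
  expect_identical(s1$kinematics, s2$kinematics)
  s3 <- generate_session(small_cfg(seed = 43, n_reaches = 3))
  expect_false(isTRUE(all.equal(s1$neural, s3$neural)))
})

test_that("session duration equals the sum of rests and reaches", {
  sess <- small_session()
  cfg <- sess$ground_truth$config
  expect_equal(ncol(sess$neural) / sess$fs_neural,
               ncol(sess$kinematics) / sess$fs_kin)
  # reach offsets + following rests tile the record exactly: final sample count
  # is a whole multiple of the kinematic step past the last offset
  expect_true(ncol(sess$kinematics) >
                max(sess$ground_truth$reaches$offset_s) * sess$fs_kin)
})

test_that("without encoding, band power is exchangeable across channels", {
  # KS tests on decorrelated (subsampled) smoothed band powers should not
  # distinguish channels when no channel is informative
  rejections <- 0L; total <- 0L
  for (seed in 1:4) {
    cfg <- small_cfg(seed = seed, informative = no_encoding(), n_reaches = 6)
    feats <- extract_features(generate_session(cfg))
    idx <- seq(1, dim(feats$values)[3], by = 200)  # every 2 s
    for (band in c("mu", "high_gamma_1")) {
      b <- match(band, feats$feature_types)
      p <- suppressWarnings(
        stats::ks.test(feats$values[1, b, idx], feats$values[2, b, idx]))$p.value
      total <- total + 1L
      if (p < 0.01) rejections <- rejections + 1L
    }
  }
  expect_lte(rejections, 1L)
})

test_that("positive high-gamma encoding is recovered with r > 0.7", {
  cfg <- small_cfg(seed = 5, informative = data.frame(
    channel = 2L, feature_type = "high_gamma_1", gain = 2, lag_ms = 0,
    stringsAsFactors = FALSE), n_reaches = 10)
  sess <- generate_session(cfg)
  feats <- extract_features(sess)
  norm <- fit_normalizer(feats$kinematics)
  pc1 <- drop(project_kin_pca(fit_kin_pca(apply_normalizer(norm, feats$kinematics)),
                              apply_normalizer(norm, feats$kinematics))[1, ])
  b <- match("high_gamma_1", feats$feature_types)
  lc <- lagged_correlation(feats$values[2, b, ], pc1)
  expect_gt(max(lc$r), 0.7)
  expect_lte(abs(lc$lag_ms[which.max(abs(lc$r))]), 150)
})

test_that("negative mu encoding yields a negative best-lag correlation", {
  cfg <- small_cfg(seed = 6, n_channels = 4, informative = data.frame(
    channel = 3L, feature_type = "mu", gain = -0.9, lag_ms = 0,
    stringsAsFactors = FALSE), n_reaches = 10)
  feats <- extract_features(generate_session(cfg))
  norm <- fit_normalizer(feats$kinematics)
  z <- apply_normalizer(norm, feats$kinematics)
  pc1 <- drop(project_kin_pca(fit_kin_pca(z), z)[1, ])
  b <- match("mu", feats$feature_types)
  lc <- lagged_correlation(feats$values[3, b, ], pc1)
  expect_lt(lc$r[which.max(abs(lc$r))], -0.4)
})

test_that("moderate negative gains keep the envelope valid and finite", {
  # (1 + g*d)+ with d in [0,1] is 1 at rest, so a finite signal results
  cfg <- small_cfg(seed = 2, informative = data.frame(
    channel = 2L, feature_type = "mu", gain = -0.5, lag_ms = 0,
    stringsAsFactors = FALSE))
  set.seed(1)
  kin <- generate_reach_kinematics(cfg)$kin
  expect_silent({x <- generate_ecog(kin, cfg)})
  expect_true(all(is.finite(x)))
})
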