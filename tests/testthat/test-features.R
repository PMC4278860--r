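test_that("common average reference removes the cross-channel mean", {
  expect_equal(common_average_reference(matrix(c(1, 3), 2, 1)),
               matrix(c(-1, 1), 2, 1))
  same <- matrix(5, 3, 10)
  expect_equal(common_average_reference(same), matrix(0, 3, 10))
  set.seed(1)
  x <- matrix(rnorm(4000), 4, 1000)
  expect_lt(max(abs(colMeans(common_average_reference(x)))), 1e-12)
  expect_error(common_average_reference(matrix(1, 1, 10)), "2 channels")
})

test_that("band filters are symmetric with the required frequency response", {
  b <- design_bandpass("mu", fs = 1000)
  expect_length(b, 401)
  expect_equal(b, rev(b))                       # linear phase
  expect_gte(fir_gain(b, 10, 1000), 0.9)        # passband center
  expect_lte(fir_gain(b, 60, 1000), 0.01)       # line-noise rejection
  bd <- design_bandpass("delta", fs = 1000)
  expect_equal(fir_gain(bd, 0, 1000), 1, tolerance = 1e-6)  # DC passes
  expect_error(design_bandpass(data.frame(name = "x", lo = 100, hi = 600),
                               fs = 1000), "Nyquist")
})

test_that("forward-backward filtering has zero phase and the closed-form kernel", {
  b <- design_bandpass("mu", fs = 1000)
  t <- seq_len(5000) / 1000
  x <- sin(2 * pi * 10 * t)
  y <- zero_phase_filter(x, b)
  cc <- stats::ccf(y[1000:4000], x[1000:4000], lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # constant through the delta low-pass survives in the interior
  bd <- design_bandpass("delta", fs = 1000)
  z <- zero_phase_filter(rep(2.5, 3000), bd)
  expect_lt(max(abs(z[1000:2000] - 2.5)), 1e-6)
  # impulse response equals the autocorrelation of b (direct-convolution oracle)
  n <- 3000; imp <- numeric(n); imp[1500] <- 1
  got <- zero_phase_filter(imp, b)
  kern <- stats::convolve(b, b, type = "open")       # b symmetric: = acf of b
  expect_equal(got[(1500 - 400):(1500 + 400)], kern, tolerance = 1e-12)
  expect_error(zero_phase_filter(rep(0, 100), b), "too short")
})

test_that("bidirectional moving average is a unit-mass triangular kernel", {
  expect_equal(moving_average(rep(5, 100), 0.1, 100)[20:80], rep(5, 61))
  w <- 10
  imp <- numeric(200); imp[100] <- 1
  y <- moving_average(imp, w / 100, 100)
  tri <- y[(100 - (w - 1)):(100 + (w - 1))]
  expect_equal(sum(y), 1, tolerance = 1e-12)
  expect_equal(tri, rev(tri))
  expect_equal(which(y > 1e-15), (100 - (w - 1)):(100 + (w - 1)))
  # oracle: smoothing equals convolution with the explicit triangle
  set.seed(2)
  x <- rnorm(500)
  ker <- (w - abs(-(w - 1):(w - 1))) / w^2
  ref <- as.numeric(stats::filter(x, ker, sides = 2))
  got <- moving_average(x, w / 100, 100)
  keep <- which(!is.na(ref))
  expect_equal(got[keep], ref[keep], tolerance = 1e-12)
  expect_error(moving_average(rep(1, 5), 1, 100), "longer than signal")
})

test_that("band power of a unit sine matches its analytic power", {
  t <- seq_len(20000) / 1000
  x <- sin(2 * pi * 10 * t)
  f <- band_power_feature(x, "mu")
  interior <- f[500:1500]
  expect_lt(max(abs(interior - log(0.5))), 0.1)   # mean power of unit sine
  g <- band_power_feature(x, "high_gamma_1")
  expect_true(all(interior > g[500:1500]))        # band selectivity
  z <- suppressMessages(band_power_feature(rep(0, 20000), "mu"))
  expect_equal(unique(z), log(1e-12))
})

test_that("the LMP passes slow structure and rejects fast oscillation", {
  expect_equal(unique(round(lmp_feature(rep(3, 10000))[450:750], 9)), 3)
  t <- seq_len(10000) / 1000
  fast <- lmp_feature(sin(2 * pi * 50 * t))
  expect_lt(max(abs(fast[450:750])), 0.01)
  ramp <- lmp_feature(t)                           # slope 1 per second
  slopes <- diff(ramp[450:750]) * 100
  expect_lt(max(abs(slopes - 1)), 0.01)
  expect_error(lmp_feature(rep(1, 100)), "too short")
})

test_that("extract_features trims jointly and matches the literal pipeline", {
  sess <- small_session()
  feats <- small_features()
  Tn <- ncol(sess$kinematics)
  m <- round(feats$trim_margin_s * 100)
  expect_equal(dim(feats$values), c(4, 8, Tn - 2 * m))
  expect_equal(dim(feats$kinematics), c(3, Tn - 2 * m))
  expect_equal(feats$feature_types, c(band_table()$name, "lmp"))
  expect_equal(dimnames(feats$values)[[1]], sess$channel_labels)
  # fast shared-FFT bank path equals the literal per-stage computation
  car <- common_average_reference(sess$neural)
  lit <- band_power_feature(car[2, ], "high_gamma_1")
  keep <- seq.int(m + 1L, Tn - m)
  expect_equal(feats$values[2, "high_gamma_1", ], lit[keep], tolerance = 1e-8)
  lit_mu <- band_power_feature(car[1, ], "mu")
  expect_equal(feats$values[1, "mu", ], lit_mu[keep], tolerance = 1e-8)
  expect_error(extract_features(sess, trim_margin_s = 100), "10 s")
})

test_that("envelope-first ordering agrees closely with the default order", {
  sess <- small_session()
  f2 <- extract_features(sess, order = "envelope_first")
  f1 <- small_features()
  # same smoothed power envelope up to aliasing of the squared carrier
  expect_gt(cor(f1$values[2, "high_gamma_1", ], f2$values[2, "high_gamma_1", ]),
            0.9)
})
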