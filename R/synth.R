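#' Configuration for synthetic recording sessions
#'
#' Describes a surrogate experiment: unconstrained point-to-point reaches from
#' a home position into a bounded workspace, separated by variable rests, with
#' a multichannel ECoG-like recording whose band envelopes co-modulate with
#' the first principal component of the movement at configurable gains and
#' lags. Defaults emulate a single recording block: 40 reaches of 2-5 s
#' separated by 2-15 s rests (roughly eight minutes), 16 channels, and three
#' informative channel/band pairs at moderate signal-to-noise: a high gamma 1
#' channel modulated positively and mu/beta channels modulated negatively, as
#' observed for movement-related ECoG band power.
#'
#' @param n_channels Number of recorded channels (>= 2).
#' @param informative data.frame with columns `channel` (index),
#'   `feature_type` (one of [feature_types()]), `gain` (signed, unitless
#'   envelope gain) and `lag_ms` (signed; negative = neural change precedes
#'   kinematics).
#' @param n_reaches Number of reaches.
#' @param reach_duration_s Length-2 interval (s) for reach durations, within
#'   `[1.2, 6.2]`.
#' @param rest_duration_s Length-2 interval (s) for rest durations, within
#'   `[0, 16.7]`.
#' @param workspace 3x2 matrix of axis intervals (cm), rows height/depth/lateral.
#' @param noise_pink_rms Background pink-noise RMS amplitude (microvolts).
#' @param carrier_rms Per-band carrier RMS amplitude (microvolts).
#' @param lmp_amp LMP encoding amplitude (microvolts per unit drive).
#' @param line_60hz_amp 60 Hz line-noise amplitude (microvolts, 0 = off).
#' @param fs_neural Neural sampling rate (Hz, default 1000).
#' @param fs_kin Kinematic sampling rate (Hz, default 100).
#' @param seed Integer RNG seed.
#' @return A validated `synth_config` list.
#' @export
#' @examples
#' cfg <- synth_config(n_channels = 4, n_reaches = 5, seed = 1)
synth_config <- function(n_channels = 16,
                         informative = data.frame(
                           channel = c(3L, 7L, 12L),
                           feature_type = c("high_gamma_1", "mu", "beta"),
                           gain = c(0.6, -0.9, -0.95),
                           lag_ms = c(-100, 0, 100),
                           stringsAsFactors = FALSE),
                         n_reaches = 45,
                         reach_duration_s = c(1.5, 3.5),
                         rest_duration_s = c(2.0, 12.0),
                         workspace = rbind(height = c(-22, 15),
                                           depth = c(15, 50),
                                           lateral = c(-25, 25)),
                         noise_pink_rms = 55,
                         carrier_rms = 25,
                         lmp_amp = 20,
                         line_60hz_amp = 0,
                         fs_neural = 1000,
                         fs_kin = 100,
                         seed = 1L) {
  workspace <- as.matrix(workspace)
  stopifnot(n_channels >= 2, nrow(workspace) == 3, ncol(workspace) == 2)
  if (any(workspace[, 2] <= workspace[, 1])) {
    stop("degenerate workspace: every axis interval must have positive width")
  }
  stopifnot(length(reach_duration_s) == 2, length(rest_duration_s) == 2)
  if (reach_duration_s[1] < 1.2 || reach_duration_s[2] > 6.2 ||
      diff(reach_duration_s) < 0) {
    stop("reach_duration_s must be an interval within [1.2, 6.2]")
  }
  if (rest_duration_s[1] < 0 || rest_duration_s[2] > 16.7 ||
      diff(rest_duration_s) < 0) {
    stop("rest_duration_s must be an interval within [0, 16.7]")
  }
  if (nrow(informative) > 0) {
    stopifnot(all(c("channel", "feature_type", "gain", "lag_ms") %in%
                    names(informative)))
    if (any(informative$channel < 1 | informative$channel > n_channels)) {
      stop("informative channel index out of range")
    }
    if (!all(informative$feature_type %in% feature_types())) {
      stop("unknown feature_type in informative table")
    }
    if (any(abs(informative$lag_ms) > 1000)) stop("|lag_ms| must be <= 1000")
    if (any(!is.finite(informative$gain))) stop("gains must be finite")
  }
  structure(list(
    n_channels = as.integer(n_channels), informative = informative,
    n_reaches = as.integer(n_reaches),
    reach_duration_s = reach_duration_s, rest_duration_s = rest_duration_s,
    workspace = workspace, noise_pink_rms = noise_pink_rms,
    carrier_rms = carrier_rms, lmp_amp = lmp_amp,
    line_60hz_amp = line_60hz_amp,
    fs_neural = fs_neural, fs_kin = fs_kin, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Minimum-jerk position profile
#'
#' The normalized minimum-jerk polynomial `s(tau) = 10 tau^3 - 15 tau^4 +
#' 6 tau^5` and its derivative, the standard smooth surrogate for natural
#' point-to-point reaches (zero velocity and acceleration at both endpoints).
#'
#' @param tau Normalized time in `[0, 1]`.
#' @return List with `s` (position fraction) and `ds` (d s / d tau).
#' @export
min_jerk_profile <- function(tau) {
  list(s = 10 * tau^3 - 15 * tau^4 + 6 * tau^5,
       ds = 30 * tau^2 - 60 * tau^3 + 30 * tau^4)
}

#' Generate a 3-D reach kinematic trace
#'
#' Alternates rests at a home position (the bottom-center of the workspace
#' front) with reach epochs to targets drawn uniformly inside the workspace
#' box. Each reach epoch consists of an outward and a return minimum-jerk leg
#' within the drawn reach duration, so the hand starts and ends every epoch at
#' the home position with zero velocity. Durations are drawn uniformly from
#' the configured intervals and rounded to whole kinematic samples.
#'
#' @param config A [synth_config()].
#' @return List with `kin` (3 x samples matrix, cm, rows height/depth/lateral)
#'   and `reaches` (data.frame: onset_s, offset_s, duration_s, target_*).
#' @export
generate_reach_kinematics <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs_kin
  ws <- config$workspace
  home <- c(ws[1, 1], ws[2, 1], mean(ws[3, ]))
  n <- config$n_reaches
  rest_n <- pmax(1L, as.integer(round(stats::runif(n + 1L,
    config$rest_duration_s[1], config$rest_duration_s[2]) * fs)))
  reach_n <- as.integer(round(stats::runif(n,
    config$reach_duration_s[1], config$reach_duration_s[2]) * fs))
  targets <- cbind(stats::runif(n, ws[1, 1], ws[1, 2]),
                   stats::runif(n, ws[2, 1], ws[2, 2]),
                   stats::runif(n, ws[3, 1], ws[3, 2]))
  segs <- list(matrix(home, nrow = 3, ncol = rest_n[1]))
  onsets <- integer(n)
  pos <- rest_n[1]
  for (i in seq_len(n)) {
    d <- reach_n[i]
    out_n <- d %/% 2L; back_n <- d - out_n
    tau_out <- seq_len(out_n) / out_n
    tau_back <- seq_len(back_n) / back_n
    s_out <- min_jerk_profile(tau_out)$s
    s_back <- 1 - min_jerk_profile(tau_back)$s
    delta <- targets[i, ] - home
    leg <- cbind(outer(delta, s_out), outer(delta, s_back))
    segs[[length(segs) + 1L]] <- home + leg
    segs[[length(segs) + 1L]] <- matrix(home, nrow = 3, ncol = rest_n[i + 1L])
    onsets[i] <- pos
    pos <- pos + d + rest_n[i + 1L]
  }
  kin <- do.call(cbind, segs)
  rownames(kin) <- c("height", "depth", "lateral")
  reaches <- if (n > 0) {
    data.frame(onset_s = onsets / fs, offset_s = (onsets + reach_n) / fs,
               duration_s = reach_n / fs,
               target_height = targets[, 1], target_depth = targets[, 2],
               target_lateral = targets[, 3])
  } else {
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               duration_s = numeric(0), target_height = numeric(0),
               target_depth = numeric(0), target_lateral = numeric(0))
  }
  list(kin = kin, reaches = reaches)
}

# Real signal from the positive-frequency half spectrum (bins 1..N/2-1).
ifft_half <- function(Shalf, N) {
  full <- complex(length.out = N)
  full[2:(N %/% 2)] <- Shalf
  full[N:(N %/% 2 + 2)] <- Conj(Shalf)
  Re(stats::fft(full, inverse = TRUE)) / N
}

# Scale a half spectrum so the synthesized N-sample signal has the target RMS
# (Parseval: sum x^2 = sum |S|^2 / N, conjugate pairs counted twice).
scale_to_rms <- function(Shalf, N, rms) {
  pw <- 2 * sum(Mod(Shalf)^2)
  if (pw == 0) return(Shalf)
  Shalf * (rms * N / sqrt(pw))
}

# Pink (1/f) background: half spectrum with random phases.
pink_spectrum <- function(f, rms, N) {
  mag <- 1 / sqrt(f)
  ph <- stats::runif(length(f), 0, 2 * pi)
  scale_to_rms(complex(modulus = mag, argument = ph), N, rms)
}

# Band-limited Gaussian carrier: complex-normal bins inside [lo, hi].
band_spectrum <- function(f, lo, hi, rms, N) {
  S <- complex(length.out = length(f))
  inband <- f > max(lo, 1e-9) & f <= hi
  S[inband] <- complex(real = stats::rnorm(sum(inband)),
                       imaginary = stats::rnorm(sum(inband)))
  scale_to_rms(S, N, rms)
}

# Latent drive: first PC of z-scored clean kinematics, oriented so that
# excursion away from home increases it, rescaled to [0, 1], at fs_kin.
latent_drive <- function(kin) {
  sds <- apply(kin, 1, stats::sd)
  if (any(sds == 0)) return(rep(0, ncol(kin)))
  z <- (kin - rowMeans(kin)) / sds
  pc <- fit_kin_pca(z)
  d <- drop(pc$loadings[1, ] %*% z)
  dist <- sqrt(colSums((kin - kin[, 1])^2))
  if (stats::cor(d, dist) < 0) d <- -d
  (d - min(d)) / (max(d) - min(d))
}

#' Synthesize a multichannel ECoG-like recording from a kinematic trace
#'
#' Each channel is pink background noise plus seven band-limited Gaussian
#' carriers (one per canonical band). For every informative
#' (channel, band, gain, lag) entry the carrier amplitude is multiplied by
#' `max(0, 1 + gain * d(t - lag))`, where `d` is the first principal component
#' of the z-scored kinematics rescaled to `[0, 1]` — positive gains emulate
#' movement-related power increases (high gamma), negative gains emulate
#' desynchronization (mu/beta/delta). An `lmp` entry instead adds a slow
#' offset `lmp_amp * gain * d(t - lag)`. Optional 60 Hz line noise is added
#' to all channels.
#'
#' @param kin 3 x samples kinematic matrix at `config$fs_kin` (cm).
#' @param config A [synth_config()].
#' @return channels x samples numeric matrix (microvolts) at `config$fs_neural`.
#' @export
generate_ecog <- function(kin, config) {
  stopifnot(inherits(config, "synth_config"), all(is.finite(kin)))
  fs <- config$fs_neural
  dec <- as.integer(round(fs / config$fs_kin))
  n <- ncol(kin) * dec
  d_kin <- latent_drive(kin)
  t_kin <- (seq_along(d_kin) - 1L) / config$fs_kin
  t_neu <- (seq_len(n) - 1L) / fs
  d <- stats::approx(t_kin, d_kin, xout = t_neu, rule = 2)$y
  tab <- band_table()
  info <- config$informative
  N <- stats::nextn(n, 2)
  f <- seq_len(N %/% 2 - 1L) * fs / N
  out <- matrix(0, nrow = config$n_channels, ncol = n)
  for (ch in seq_len(config$n_channels)) {
    # background: pink noise plus all non-informative carriers, one transform
    acc <- pink_spectrum(f, config$noise_pink_rms, N)
    extra <- numeric(n)
    for (b in seq_len(nrow(tab))) {
      Sb <- band_spectrum(f, tab$lo[b], tab$hi[b], config$carrier_rms, N)
      hit <- which(info$channel == ch & info$feature_type == tab$name[b])
      if (length(hit)) {
        carrier <- ifft_half(Sb, N)[seq_len(n)]
        for (j in hit) {
          dl <- lag_shift(d, info$lag_ms[j], fs)
          mod <- pmax(0, 1 + info$gain[j] * dl)
          if (all(mod == 0)) {
            stop("gain ", info$gain[j], " drives the ", tab$name[b],
                 " modulation negative everywhere")
          }
          carrier <- carrier * mod
        }
        extra <- extra + carrier
      } else {
        acc <- acc + Sb
      }
    }
    x <- ifft_half(acc, N)[seq_len(n)] + extra
    hit <- which(info$channel == ch & info$feature_type == "lmp")
    for (j in hit) {
      dl <- lag_shift(d, info$lag_ms[j], fs)
      x <- x + config$lmp_amp * info$gain[j] * dl
    }
    if (config$line_60hz_amp > 0) {
      x <- x + config$line_60hz_amp * sin(2 * pi * 60 * t_neu +
                                          stats::runif(1, 0, 2 * pi))
    }
    out[ch, ] <- x
  }
  out
}

# Shift a series so that the output at time t equals x(t - lag_ms); values
# shifted in from outside the record repeat the edge sample.
lag_shift <- function(x, lag_ms, fs) {
  s <- as.integer(round(lag_ms / 1000 * fs))
  n <- length(x)
  idx <- pmin(pmax(seq_len(n) - s, 1L), n)
  x[idx]
}

#' Generate a complete synthetic recording session
#'
#' Composes [generate_reach_kinematics()] and [generate_ecog()] under the
#' configured seed; bit-identical for a fixed seed. The returned session keeps
#' a `ground_truth` record (informative table, latent drive at the kinematic
#' rate, reach table) for downstream verification.
#'
#' @param config A [synth_config()].
#' @return An `ecog_session`: list with `neural` (channels x samples, uV,
#'   `fs_neural`), `kinematics` (3 x samples, cm, `fs_kin`), rates,
#'   `channel_labels`, `ground_truth`.
#' @export
generate_session <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  k <- generate_reach_kinematics(config)
  neural <- generate_ecog(k$kin, config)
  labels <- sprintf("ch%02d", seq_len(config$n_channels))
  rownames(neural) <- labels
  structure(list(
    neural = neural, kinematics = k$kin,
    fs_neural = config$fs_neural, fs_kin = config$fs_kin,
    channel_labels = labels,
    ground_truth = list(informative = config$informative,
                        drive = latent_drive(k$kin),
                        reaches = k$reaches,
                        config = config)
  ), class = "ecog_session")
}

#' @export
print.ecog_session <- function(x, ...) {
  cat("<ecog_session> ", nrow(x$neural), " channels x ", ncol(x$neural),
      " samples @ ", x$fs_neural, " Hz (", round(ncol(x$neural) / x$fs_neural, 1),
      " s); kinematics 3 x ", ncol(x$kinematics), " @ ", x$fs_kin, " Hz\n",
      sep = "")
  invisible(x)
}
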