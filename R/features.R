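#' Common average reference (CAR)
#'
#' Subtracts, at every sample, the instantaneous mean across channels from each
#' channel, removing spatial bias from the recording reference. Requires at
#' least two channels.
#'
#' @param neural channels x samples numeric matrix.
#' @return Matrix of the same shape with zero cross-channel mean at every
#'   sample.
#' @export
common_average_reference <- function(neural) {
  if (!is.matrix(neural)) stop("neural must be a channels x samples matrix")
  if (nrow(neural) < 2L) stop("CAR requires at least 2 channels")
  sweep(neural, 2L, colMeans(neural), "-")
}

#' Smoothed log band-power feature for one channel
#'
#' The band-power pipeline: zero-phase FIR bandpass filter at the neural rate,
#' downsample to `fs_out`, square to instantaneous power, smooth with a
#' `smooth_s`-second forward-backward moving average, and log-transform with a
#' small guard `log(p + eps)` so silent channels stay finite. With
#' `order = "envelope_first"` squaring and smoothing happen at the neural rate
#' before downsampling (an anti-aliased variant); the default follows the
#' filter -> downsample -> square -> smooth -> log order.
#'
#' @param x One channel at `fs_in` Hz (numeric vector, microvolts).
#' @param band Band name or one-row band definition (see [band_table()]).
#' @param fs_in Input sampling rate in Hz (default 1000).
#' @param fs_out Output (kinematic) rate in Hz (default 100).
#' @param smooth_s Smoothing window in seconds (default 1).
#' @param order `"paper"` or `"envelope_first"` pipeline ordering.
#' @param eps Additive guard before the log, in microvolts squared.
#' @param b Optional precomputed FIR coefficients (skips the design step).
#' @return Feature trace at `fs_out` Hz (log power, dimensionless).
#' @export
band_power_feature <- function(x, band, fs_in = 1000, fs_out = 100,
                               smooth_s = 1, order = c("paper", "envelope_first"),
                               eps = 1e-12, b = NULL) {
  order <- match.arg(order)
  if (!all(is.finite(x))) stop("x contains non-finite values")
  if (all(x == 0)) message("band_power_feature: all-zero input; returning log(eps)")
  if (is.null(b)) b <- design_bandpass(band, fs_in)
  y <- zero_phase_filter(x, b)
  dec <- as.integer(round(fs_in / fs_out))
  if (order == "paper") {
    y <- y[seq(1L, length(y), by = dec)]
    p <- moving_average(y^2, smooth_s, fs_out, bidirectional = TRUE)
  } else {
    p <- moving_average(y^2, smooth_s, fs_in, bidirectional = TRUE)
    p <- p[seq(1L, length(p), by = dec)]
  }
  log(p + eps)
}

#' Local motor potential (LMP) feature for one channel
#'
#' The LMP is the heavily smoothed time-domain amplitude of the (CAR'd) ECoG
#' signal: a 2-second moving average applied forward and backward, then
#' downsampled to the kinematic rate. Units remain microvolts.
#'
#' @inheritParams band_power_feature
#' @param smooth_s Smoothing window in seconds (default 2).
#' @return Feature trace at `fs_out` Hz (microvolts).
#' @export
lmp_feature <- function(x, fs_in = 1000, fs_out = 100, smooth_s = 2) {
  if (!all(is.finite(x))) stop("x contains non-finite values")
  if (length(x) <= 4 * fs_in) {
    stop("input too short for LMP: need more than ", 4 * fs_in, " samples")
  }
  y <- moving_average(x, smooth_s, fs_in, bidirectional = TRUE)
  dec <- as.integer(round(fs_in / fs_out))
  y[seq(1L, length(y), by = dec)]
}

#' Extract the full feature tensor from a recording session
#'
#' Applies the common average reference, then computes the seven smoothed log
#' band-power features and the LMP for every channel, at the kinematic rate.
#' Filter edge transients are removed by trimming `trim_margin_s` seconds from
#' both ends of the features *and* the kinematics jointly, preserving
#' alignment.
#'
#' @param session An `ecog_session` (see [generate_session()], [read_session()]).
#' @param trim_margin_s Seconds trimmed from each end (default 2, the largest
#'   smoothing window).
#' @param order Pipeline ordering passed to [band_power_feature()].
#' @param eps Log guard passed to [band_power_feature()].
#' @return A `feature_tensor`: list with `values` (channels x 8 x samples
#'   array), `kinematics` (3 x samples, trimmed to match), `channel_labels`,
#'   `feature_types`, `fs`, `trim_margin_s`.
#' @export
extract_features <- function(session, trim_margin_s = 2,
                             order = c("paper", "envelope_first"), eps = 1e-12) {
  order <- match.arg(order)
  stopifnot(inherits(session, "ecog_session"))
  fs_in <- session$fs_neural; fs_out <- session$fs_kin
  neural <- common_average_reference(session$neural)
  C <- nrow(neural)
  tab <- band_table()
  bank <- lapply(seq_len(nrow(tab)), function(i) design_bandpass(tab[i, ], fs_in))
  plan <- bank_plan(ncol(neural), bank)
  dec <- as.integer(round(fs_in / fs_out))
  ftypes <- feature_types()
  nfeat <- length(ftypes)
  Tn <- ncol(session$kinematics)
  m <- as.integer(round(trim_margin_s * fs_out))
  if (Tn - 2L * m < 10L * fs_out) {
    stop("trimming ", trim_margin_s, " s per end leaves < 10 s of data")
  }
  vals <- array(NA_real_, dim = c(C, nfeat, Tn),
                dimnames = list(session$channel_labels, ftypes, NULL))
  for (c in seq_len(C)) {
    xc <- neural[c, ]
    filt <- bank_apply(xc, plan)
    for (i in seq_len(nrow(tab))) {
      y <- filt[[i]]
      if (order == "paper") {
        y <- y[seq(1L, length(y), by = dec)]
        p <- moving_average(y^2, 1, fs_out, bidirectional = TRUE)
      } else {
        p <- moving_average(y^2, 1, fs_in, bidirectional = TRUE)
        p <- p[seq(1L, length(p), by = dec)]
      }
      vals[c, i, ] <- log(p + eps)
    }
    vals[c, nfeat, ] <- lmp_feature(xc, fs_in, fs_out)
  }
  keep <- seq.int(m + 1L, Tn - m)
  structure(list(
    values = vals[, , keep, drop = FALSE],
    kinematics = session$kinematics[, keep, drop = FALSE],
    channel_labels = session$channel_labels,
    feature_types = ftypes,
    fs = fs_out,
    trim_margin_s = trim_margin_s
  ), class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<feature_tensor> ", d[1], " channels x ", d[2], " feature types x ",
      d[3], " samples @ ", x$fs, " Hz (",
      round(d[3] / x$fs, 1), " s, trim ", x$trim_margin_s, " s/end)\n", sep = "")
  invisible(x)
}

# Flatten a feature tensor to a samples x (channels*types) matrix with a
# parallel candidate table (channel, feature_type).
feature_matrix <- function(feats) {
  d <- dim(feats$values)
  X <- matrix(aperm(feats$values, c(3L, 1L, 2L)), nrow = d[3])
  cand <- expand.grid(channel = seq_len(d[1]), type = seq_len(d[2]),
                      KEEP.OUT.ATTRS = FALSE)
  cand$channel_label <- feats$channel_labels[cand$channel]
  cand$feature_type <- feats$feature_types[cand$type]
  colnames(X) <- paste(cand$channel_label, cand$feature_type, sep = ".")
  list(X = X, candidates = cand)
}
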