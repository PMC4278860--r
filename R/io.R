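#' Write a recording session to a plain-text container
#'
#' Persists a session as a directory holding `neural.csv` (samples x
#' channels, microvolts), `kinematics.csv` (samples x 3, cm) and `meta.yaml`
#' (rates, labels, precision). Values are stored rounded to `digits` decimal
#' places; at that declared precision the round-trip `read_session(write_session(x))`
#' is exact.
#'
#' @param session An `ecog_session`.
#' @param path Directory to create/overwrite.
#' @param digits Stored decimal precision (default 6).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, digits = 6) {
  stopifnot(inherits(session, "ecog_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  neu <- data.table::as.data.table(t(round(session$neural, digits)))
  data.table::setnames(neu, session$channel_labels)
  data.table::fwrite(neu, file.path(path, "neural.csv"))
  kin <- data.table::as.data.table(t(round(session$kinematics, digits)))
  data.table::setnames(kin, c("height", "depth", "lateral"))
  data.table::fwrite(kin, file.path(path, "kinematics.csv"))
  meta <- list(fs_neural = session$fs_neural, fs_kin = session$fs_kin,
               channel_labels = as.list(session$channel_labels),
               digits = digits)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read a recording session from a plain-text container
#'
#' Reads a directory written by [write_session()] (or assembled by hand from
#' a neural CSV plus a kinematics CSV and a `meta.yaml`). Validates that the
#' neural and kinematic durations agree to within one kinematic sample.
#'
#' @param path Session directory.
#' @return An `ecog_session`.
#' @export
read_session <- function(path) {
  metaf <- file.path(path, "meta.yaml")
  if (!file.exists(metaf)) stop("missing field source: meta.yaml not found in ", path)
  meta <- yaml::read_yaml(metaf)
  for (f in c("fs_neural", "fs_kin", "channel_labels")) {
    if (is.null(meta[[f]])) stop("missing field in meta.yaml: ", f)
  }
  neu <- data.table::fread(file.path(path, "neural.csv"))
  kin <- data.table::fread(file.path(path, "kinematics.csv"))
  neural <- t(as.matrix(neu))
  kinematics <- t(as.matrix(kin))
  dur_n <- ncol(neural) / meta$fs_neural
  dur_k <- ncol(kinematics) / meta$fs_kin
  if (abs(dur_n - dur_k) > 1 / meta$fs_kin + 1e-9) {
    stop("duration mismatch: neural ", dur_n, " s vs kinematics ", dur_k,
         " s (tolerance one kinematic sample)")
  }
  if (nrow(neural) < 2) stop("need at least 2 channels")
  labels <- unlist(meta$channel_labels)
  rownames(neural) <- labels
  rownames(kinematics) <- c("height", "depth", "lateral")
  structure(list(neural = neural, kinematics = kinematics,
                 fs_neural = meta$fs_neural, fs_kin = meta$fs_kin,
                 channel_labels = labels, ground_truth = NULL),
            class = "ecog_session")
}

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain with defaults matching the
#' package's canonical settings: 401 filter taps, 1 s band-power and 2 s LMP
#' smoothing, a +/-1000 ms lag grid at 50 ms, 5 folds, 9 inputs, 1024
#' shuffles, 2 s trim margin. Serializes losslessly to YAML.
#'
#' @param synth A [synth_config()] for simulated input (or NULL to read).
#' @param session_path Optional session directory to read instead of
#'   simulating.
#' @param targets Kinematic targets to decode.
#' @param n_inputs,folds,n_shuffles,shuffle_mode,trim_margin_s,order,seed
#'   Stage parameters; see the stage functions.
#' @param lag_max_ms,lag_step_ms Lag grid bounds/step (ms).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(), session_path = NULL,
                            targets = "pc1", n_inputs = 9, folds = 5,
                            n_shuffles = 1024,
                            shuffle_mode = "circular_shift",
                            trim_margin_s = 2, order = "paper",
                            lag_max_ms = 1000, lag_step_ms = 50, seed = 1L) {
  structure(list(synth = synth, session_path = session_path,
                 targets = targets, n_inputs = n_inputs, folds = folds,
                 n_shuffles = n_shuffles, shuffle_mode = shuffle_mode,
                 trim_margin_s = trim_margin_s, order = order,
                 lag_max_ms = lag_max_ms, lag_step_ms = lag_step_ms,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: the config.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (!is.null(x$synth)) {
    x$synth <- unclass(x$synth)
    x$synth$workspace <- as.list(as.data.frame(t(x$synth$workspace)))
    x$synth$informative <- as.list(x$synth$informative)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(x$synth)) {
    s <- x$synth
    ws <- do.call(rbind, s$workspace)
    syn <- synth_config(
      n_channels = s$n_channels,
      informative = as.data.frame(s$informative, stringsAsFactors = FALSE),
      n_reaches = s$n_reaches, reach_duration_s = unlist(s$reach_duration_s),
      rest_duration_s = unlist(s$rest_duration_s), workspace = ws,
      noise_pink_rms = s$noise_pink_rms, carrier_rms = s$carrier_rms,
      lmp_amp = s$lmp_amp, line_60hz_amp = s$line_60hz_amp,
      fs_neural = s$fs_neural, fs_kin = s$fs_kin, seed = s$seed)
  }
  pipeline_config(synth = syn, session_path = x$session_path,
                  targets = unlist(x$targets), n_inputs = x$n_inputs,
                  folds = x$folds, n_shuffles = x$n_shuffles,
                  shuffle_mode = x$shuffle_mode,
                  trim_margin_s = x$trim_margin_s, order = x$order,
                  lag_max_ms = x$lag_max_ms, lag_step_ms = x$lag_step_ms,
                  seed = x$seed)
}

#' Run the full decoding pipeline
#'
#' Simulate (or read) a session, extract features, decode every requested
#' target under cross-validation, optionally calibrate chance with a shuffle
#' null for the first target, and assemble a per-target report table (median
#' r, null maximum, Bonferroni-corrected Wilcoxon p). Deterministic for a
#' fixed config seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to stderr?
#' @return List with `session`, `features`, `decoders` (one per target),
#'   `null` (or NULL if `n_shuffles = 0`), `report` (data.frame).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[ecogreach] ", ...)
  grid <- lag_grid(config$lag_max_ms, config$lag_step_ms)
  if (!is.null(config$session_path)) {
    say("reading session from ", config$session_path)
    session <- read_session(config$session_path)
  } else {
    say("simulating session (seed ", config$synth$seed, ")")
    session <- generate_session(config$synth)
  }
  say("extracting features (order=", config$order,
      ", trim=", config$trim_margin_s, " s)")
  feats <- extract_features(session, trim_margin_s = config$trim_margin_s,
                            order = config$order)
  decoders <- lapply(config$targets, function(tg) {
    say("decoding ", tg, " (", config$n_inputs, " inputs, ",
        config$folds, " folds)")
    reach_decoder(feats, target = tg, n_inputs = config$n_inputs,
                  folds = config$folds, grid = grid)
  })
  names(decoders) <- config$targets
  null <- NULL
  if (config$n_shuffles > 0) {
    say("shuffle null (", config$n_shuffles, " x ", config$shuffle_mode, ")")
    null <- shuffle_null(feats, n_inputs = config$n_inputs,
                         n_shuffles = config$n_shuffles,
                         mode = config$shuffle_mode,
                         target = config$targets[1], folds = config$folds,
                         grid = grid, seed = config$seed)
  }
  report <- data.frame(
    target = config$targets,
    median_r = vapply(decoders, function(d) d$cv$median_r, numeric(1)),
    null_max_r = if (is.null(null)) NA_real_ else max(null$r),
    p_vs_chance = vapply(decoders, function(d) {
      if (is.null(null)) return(NA_real_)
      wilcoxon_vs_chance(d$cv$r, null, n_comparisons = length(decoders))$p
    }, numeric(1)))
  report$significant <- !is.na(report$p_vs_chance) & report$p_vs_chance < 0.05
  say("done")
  list(session = session, features = feats, decoders = decoders,
       null = null, report = report)
}
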