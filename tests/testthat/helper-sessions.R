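# Shared fixtures: built in code, cached per test run.

small_cfg <- function(seed = 7, ...) {
  defaults <- list(
    n_channels = 4,
    informative = data.frame(channel = 2L, feature_type = "high_gamma_1",
                             gain = 1.5, lag_ms = 0, stringsAsFactors = FALSE),
    n_reaches = 8,
    reach_duration_s = c(1.5, 3.0),
    rest_duration_s = c(1.0, 3.0),
    seed = seed)
  dots <- list(...)
  args <- defaults
  for (nm in names(dots)) args[[nm]] <- dots[[nm]]
  do.call(synth_config, args)
}

no_encoding <- function() {
  data.frame(channel = integer(0), feature_type = character(0),
             gain = numeric(0), lag_ms = numeric(0),
             stringsAsFactors = FALSE)
}

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# One small encoded session + its features, reused across files.
small_session <- function() cached("small_session",
                                   generate_session(small_cfg()))
small_features <- function() cached("small_features",
                                    extract_features(small_session()))
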