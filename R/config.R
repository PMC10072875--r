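#' Load and validate an analysis configuration
#'
#' Configurations are YAML files with one named parameter group per pipeline
#' stage (spectral grid, band edges, seizure-detector thresholds, window
#' lengths, cross-validation settings, simulation parameters). Every value is
#' checked against its documented range at load time so a malformed config
#' fails before any stage runs.
#'
#' @param path YAML file; defaults to the configuration shipped with the
#'   package.
#' @return A named list of parameter groups, classed `analysis_config`.
#' @examples
#' cfg <- load_analysis_config()
#' cfg$seizure$threshold_k
#' @export
load_analysis_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml", package = "attnephys")
  }
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  validate_analysis_config(cfg)
}

#' @rdname load_analysis_config
#' @param cfg A configuration list (as produced by [yaml::read_yaml()]).
#' @export
validate_analysis_config <- function(cfg) {
  need <- function(group, field, lo = -Inf, hi = Inf) {
    v <- cfg[[group]][[field]]
    if (is.null(v)) stop("config: missing ", group, "$", field)
    if (!is.numeric(v) || any(v < lo) || any(v > hi)) {
      stop("config: ", group, "$", field, " out of range [", lo, ", ", hi, "]")
    }
    v
  }
  need("spectral", "omega0", 2, 20)
  fmin <- need("spectral", "f_min_hz", 0.01, 1000)
  fmax <- need("spectral", "f_max_hz", 0.01, 1000)
  if (fmin >= fmax) stop("config: spectral f_min_hz must be below f_max_hz")
  need("spectral", "n_voices", 4, 512)
  need("spectral", "decimate_to_hz", 2 * fmax, 30000)
  if (is.null(cfg$bands) || length(cfg$bands) == 0) stop("config: missing bands")
  for (b in names(cfg$bands)) {
    edges <- cfg$bands[[b]]
    if (length(edges) != 2 || edges[1] <= 0 || edges[1] >= edges[2]) {
      stop("config: band '", b, "' must be [lo, hi] with 0 < lo < hi")
    }
  }
  need("seizure", "threshold_k", 0.1, 100)
  mind <- need("seizure", "min_dur_s", 0, 3600)
  maxd <- need("seizure", "max_dur_s", mind, 3600)
  need("seizure", "merge_gap_s", 0, 10)
  need("seizure", "margin_s", 0, 600)
  if (!cfg$seizure$margin_anchor %in% c("trial", "cue")) {
    stop("config: seizure$margin_anchor must be 'trial' or 'cue'")
  }
  need("photometry", "pre_s", 0, 60)
  need("photometry", "post_s", 0.1, 600)
  need("intracellular", "failure_threshold_mv", 0, 100)
  need("intracellular", "response_window_s", 1e-4, 1)
  need("behavior", "omission_limit_s", 0, 600)
  if (!cfg$behavior$rt_anchor %in% c("cue_off", "init")) {
    stop("config: behavior$rt_anchor must be 'cue_off' or 'init'")
  }
  need("csd", "spacing_um", 1, 10000)
  need("decoding", "outlier_factor", 1, 1000)
  need("decoding", "k_neighbors", 1, 100)
  need("decoding", "k_folds", 2, 100)
  need("decoding", "repeats", 1, 100)
  need("decoding", "row_subsample", 0.05, 1)
  need("decoding", "col_subsample", 0.05, 1)
  need("decoding", "nrounds", 1, 100000)
  need("decoding", "eta", 1e-4, 1)
  structure(cfg, class = c("analysis_config", "list"))
}
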