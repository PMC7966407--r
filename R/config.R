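# Pipeline configuration: defaults, validation, YAML round-trip.

#' Default pipeline configuration
#'
#' Defaults follow the simulation study conditions: 5 Hz sampling over a
#' 10-minute run (N = 3000), 30 trials of 200 ms with ITIs uniform in
#' 2-60 s, alpha = 0.05 and a 10% FOV threshold.
#'
#' @return Named list of settings (class `nirs_config`).
#' @export
default_config <- function() {
  structure(list(
    fs = 5, run_length = 600,
    n_trials = 30, trial_duration = 0.2, iti_range = c(2, 60),
    n_vertices = 300, roi_radius_mm = 12,
    n_sources = 4, n_detectors = 8, decay_scale_mm = 12,
    fov_threshold = 0.1,
    model_id = 1, snr_db = 0,
    window = c(-5, 30), drift_cutoff_hz = 0.01, alpha = 0.05,
    cov_window = c(0, 60),
    seed = 1
  ), class = "nirs_config")
}

validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$fs) && cfg$fs > 0, "fs: must be a positive number")
  chk(is.numeric(cfg$run_length) && cfg$run_length > 0,
      "run_length: must be positive")
  chk(is.numeric(cfg$alpha) && length(cfg$alpha) == 1 &&
        cfg$alpha > 0 && cfg$alpha < 1, "alpha: must be in (0, 1)")
  chk(cfg$model_id %in% 1:4, "model_id: must be 1, 2, 3 or 4")
  chk(length(cfg$iti_range) == 2 && cfg$iti_range[1] <= cfg$iti_range[2],
      "iti_range: must be an increasing pair")
  chk(length(cfg$window) == 2 && cfg$window[1] < cfg$window[2],
      "window: must be an increasing pair")
  chk(is.numeric(cfg$fov_threshold) && cfg$fov_threshold >= 0 &&
        cfg$fov_threshold <= 1, "fov_threshold: must be in [0, 1]")
  chk(is.numeric(cfg$seed), "seed: must be numeric")
  if (length(errs) > 0)
    stop_config("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Missing keys take their defaults; unknown keys are rejected; every
#' invalid field is named in the error.
#'
#' @param path YAML file (an empty file yields all defaults).
#' @return A validated `nirs_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop_config("unknown configuration key(s): ",
                paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(unclass(defaults), user)
  class(cfg) <- "nirs_config"
  validate_config(cfg)
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg A `nirs_config`.
#' @param path Output file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.nirs_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x))
    cat("  ", k, ": ", paste(x[[k]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
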