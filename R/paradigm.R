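# Event paradigms and stimulus vectors.

#' Generate a rapid event-related paradigm
#'
#' Draws inter-trial intervals uniformly in `iti_range` (one gap before
#' every trial and one after the last) and rescales all gaps by a common
#' factor so the run is filled exactly. Onsets are deterministic per seed.
#'
#' @param n_trials Number of trials.
#' @param trial_duration Trial duration, s.
#' @param iti_range Length-2 numeric, uniform ITI range in s.
#' @param run_length Run duration, s.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @return Object of class `nirs_paradigm`: `onsets`, `durations` (s),
#'   `run_length`, `fs`, and the binary `stimulus` vector of length
#'   `round(run_length * fs)`.
#' @export
generate_paradigm <- function(n_trials = 30, trial_duration = 0.2,
                              iti_range = c(2, 60), run_length = 600,
                              fs = 5, seed = 1) {
  assert_scalar_number(n_trials, "n_trials", lower = 1)
  assert_scalar_number(trial_duration, "trial_duration", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(run_length, "run_length", lower = 0, strict_lower = TRUE)
  assert_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  if (length(iti_range) != 2L || iti_range[1] > iti_range[2] || iti_range[1] < 0)
    stop_config("iti_range must be an increasing non-negative pair")
  if (n_trials * trial_duration + (n_trials + 1) * iti_range[1] > run_length)
    stop_config("infeasible paradigm: ", n_trials, " trials of ",
                trial_duration, " s with minimum ITI ", iti_range[1],
                " s exceed the ", run_length, " s run")

  set.seed(seed)
  gaps <- stats::runif(n_trials + 1, iti_range[1], iti_range[2])
  gaps <- gaps * (run_length - n_trials * trial_duration) / sum(gaps)
  onsets <- cumsum(gaps)[seq_len(n_trials)] +
    (seq_len(n_trials) - 1) * trial_duration
  durations <- rep(trial_duration, n_trials)

  N <- round(run_length * fs)
  stimulus <- numeric(N)
  for (i in seq_len(n_trials)) {
    start <- round(onsets[i] * fs) + 1
    len <- max(1L, round(durations[i] * fs))
    idx <- start:(start + len - 1)
    idx <- idx[idx >= 1 & idx <= N]
    stimulus[idx] <- 1
  }

  structure(list(onsets = onsets, durations = durations,
                 run_length = run_length, fs = fs, stimulus = stimulus,
                 n_trials = n_trials, seed = seed),
            class = "nirs_paradigm")
}

#' @export
print.nirs_paradigm <- function(x, ...) {
  cat("Paradigm:", x$n_trials, "trials of", x$durations[1], "s over",
      x$run_length, "s at", x$fs, "Hz (", sum(x$stimulus),
      "active samples )\n")
  invisible(x)
}

#' Build a paradigm from known event onsets
#'
#' Constructor for real (or externally generated) designs where onsets
#' and durations are given rather than drawn.
#'
#' @param onsets Event onsets, s.
#' @param durations Event durations, s (scalar recycled).
#' @param run_length Run duration, s.
#' @param fs Sampling rate, Hz.
#' @return A `nirs_paradigm` (see [generate_paradigm()]).
#' @export
paradigm_from_events <- function(onsets, durations, run_length, fs = 5) {
  assert_scalar_number(run_length, "run_length", lower = 0, strict_lower = TRUE)
  assert_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  durations <- rep_len(durations, length(onsets))
  if (any(onsets < 0) || any(onsets + durations > run_length))
    stop_config("events must lie within [0, run_length]")
  N <- round(run_length * fs)
  stimulus <- numeric(N)
  for (i in seq_along(onsets)) {
    start <- round(onsets[i] * fs) + 1
    len <- max(1L, round(durations[i] * fs))
    idx <- start:(start + len - 1)
    stimulus[idx[idx >= 1 & idx <= N]] <- 1
  }
  structure(list(onsets = onsets, durations = durations,
                 run_length = run_length, fs = fs, stimulus = stimulus,
                 n_trials = length(onsets), seed = NA_integer_),
            class = "nirs_paradigm")
}

#' Convolve a stimulus vector with an HRF curve
#'
#' Discrete convolution with zero boundary conditions (the stimulus is
#' taken as 0 outside the run), truncated to the run length.
#'
#' @param paradigm A `nirs_paradigm`.
#' @param hrf An `hrf_curve` sampled at the paradigm rate.
#' @return Numeric vector of length `length(paradigm$stimulus)`.
#' @export
convolve_stimulus <- function(paradigm, hrf) {
  stopifnot(inherits(paradigm, "nirs_paradigm"), inherits(hrf, "hrf_curve"))
  if (abs(hrf$fs - paradigm$fs) > 1e-9)
    stop("HRF and paradigm sampling rates differ")
  s <- paradigm$stimulus
  h <- hrf$values
  full <- stats::convolve(s, rev(h), type = "open")
  full[seq_along(s)]
}
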