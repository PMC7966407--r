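# Synthetic resting-state physiological + instrumental noise.
#
# Channel noise is modelled as the sum of (i) an AR(1) baseline capturing
# serial correlation of slow hemodynamic/instrumental drifts, (ii)
# sinusoidal physiological oscillations at cardiac, respiratory and
# Mayer-wave frequencies with a random phase per channel, (iii) white
# measurement noise, and (iv) a shared "superficial" component added to
# every channel with a random weight, inducing the spatial correlation
# produced by scalp hemodynamics. All components are stationary; output
# is reproducible per seed. Absolute scale is irrelevant downstream
# because simulated datasets rescale the noise to a target SNR.

#' Default resting-noise configuration
#'
#' @return Named list of generator parameters: AR(1) coefficient `rho`
#'   and innovation scale `ar_sd`; `freqs`/`amps` of the physiological
#'   sinusoids (Hz, a.u.); `white_sd`; `shared_weight_range` for the
#'   common superficial component (set to `c(0, 0)` to disable);
#'   `phase_jitter` (rad/sample), a random-walk phase drift making the
#'   oscillations quasi-periodic (0 = phase-coherent).
#' @export
resting_noise_params <- function() {
  list(
    rho = 0.8, ar_sd = 0.5,
    freqs = c(cardiac = 1.1, respiratory = 0.25, mayer = 0.1),
    amps = c(cardiac = 0.4, respiratory = 0.5, mayer = 0.6),
    white_sd = 0.2,
    shared_weight_range = c(0.5, 1.5),
    phase_jitter = 0
  )
}

#' Generate synthetic resting-state channel noise
#'
#' @param n_channels Number of channels.
#' @param n Number of samples (>= 2).
#' @param fs Sampling rate, Hz.
#' @param params Configuration list, see [resting_noise_params()];
#'   entries override the defaults.
#' @param seed Integer seed.
#' @return channels x n numeric matrix.
#' @export
generate_resting_noise <- function(n_channels, n, fs = 5,
                                   params = list(), seed = 1) {
  assert_scalar_number(n_channels, "n_channels", lower = 1)
  assert_scalar_number(n, "n", lower = 2)
  assert_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  p <- utils::modifyList(resting_noise_params(), params)
  if (abs(p$rho) >= 1) stop_config("rho must be in (-1, 1)")

  set.seed(seed)
  tt <- (seq_len(n) - 1) / fs
  out <- matrix(0, n_channels, n)

  make_channel <- function() {
    ar <- if (p$ar_sd > 0) {
      as.numeric(stats::arima.sim(list(ar = p$rho), n = n,
                                  sd = p$ar_sd))
    } else numeric(n)
    osc <- numeric(n)
    for (i in seq_along(p$freqs)) {
      if (p$amps[i] > 0 && p$freqs[i] < fs / 2) {
        phase <- stats::runif(1, 0, 2 * pi)
        if (p$phase_jitter > 0) {
          # quasi-periodic oscillation: the phase drifts as a random
          # walk, so coherence decays over ~(1/phase_jitter)^2 samples
          phase <- phase + cumsum(stats::rnorm(n, 0, p$phase_jitter))
        }
        osc <- osc + p$amps[i] * sin(2 * pi * p$freqs[i] * tt + phase)
      }
    }
    ar + osc + stats::rnorm(n, 0, p$white_sd)
  }

  shared <- if (diff(range(p$shared_weight_range)) > 0 ||
                p$shared_weight_range[1] > 0) make_channel() else NULL
  for (c in seq_len(n_channels)) {
    out[c, ] <- make_channel()
    if (!is.null(shared)) {
      w <- stats::runif(1, p$shared_weight_range[1], p$shared_weight_range[2])
      out[c, ] <- out[c, ] + w * shared
    }
  }
  out
}
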