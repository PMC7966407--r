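# SNR-controlled simulated datasets.

#' Most ROI-sensitive 830 nm channel
#'
#' @param sens A `nirs_sensitivity`.
#' @param roi Vertex index set.
#' @return Channel index (row of `sens$channels`) with maximal summed
#'   830 nm sensitivity over the ROI.
#' @export
best_roi_channel <- function(sens, roi) {
  stopifnot(inherits(sens, "nirs_sensitivity"))
  if (length(roi) == 0L) stop_config("ROI is empty")
  A830 <- sens$A[["830"]]
  which.max(rowSums(A830[, roi, drop = FALSE]))
}

#' Scale resting noise to a target SNR and assemble the simulated OD
#'
#' The SNR (dB) is defined on the 830 nm channel with the largest summed
#' sensitivity over the ROI as
#' `SNR = 10 log10(P_signal / (tau^2 P_noise))`, with `P` the mean sum of
#' squares. A single scaling factor `tau` is applied to the noise of
#' every channel at both wavelengths, preserving relative amplitudes,
#' and the simulated recording is `od_sim = od_noise_free + tau * noise`.
#'
#' @param noise_free,noise `od_timeseries` of identical shape.
#' @param target_snr_db Target SNR in dB.
#' @param sens A `nirs_sensitivity` (defines the best channel).
#' @param roi Vertex index set.
#' @return List with `tau`, `od_sim`, `best_channel`.
#' @export
scale_noise_to_snr <- function(noise_free, noise, target_snr_db, sens, roi) {
  stopifnot(inherits(noise_free, "od_timeseries"),
            inherits(noise, "od_timeseries"))
  if (n_samples(noise_free) != n_samples(noise))
    stop("noise_free and noise sample counts differ")
  best <- best_roi_channel(sens, roi)
  p_sig <- mean(noise_free$values[["830"]][best, ]^2)
  p_noise <- mean(noise$values[["830"]][best, ]^2)
  if (p_noise <= 0) stop_config("zero noise power on the best channel")
  tau <- sqrt(p_sig / (p_noise * 10^(target_snr_db / 10)))
  od_sim <- od_map2(noise_free, od_scale(noise, tau), `+`)
  list(tau = tau, od_sim = od_sim, best_channel = best)
}

#' Recompute the SNR of a simulated dataset
#'
#' @param noise_free,noise `od_timeseries` (unscaled noise).
#' @param tau Noise scaling factor.
#' @param best_channel Channel index at 830 nm.
#' @return SNR in dB.
#' @export
compute_snr_db <- function(noise_free, noise, tau, best_channel) {
  p_sig <- mean(noise_free$values[["830"]][best_channel, ]^2)
  p_noise <- mean(noise$values[["830"]][best_channel, ]^2)
  10 * log10(p_sig / (tau^2 * p_noise))
}

#' Simulate a complete two-wavelength fNIRS dataset
#'
#' The ROI vertices share one HbO and one HbR time course (stimulus train
#' convolved with the model HRFs, +3/-1 umol/L extrema); all other
#' vertices are silent. Concentrations are converted to absorption via
#' the extinction coefficients, projected to channel space with the
#' sensitivity model, and synthetic resting noise is added after scaling
#' to the target SNR.
#'
#' @param surface A `nirs_surface`.
#' @param montage A `nirs_montage`.
#' @param sens A `nirs_sensitivity`.
#' @param model_id HRF model (1-4), see [hrf_model_table()].
#' @param paradigm A `nirs_paradigm`.
#' @param target_snr_db Target SNR, dB.
#' @param seed Integer seed (noise generation).
#' @param noise_params Overrides for [resting_noise_params()].
#' @return Object of class `nirs_simulation` carrying `od_sim`,
#'   `od_noise_free`, the unscaled `noise`, `tau`, `target_snr_db`,
#'   `best_channel` and the ground truth (HRF curves, ROI time courses,
#'   ROI vertex set, model id).
#' @export
simulate_dataset <- function(surface, montage, sens, model_id, paradigm,
                             target_snr_db, seed = 1, noise_params = list()) {
  stopifnot(inherits(surface, "nirs_surface"),
            inherits(sens, "nirs_sensitivity"),
            inherits(paradigm, "nirs_paradigm"))
  if (length(surface$roi) == 0L) stop_config("ROI is empty")

  hrfs <- make_hemoglobin_hrfs(model_id, fs = paradigm$fs)
  hbo_series <- convolve_stimulus(paradigm, hrfs$HbO)
  hbr_series <- convolve_stimulus(paradigm, hrfs$HbR)

  mua <- hemoglobin_to_absorption(hbo_series, hbr_series,
                                  wavelengths = sens$wavelengths)
  V <- sens$n_vertices
  N <- length(paradigm$stimulus)
  dmua <- lapply(mua, function(series) {
    m <- matrix(0, V, N)
    m[surface$roi, ] <- rep(series, each = length(surface$roi))
    m
  })
  od_noise_free <- forward_project(sens, dmua, fs = paradigm$fs)

  n_ch <- nrow(sens$channels)
  noise_mat <- generate_resting_noise(2 * n_ch, N, fs = paradigm$fs,
                                      params = noise_params, seed = seed)
  noise <- od_timeseries(
    list("685" = noise_mat[seq_len(n_ch), , drop = FALSE],
         "830" = noise_mat[n_ch + seq_len(n_ch), , drop = FALSE]),
    fs = paradigm$fs, channels = sens$channels)

  scaled <- scale_noise_to_snr(od_noise_free, noise, target_snr_db,
                               sens, surface$roi)

  structure(list(
    od_sim = scaled$od_sim, od_noise_free = od_noise_free, noise = noise,
    tau = scaled$tau, target_snr_db = target_snr_db,
    best_channel = scaled$best_channel,
    ground_truth = list(hrfs = hrfs, hbo_series = hbo_series,
                        hbr_series = hbr_series, roi = surface$roi,
                        model_id = model_id),
    paradigm = paradigm, seed = seed
  ), class = "nirs_simulation")
}

#' @export
print.nirs_simulation <- function(x, ...) {
  cat("Simulated fNIRS dataset: model", x$ground_truth$model_id,
      "at", x$target_snr_db, "dB (tau =", signif(x$tau, 4), ")\n")
  print(x$od_sim)
  invisible(x)
}
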