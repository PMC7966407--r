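# End-to-end orchestration: simulate -> reconstruct -> deconvolve ->
# metrics, and the SNR-sweep evaluation harness.

#' Reconstruct and deconvolve a simulated dataset
#'
#' Full analysis chain on one `nirs_simulation`: channel noise covariance
#' from the stored (scaled) resting recording, per-wavelength ReML
#' reconstruction, conversion to hemoglobin, vertex-wise AR(1)-MLE
#' deconvolution over the FOV, and recovery metrics per chromophore.
#'
#' @param sim A `nirs_simulation`.
#' @param sens The `nirs_sensitivity` used to simulate.
#' @param cov_window Rest window (s) for the channel covariance.
#' @param alpha Significance level for the Bonferroni-corrected F-maps.
#' @param window,drift_cutoff_hz Deconvolution settings, see
#'   [build_design_matrix()].
#' @return List with `reml`, `hb`, `map` and `metrics` (data.frame, one
#'   row per chromophore).
#' @export
evaluate_dataset <- function(sim, sens, cov_window = c(0, 60), alpha = 0.05,
                             window = c(-5, 30), drift_cutoff_hz = 0.01) {
  stopifnot(inherits(sim, "nirs_simulation"))
  rest <- od_scale(sim$noise, sim$tau)
  c1 <- estimate_channel_covariance(rest, window = cov_window)
  reml <- reml_reconstruct(sim$od_sim, sens, c1)
  hb <- reml_to_hemoglobin(reml)
  # effect sizes (and hence peak-vertex selection) are taken at the
  # first-peak latency of the simulated model for each chromophore
  ttp1 <- c(HbO = sim$ground_truth$hrfs$HbO$params$ttp1,
            HbR = sim$ground_truth$hrfs$HbR$params$ttp1)
  map <- map_deconvolution(hb, sim$paradigm, fov = sens$fov, alpha = alpha,
                           window = window,
                           drift_cutoff_hz = drift_cutoff_hz,
                           ttp1_s = ttp1)
  metrics <- rbind(hrf_recovery_metrics(map, sim, "HbO"),
                   hrf_recovery_metrics(map, sim, "HbR"))
  list(reml = reml, hb = hb, map = map, metrics = metrics)
}

#' Run an SNR sweep of simulated recoveries
#'
#' For every (model, SNR, replicate) cell: simulate a dataset, run the
#' full reconstruction/deconvolution chain and collect the recovery
#' metrics for both chromophores. Each replicate uses its own derived
#' seed (and, by default, its own toy anatomy seed), emulating repeated
#' subjects. Failed cells are recorded with `failed = TRUE` rather than
#' aborting the sweep.
#'
#' @param models Integer vector of HRF model ids (1-4).
#' @param snr_db Numeric vector of SNR levels (dB).
#' @param replicates Replicates per cell.
#' @param seed Base integer seed.
#' @param anatomy_per_replicate Regenerate the toy anatomy per replicate
#'   (TRUE) or share one across the sweep (FALSE, faster).
#' @param setup Optional shared setup from [sweep_setup()]; overrides
#'   `anatomy_per_replicate`.
#' @param ... Passed to [evaluate_dataset()].
#' @return data.frame, one row per cell x replicate x chromophore, of
#'   class `nirs_sweep`.
#' @export
run_snr_sweep <- function(models = 1:4, snr_db = seq(-30, 10, by = 2),
                          replicates = 1, seed = 1,
                          anatomy_per_replicate = TRUE, setup = NULL, ...) {
  rows <- list()
  for (m in models) for (s in snr_db) for (r in seq_len(replicates)) {
    rep_seed <- (seed + 7919L * r) %% .Machine$integer.max
    st <- if (!is.null(setup)) setup
          else sweep_setup(seed = if (anatomy_per_replicate) rep_seed else seed)
    row <- tryCatch({
      paradigm <- generate_paradigm(fs = 5, seed = rep_seed + 1L)
      sim <- simulate_dataset(st$surface, st$montage, st$sens, m, paradigm,
                              target_snr_db = s, seed = rep_seed + 2L)
      ev <- evaluate_dataset(sim, st$sens, ...)
      cbind(ev$metrics, replicate = r, seed = rep_seed, failed = FALSE)
    }, error = function(e) {
      data.frame(chromophore = NA, model_id = m, snr_db = s, vertex = NA,
                 not_significant = NA, mse = NA, ttp1 = NA, fwhm1 = NA,
                 ttp2 = NA, fwhm2 = NA, gamma = NA, err_ttp1 = NA,
                 err_fwhm1 = NA, err_ttp2 = NA, err_fwhm2 = NA,
                 replicate = r, seed = rep_seed, failed = TRUE,
                 message = conditionMessage(e))
    })
    if (is.null(row$message)) row$message <- ""
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nirs_sweep", class(out))
  out
}

#' Build the shared anatomy/montage/sensitivity for a sweep cell
#'
#' @param seed Integer seed.
#' @param n_vertices,roi_radius_mm,n_sources,n_detectors,decay_scale_mm
#'   Geometry settings (defaults match the simulation study conditions:
#'   4 sources, 8 detectors targeting a ~12 mm ROI).
#' @return List with `surface`, `montage`, `sens`.
#' @export
sweep_setup <- function(seed = 1, n_vertices = 300, roi_radius_mm = 12,
                        n_sources = 4, n_detectors = 8,
                        decay_scale_mm = 12) {
  surface <- generate_toy_anatomy(n_vertices = n_vertices,
                                  roi_radius_mm = roi_radius_mm, seed = seed)
  montage <- generate_montage(surface, n_sources = n_sources,
                              n_detectors = n_detectors, seed = seed)
  sens <- compute_synthetic_sensitivity(surface, montage,
                                        decay_scale_mm = decay_scale_mm)
  list(surface = surface, montage = montage, sens = sens)
}

#' Summarize a sweep per (model, chromophore, SNR) cell
#'
#' @param sweep A `nirs_sweep` data.frame.
#' @return data.frame of cell means and standard deviations of the error
#'   metrics, with replicate counts and the share of non-significant
#'   fallback selections.
#' @export
summarize_sweep <- function(sweep) {
  ok <- sweep[!sweep$failed & !is.na(sweep$chromophore), , drop = FALSE]
  cells <- split(ok, interaction(ok$model_id, ok$chromophore, ok$snr_db,
                                 drop = TRUE))
  rows <- lapply(cells, function(d) {
    data.frame(
      model_id = d$model_id[1], chromophore = d$chromophore[1],
      snr_db = d$snr_db[1], n = nrow(d),
      frac_not_significant = mean(d$not_significant),
      mse_mean = mean(d$mse), mse_sd = stats::sd(d$mse),
      err_ttp1_mean = mean(d$err_ttp1), err_ttp1_sd = stats::sd(d$err_ttp1),
      err_fwhm1_mean = mean(d$err_fwhm1),
      err_ttp2_mean = mean(d$err_ttp2), err_fwhm2_mean = mean(d$err_fwhm2)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$model_id, out$chromophore, out$snr_db), , drop = FALSE]
}
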