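# Vertex-wise deconvolution maps with Bonferroni-corrected F thresholds.

#' Deconvolve every field-of-view vertex of a hemoglobin reconstruction
#'
#' Applies the two-pass AR(1)-MLE FIR deconvolution to the time series of
#' each vertex inside the montage field of view, for each chromophore.
#' F-maps are thresholded at `alpha` after Bonferroni correction over the
#' number of FOV vertices, and an effect-size map is extracted at the FIR
#' sample nearest the first-peak latency (reporting convention: 6 s for
#' HbO, 8 s for HbR, the canonical latencies).
#'
#' @param hb List of `surface_timeseries` per chromophore
#'   (e.g. from [reml_to_hemoglobin()]).
#' @param paradigm A `nirs_paradigm`.
#' @param fov Integer vertex indices of the field of view.
#' @param alpha Family-wise significance level (default 0.05).
#' @param window,drift_cutoff_hz Passed to [build_design_matrix()].
#' @param ttp1_s Named numeric: effect-size latency (s) per chromophore.
#' @return Object of class `nirs_decon_map`: per chromophore a list with
#'   `beta_h` (K x |FOV| FIR coefficient matrix), `F`, `p`, `rho`,
#'   `significant` (logical over FOV), `effect_size`, `F_threshold`;
#'   plus `fov`, `alpha`, `design` geometry and the FIR `time` grid.
#' @export
map_deconvolution <- function(hb, paradigm, fov, alpha = 0.05,
                              window = c(-5, 30), drift_cutoff_hz = 0.01,
                              ttp1_s = c(HbO = 6, HbR = 8)) {
  if (length(fov) == 0L) stop_config("field of view is empty")
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  design <- build_design_matrix(paradigm, window = window,
                                drift_cutoff_hz = drift_cutoff_hz)
  K <- design$K
  m <- length(fov)
  thr <- stats::qf(1 - alpha / m, design$K, design$N - design$L)

  res <- list()
  for (chrom in names(hb)) {
    ts <- hb[[chrom]]
    stopifnot(inherits(ts, "surface_timeseries"))
    Y <- t(ts$values[fov, , drop = FALSE])        # N x |FOV|
    fit <- ar1_mle_multi(design, Y)
    idx <- which.min(abs(design$time - ttp1_s[[chrom]]))
    res[[chrom]] <- list(
      beta_h = fit$beta[seq_len(K), , drop = FALSE],
      F = fit$F, p = fit$p, rho = fit$rho,
      significant = fit$F > thr,
      effect_size = fit$beta[idx, ],
      ttp1_index = idx, ttp1_s = ttp1_s[[chrom]],
      F_threshold = thr
    )
  }
  structure(list(chromophores = res, fov = fov, alpha = alpha,
                 K = design$K, M = design$M, k0 = design$k0,
                 k1 = design$k1, fs = design$fs, N = design$N,
                 L = design$L, time = design$time),
            class = "nirs_decon_map")
}

#' @export
print.nirs_decon_map <- function(x, ...) {
  cat("Deconvolution map over", length(x$fov), "FOV vertices (alpha =",
      x$alpha, ", Bonferroni )\n")
  for (chrom in names(x$chromophores)) {
    r <- x$chromophores[[chrom]]
    cat("  ", chrom, ": ", sum(r$significant), " significant vertices (F > ",
        signif(r$F_threshold, 4), ")\n", sep = "")
  }
  invisible(x)
}

#' Sensor-level SNR estimate from a deconvolved channel
#'
#' Deconvolves a single channel's OD time series and returns the
#' logarithmic ratio of the power of the predicted evoked response
#' (FIR block times its coefficients) to the residual power.
#'
#' @param od_channel Numeric vector (one channel, recommended 830 nm).
#' @param paradigm A `nirs_paradigm`.
#' @param window,drift_cutoff_hz Passed to [build_design_matrix()].
#' @return SNR in dB (`Inf`, flagged with a warning, when the residual
#'   power is zero).
#' @export
estimate_sensor_snr <- function(od_channel, paradigm, window = c(-5, 30),
                                drift_cutoff_hz = 0.01) {
  design <- build_design_matrix(paradigm, window = window,
                                drift_cutoff_hz = drift_cutoff_hz)
  fit <- deconvolve_ar1_mle(od_channel, design)
  pred <- design$X[, seq_len(design$K), drop = FALSE] %*%
    fit$beta[seq_len(design$K)]
  p_sig <- mean(pred^2)
  p_res <- mean(fit$residuals^2)
  if (p_res <= 0) {
    warning("zero residual power; SNR is infinite")
    return(Inf)
  }
  10 * log10(p_sig / p_res)
}
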