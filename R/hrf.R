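# Difference-of-two-gammas hemodynamic response functions.
#
# The HRF is modelled as
#   HRF(t) = (t/TTP1)^a1 exp(-(t - TTP1)/b1)
#            - gamma * (t/TTP2)^a2 exp(-(t - TTP2)/b2),  t >= 0,
# with shape/scale parameters tied to the peak latency (TTP, s) and full
# width at half maximum (FWHM, s) of each lobe:
#   a_i = 8 ln(2) TTPi^2 / FWHMi^2,   b_i = FWHMi^2 / (8 ln(2) TTPi).
# Each gamma lobe then peaks exactly at its TTP with value 1, and its
# width at half maximum approaches FWHMi for narrow lobes.

#' Four reference HRF shapes
#'
#' Parameter table for the simulated HbO responses: the canonical shape
#' (model 1), a short-duration response (2), a long-duration response with
#' no undershoot (3) and a large-undershoot response (4). TTP/FWHM in
#' seconds; `gamma` is the undershoot-to-peak ratio.
#'
#' @return data.frame with one row per model.
#' @export
hrf_model_table <- function() {
  data.frame(
    model_id = 1:4,
    label = c("canonical", "short duration", "long duration",
              "large undershoot"),
    ttp1 = c(6, 5, 5, 5),
    fwhm1 = c(5.2, 1, 10, 5.2),
    ttp2 = c(15, 6, NA, 15),
    fwhm2 = c(9, 2, NA, 9),
    gamma = c(0.1, 0.1, 0, 0.5)
  )
}

#' Gamma-lobe shape parameters from peak latency and width
#'
#' @param ttp Time to peak, s (> 0).
#' @param fwhm Full width at half maximum, s (> 0).
#' @return List with shape exponent `a` (unitless) and scale `b` (s).
#' @export
gamma_shape_params <- function(ttp, fwhm) {
  assert_scalar_number(ttp, "ttp", lower = 0, strict_lower = TRUE)
  assert_scalar_number(fwhm, "fwhm", lower = 0, strict_lower = TRUE)
  l2 <- 8 * log(2)
  list(a = l2 * ttp^2 / fwhm^2, b = fwhm^2 / (l2 * ttp))
}

#' HRF parameter set
#'
#' @param ttp1,fwhm1 Main-lobe peak latency and width, s.
#' @param ttp2,fwhm2 Undershoot-lobe peak latency and width, s (ignored
#'   when `gamma = 0`).
#' @param gamma Undershoot ratio, >= 0.
#' @return Object of class `hrf_params` carrying the primary parameters
#'   and the derived shape/scale pairs.
#' @export
hrf_params <- function(ttp1, fwhm1, ttp2 = NA, fwhm2 = NA, gamma = 0) {
  assert_scalar_number(gamma, "gamma", lower = 0)
  p1 <- gamma_shape_params(ttp1, fwhm1)
  if (gamma > 0) {
    p2 <- gamma_shape_params(ttp2, fwhm2)
  } else {
    ttp2 <- NA_real_; fwhm2 <- NA_real_
    p2 <- list(a = NA_real_, b = NA_real_)
  }
  structure(list(ttp1 = ttp1, fwhm1 = fwhm1, ttp2 = ttp2, fwhm2 = fwhm2,
                 gamma = gamma, a1 = p1$a, b1 = p1$b, a2 = p2$a, b2 = p2$b),
            class = "hrf_params")
}

#' Evaluate the (unscaled) difference-of-gammas HRF
#'
#' Pointwise evaluation; the response is defined as 0 for t < 0. With
#' `gamma = 0` the curve peaks at exactly 1 at t = TTP1.
#'
#' @param params An `hrf_params`.
#' @param t Numeric vector of times, s.
#' @return Numeric vector, unscaled response.
#' @export
evaluate_hrf <- function(params, t) {
  stopifnot(inherits(params, "hrf_params"))
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  # lobes evaluated in log space: (t/TTP)^a e^{-(t-TTP)/b} can otherwise
  # underflow/overflow to 0 * Inf for extreme shape parameters
  lobe <- function(ttp, a, b)
    exp(a * log(tp / ttp) - (tp - ttp) / b)
  v <- lobe(params$ttp1, params$a1, params$b1)
  if (params$gamma > 0) {
    v <- v - params$gamma * lobe(params$ttp2, params$a2, params$b2)
  }
  out[pos] <- v
  out
}

#' Build scaled HbO and HbR HRF curves for a reference model
#'
#' The HbO curve uses the model's tabulated parameters and is scaled so
#' its maximum is +3 umol/L. The HbR curve uses the same parameters with
#' both peak latencies delayed by 2 s, is sign-inverted (so the main lobe
#' is a decrease), and scaled so its extremum is -1 umol/L.
#'
#' @param model_id Integer 1-4, row of [hrf_model_table()].
#' @param fs Sampling rate of the time grid, Hz.
#' @param window Curve support, s (evaluated on `seq(0, window, by = 1/fs)`).
#' @return List with elements `HbO` and `HbR`, each of class `hrf_curve`:
#'   `time` (s), `values` (umol/L), `chromophore`, `model_id`, `params`.
#' @export
make_hemoglobin_hrfs <- function(model_id, fs = 5, window = 40) {
  tab <- hrf_model_table()
  if (!is.numeric(model_id) || length(model_id) != 1L ||
      !(model_id %in% tab$model_id))
    stop_config("unknown model_id: ", model_id)
  row <- tab[tab$model_id == model_id, ]
  tgrid <- seq(0, window, by = 1 / fs)

  p_hbo <- hrf_params(row$ttp1, row$fwhm1, row$ttp2, row$fwhm2, row$gamma)
  v_hbo <- evaluate_hrf(p_hbo, tgrid)
  v_hbo <- v_hbo / max(v_hbo) * 3

  p_hbr <- hrf_params(row$ttp1 + 2, row$fwhm1,
                      if (row$gamma > 0) row$ttp2 + 2 else NA,
                      row$fwhm2, row$gamma)
  v_hbr <- -evaluate_hrf(p_hbr, tgrid)
  v_hbr <- v_hbr / abs(min(v_hbr)) * 1

  curve <- function(values, chromophore, params) {
    structure(list(time = tgrid, values = values, chromophore = chromophore,
                   model_id = model_id, params = params, fs = fs),
              class = "hrf_curve")
  }
  list(HbO = curve(v_hbo, "HbO", p_hbo), HbR = curve(v_hbr, "HbR", p_hbr))
}

#' @export
print.hrf_curve <- function(x, ...) {
  ext <- x$values[which.max(abs(x$values))]
  cat("HRF curve (model ", x$model_id, ", ", x$chromophore, "): ",
      length(x$time), " samples over ", max(x$time), " s, extremum ",
      signif(ext, 4), " umol/L at ", x$time[which.max(abs(x$values))],
      " s\n", sep = "")
  invisible(x)
}
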