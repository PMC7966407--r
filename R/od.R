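# Channel- and vertex-space time-series containers.

#' Channel-space optical-density time series
#'
#' Container for two-wavelength, multi-channel OD changes (base-e,
#' dimensionless). Values are stored as one channels x samples matrix per
#' wavelength; both blocks share the channel list and sample count.
#'
#' @param values Named list of channels x samples matrices, names =
#'   wavelengths in nm.
#' @param fs Sampling rate, Hz.
#' @param channels data.frame describing the channels (source, detector).
#' @return Object of class `od_timeseries`.
#' @export
od_timeseries <- function(values, fs, channels = NULL) {
  stopifnot(is.list(values), length(values) >= 1)
  values <- lapply(values, function(m) if (is.matrix(m)) m else matrix(m, nrow = 1))
  ns <- vapply(values, ncol, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all wavelength blocks must share the sample count")
  if (!all(vapply(values, function(m) all(is.finite(m)), logical(1))))
    stop("OD values must be finite")
  assert_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  structure(list(values = values, fs = fs, channels = channels,
                 wavelengths = as.numeric(names(values))),
            class = "od_timeseries")
}

#' @export
print.od_timeseries <- function(x, ...) {
  cat("OD time series:", nrow(x$values[[1]]), "channels x",
      ncol(x$values[[1]]), "samples per wavelength (",
      paste(names(x$values), collapse = "/"), "nm ) at", x$fs, "Hz\n")
  invisible(x)
}

n_samples <- function(od) ncol(od$values[[1]])

# elementwise arithmetic over the wavelength blocks
od_map2 <- function(a, b, f) {
  stopifnot(identical(names(a$values), names(b$values)))
  vals <- Map(f, a$values, b$values)
  od_timeseries(vals, fs = a$fs, channels = a$channels)
}

od_scale <- function(a, k) {
  od_timeseries(lapply(a$values, function(m) k * m), fs = a$fs,
                channels = a$channels)
}

#' Vertex-space time series on the cortical surface
#'
#' @param values vertices x samples matrix.
#' @param quantity One of `"mua"` (absorption change, 1/cm), `"HbO"` or
#'   `"HbR"` (concentration change, umol/L).
#' @param fs Sampling rate, Hz.
#' @return Object of class `surface_timeseries`.
#' @export
surface_timeseries <- function(values, quantity = c("mua", "HbO", "HbR"),
                               fs = 5) {
  quantity <- match.arg(quantity)
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(list(values = values, quantity = quantity, fs = fs),
            class = "surface_timeseries")
}

#' @export
print.surface_timeseries <- function(x, ...) {
  cat("Surface time series (", x$quantity, "): ", nrow(x$values),
      " vertices x ", ncol(x$values), " samples at ", x$fs, " Hz\n", sep = "")
  invisible(x)
}
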