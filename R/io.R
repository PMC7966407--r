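# File I/O: ascii PLY meshes, CSV matrices with JSON sidecars, minimal
# SNIRF export, and the artifact-directory pipeline runner.

#' Write a toy surface as ascii PLY plus a JSON manifest
#'
#' The PLY holds the cortical vertices and faces; the JSON manifest
#' (same basename, `.json`) stores the ROI vertex list, the scalp offset
#' and the generating parameters.
#'
#' @param surface A `nirs_surface`.
#' @param path Output `.ply` path.
#' @export
write_surface_ply <- function(surface, path) {
  stopifnot(inherits(surface, "nirs_surface"))
  v <- surface$vertices
  f <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(v)),
    "property float x", "property float y", "property float z",
    paste("element face", nrow(f)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  utils::write.table(format(v, digits = 8, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  manifest <- list(roi_vertices = surface$roi,
                   scalp_offset_mm = surface$scalp_offset_mm,
                   sphere_radius_mm = surface$sphere_radius_mm,
                   roi_radius_mm = surface$roi_radius_mm,
                   seed = surface$seed)
  jsonlite::write_json(manifest, sub("\\.ply$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a toy surface written by [write_surface_ply()]
#'
#' @param path `.ply` path (the `.json` manifest must sit next to it).
#' @return A `nirs_surface` (scalp rebuilt from the manifest offset).
#' @export
read_surface_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 lines, value = TRUE)))
  body <- which(lines == "end_header") + 1L
  v <- do.call(rbind, lapply(lines[body:(body + nv - 1L)],
                             function(l) as.numeric(strsplit(l, " ")[[1]])))
  colnames(v) <- c("x", "y", "z")
  f <- do.call(rbind, lapply(lines[(body + nv):(body + nv + nf - 1L)],
                             function(l) as.integer(strsplit(l, " ")[[1]])[-1] + 1L))
  man <- jsonlite::read_json(sub("\\.ply$", ".json", path),
                             simplifyVector = TRUE)
  R <- man$sphere_radius_mm
  structure(list(
    vertices = v, faces = f,
    scalp = v * (R + man$scalp_offset_mm) / R,
    roi = man$roi_vertices, roi_radius_mm = man$roi_radius_mm,
    sphere_radius_mm = R, scalp_offset_mm = man$scalp_offset_mm,
    seed = man$seed, degenerate_roi = length(man$roi_vertices) < 5
  ), class = "nirs_surface")
}

#' Write an OD time series as per-wavelength CSVs with a JSON sidecar
#'
#' @param od An `od_timeseries`.
#' @param stem Output path stem; files `<stem>_<wavelength>.csv` and
#'   `<stem>.json` are produced.
#' @export
write_od_csv <- function(od, stem) {
  stopifnot(inherits(od, "od_timeseries"))
  for (w in names(od$values)) {
    utils::write.table(od$values[[w]], paste0(stem, "_", w, ".csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  side <- list(fs = od$fs, wavelengths = od$wavelengths,
               n_channels = nrow(od$values[[1]]),
               n_samples = ncol(od$values[[1]]),
               channels = od$channels)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(stem)
}

#' Read an OD time series written by [write_od_csv()]
#'
#' @param stem Path stem used at write time.
#' @return An `od_timeseries`.
#' @export
read_od_csv <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  vals <- lapply(as.character(side$wavelengths), function(w) {
    as.matrix(utils::read.table(paste0(stem, "_", w, ".csv"), sep = ","))
  })
  vals <- lapply(vals, function(m) { dimnames(m) <- NULL; m })
  names(vals) <- as.character(side$wavelengths)
  ch <- if (!is.null(side$channels)) as.data.frame(side$channels) else NULL
  od_timeseries(vals, fs = side$fs, channels = ch)
}

#' Write a surface time series as CSV with a JSON sidecar
#'
#' @param ts A `surface_timeseries`.
#' @param stem Output path stem; `<stem>.csv` (vertices x samples) and
#'   `<stem>.json` are produced.
#' @export
write_surface_csv <- function(ts, stem) {
  stopifnot(inherits(ts, "surface_timeseries"))
  utils::write.table(ts$values, paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(quantity = ts$quantity, fs = ts$fs,
                            n_vertices = nrow(ts$values),
                            n_samples = ncol(ts$values)),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a surface time series written by [write_surface_csv()]
#'
#' @param stem Path stem used at write time.
#' @return A `surface_timeseries`.
#' @export
read_surface_csv <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(stem, ".csv"), sep = ","))
  dimnames(m) <- NULL
  surface_timeseries(m, side$quantity, fs = side$fs)
}

#' Export channel data to a minimal SNIRF (HDF5) file
#'
#' Writes `/formatVersion`, `/nirs/data1` (`dataTimeSeries`, `time`,
#' per-channel `measurementList`) and `/nirs/probe` (source/detector
#' positions, wavelengths). The HDF5 write is delegated to the Python
#' interpreter on the PATH (h5py), since the package itself has no HDF5
#' binding; an informative error is raised when none is available.
#'
#' @param od An `od_timeseries`.
#' @param montage A `nirs_montage` with matching channel table.
#' @param path Output `.snirf` path.
#' @export
export_snirf <- function(od, montage, path) {
  stopifnot(inherits(od, "od_timeseries"), inherits(montage, "nirs_montage"))
  if (!identical(nrow(od$values[[1]]), nrow(montage$channels)))
    stop("channel count of the OD data does not match the montage")
  py <- Sys.which("python")
  if (py == "") stop("no python interpreter on PATH for the HDF5 write")

  tmp <- tempfile(fileext = ".json")
  N <- n_samples(od)
  payload <- list(
    path = path,
    time = (seq_len(N) - 1) / od$fs,
    data = do.call(rbind, od$values),   # (2P) x N, wavelength blocks
    source_pos = montage$sources, detector_pos = montage$detectors,
    wavelengths = as.numeric(names(od$values)),
    source_idx = montage$channels$source,
    detector_idx = montage$channels$detector
  )
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "snirf_io.py", package = "nirsdot")
  status <- system2(py, c(script, "write", shQuote(tmp)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("SNIRF export failed:\n", paste(status, collapse = "\n"))
  invisible(path)
}

#' Read back a SNIRF file written by [export_snirf()]
#'
#' @param path `.snirf` path.
#' @return List with `data` ((2P) x N matrix), `time`, `wavelengths`.
#' @export
read_snirf <- function(path) {
  py <- Sys.which("python")
  if (py == "") stop("no python interpreter on PATH for the HDF5 read")
  tmp <- tempfile(fileext = ".json")
  script <- system.file("python", "snirf_io.py", package = "nirsdot")
  status <- system2(py, c(script, "read", shQuote(path), shQuote(tmp)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("SNIRF read failed:\n", paste(status, collapse = "\n"))
  out <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  out$data <- as.matrix(out$data)
  dimnames(out$data) <- NULL
  out
}

#' Run the full pipeline from a configuration and write artifacts
#'
#' Executes simulate -> ReML -> deconvolution maps -> metrics and writes
#' every stage's output (CSV/JSON) plus a provenance log into `out_dir`.
#' Outputs are deterministic for a fixed config seed.
#'
#' @param cfg A `nirs_config` (see [default_config()], [load_config()]).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list of stage results.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(out_dir, "pipeline_log.txt")
  say <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                           "\n", file = log, append = TRUE)
  say("pipeline start; seed", cfg$seed)

  st <- sweep_setup(seed = cfg$seed, n_vertices = cfg$n_vertices,
                    roi_radius_mm = cfg$roi_radius_mm,
                    n_sources = cfg$n_sources, n_detectors = cfg$n_detectors,
                    decay_scale_mm = cfg$decay_scale_mm)
  write_surface_ply(st$surface, file.path(out_dir, "surface.ply"))
  paradigm <- generate_paradigm(cfg$n_trials, cfg$trial_duration,
                                cfg$iti_range, cfg$run_length, cfg$fs,
                                seed = cfg$seed)
  utils::write.csv(data.frame(onset_s = paradigm$onsets,
                              duration_s = paradigm$durations),
                   file.path(out_dir, "paradigm.csv"), row.names = FALSE)
  say("simulating model", cfg$model_id, "at", cfg$snr_db, "dB")
  sim <- simulate_dataset(st$surface, st$montage, st$sens, cfg$model_id,
                          paradigm, target_snr_db = cfg$snr_db,
                          seed = cfg$seed + 1)
  write_od_csv(sim$od_sim, file.path(out_dir, "od_sim"))

  say("reconstructing and deconvolving")
  ev <- evaluate_dataset(sim, st$sens, cov_window = cfg$cov_window,
                         alpha = cfg$alpha, window = cfg$window,
                         drift_cutoff_hz = cfg$drift_cutoff_hz)
  for (chrom in names(ev$map$chromophores)) {
    r <- ev$map$chromophores[[chrom]]
    utils::write.csv(
      data.frame(vertex = ev$map$fov, F = r$F, p = r$p,
                 significant = r$significant, effect_size = r$effect_size),
      file.path(out_dir, paste0("fmap_", chrom, ".csv")), row.names = FALSE)
    utils::write.table(r$beta_h,
      file.path(out_dir, paste0("hrf_", chrom, ".csv")), sep = ",",
      row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(ev$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(cfg), tau = sim$tau,
         best_channel = sim$best_channel,
         h1 = as.list(ev$reml$h1), h2 = as.list(ev$reml$h2),
         reml_converged = as.list(ev$reml$converged),
         F_threshold = ev$map$chromophores$HbO$F_threshold,
         fov_size = length(ev$map$fov),
         version = as.character(utils::packageVersion("nirsdot"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  say("pipeline done")
  invisible(list(setup = st, sim = sim, evaluation = ev))
}
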