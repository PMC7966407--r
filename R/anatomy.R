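# Toy cortical anatomy, optode montages and synthetic sensitivity profiles.
#
# These stand in for the subject-specific head models used in practice
# (T1-MRI segmentation, Monte Carlo photon transport and optimal-montage
# solvers are deliberately out of scope): the surface is a spherical-cap
# cortical patch with an offset scalp shell, optodes are placed greedily
# near the region of interest under the standard source-detector separation
# constraints, and channel sensitivities follow a parametric exponential
# "banana" profile that reproduces the qualitative structure of photon-path
# sensitivity maps (localized, overlapping, severely ill-conditioned).

#' Generate a toy cortical surface patch with a scalp shell and an ROI
#'
#' Builds a curved open cortical surface (a spherical cap tessellated in
#' concentric rings), a scalp surface obtained by pushing every vertex
#' outwards along its radial normal, and a contiguous region of interest
#' (ROI) analogous to a functionally defined cortical target such as the
#' motor "hand knob".
#'
#' @param n_vertices Approximate number of cortical vertices (>= 50).
#' @param roi_radius_mm Geodesic-ball radius (mm) of the ROI around the
#'   patch apex.
#' @param sphere_radius_mm Radius (mm) of the sphere the cortical patch
#'   lies on. Default 70 mm, a plausible adult cortical-shell radius.
#' @param cap_angle_deg Half-opening angle of the cap in degrees.
#' @param scalp_offset_mm Radial scalp-cortex distance (mm), >= 10.
#' @param jitter Fractional tangential jitter of interior vertices
#'   (breaks the exact ring symmetry; 0 disables).
#' @param seed Integer seed; the construction is deterministic per seed.
#'
#' @return An object of class `nirs_surface`: list with `vertices` (V x 3,
#'   mm), `faces` (F x 3, 1-based), `scalp` (V x 3, mm), `roi`
#'   (vertex indices), plus the generating parameters.
#' @export
generate_toy_anatomy <- function(n_vertices = 300, roi_radius_mm = 12,
                                 sphere_radius_mm = 70, cap_angle_deg = 60,
                                 scalp_offset_mm = 12, jitter = 0.25,
                                 seed = 1) {
  assert_scalar_number(n_vertices, "n_vertices", lower = 50)
  assert_scalar_number(roi_radius_mm, "roi_radius_mm", lower = 0, strict_lower = TRUE)
  assert_scalar_number(sphere_radius_mm, "sphere_radius_mm", lower = 10)
  assert_scalar_number(scalp_offset_mm, "scalp_offset_mm", lower = 10)
  R <- sphere_radius_mm
  cap <- cap_angle_deg * pi / 180

  # ring layout: spacing chosen so the cap holds ~n_vertices vertices
  area <- 2 * pi * R^2 * (1 - cos(cap))
  spacing <- sqrt(area / n_vertices)
  n_rings <- max(3L, round(R * cap / spacing))
  dtheta <- cap / n_rings

  theta <- c(0)
  phi <- c(0)
  ring_id <- c(0L)
  for (k in seq_len(n_rings)) {
    tk <- k * dtheta
    nk <- max(6L, round(2 * pi * R * sin(tk) / spacing))
    theta <- c(theta, rep(tk, nk))
    phi <- c(phi, 2 * pi * (seq_len(nk) - 1) / nk)
    ring_id <- c(ring_id, rep(k, nk))
  }

  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  interior <- ring_id > 0L & ring_id < n_rings
  phi[interior] <- phi[interior] +
    jitter * dtheta * stats::runif(sum(interior), -1, 1)
  theta[interior] <- pmax(dtheta * 0.4, theta[interior] +
    jitter * dtheta * stats::runif(sum(interior), -1, 1))

  vertices <- cbind(
    R * sin(theta) * cos(phi),
    R * sin(theta) * sin(phi),
    R * cos(theta)
  )
  colnames(vertices) <- c("x", "y", "z")

  faces <- cap_triangulate(ring_id, phi)
  stopifnot(all(faces >= 1), all(faces <= nrow(vertices)))

  scalp <- vertices * (R + scalp_offset_mm) / R

  apex <- which.max(vertices[, "z"])
  droi <- dist_to_rows(vertices[apex, ], vertices)
  roi <- which(droi <= roi_radius_mm)
  degenerate_roi <- length(roi) < 5L
  if (degenerate_roi)
    warning("ROI of fewer than 5 vertices: radius ", roi_radius_mm,
            " mm is degenerate at this mesh resolution")

  structure(list(
    vertices = vertices, faces = faces, scalp = scalp,
    roi = roi, roi_radius_mm = roi_radius_mm,
    sphere_radius_mm = R, cap_angle_deg = cap_angle_deg,
    scalp_offset_mm = scalp_offset_mm, seed = seed,
    spacing_mm = spacing, degenerate_roi = degenerate_roi
  ), class = "nirs_surface")
}

# Triangulate concentric rings: fan around the apex, strips between rings.
cap_triangulate <- function(ring_id, phi) {
  faces <- list()
  rings <- split(seq_along(ring_id), ring_id)
  # apex fan
  r1 <- rings[["1"]]
  n1 <- length(r1)
  for (i in seq_len(n1))
    faces[[length(faces) + 1L]] <- c(1L, r1[i], r1[i %% n1 + 1L])
  # strips
  n_rings <- max(ring_id)
  for (k in seq_len(n_rings - 1L)) {
    a <- rings[[as.character(k)]]
    b <- rings[[as.character(k + 1L)]]
    pa <- phi[a]; pb <- phi[b]
    na <- length(a); nb <- length(b)
    # walk the outer ring, connect each outer edge to the nearest inner vertex
    for (j in seq_len(nb)) {
      j2 <- j %% nb + 1L
      ia <- which.min(pmin(abs(pa - pb[j]), 2 * pi - abs(pa - pb[j])))
      ia2 <- which.min(pmin(abs(pa - pb[j2]), 2 * pi - abs(pa - pb[j2])))
      faces[[length(faces) + 1L]] <- c(a[ia], b[j], b[j2])
      if (ia2 != ia) {
        faces[[length(faces) + 1L]] <- c(a[ia], b[j2], a[ia2])
      }
    }
  }
  fm <- do.call(rbind, faces)
  fm[!duplicated(t(apply(fm, 1, sort))), , drop = FALSE]
}

#' @export
print.nirs_surface <- function(x, ...) {
  cat("Toy cortical surface:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  cat("  ROI:", length(x$roi), "vertices (radius", x$roi_radius_mm, "mm)\n")
  cat("  scalp offset:", x$scalp_offset_mm, "mm\n")
  invisible(x)
}

#' Place an fNIRS montage near the ROI
#'
#' Greedy optode placement over the scalp vertex grid targeting the ROI
#' centroid: optodes are chosen closest (by scalp projection) to the ROI
#' while enforcing the standard constraints of continuous-wave fNIRS
#' montages: every source-detector channel separation within 2.5--3.5 cm,
#' a minimum optode-optode spacing of 2 cm, and every source measured by
#' at least two detectors.
#'
#' @param surface A `nirs_surface`.
#' @param n_sources,n_detectors Number of optodes (>= 1 source, >= 2
#'   detectors).
#' @param wavelengths Pair of wavelengths in nm.
#' @param seed Integer seed (tie-breaking jitter of candidate scores).
#'
#' @return An object of class `nirs_montage`: `sources`/`detectors`
#'   (positions, mm, on the scalp), `channels` (data.frame with
#'   `source`, `detector`, `separation_mm`, ordered lexicographically),
#'   `wavelengths`.
#' @export
generate_montage <- function(surface, n_sources = 4, n_detectors = 8,
                             wavelengths = c(685, 830), seed = 1) {
  stopifnot(inherits(surface, "nirs_surface"))
  assert_scalar_number(n_sources, "n_sources", lower = 1)
  assert_scalar_number(n_detectors, "n_detectors", lower = 2)
  if (length(wavelengths) != 2L)
    stop_config("exactly two wavelengths are required")

  sep_range <- c(25, 35)   # mm, channel separation window
  min_optode <- 20         # mm, optode density constraint

  scalp <- surface$scalp
  roi_centroid <- colMeans(surface$vertices[surface$roi, , drop = FALSE])
  # projection of the ROI centroid onto the scalp shell
  proj <- roi_centroid / sqrt(sum(roi_centroid^2)) *
    (surface$sphere_radius_mm + surface$scalp_offset_mm)
  score <- dist_to_rows(proj, scalp)
  set.seed(seed)
  score <- score + stats::runif(length(score), 0, 1e-6)
  order_idx <- order(score)

  sources <- integer(0)
  detectors <- integer(0)
  ok_spacing <- function(idx, placed) {
    if (length(placed) == 0L) return(TRUE)
    all(dist_to_rows(scalp[idx, ], scalp[placed, , drop = FALSE]) >= min_optode)
  }
  in_window <- function(idx, others) {
    if (length(others) == 0L) return(logical(0))
    d <- dist_to_rows(scalp[idx, ], scalp[others, , drop = FALSE])
    d >= sep_range[1] & d <= sep_range[2]
  }

  # Seed a source at the best scalp vertex, then fill greedily in score
  # order. A new source (after the seed) must already see two detectors in
  # the separation window; a new detector must see at least one source.
  for (idx in order_idx) {
    if (length(sources) == n_sources && length(detectors) == n_detectors)
      break
    placed <- c(sources, detectors)
    if (!ok_spacing(idx, placed)) next
    can_source <- length(sources) < n_sources &&
      (length(placed) == 0L || sum(in_window(idx, detectors)) >= 2L)
    can_detector <- length(detectors) < n_detectors &&
      length(sources) >= 1L && any(in_window(idx, sources))
    if (can_detector && (!can_source ||
        length(detectors) / n_detectors <= length(sources) / n_sources)) {
      detectors <- c(detectors, idx)
    } else if (can_source) {
      sources <- c(sources, idx)
    }
  }

  if (length(sources) < n_sources || length(detectors) < n_detectors)
    stop_config("montage infeasible: could not place ", n_sources,
                " sources and ", n_detectors, " detectors with separations in [",
                sep_range[1], ", ", sep_range[2], "] mm on this scalp")

  dmat <- cross_dist(scalp[sources, , drop = FALSE],
                     scalp[detectors, , drop = FALSE])
  pairs <- which(dmat >= sep_range[1] & dmat <= sep_range[2], arr.ind = TRUE)
  if (nrow(pairs) == 0L)
    stop_config("montage infeasible: no channel satisfies the separation window")
  channels <- data.frame(source = pairs[, 1], detector = pairs[, 2])
  channels <- channels[order(channels$source, channels$detector), , drop = FALSE]
  rownames(channels) <- NULL
  channels$separation_mm <- dmat[cbind(channels$source, channels$detector)]

  per_source <- table(factor(channels$source, levels = seq_along(sources)))
  if (any(per_source < 2))
    stop_config("montage infeasible: source(s) ",
                paste(which(per_source < 2), collapse = ", "),
                " measured by fewer than two detectors")

  structure(list(
    sources = scalp[sources, , drop = FALSE],
    detectors = scalp[detectors, , drop = FALSE],
    source_vertex = sources, detector_vertex = detectors,
    channels = channels, wavelengths = sort(wavelengths),
    separation_range_mm = sep_range, seed = seed
  ), class = "nirs_montage")
}

#' @export
print.nirs_montage <- function(x, ...) {
  cat("fNIRS montage:", nrow(x$sources), "sources,", nrow(x$detectors),
      "detectors,", nrow(x$channels), "channels\n")
  cat("  separations:", round(min(x$channels$separation_mm), 1), "-",
      round(max(x$channels$separation_mm), 1), "mm; wavelengths:",
      paste(x$wavelengths, collapse = "/"), "nm\n")
  invisible(x)
}

#' Synthetic channel-to-cortex sensitivity model
#'
#' Parametric stand-in for Monte Carlo photon-transport sensitivity maps:
#' the sensitivity of channel (s, d) at cortical vertex v is
#' `gain(lambda) * exp(-d_s(v)/decay) * exp(-d_d(v)/decay)`, with `d_s`,
#' `d_d` the distances (mm) from the vertex to the source and detector
#' scalp positions. This reproduces the banana-shaped, overlapping,
#' depth-penalized profiles of diffuse light propagation. The field of
#' view (FOV) collects all vertices whose best channel sensitivity reaches
#' a fraction (default 10%) of the global maximum; sub-threshold values
#' are retained in the matrix.
#'
#' @param surface A `nirs_surface`.
#' @param montage A `nirs_montage`.
#' @param decay_scale_mm Exponential decay scale (mm), > 0. Default 12 mm.
#' @param wavelength_gain Named numeric: per-wavelength multiplicative
#'   gain (the two wavelengths share the geometry and differ only by
#'   this factor).
#' @param fov_threshold_fraction FOV threshold as a fraction of the global
#'   maximum coefficient (default 0.1).
#'
#' @return Object of class `nirs_sensitivity`: `A` (named list of
#'   channels x vertices matrices, units cm so that `OD = A %*% mua` is
#'   dimensionless for `mua` in 1/cm), `fov` (vertex indices),
#'   `fov_threshold_fraction`, `channels`, `wavelengths`.
#' @export
compute_synthetic_sensitivity <- function(surface, montage,
                                          decay_scale_mm = 12,
                                          wavelength_gain = c("685" = 0.8, "830" = 1.0),
                                          fov_threshold_fraction = 0.1) {
  stopifnot(inherits(surface, "nirs_surface"), inherits(montage, "nirs_montage"))
  assert_scalar_number(decay_scale_mm, "decay_scale_mm", lower = 0, strict_lower = TRUE)
  assert_scalar_number(fov_threshold_fraction, "fov_threshold_fraction",
                       lower = 0, upper = 1)
  wl <- as.character(montage$wavelengths)
  if (!all(wl %in% names(wavelength_gain)))
    stop_config("wavelength_gain must name gains for ",
                paste(wl, collapse = " and "), " nm")

  V <- nrow(surface$vertices)
  ds <- cross_dist(montage$sources, surface$vertices)     # S x V
  dd <- cross_dist(montage$detectors, surface$vertices)   # D x V
  ch <- montage$channels
  base <- exp(-(ds[ch$source, , drop = FALSE] +
                dd[ch$detector, , drop = FALSE]) / decay_scale_mm)

  A <- lapply(wl, function(w) {
    m <- wavelength_gain[[w]] * base
    dimnames(m) <- NULL
    m
  })
  names(A) <- wl

  gmax <- max(vapply(A, max, numeric(1)))
  best <- do.call(pmax, lapply(A, function(m) apply(m, 2, max)))
  fov <- which(best >= fov_threshold_fraction * gmax)
  if (length(fov) == 0L)
    stop_config("empty field of view: increase decay_scale_mm")
  if (!any(surface$roi %in% fov))
    warning("no ROI vertex inside the field of view; the montage does not ",
            "cover the target")

  structure(list(
    A = A, fov = fov, fov_threshold_fraction = fov_threshold_fraction,
    channels = ch, wavelengths = montage$wavelengths,
    decay_scale_mm = decay_scale_mm, wavelength_gain = wavelength_gain,
    n_vertices = V
  ), class = "nirs_sensitivity")
}

#' Recompute the field of view from a sensitivity matrix
#'
#' @param sens A `nirs_sensitivity`.
#' @return Integer vertex indices whose best channel sensitivity reaches
#'   the stored fraction of the global maximum.
#' @export
recompute_fov <- function(sens) {
  stopifnot(inherits(sens, "nirs_sensitivity"))
  gmax <- max(vapply(sens$A, max, numeric(1)))
  best <- do.call(pmax, lapply(sens$A, function(m) apply(m, 2, max)))
  which(best >= sens$fov_threshold_fraction * gmax)
}

#' Apply the linear forward model
#'
#' Maps per-vertex absorption changes to channel optical-density changes,
#' `OD^lambda = A^lambda %*% mua^lambda`, independently per wavelength.
#'
#' @param sens A `nirs_sensitivity`.
#' @param dmua Named list (per wavelength) of vertices x samples matrices
#'   of absorption change (1/cm).
#' @return An `od_timeseries` (see [od_timeseries()]) with one
#'   channels x samples block per wavelength (dimensionless base-e OD).
#' @param fs Sampling rate in Hz attached to the output.
#' @export
forward_project <- function(sens, dmua, fs = 5) {
  stopifnot(inherits(sens, "nirs_sensitivity"))
  wl <- as.character(sens$wavelengths)
  if (!all(wl %in% names(dmua)))
    stop_config("dmua must be a named list with entries for ",
                paste(wl, collapse = " and "))
  vals <- lapply(wl, function(w) {
    m <- dmua[[w]]
    if (!is.matrix(m)) m <- matrix(m, ncol = 1)
    if (nrow(m) != ncol(sens$A[[w]]))
      stop("vertex dimension mismatch: A has ", ncol(sens$A[[w]]),
           " columns, dmua has ", nrow(m), " rows")
    sens$A[[w]] %*% m
  })
  names(vals) <- wl
  ns <- vapply(vals, ncol, integer(1))
  if (length(unique(ns)) != 1L)
    stop("wavelength blocks disagree in sample count")
  od_timeseries(vals, fs = fs, channels = sens$channels)
}
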