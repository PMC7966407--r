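test_that("toy anatomy is deterministic, curved, with contiguous ROI and offset scalp", {
  s1 <- generate_toy_anatomy(n_vertices = 200, roi_radius_mm = 10, seed = 1)
  s2 <- generate_toy_anatomy(n_vertices = 200, roi_radius_mm = 10, seed = 1)
  expect_identical(s1$vertices, s2$vertices)
  expect_identical(s1$roi, s2$roi)
  s3 <- generate_toy_anatomy(n_vertices = 200, roi_radius_mm = 10, seed = 2)
  expect_false(identical(s1$vertices, s3$vertices))

  expect_gte(nrow(s1$vertices), 50)
  expect_gte(length(s1$roi), 5)
  expect_true(all(s1$faces >= 1 & s1$faces <= nrow(s1$vertices)))
  # scalp strictly outside along the radial normal
  expect_true(all(sqrt(rowSums(s1$scalp^2)) - sqrt(rowSums(s1$vertices^2))
                  >= 10 - 1e-9))
  # ROI contiguity: every ROI vertex within one BFS step of the rest
  for (v in s1$roi)
    expect_lt(mesh_edge_distance(s1, setdiff(s1$roi, v), v), 2)
})

test_that("degenerate ROI radius is flagged, bad config errors", {
  expect_warning(generate_toy_anatomy(n_vertices = 200, roi_radius_mm = 0.001),
                 "degenerate")
  expect_error(generate_toy_anatomy(n_vertices = 10), "n_vertices")
  expect_error(generate_toy_anatomy(roi_radius_mm = 0), "roi_radius_mm")
})

test_that("montage honours separation and pair-density constraints", {
  st <- local_setup()
  mg <- st$montage
  expect_equal(nrow(mg$sources), 4)
  expect_equal(nrow(mg$detectors), 8)
  # every channel separation within 2.5-3.5 cm
  sep_cm <- mg$channels$separation_mm / 10
  expect_true(all(sep_cm >= 2.5 & sep_cm <= 3.5))
  # recompute separations from positions
  d <- sqrt(rowSums((mg$sources[mg$channels$source, , drop = FALSE] -
                     mg$detectors[mg$channels$detector, , drop = FALSE])^2))
  expect_equal(d, mg$channels$separation_mm, tolerance = 1e-12)
  # every source in >= 2 channels, no duplicate channels
  expect_true(all(table(mg$channels$source) >= 2))
  expect_false(any(duplicated(mg$channels[, c("source", "detector")])))
  # channel ordering is lexicographic
  expect_false(is.unsorted(order(mg$channels$source, mg$channels$detector)))
})

test_that("minimal montage has two channels sharing the source; infeasible cases error", {
  surface <- generate_toy_anatomy(seed = 4)
  mg <- generate_montage(surface, n_sources = 1, n_detectors = 2, seed = 4)
  expect_equal(nrow(mg$channels), 2)
  expect_true(all(mg$channels$source == 1))
  expect_error(generate_montage(surface, n_sources = 4, n_detectors = 1),
               "n_detectors")
  # a tiny scalp cannot host 8 sources and 16 detectors at 2 cm spacing
  small <- generate_toy_anatomy(n_vertices = 60, sphere_radius_mm = 30,
                                cap_angle_deg = 30, seed = 1)
  expect_error(generate_montage(small, n_sources = 8, n_detectors = 16),
               "infeasible")
})

test_that("sensitivity is nonnegative, symmetric in optodes, peaked between them", {
  st <- local_setup()
  sens <- st$sens
  A <- sens$A
  expect_true(all(A[["685"]] >= 0) && all(A[["830"]] >= 0))
  # two wavelengths differ only by the gain ratio
  ratio <- sens$wavelength_gain[["685"]] / sens$wavelength_gain[["830"]]
  expect_equal(A[["685"]], ratio * A[["830"]], tolerance = 1e-12)

  # brute-force check: the channel row maximum lies near the midpoint of
  # the optode scalp projections (closer to it than to either optode)
  mg <- st$montage
  for (c_idx in c(1, nrow(mg$channels))) {
    src <- mg$sources[mg$channels$source[c_idx], ]
    det <- mg$detectors[mg$channels$detector[c_idx], ]
    v <- st$surface$vertices[which.max(A[["830"]][c_idx, ]), ]
    mid <- (src + det) / 2
    expect_lt(sqrt(sum((v - mid)^2)),
              max(sqrt(sum((v - src)^2)), sqrt(sum((v - det)^2))))
  }

  # symmetry: swapping source and detector positions leaves the channel
  # sensitivity unchanged (the profile depends on the unordered pair)
  surf <- st$surface
  d1 <- dist_fun <- function(p) sqrt(colSums((t(surf$vertices) - p)^2))
  src <- mg$sources[1, ]; det <- mg$detectors[1, ]
  prof_ab <- exp(-(d1(src) + d1(det)) / sens$decay_scale_mm)
  prof_ba <- exp(-(d1(det) + d1(src)) / sens$decay_scale_mm)
  expect_identical(prof_ab, prof_ba)
})

test_that("FOV recomputation reproduces the stored set; thresholds behave", {
  st <- local_setup()
  expect_identical(recompute_fov(st$sens), st$sens$fov)
  expect_true(any(st$surface$roi %in% st$sens$fov))
  # FOV definition: vertices whose best sensitivity < fraction*max excluded
  sens <- st$sens
  gmax <- max(sapply(sens$A, max))
  best <- do.call(pmax, lapply(sens$A, function(m) apply(m, 2, max)))
  expect_setequal(sens$fov, which(best >= 0.1 * gmax))
  # infinite decay: uniform sensitivity, every vertex in the FOV
  flat <- compute_synthetic_sensitivity(st$surface, st$montage,
                                        decay_scale_mm = 1e9)
  expect_equal(length(flat$fov), nrow(st$surface$vertices))
})

test_that("forward projection matches a loop oracle and is linear", {
  st <- local_setup()
  sens <- st$sens
  V <- sens$n_vertices
  set.seed(42)
  x <- matrix(rnorm(V * 3), V, 3)
  y <- matrix(rnorm(V * 3), V, 3)
  dm <- function(m) list("685" = m, "830" = m)

  od <- forward_project(sens, dm(x))
  # explicit loop-based oracle on a few channels/samples
  for (c_idx in c(1, 3)) for (t_idx in 1:3) {
    expect_equal(od$values[["830"]][c_idx, t_idx],
                 sum(sens$A[["830"]][c_idx, ] * x[, t_idx]),
                 tolerance = 1e-12)
  }
  # linearity to machine precision
  lhs <- forward_project(sens, dm(2.5 * x - 1.25 * y))
  rhs_x <- forward_project(sens, dm(x))
  rhs_y <- forward_project(sens, dm(y))
  for (w in c("685", "830"))
    expect_equal(lhs$values[[w]],
                 2.5 * rhs_x$values[[w]] - 1.25 * rhs_y$values[[w]],
                 tolerance = 1e-12)
  # zero in, zero out; unit impulse picks out a column of A
  od0 <- forward_project(sens, dm(matrix(0, V, 1)))
  expect_true(all(od0$values[["830"]] == 0))
  e <- matrix(0, V, 1); e[7] <- 1
  expect_equal(as.numeric(forward_project(sens, dm(e))$values[["830"]]),
               sens$A[["830"]][, 7], tolerance = 1e-15)
  # dimension mismatch errors
  expect_error(forward_project(sens, dm(matrix(0, V + 1, 2))), "mismatch")
})
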