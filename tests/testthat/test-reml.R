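test_that("channel covariance estimation: shrinkage, degeneracy, consistency", {
  set.seed(2)
  # white unit-variance channels converge to the identity
  od <- od_timeseries(list("685" = matrix(rnorm(4 * 2000), 4),
                           "830" = matrix(rnorm(4 * 2000), 4)), fs = 5)
  cc <- estimate_channel_covariance(od, window = c(0, 400), shrinkage = 0)
  expect_equal(diag(cc$C[["830"]]), rep(1, 4), tolerance = 0.15)
  expect_true(all(abs(cc$C[["830"]][upper.tri(diag(4))]) < 0.1))
  # full shrinkage is exactly diagonal
  cs <- estimate_channel_covariance(od, window = c(0, 400), shrinkage = 1)
  expect_true(all(cs$C[["685"]][upper.tri(diag(4))] == 0))
  # constant input: zero matrix, flagged degenerate
  odc <- od_timeseries(list("685" = matrix(1, 3, 500),
                            "830" = matrix(1, 3, 500)), fs = 5)
  cd <- estimate_channel_covariance(odc, window = c(0, 100))
  expect_true(cd$degenerate)
  expect_true(all(cd$C[["830"]] == 0))
  # too-short window errors
  expect_error(estimate_channel_covariance(od, window = c(0, 1)), "window")
})

test_that("frozen-hyperparameter ReML equals the Tikhonov closed form", {
  set.seed(7)
  P <- 6; V <- 25; N <- 40
  A <- matrix(abs(rnorm(P * V, sd = 0.5)), P, V)
  Y <- matrix(rnorm(P * N), P, N)
  sens <- structure(list(A = list("685" = 0.8 * A, "830" = A),
                         fov = seq_len(V), fov_threshold_fraction = 0.1,
                         channels = data.frame(source = seq_len(P)),
                         wavelengths = c(685, 830), n_vertices = V),
                    class = "nirs_sensitivity")
  od <- od_timeseries(list("685" = 0.8 * Y, "830" = Y), fs = 5)
  c1 <- structure(list(C = list("685" = diag(P), "830" = diag(P)),
                       window = c(0, 8), shrinkage = 0, degenerate = FALSE),
                  class = "nirs_noise_cov")
  h <- c(2.5, 0.7)
  res <- reml_reconstruct(od, sens, c1, hyperparameters = h)
  lambda <- h[1] / h[2]
  for (w in c("685", "830")) {
    Aw <- sens$A[[w]]
    oracle <- t(Aw) %*% solve(lambda * diag(P) + Aw %*% t(Aw),
                              od$values[[w]])
    expect_equal(res$dmua[[w]]$values, oracle, tolerance = 1e-8)
  }
  # linear in the data at fixed hyperparameters
  od2 <- od_timeseries(list("685" = matrix(rnorm(P * N), P),
                            "830" = matrix(rnorm(P * N), P)), fs = 5)
  od_sum <- nirsdot:::od_map2(od, od2, `+`)
  r1 <- reml_reconstruct(od, sens, c1, hyperparameters = h)
  r2 <- reml_reconstruct(od2, sens, c1, hyperparameters = h)
  r12 <- reml_reconstruct(od_sum, sens, c1, hyperparameters = h)
  expect_equal(r12$dmua[["830"]]$values,
               r1$dmua[["830"]]$values + r2$dmua[["830"]]$values,
               tolerance = 1e-10)
  # zero data give a zero reconstruction
  od0 <- od_timeseries(list("685" = matrix(0, P, 3), "830" = matrix(0, P, 3)),
                       fs = 5)
  r0 <- reml_reconstruct(od0, sens, c1, hyperparameters = h)
  expect_true(all(r0$dmua[["830"]]$values == 0))
})

test_that("free energy is monotone and the gradient vanishes at convergence", {
  set.seed(11)
  P <- 6; V <- 20; N <- 200
  A <- matrix(abs(rnorm(P * V, sd = 0.5)), P, V)
  X <- matrix(rnorm(V * N, sd = 0.5), V, N)
  Y <- A %*% X + matrix(rnorm(P * N, sd = 0.5), P, N)
  sens <- structure(list(A = list("685" = A, "830" = A),
                         fov = seq_len(V), fov_threshold_fraction = 0.1,
                         channels = data.frame(source = seq_len(P)),
                         wavelengths = c(685, 830), n_vertices = V),
                    class = "nirs_sensitivity")
  od <- od_timeseries(list("685" = Y, "830" = Y), fs = 5)
  c1 <- structure(list(C = list("685" = diag(P), "830" = diag(P)),
                       window = c(0, 40), shrinkage = 0, degenerate = FALSE),
                  class = "nirs_noise_cov")
  res <- reml_reconstruct(od, sens, c1, tol = 1e-10,
                          share_hyperparameters = FALSE)
  expect_true(all(res$converged))
  for (w in c("685", "830")) {
    trace <- res$free_energy[[w]]
    expect_true(all(diff(trace) >= -1e-8 * abs(trace[-length(trace)])))
    # gradient stationarity: tr((Sigma^-1 - Sigma^-1 S Sigma^-1) Q_i) ~ 0
    h <- c(res$h1[w], res$h2[w])
    S <- tcrossprod(od$values[[w]]) / N
    Sigma <- h[1] * diag(P) + h[2] * tcrossprod(A)
    Sinv <- solve(Sigma)
    M <- Sinv - Sinv %*% S %*% Sinv
    for (Q in list(diag(P), tcrossprod(A)))
      expect_lt(abs(sum(M * Q)), 1e-4)
  }
})

test_that("noise-free simulations are recovered in place and in time", {
  st <- local_setup()
  par <- generate_paradigm(seed = 7)
  sim <- simulate_dataset(st$surface, st$montage, st$sens, 1, par,
                          target_snr_db = 20, seed = 11)
  rest <- nirsdot:::od_scale(sim$noise, sim$tau)
  c1 <- estimate_channel_covariance(rest)
  res <- reml_reconstruct(sim$od_sim, st$sens, c1)
  mua_true <- hemoglobin_to_absorption(sim$ground_truth$hbo_series,
                                       sim$ground_truth$hbr_series)
  # ROI-mean reconstructed time course tracks the truth
  rec <- colMeans(res$dmua[["830"]]$values[st$surface$roi, ])
  expect_gt(cor(rec, mua_true[["830"]]), 0.99)
  # spatial peak at the first-lobe latency is on or next to the ROI
  ttp_idx <- which.min(abs((seq_along(rec) - 1) / par$fs - 6))
  peak_vertex <- which.max(abs(res$dmua[["830"]]$values[, ttp_idx]))
  expect_lte(mesh_edge_distance(st$surface, st$surface$roi, peak_vertex), 2)
  # hemoglobin conversion round-trips the reconstruction
  hb <- reml_to_hemoglobin(res)
  back <- hemoglobin_to_absorption(hb$HbO$values, hb$HbR$values)
  expect_equal(back[["830"]], res$dmua[["830"]]$values, tolerance = 1e-10)
})
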