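test_that("paradigm generation packs trials, is deterministic, flags infeasibility", {
  p <- generate_paradigm(seed = 7)
  expect_length(p$onsets, 30)
  expect_equal(sum(p$stimulus), 30)   # 200 ms trials occupy one 5 Hz sample
  expect_length(p$stimulus, 3000)
  expect_true(all(p$onsets + p$durations <= p$run_length))
  expect_identical(p$stimulus, generate_paradigm(seed = 7)$stimulus)
  expect_false(identical(p$onsets, generate_paradigm(seed = 8)$onsets))

  p1 <- generate_paradigm(n_trials = 1, seed = 1)
  expect_equal(sum(p1$stimulus), 1)
  expect_error(generate_paradigm(iti_range = c(60, 60), n_trials = 30,
                                 run_length = 600), "infeasible")
})

test_that("hemoglobin <-> absorption conversion round-trips and scales correctly", {
  expect_equal(hemoglobin_to_absorption(0, 0)[["685"]], 0)
  # pure HbO: the wavelength ratio equals the extinction ratio
  mua <- hemoglobin_to_absorption(1, 0)
  tab <- extinction_table("e")
  expect_equal(mua[["685"]] / mua[["830"]],
               tab$alpha_hbo[1] / tab$alpha_hbo[2], tolerance = 1e-12)
  # constructed case: pure 1 uM HbO recovers exactly
  hb <- absorption_to_hemoglobin(mua)
  expect_equal(hb$HbO, 1, tolerance = 1e-10)
  expect_equal(hb$HbR, 0, tolerance = 1e-10)
  # random round trip to 1e-10
  set.seed(1)
  dhbo <- rnorm(50); dhbr <- rnorm(50)
  back <- absorption_to_hemoglobin(hemoglobin_to_absorption(dhbo, dhbr))
  expect_equal(back$HbO, dhbo, tolerance = 1e-10)
  expect_equal(back$HbR, dhbr, tolerance = 1e-10)
  # extinction matrix is well-conditioned
  E <- nirsdot:::extinction_matrix()
  expect_lt(kappa(E, exact = TRUE), 100)
  expect_error(hemoglobin_to_absorption(1, 0, wavelengths = c(700, 830)),
               "700")
})

test_that("resting noise is seed-reproducible and stationary with the right spectrum", {
  n1 <- generate_resting_noise(4, 3000, seed = 5)
  expect_identical(n1, generate_resting_noise(4, 3000, seed = 5))
  expect_false(identical(n1, generate_resting_noise(4, 3000, seed = 6)))

  # PSD local maxima near the configured physiological frequencies
  long <- generate_resting_noise(1, 6000, fs = 5, seed = 2)
  sp <- spec.pgram(ts(as.numeric(long), frequency = 5), spans = 9,
                   plot = FALSE, taper = 0)
  peaks <- sp$freq[which(diff(sign(diff(sp$spec))) == -2) + 1]
  for (f0 in c(1.1, 0.25, 0.1))
    expect_true(any(abs(peaks - f0) < 0.05), label = paste("peak near", f0))

  # AR component alone has lag-1 autocorrelation ~ rho
  ar_only <- list(amps = c(cardiac = 0, respiratory = 0, mayer = 0),
                  white_sd = 0, shared_weight_range = c(0, 0))
  x <- as.numeric(generate_resting_noise(1, 3000, params = ar_only, seed = 3))
  expect_equal(acf(x, lag.max = 1, plot = FALSE)$acf[2], 0.8,
               tolerance = 0.05)

  # split-half stationarity
  y <- as.numeric(generate_resting_noise(1, 3000, seed = 4))
  expect_lt(var(y[1:1500]) / var(y[1501:3000]), 2)
  expect_gt(var(y[1:1500]) / var(y[1501:3000]), 0.5)
})

test_that("noise scaling hits the target SNR exactly and tau is monotone", {
  st <- local_setup()
  par <- generate_paradigm(seed = 7)
  sim <- simulate_dataset(st$surface, st$montage, st$sens, 1, par,
                          target_snr_db = -10, seed = 11)
  # self-consistency of the SNR definition
  expect_equal(compute_snr_db(sim$od_noise_free, sim$noise, sim$tau,
                              sim$best_channel), -10, tolerance = 1e-9)
  # decomposition od_sim = od_noise_free + tau * noise is exact
  for (w in c("685", "830"))
    expect_equal(sim$od_sim$values[[w]],
                 sim$od_noise_free$values[[w]] + sim$tau * sim$noise$values[[w]],
                 tolerance = 1e-12)

  # closed-form tau when signal and noise powers match on the best channel
  fake_sens <- structure(list(
    A = list("830" = matrix(c(1, 0, 0, 2), 2, 2)),
    n_vertices = 2, channels = data.frame(source = c(1, 1), detector = 1:2)
  ), class = "nirs_sensitivity")
  mk <- function(v) od_timeseries(list("685" = rbind(v, v), "830" = rbind(v, v)),
                                  fs = 5)
  sig <- mk(rep(c(1, -1), 50))
  ns <- mk(rep(c(-1, 1), 50))
  expect_equal(scale_noise_to_snr(sig, ns, 0, fake_sens, roi = 2)$tau, 1,
               tolerance = 1e-12)
  expect_equal(scale_noise_to_snr(sig, ns, -10, fake_sens, roi = 2)$tau,
               sqrt(10), tolerance = 1e-12)
  expect_error(scale_noise_to_snr(sig, mk(rep(0, 100)), 0, fake_sens, 2),
               "noise power")

  # tau decreases monotonically with the target SNR
  taus <- sapply(c(-20, -10, 0, 10), function(snr)
    scale_noise_to_snr(sig, ns, snr, fake_sens, roi = 2)$tau)
  expect_true(all(diff(taus) < 0))
})

test_that("simulated datasets carry ground truth and collapse to the clean signal at high SNR", {
  st <- local_setup()
  par <- generate_paradigm(seed = 7)
  sim <- simulate_dataset(st$surface, st$montage, st$sens, 1, par,
                          target_snr_db = 60, seed = 11)
  b <- sim$best_channel
  expect_gt(cor(sim$od_sim$values[["830"]][b, ],
                sim$od_noise_free$values[["830"]][b, ]), 0.99)
  # ROI time course is the stimulus convolved with the scaled HRF
  expect_equal(max(sim$ground_truth$hbo_series) > 0, TRUE)
  empty_roi <- st$surface
  empty_roi$roi <- integer(0)
  expect_error(simulate_dataset(empty_roi, st$montage, st$sens, 1, par, 0),
               "ROI")
})
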