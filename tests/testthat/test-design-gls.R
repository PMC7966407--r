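test_that("design matrix: drift count, Toeplitz structure, orthonormal drifts", {
  # M = 12 cosines below 0.01 Hz for a 10-min run at 5 Hz
  p <- generate_paradigm(seed = 7)
  d <- build_design_matrix(p, window = c(-5, 30), drift_cutoff_hz = 0.01)
  expect_equal(d$M, 12)
  expect_equal(d$K, 176)
  expect_equal(d$L, 188)

  # single event at sample 3 with k0=0, k1=2: ones at rows 3, 4, 5
  p1 <- structure(list(onsets = 0.4, durations = 0.2, run_length = 2,
                       fs = 5, stimulus = c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
                       n_trials = 1, seed = 1), class = "nirs_paradigm")
  d1 <- build_design_matrix(p1, window = c(0, 0.4), drift_cutoff_hz = 0.01)
  expect_equal(d1$K, 3)
  for (i in 1:3) expect_equal(which(d1$X[, i] == 1), 2 + i)

  # drift block Gram matrix is the identity
  G <- crossprod(d$X[, d$K + seq_len(d$M)])
  expect_equal(G, diag(d$M), tolerance = 1e-10)

  # bit-identical reproducibility
  expect_identical(d$X, build_design_matrix(p, window = c(-5, 30))$X)

  # eventless runs carry a rank warning
  p0 <- p; p0$stimulus <- numeric(length(p$stimulus))
  expect_warning(build_design_matrix(p0), "rank")
})

test_that("GLS equals OLS at rho 0 and whitened OLS at known rho", {
  set.seed(13)
  d <- small_design()
  N <- d$N
  y <- rnorm(N)
  # rho = 0: normal-equations oracle
  f0 <- fit_gls(y, d, rho = 0)
  beta_ols <- solve(crossprod(d$X), crossprod(d$X, y))
  expect_equal(f0$beta, as.numeric(beta_ols), tolerance = 1e-10)
  expect_equal(f0$sigma2, sum((y - d$X %*% beta_ols)^2) / N,
               tolerance = 1e-10)
  # rho = 0.7: dense-Omega oracle on the first 150 samples
  ds <- build_design_matrix(
    generate_paradigm(n_trials = 4, iti_range = c(2, 6), run_length = 30,
                      fs = 5, seed = 2), window = c(-1, 6))
  ys <- rnorm(ds$N)
  f7 <- fit_gls(ys, ds, rho = 0.7)
  Om <- dense_ar1(ds$N, 0.7)
  Oi <- solve(Om)
  beta_gls <- solve(t(ds$X) %*% Oi %*% ds$X, t(ds$X) %*% Oi %*% ys)
  expect_equal(f7$beta, as.numeric(beta_gls), tolerance = 1e-8)
  r <- ys - ds$X %*% beta_gls
  expect_equal(f7$sigma2, as.numeric(t(r) %*% Oi %*% r) / ds$N,
               tolerance = 1e-8)
  # F statistic against the explicit quadratic form
  Th <- solve(t(ds$X) %*% Oi %*% ds$X)[seq_len(ds$K), seq_len(ds$K)]
  bh <- as.numeric(beta_gls)[seq_len(ds$K)]
  Fo <- (ds$N - ds$L) / ds$N * (bh %*% solve(Th, bh)) / (ds$K * f7$sigma2)
  expect_equal(f7$F, as.numeric(Fo), tolerance = 1e-8)

  # perfect fit: zero variance, exact recovery
  beta_true <- rnorm(ds$L)
  fp <- fit_gls(as.numeric(ds$X %*% beta_true), ds, rho = 0.3)
  expect_equal(fp$beta, beta_true, tolerance = 1e-8)
  expect_lt(fp$sigma2, 1e-16)
})

test_that("AR(1) estimation is consistent and clipped", {
  set.seed(3)
  # white noise: near zero
  expect_lt(abs(estimate_ar1(rnorm(3000))$rho), 0.05)
  # AR(1) at 0.7: consistent
  x <- as.numeric(arima.sim(list(ar = 0.7), 3000))
  expect_equal(estimate_ar1(x)$rho, 0.7, tolerance = 0.05)
  # alternating sequence: clipped at -0.99
  expect_equal(estimate_ar1(rep(c(1, -1), 100))$rho, -0.99)
  # constant residuals: flagged degenerate with rho 0
  dg <- estimate_ar1(rep(2, 50))
  expect_true(dg$degenerate)
  expect_equal(dg$rho, 0)
  # matrix form agrees with the scalar form
  M <- cbind(x, rnorm(3000))
  expect_equal(unname(estimate_ar1(M)[1]), estimate_ar1(x)$rho, tolerance = 1e-12)
})

test_that("two-pass AR(1)-MLE recovers coefficients within GLS error", {
  set.seed(5)
  d <- small_design()
  beta_true <- c(evaluate_hrf(hrf_params(6, 5.2, gamma = 0), d$time),
                 rnorm(d$M, sd = 0.1))
  y_clean <- as.numeric(d$X %*% beta_true)
  # noise-free: exact recovery
  f <- deconvolve_ar1_mle(y_clean, d)
  expect_equal(f$beta, beta_true, tolerance = 1e-8)
  expect_lt(f$sigma2, 1e-16)
  # AR(1) noise: estimate close to truth, rho recovered
  y <- y_clean + 0.5 * as.numeric(arima.sim(list(ar = 0.5), d$N))
  f2 <- deconvolve_ar1_mle(y, d)
  expect_equal(f2$rho, 0.5, tolerance = 0.15)
  se <- sqrt(diag(solve(crossprod(d$X))) * f2$sigma2 * d$N / (d$N - d$L))
  expect_true(all(abs(f2$beta - beta_true) < 4 * se))
  # the multi-series engine agrees with the scalar path
  multi <- nirsdot:::ar1_mle_multi(d, cbind(y, y_clean))
  expect_equal(multi$beta[, 1], f2$beta, tolerance = 1e-10)
  expect_equal(multi$F[1], f2$F, tolerance = 1e-10)
})

test_that("partial F-test: zero coefficients, t^2 identity, scale invariance, null distribution", {
  set.seed(17)
  d <- small_design()
  # y in the drift span: FIR block estimated at ~0 gives F ~ 0
  y_drift <- as.numeric(d$X[, d$K + 1] * 3)
  f0 <- fit_gls(y_drift, d, rho = 0)
  expect_equal(f0$F, 0, tolerance = 1e-12)
  expect_equal(f0$p, 1, tolerance = 1e-10)

  # K = 1: F equals the squared t statistic from lm()
  p1 <- small_paradigm()
  d1 <- build_design_matrix(p1, window = c(0, 0))
  y <- rnorm(d1$N)
  f1 <- fit_gls(y, d1, rho = 0)
  lmfit <- summary(lm(y ~ 0 + d1$X))
  expect_equal(f1$F, lmfit$coefficients[1, "t value"]^2, tolerance = 1e-8)

  # F is invariant to positive rescaling of the data
  y2 <- rnorm(d$N)
  expect_equal(fit_gls(y2, d)$F, fit_gls(7.3 * y2, d)$F, tolerance = 1e-10)

  # null distribution: empirical F CDF consistent with F(K, N-L)
  Y <- matrix(rnorm(d$N * 400), d$N, 400)
  fits <- nirsdot:::ar1_mle_multi(d, Y)
  ks <- suppressWarnings(ks.test(fits$F, pf, d$K, d$N - d$L))
  expect_gt(ks$p.value, 0.01)

  # threshold reporting
  ft <- partial_f_test(fit_gls(y2, d), alpha = 0.05)
  expect_equal(ft$threshold, qf(0.95, d$K, d$N - d$L))
  # FIR windows that exhaust the degrees of freedom are rejected
  too_wide <- suppressWarnings(
    build_design_matrix(small_paradigm(), window = c(-5, 110)))
  expect_error(fit_gls(rnorm(too_wide$N), too_wide), "degrees of freedom")
})
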