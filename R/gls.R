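# AR(1) generalized least squares, two-pass maximum-likelihood
# deconvolution and the partial F-test.
#
# For AR(1) correlation Omega_ij = rho^|i-j|, the inverse is tridiagonal:
#   (1 - rho^2) Omega^{-1} has diagonal (1, 1+rho^2, ..., 1+rho^2, 1)
#   and off-diagonal -rho,
# so all GLS cross-products are assembled from three precomputed Gram
# pieces of the design (X'X, the lag-1 product, and the boundary rows) in
# O(L^2) per series. This makes fitting thousands of vertices/series
# against one design matrix cheap: the N x L products are shared, and
# only an L x L solve is per-series. The explicit whitening filter
# (first sample scaled by sqrt(1 - rho^2), then y_n - rho y_{n-1}) gives
# the identical estimator and is used as the reference in tests.

ar1_design_grams <- function(X) {
  N <- nrow(X)
  list(
    G0 = crossprod(X),
    G1 = crossprod(X[-N, , drop = FALSE], X[-1, , drop = FALSE]),
    x1 = X[1, ], xN = X[N, ], N = N
  )
}

# GLS normal equations for one rho: returns M = (1-rho^2) X'Omega^{-1}X
ar1_normal_matrix <- function(g, rho) {
  (1 + rho^2) * g$G0 - rho^2 * (tcrossprod(g$x1) + tcrossprod(g$xN)) -
    rho * (g$G1 + t(g$G1))
}

#' Fit many series against one design with per-series AR(1) coefficients
#'
#' Core engine shared by [fit_gls()], [deconvolve_ar1_mle()] and
#' [map_deconvolution()]. Computes, for every column of `Y`, the GLS
#' estimate, the ML variance, the partial F statistic over the K FIR
#' coefficients and its p-value.
#'
#' @param design A `nirs_design`.
#' @param Y N x V matrix (each column one series).
#' @param rho Numeric vector of length V (AR(1) coefficient per series).
#' @return List of per-series results: `beta` (L x V), `sigma2`, `F`,
#'   `p`, `dof`.
#' @export
ar1_gls_fit <- function(design, Y, rho) {
  stopifnot(inherits(design, "nirs_design"))
  X <- design$X
  N <- design$N; L <- design$L; K <- design$K
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  V <- ncol(Y)
  if (length(rho) == 1L) rho <- rep(rho, V)
  if (K >= N - L) stop("insufficient degrees of freedom: K >= N - L")

  g <- ar1_design_grams(X)
  C0 <- crossprod(X, Y)                                  # L x V
  C1a <- crossprod(X[-N, , drop = FALSE], Y[-1, , drop = FALSE])
  C1b <- crossprod(X[-1, , drop = FALSE], Y[-N, , drop = FALSE])
  yy <- colSums(Y^2)
  ylag <- colSums(Y[-N, , drop = FALSE] * Y[-1, , drop = FALSE])
  y1 <- Y[1, ]; yN <- Y[N, ]

  beta <- matrix(NA_real_, L, V)
  sigma2 <- Fstat <- pval <- numeric(V)
  for (j in seq_len(V)) {
    r <- rho[j]
    M <- ar1_normal_matrix(g, r)
    v <- (1 + r^2) * C0[, j] - r^2 * (g$x1 * y1[j] + g$xN * yN[j]) -
      r * (C1a[, j] + C1b[, j])
    q <- (1 + r^2) * yy[j] - r^2 * (y1[j]^2 + yN[j]^2) - 2 * r * ylag[j]
    Mc <- tryCatch(chol(M), error = function(e)
      stop("design matrix is rank deficient under GLS whitening"))
    b <- backsolve(Mc, forwardsolve(t(Mc), v))
    beta[, j] <- b
    rss_w <- max(q - sum(v * b), 0)               # (1-rho^2) * GLS RSS
    sigma2[j] <- rss_w / ((1 - r^2) * N)
    # partial F over the K FIR coefficients; the (1-rho^2) factors in
    # Theta_h and sigma2 cancel
    Minv <- chol2inv(Mc)
    Th <- Minv[seq_len(K), seq_len(K), drop = FALSE]
    bh <- b[seq_len(K)]
    quad <- sum(bh * solve(Th, bh))
    tol <- 1e-12 * max(q, .Machine$double.xmin)
    Fstat[j] <- if (rss_w > tol) {
      (N - L) * quad / (K * rss_w)
    } else if (quad > tol) Inf else 0   # perfect fit vs. all-zero block
    pval[j] <- stats::pf(Fstat[j], K, N - L, lower.tail = FALSE)
  }
  list(beta = beta, sigma2 = sigma2, F = Fstat, p = pval,
       dof = c(K, N - L), rho = rho)
}

#' Estimate an AR(1) coefficient from residuals
#'
#' Lag-1 Yule-Walker estimate (lag-1 autocovariance over lag-0), clipped
#' to (-0.99, 0.99). Constant residuals yield rho = 0 with a degeneracy
#' flag.
#'
#' @param residuals Numeric vector (length >= 3) or matrix (series in
#'   columns).
#' @return For a vector: list with `rho` and `degenerate`. For a matrix:
#'   numeric vector of rho per column.
#' @export
estimate_ar1 <- function(residuals) {
  if (is.matrix(residuals)) {
    N <- nrow(residuals)
    if (N < 3) stop("need at least 3 samples")
    E <- sweep(residuals, 2, colMeans(residuals))
    c0 <- colSums(E^2)
    c1 <- colSums(E[-N, , drop = FALSE] * E[-1, , drop = FALSE])
    rho <- ifelse(c0 > 0, c1 / c0, 0)
    return(pmin(pmax(rho, -0.99), 0.99))
  }
  if (length(residuals) < 3) stop("need at least 3 samples")
  e <- residuals - mean(residuals)
  c0 <- sum(e^2)
  if (c0 <= .Machine$double.eps * length(e)) {
    return(list(rho = 0, degenerate = TRUE))
  }
  c1 <- sum(e[-length(e)] * e[-1])
  list(rho = min(max(c1 / c0, -0.99), 0.99), degenerate = FALSE)
}

#' Generalized least squares with a known AR(1) coefficient
#'
#' @param y Numeric vector of length N.
#' @param design A `nirs_design`.
#' @param rho AR(1) coefficient in (-1, 1).
#' @return Object of class `nirs_glmfit`: `beta` (first K entries are
#'   the FIR HRF samples), `sigma2` (ML, 1/N normalization), `F`, `p`,
#'   `dof`, `residuals` (unwhitened), `rho`, plus the design geometry.
#' @export
fit_gls <- function(y, design, rho = 0) {
  stopifnot(inherits(design, "nirs_design"))
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  fit <- ar1_gls_fit(design, matrix(y, ncol = 1), rho)
  beta <- fit$beta[, 1]
  structure(list(
    beta = beta, sigma2 = fit$sigma2[1], F = fit$F[1], p = fit$p[1],
    dof = fit$dof, residuals = y - design$X %*% beta, rho = rho,
    K = design$K, M = design$M, k0 = design$k0, k1 = design$k1,
    fs = design$fs, N = design$N, L = design$L, time = design$time
  ), class = "nirs_glmfit")
}

#' Two-pass AR(1) maximum-likelihood deconvolution
#'
#' First pass: ordinary least squares (identity correlation). The AR(1)
#' coefficient is then estimated from the residuals by Yule-Walker, and
#' a second, generalized pass is run with the estimated coefficient.
#'
#' @param y Numeric vector.
#' @param design A `nirs_design`.
#' @return A `nirs_glmfit` (with `rho` the estimated coefficient).
#' @export
deconvolve_ar1_mle <- function(y, design) {
  ols <- fit_gls(y, design, rho = 0)
  rho <- estimate_ar1(as.numeric(ols$residuals))$rho
  fit_gls(y, design, rho = rho)
}

#' Partial F-test on the FIR coefficient block
#'
#' Tests that all K FIR (HRF) coefficients are jointly zero:
#' `F = (N - L)/N * (beta_h' Theta_h^{-1} beta_h) / (K sigma2_hat)`,
#' F-distributed with (K, N - L) degrees of freedom under the null; the
#' (N - L)/N factor converts the ML variance to the unbiased scale.
#'
#' @param fit A `nirs_glmfit`.
#' @param alpha Significance level for the reported threshold.
#' @return List with `F`, `p`, `dof`, `threshold` (the (1 - alpha)
#'   F quantile) and `significant`.
#' @export
partial_f_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "nirs_glmfit"))
  thr <- stats::qf(1 - alpha, fit$dof[1], fit$dof[2])
  list(F = fit$F, p = fit$p, dof = fit$dof, threshold = thr,
       significant = fit$F > thr)
}

#' @export
print.nirs_glmfit <- function(x, ...) {
  cat("FIR GLM fit: K =", x$K, ", M =", x$M, ", rho =", signif(x$rho, 3),
      "\n  F(", x$dof[1], ",", x$dof[2], ") =", signif(x$F, 4),
      ", p =", format.pval(x$p), "\n")
  invisible(x)
}

# Vectorized two-pass AR(1)-MLE over the columns of Y.
ar1_mle_multi <- function(design, Y) {
  X <- design$X
  qrX <- qr(X)
  B0 <- qr.coef(qrX, Y)
  resid <- Y - X %*% B0
  rho <- estimate_ar1(resid)
  ar1_gls_fit(design, Y, rho)
}
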