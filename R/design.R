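# FIR + discrete-cosine-drift design matrices.

#' Build the FIR + cosine-drift design matrix
#'
#' The first K columns are shifted copies of the binary stimulus vector
#' (Toeplitz structure with zero boundary conditions): column i models
#' the response coefficient at lag `k0 + i - 1` samples, so the FIR
#' window `[k0_s, k1_s]` may start before the stimulus (`k0 < 0`). The
#' last M columns are the orthonormal discrete-cosine drift basis
#'   d_1[n] = sqrt(1/N),
#'   d_m[n] = sqrt(2/N) cos(pi (2n+1)(m-1) / (2N)),  m >= 2,
#' keeping every cosine of frequency (m-1)/(2T) strictly below
#' `drift_cutoff_hz` (T = N/fs).
#'
#' @param paradigm A `nirs_paradigm`.
#' @param window Length-2 numeric `c(k0_s, k1_s)`: pre/post-stimulus FIR
#'   bounds in seconds. Default -5 to 30 s.
#' @param drift_cutoff_hz Drift cutoff frequency, Hz (default 0.01).
#' @return Object of class `nirs_design`: `X` (N x L), `K`, `M`, `k0`,
#'   `k1` (samples), `fs`, `time` (FIR lag grid, s), `rank_deficient`
#'   flag.
#' @export
build_design_matrix <- function(paradigm, window = c(-5, 30),
                                drift_cutoff_hz = 0.01) {
  stopifnot(inherits(paradigm, "nirs_paradigm"))
  assert_scalar_number(drift_cutoff_hz, "drift_cutoff_hz", lower = 0,
                       strict_lower = TRUE)
  fs <- paradigm$fs
  k0 <- round(window[1] * fs)
  k1 <- round(window[2] * fs)
  K <- k1 - k0 + 1
  if (K < 1) stop_config("FIR window must span at least one sample")
  s <- paradigm$stimulus
  N <- length(s)

  # FIR block: X[n, i] = s[n - (i + k0 - 1)] (1-based n)
  Xf <- matrix(0, N, K)
  for (i in seq_len(K)) {
    shift <- i + k0 - 1
    src <- seq_len(N) - shift
    ok <- src >= 1 & src <= N
    Xf[ok, i] <- s[src[ok]]
  }

  T_run <- N / fs
  M <- sum((seq_len(N) - 1) / (2 * T_run) < drift_cutoff_hz)
  n0 <- seq_len(N) - 1
  Xd <- vapply(seq_len(M), function(m) {
    if (m == 1) rep(sqrt(1 / N), N)
    else sqrt(2 / N) * cos(pi * (2 * n0 + 1) * (m - 1) / (2 * N))
  }, numeric(N))

  X <- cbind(Xf, Xd)
  rank_deficient <- qr(X)$rank < ncol(X)
  if (rank_deficient)
    warning("design matrix is rank deficient (e.g., no events in the run)")

  structure(list(X = X, K = K, M = M, k0 = k0, k1 = k1, fs = fs,
                 N = N, L = K + M, time = (k0:k1) / fs,
                 drift_cutoff_hz = drift_cutoff_hz,
                 rank_deficient = rank_deficient),
            class = "nirs_design")
}

#' @export
print.nirs_design <- function(x, ...) {
  cat("FIR design: N =", x$N, ", K =", x$K, "FIR lags (",
      x$time[1], "to", x$time[x$K], "s ), M =", x$M, "drift cosines\n")
  invisible(x)
}
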