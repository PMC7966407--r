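# Hierarchical ReML tomographic inverse.
#
# Per wavelength, the channel data y_t obey the two-level model
#   y_t = A x_t + e1,  e1 ~ N(0, h1 C1),   x_t ~ N(0, h2 C2),  C2 = I,
# so marginally y_t ~ N(0, Sigma), Sigma = h1 C1 + h2 A A'. The
# hyperparameters (h1, h2) are estimated once per run by maximizing the
# restricted log-likelihood / free energy of the temporal second-moment
# matrix S = (1/T) Y Y',
#   F(h) = -(T/2) [ log|Sigma| + tr(Sigma^{-1} S) ] + const,
# by Fisher scoring on log-hyperparameters (positivity by construction)
# with step-halving so F never decreases. The posterior mean map,
# x_hat_t = h2 A' Sigma^{-1} y_t, is the L2-minimum-norm / Tikhonov
# estimate with data-driven regularization h1/h2.

#' Estimate the channel noise covariance from a rest period
#'
#' Sample covariance over the window, shrunk toward its diagonal:
#' `(1 - s) C + s diag(C)`; positive semi-definiteness is preserved for
#' s in [0, 1].
#'
#' @param od_rest An `od_timeseries` of resting data.
#' @param window Length-2 numeric, start/end of the estimation window (s).
#' @param shrinkage Shrinkage weight in [0, 1].
#' @return Object of class `nirs_noise_cov`: list per wavelength of
#'   channels x channels matrices, plus the window and a `degenerate`
#'   flag (constant input).
#' @export
estimate_channel_covariance <- function(od_rest, window = c(0, 60),
                                        shrinkage = 0.1) {
  stopifnot(inherits(od_rest, "od_timeseries"))
  assert_scalar_number(shrinkage, "shrinkage", lower = 0, upper = 1)
  idx <- which((seq_len(n_samples(od_rest)) - 1) / od_rest$fs >= window[1] &
               (seq_len(n_samples(od_rest)) - 1) / od_rest$fs < window[2])
  n_ch <- nrow(od_rest$values[[1]])
  if (length(idx) < 2 * n_ch)
    stop_config("covariance window too short: ", length(idx),
                " samples for ", n_ch, " channels (need >= 2x)")
  degenerate <- FALSE
  C <- lapply(od_rest$values, function(m) {
    x <- t(m[, idx, drop = FALSE])
    cc <- stats::cov(x)
    if (all(abs(cc) < .Machine$double.eps * 100)) degenerate <<- TRUE
    (1 - shrinkage) * cc + shrinkage * diag(diag(cc), n_ch)
  })
  structure(list(C = C, window = window, shrinkage = shrinkage,
                 degenerate = degenerate),
            class = "nirs_noise_cov")
}

# Free energy (up to an additive constant) for one wavelength.
reml_free_energy <- function(h, C1, AAt, S, T) {
  Sigma <- h[1] * C1 + h[2] * AAt
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(list(F = -Inf))
  logdet <- 2 * sum(log(diag(R)))
  Sinv <- chol2inv(R)
  list(F = -(T / 2) * (logdet + sum(Sinv * S)), Sinv = Sinv)
}

#' ReML reconstruction of absorption changes on the cortical surface
#'
#' @param od An `od_timeseries` (both wavelengths).
#' @param sens A `nirs_sensitivity`.
#' @param c1 A `nirs_noise_cov` from [estimate_channel_covariance()].
#' @param max_iter Maximum Fisher-scoring iterations.
#' @param tol Relative free-energy convergence tolerance.
#' @param hyperparameters Optional fixed `c(h1, h2)`: skips estimation
#'   and applies the corresponding linear inverse directly.
#' @param share_hyperparameters Estimate one (h1, h2) pair jointly over
#'   both wavelength blocks (the fusion model; default) instead of
#'   independently per wavelength. Sharing keeps the two linear inverse
#'   operators on a common amplitude scale, which matters for the
#'   downstream spectral unmixing into HbO/HbR.
#' @return Object of class `nirs_reml`: per-wavelength `dmua`
#'   (`surface_timeseries`, 1/cm), hyperparameters `h1`/`h2`,
#'   `free_energy` traces, `iterations`, `converged`.
#' @export
reml_reconstruct <- function(od, sens, c1, max_iter = 128, tol = 1e-6,
                             hyperparameters = NULL,
                             share_hyperparameters = TRUE) {
  stopifnot(inherits(od, "od_timeseries"), inherits(sens, "nirs_sensitivity"),
            inherits(c1, "nirs_noise_cov"))
  wl <- as.character(sens$wavelengths)
  out <- list(dmua = list(), h1 = numeric(), h2 = numeric(),
              free_energy = list(), iterations = integer(),
              converged = logical())

  # per-wavelength model pieces; the fusion system is block diagonal so
  # the free energy is the sum of the two blocks' contributions
  blocks <- lapply(wl, function(w) {
    A <- sens$A[[w]]
    Y <- od$values[[w]]
    C1 <- c1$C[[w]]
    ev <- eigen(C1, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("C1 at ", w, " nm is not positive semi-definite")
    # tiny ridge keeps Sigma invertible if C1 is singular
    C1 <- C1 + diag(1e-10 * max(diag(C1), 1), nrow(C1))
    list(A = A, Y = Y, C1 = C1, AAt = tcrossprod(A),
         T = ncol(Y), S = tcrossprod(Y) / ncol(Y))
  })
  names(blocks) <- wl

  groups <- if (share_hyperparameters) list(fusion = wl)
            else as.list(stats::setNames(wl, wl))

  for (grp in groups) {
    bl <- blocks[grp]
    fe_all <- function(h) {
      parts <- lapply(bl, function(b)
        reml_free_energy(h, b$C1, b$AAt, b$S, b$T))
      list(F = sum(vapply(parts, `[[`, numeric(1), "F")), parts = parts)
    }

    if (!is.null(hyperparameters)) {
      h <- hyperparameters
      fe <- fe_all(h)
      trace <- fe$F
      iter <- 0L
      conv <- TRUE
    } else {
      h <- c(
        sum(vapply(bl, function(b) sum(diag(b$S)), numeric(1))) /
          sum(vapply(bl, function(b) sum(diag(b$C1)), numeric(1))),
        sum(vapply(bl, function(b) sum(diag(b$S)), numeric(1))) /
          sum(vapply(bl, function(b) sum(diag(b$AAt)), numeric(1)))
      )
      fe <- fe_all(h)
      trace <- fe$F
      conv <- FALSE
      iter <- 0L
      for (it in seq_len(max_iter)) {
        iter <- it
        g <- c(0, 0)
        H <- matrix(0, 2, 2)
        for (b_i in seq_along(bl)) {
          b <- bl[[b_i]]
          Sinv <- fe$parts[[b_i]]$Sinv
          Q <- list(b$C1, b$AAt)
          SinvS <- Sinv %*% b$S
          g <- g + vapply(1:2, function(i) {
            -(b$T / 2) * (sum(Sinv * Q[[i]]) -
                           sum((SinvS %*% Sinv) * Q[[i]])) * h[i]
          }, numeric(1))
          SQ <- lapply(Q, function(q) Sinv %*% q)
          for (i in 1:2) for (j in 1:2)
            H[i, j] <- H[i, j] +
              (b$T / 2) * sum(SQ[[i]] * t(SQ[[j]])) * h[i] * h[j]
        }
        step <- tryCatch(solve(H + diag(1e-8 * max(diag(H)), 2), g),
                         error = function(e) g / max(diag(H)))
        # step-halving: never decrease the free energy
        alpha <- 1
        repeat {
          h_new <- h * exp(pmax(pmin(alpha * step, 8), -8))
          fe_new <- fe_all(h_new)
          if (fe_new$F >= fe$F - 1e-8 * abs(fe$F) || alpha < 1e-4) break
          alpha <- alpha / 2
        }
        dF <- fe_new$F - fe$F
        h <- h_new
        fe <- fe_new
        trace <- c(trace, fe$F)
        if (abs(dF) < tol * abs(fe$F)) { conv <- TRUE; break }
      }
      if (!conv)
        warning("ReML (", paste(grp, collapse = "+"),
                " nm) did not converge in ", max_iter, " iterations")
    }

    for (b_i in seq_along(bl)) {
      w <- grp[b_i]
      b <- bl[[b_i]]
      X <- h[2] * crossprod(b$A, fe$parts[[b_i]]$Sinv %*% b$Y)
      out$dmua[[w]] <- surface_timeseries(X, "mua", fs = od$fs)
      out$h1[w] <- h[1]
      out$h2[w] <- h[2]
      out$free_energy[[w]] <- trace
      out$iterations[w] <- iter
      out$converged[w] <- conv
    }
  }
  out$dmua <- out$dmua[wl]
  structure(out, class = "nirs_reml")
}

#' @export
print.nirs_reml <- function(x, ...) {
  for (w in names(x$dmua)) {
    cat(w, "nm: h1 =", signif(x$h1[w], 4), ", h2 =", signif(x$h2[w], 4),
        ",", x$iterations[w], "iterations,",
        if (x$converged[w]) "converged" else "NOT converged", "\n")
  }
  invisible(x)
}

#' Convert a ReML reconstruction to hemoglobin surface time series
#'
#' @param reml A `nirs_reml`.
#' @return List of `surface_timeseries` objects `HbO` and `HbR` (umol/L).
#' @export
reml_to_hemoglobin <- function(reml) {
  stopifnot(inherits(reml, "nirs_reml"))
  wl <- names(reml$dmua)
  dmua <- lapply(reml$dmua, function(s) s$values)
  hb <- absorption_to_hemoglobin(dmua, wavelengths = as.numeric(wl))
  fs <- reml$dmua[[1]]$fs
  list(HbO = surface_timeseries(hb$HbO, "HbO", fs = fs),
       HbR = surface_timeseries(hb$HbR, "HbR", fs = fs))
}
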