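#' @keywords internal
"_PACKAGE"

# Internal validation helpers -------------------------------------------------

stop_config <- function(...) {
  stop(structure(
    class = c("nirsdot_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a finite numeric scalar")
  if (strict_lower && x <= lower)
    stop_config(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_config(name, " must be >= ", lower)
  if (x > upper)
    stop_config(name, " must be <= ", upper)
  invisible(x)
}

# Euclidean distances between one point and rows of a matrix (mm).
dist_to_rows <- function(p, m) {
  sqrt(colSums((t(m) - p)^2))
}

# Pairwise distances between rows of a and rows of b.
cross_dist <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
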