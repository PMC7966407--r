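# Shared fixtures, built once per test run.

# small default geometry used across tests
local_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sweep_setup(seed = 3)
    cache
  }
})

# short paradigm/design for fast GLM tests: 2-minute run at 5 Hz
small_paradigm <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_paradigm(n_trials = 8, trial_duration = 0.2,
                                  iti_range = c(2, 20), run_length = 120,
                                  fs = 5, seed = 11)
    cache
  }
})

small_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_design_matrix(small_paradigm(), window = c(-2, 12))
    cache
  }
})

# dense AR(1) correlation matrix, for the explicit-whitening oracle
dense_ar1 <- function(n, rho) rho^abs(outer(seq_len(n), seq_len(n), "-"))

# graph (edge-count) distance from a vertex set over the mesh faces
mesh_edge_distance <- function(surface, from_set, to_vertex) {
  edges <- rbind(surface$faces[, c(1, 2)], surface$faces[, c(2, 3)],
                 surface$faces[, c(1, 3)])
  nb <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  dist <- rep(Inf, nrow(surface$vertices))
  dist[from_set] <- 0
  frontier <- from_set
  d <- 0
  while (length(frontier) > 0 && is.infinite(dist[to_vertex])) {
    d <- d + 1
    frontier <- unique(unlist(nb[as.character(frontier)]))
    frontier <- frontier[is.infinite(dist[frontier])]
    dist[frontier] <- d
  }
  dist[to_vertex]
}
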