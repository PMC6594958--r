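# Small, fast configurations shared across test files.

small_volume_config <- function(...) {
  defaults <- list(
    volume_shape_um = c(300, 300, 140),
    n_tubules = 4,
    tubule_radius_um = 35,
    n_nests_per_class = c(Bright = 3, Mid = 2),
    nest_size_sampler = function(n) rep(4L, n),
    n_singletons = 4,
    n_autofluor_blobs = 2,
    noise_sd = 0.02)
  args <- defaults
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(volume_sim_config, args)
}

small_flow_config <- function(...) {
  defaults <- list(
    ages = c("P2", "P3"),
    subset_counts = list(
      P2 = c(Bright = 100, Mid = 100, Dim = 100, eGFPneg = 200,
             nongerm = 500),
      P3 = c(Bright = 420, Mid = 150, Dim = 120, eGFPneg = 200,
             nongerm = 500)),
    n_control = 1000L)
  args <- defaults
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(flow_sim_config, args)
}

small_counts_config <- function(...) {
  defaults <- list(
    n_cells = c(P6 = 400),
    n_genes = 200)
  args <- defaults
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(continuum_sim_config, args)
}

# Independent oracle: connected components of the <= cutoff graph by
# union-find over all pairs (no hclust involved).
brute_force_components <- function(dmat, cutoff) {
  n <- nrow(dmat)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (dmat[i, j] <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  # path-compress into canonical labels
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# TRUE when two labelings induce the same partition
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
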