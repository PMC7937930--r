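# Small fixtures shared across tests: meshes are built in code, never stored.

# Chain mesh v1-v2-...-vn with unit edges, realized as degenerate-free
# triangles by offsetting a parallel row of helper vertices.
chain_mesh <- function(n = 4) {
  coords <- rbind(cbind(seq_len(n) - 1, 0, 0),
                  cbind(seq_len(n) - 1, 1, 0))
  tri <- do.call(rbind, lapply(seq_len(n - 1), function(i)
    rbind(c(i, i + 1, n + i), c(i + 1, n + i + 1, n + i))))
  cortical_mesh(coords, tri)
}

# Regular unit-spaced triangulated grid via the synthetic patch generator.
grid_mesh <- function(n_rows, n_cols, edge_mm = 1) {
  make_visuotopic_patch(n_rows, n_cols, edge_mm = edge_mm)$mesh
}

# Independent all-pairs shortest-path oracle (Floyd-Warshall) on the mesh
# edge graph, coded without igraph.
floyd_warshall <- function(mesh) {
  n <- mesh$n_vertices
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  tri <- mesh$triangles
  edges <- unique(rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)]))
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    len <- sqrt(sum((mesh$coords[i, ] - mesh$coords[j, ])^2))
    D[i, j] <- min(D[i, j], len)
    D[j, i] <- D[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    upd <- D[i, k] + D[k, ]
    better <- upd < D[i, ]
    D[i, better] <- upd[better]
  }
  D
}

# Small coupled scene: returns experiment list from make_two_scan_experiment
# with every true (center, sigma) on the supplied grid.
small_scene <- function(seed, n_rows = 7, n_source_cols = 7, n_target_cols = 2,
                        n_timepoints = 60, noise_sd = 1,
                        sigma_choices = default_sigma_grid()[c(10, 12, 14)],
                        spatial_corr_mm = 3, beta = 1) {
  make_two_scan_experiment(
    synthetic_scene_config(n_rows = n_rows, n_source_cols = n_source_cols,
                           n_target_cols = n_target_cols,
                           n_timepoints = n_timepoints, noise_sd = noise_sd,
                           sigma_choices_mm = sigma_choices,
                           spatial_corr_mm = spatial_corr_mm, beta = beta),
    seed = seed)
}

# Brute-force connective-field enumerator, independent of fit_cf_grid's
# vectorized path: explicit loops, kernel and OLS recomputed from scratch.
brute_force_cf <- function(mesh, source_roi, source_block, y, sigma_grid) {
  S <- source_block$values[match(source_roi$vertex_ids,
                                 source_block$vertex_ids), , drop = FALSE]
  best <- NULL
  for (sg in sigma_grid) for (ci in source_roi$vertex_ids) {
    d <- geodesic_distances(mesh, ci, source_roi$vertex_ids)
    w <- exp(-d^2 / (2 * sg^2))
    w <- w / sum(w)
    p <- as.numeric(w %*% S)
    beta <- sum(p * y) / sum(p^2)
    ve <- 1 - sum((y - beta * p)^2) / sum(y^2)
    if (is.null(best) || ve > best$ve)
      best <- list(center = ci, sigma_mm = sg, beta = beta, ve = ve)
  }
  best
}

# Sinusoid amplitude by regression on the quadrature pair at frequency f.
sin_amplitude <- function(y, f, tr_s) {
  t <- (seq_along(y) - 1) * tr_s
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  sqrt(sum(qr.coef(qr(X), y)^2))
}
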