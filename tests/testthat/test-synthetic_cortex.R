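# Synthetic patch, source-signal, and forward-model generators.

test_that("visuotopic patch hits exact eccentricity endpoints and is monotone", {
  p <- make_visuotopic_patch(2, 2, ecc_range_deg = c(1, 7))
  expect_identical(sort(unique(p$prf$ecc_deg)), c(1, 7))
  p20 <- make_visuotopic_patch(20, 20, ecc_range_deg = c(1, 7))
  row_idx <- rep(1:20, each = 20)
  expect_equal(cor(row_idx, p20$prf$ecc_deg, method = "spearman"), 1.0)
  # polar angle varies linearly along columns
  col_idx <- rep(1:20, times = 20)
  expect_equal(cor(col_idx, p20$prf$polar_rad, method = "spearman"), 1.0)
  expect_true(all(p20$prf$ve == 1))
})

test_that("patch generation is deterministic and validates ranges", {
  a <- make_visuotopic_patch(5, 4, seed = 1)
  b <- make_visuotopic_patch(5, 4, seed = 1)
  expect_identical(a$mesh$coords, b$mesh$coords)
  expect_identical(a$mesh$triangles, b$mesh$triangles)
  expect_identical(a$prf, b$prf)
  expect_error(make_visuotopic_patch(1, 4), "n_rows")
  expect_error(make_visuotopic_patch(4, 4, ecc_range_deg = c(1, 12)), "10.2")
  expect_error(make_visuotopic_patch(4, 4, ecc_range_deg = c(7, 1)), "increasing")
})

test_that("source signals are unit variance, band-limited, and spatially structured", {
  m <- grid_mesh(8, 8)
  roi <- cf_roi("src", 1:64, m)
  blk <- simulate_source_signals(m, roi, n_timepoints = 350, tr_s = 2,
                                 spatial_corr_mm = 0, seed = 11)
  v <- apply(blk$values, 1, var)
  expect_true(all(abs(v - 1) < 1e-6))
  expect_true(all(abs(rowMeans(blk$values)) < 1e-12))
  # spatial_corr 0: essentially uncorrelated vertices
  C <- cor(t(blk$values))
  expect_lt(mean(abs(C[upper.tri(C)])), 0.1)
  # spectral power above 0.15 Hz below 5% (band 0.01-0.1 Hz)
  pgram <- abs(mvfft(t(blk$values)))^2
  j <- seq_len(350) - 1
  f <- pmin(j, 350 - j) / (350 * 2)  # folded to [0, Nyquist]
  expect_lt(sum(pgram[f > 0.15, ]) / sum(pgram), 0.05)
  # positive correlation length: nearby vertices more similar
  blk2 <- simulate_source_signals(m, roi, n_timepoints = 350, tr_s = 2,
                                  spatial_corr_mm = 4, seed = 12)
  C2 <- cor(t(blk2$values))
  D <- geodesic_distance_matrix(m, roi$vertex_ids)
  near <- D > 0 & D <= 2; far <- D >= 6
  expect_gt(mean(C2[near]), mean(C2[far]) + 0.2)
  expect_error(simulate_source_signals(m, roi, 100, 2, band_hz = c(0.01, 0.3)),
               "Nyquist")
})

test_that("forward model is exact when noiseless and null when uncoupled", {
  ex <- small_scene(seed = 21, noise_sd = 0)
  s <- ex$scans[[1]]
  # noiseless, beta = 1: target equals the kernel-weighted source sum exactly
  i <- 1
  k <- cf_kernel(ex$mesh, ex$source_roi, ex$truth$center[i], ex$truth$sigma_mm[i])
  expect_equal(s$target$values[i, ], predict_timecourse(k, s$source),
               tolerance = 1e-12)
  # doubling beta doubles the fitted OLS beta on noiseless data
  truth2 <- synthetic_ground_truth(ex$truth$target_vertex, ex$truth$center,
                                   ex$truth$sigma_mm, 2, 0,
                                   source_roi = ex$source_roi)
  t2 <- simulate_target_from_cf(s$source, ex$mesh, ex$source_roi, truth2)
  b1 <- ols_beta_ve(predict_timecourse(k, s$source), s$target$values[i, ])$beta
  b2 <- ols_beta_ve(predict_timecourse(k, s$source), t2$values[i, ])$beta
  expect_equal(b2, 2 * b1, tolerance = 1e-10)
})

test_that("uncoupled targets are uncorrelated with every source vertex", {
  sc <- synthetic_scene_config(n_rows = 7, n_source_cols = 7, n_target_cols = 2,
                               n_timepoints = 350, beta = 0, noise_sd = 1,
                               spatial_corr_mm = 3)
  ex <- make_two_scan_experiment(sc, seed = 31)
  s <- ex$scans[[1]]
  r <- cor(s$target$values[1, ], t(s$source$values))
  expect_lt(max(abs(r)), 0.2)
})

test_that("ground truth constructor enforces its invariants", {
  expect_error(synthetic_ground_truth(1:2, 1, c(0, 1), c(1, 1), 0.5), "sigma")
  expect_error(synthetic_ground_truth(1:2, 1, 1, -1, 0.5), "beta")
  m <- grid_mesh(3, 3)
  roi <- cf_roi("src", 1:4, m)
  expect_error(synthetic_ground_truth(9L, 8L, 2, 1, 0, source_roi = roi),
               "source ROI")
})

test_that("two-scan experiments share ground truth but differ in noise", {
  ex <- small_scene(seed = 41)
  expect_identical(ex$scans[[1]]$target$vertex_ids, ex$truth$target_vertex)
  expect_false(identical(ex$scans[[1]]$target$values, ex$scans[[2]]$target$values))
  expect_false(identical(ex$scans[[1]]$source$values, ex$scans[[2]]$source$values))
  # determinism under the master seed
  ex2 <- small_scene(seed = 41)
  expect_identical(ex$scans, ex2$scans)
  expect_identical(as.data.frame(ex$truth), as.data.frame(ex2$truth))
  # defaults of the stated world: 350 volumes at TR 2 s
  ex3 <- make_two_scan_experiment(seed = 1)
  expect_identical(ncol(ex3$scans[[1]]$source$values), 350L)
  expect_identical(ex3$scans[[1]]$source$tr_s, 2)
})

test_that("noiseless scans are identical across repetitions and fits agree", {
  ex <- small_scene(seed = 51, noise_sd = 0)
  f1 <- fit_cf_grid(ex$mesh, ex$source_roi, ex$scans[[1]]$source,
                    ex$scans[[1]]$target$values[1, ])
  f2 <- fit_cf_grid(ex$mesh, ex$source_roi, ex$scans[[2]]$source,
                    ex$scans[[2]]$target$values[1, ])
  expect_identical(f1$center, f2$center)
  expect_identical(f1$sigma_mm, f2$sigma_mm)
})

test_that("scene fixtures are written as plain text and reload", {
  ex <- small_scene(seed = 61, n_timepoints = 20)
  d <- tempfile("scene")
  write_scene_fixtures(ex, d)
  expect_true(all(file.exists(file.path(d, c("patch.surf.gii", "V1.label.gii",
                                             "scan1_source.tsv",
                                             "ground_truth.json")))))
  blk <- read_series_tsv(file.path(d, "scan1_source.tsv"))
  expect_equal(blk$values, ex$scans[[1]]$source$values,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(blk$tr_s, ex$scans[[1]]$source$tr_s)
})
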