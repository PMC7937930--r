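# Kernel, predictor, OLS, and exhaustive grid fitting.

test_that("kernel weights follow the geodesic Gaussian closed form", {
  m <- chain_mesh(5)
  roi <- cf_roi("src", 1:5, m)
  k <- cf_kernel(m, roi, 2, sigma_mm = 1)
  d <- geodesic_distances(m, 2, roi$vertex_ids)
  raw <- exp(-d^2 / 2)
  expect_equal(k$weights, unname(raw / sum(raw)), tolerance = 1e-12)
  expect_equal(sum(k$weights), 1, tolerance = 1e-9)
  # maximal at the center; a vertex at d = sigma has raw weight exp(-1/2)
  expect_identical(which.max(k$weights), 2L)
  kmax <- cf_kernel(m, roi, 2, sigma_mm = 1, normalize = "max")
  expect_equal(kmax$weights[3], exp(-1 / 2), tolerance = 1e-12)
  expect_equal(kmax$weights[2], 1)
  expect_error(cf_kernel(m, roi, 2, -1), "positive")
  expect_error(cf_kernel(m, cf_roi("s", 1:3, m), 5, 1), "not in source ROI")
})

test_that("very wide kernels approach the uniform ROI average", {
  m <- grid_mesh(5, 5)
  roi <- cf_roi("src", 1:25, m)
  k <- cf_kernel(m, roi, 13, sigma_mm = 100 * 8)  # 100x patch diameter
  expect_true(all(abs(k$weights - 1 / 25) < 0.01 / 25))
})

test_that("predicted time courses are kernel-weighted source combinations", {
  m <- chain_mesh(4)
  roi <- cf_roi("src", 1:4, m)
  set.seed(8)
  blk <- timeseries_block(matrix(rnorm(4 * 30), 4), 2, 1:4)
  # near-delta kernel returns the center's series
  kd <- cf_kernel(m, roi, 3, sigma_mm = 1e-3)
  expect_equal(predict_timecourse(kd, blk), blk$values[3, ], tolerance = 1e-9)
  # huge sigma returns the ROI mean series
  ku <- cf_kernel(m, roi, 2, sigma_mm = 1e4)
  expect_equal(predict_timecourse(ku, blk), colMeans(blk$values),
               tolerance = 1e-6)
  # linearity in the source signals
  blk2 <- timeseries_block(blk$values * 2 + 1, 2, 1:4)
  k <- cf_kernel(m, roi, 2, 1.5)
  expect_equal(predict_timecourse(k, blk2),
               2 * predict_timecourse(k, blk) + 1, tolerance = 1e-12)
})

test_that("OLS beta and VE satisfy their algebraic identities", {
  set.seed(9)
  p <- rnorm(350)
  expect_equal(ols_beta_ve(p, 2 * p), list(beta = 2, ve = 1), tolerance = 1e-12)
  # orthogonal target: beta 0, VE 0
  y <- rnorm(350)
  y_perp <- y - sum(y * p) / sum(p^2) * p
  fit <- ols_beta_ve(p, y_perp)
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(fit$ve, 0, tolerance = 1e-12)
  # VE equals squared Pearson correlation for zero-mean series
  pc <- p - mean(p); yc <- y - mean(y)
  expect_equal(ols_beta_ve(pc, yc)$ve, cor(pc, yc)^2, tolerance = 1e-10)
  expect_error(ols_beta_ve(rep(0, 10), rnorm(10)), "degenerate")
})

test_that("noiseless synthetic targets are inverted exactly by the grid fit", {
  ex <- small_scene(seed = 71, noise_sd = 0)
  s <- ex$scans[[1]]
  for (i in seq_len(nrow(ex$truth))) {
    fit <- fit_cf_grid(ex$mesh, ex$source_roi, s$source, s$target$values[i, ])
    expect_identical(fit$center, ex$truth$center[i])
    expect_identical(fit$sigma_mm, ex$truth$sigma_mm[i])
    expect_gte(fit$ve, 0.999)
  }
})

test_that("grid fit equals the independent brute-force enumerator", {
  sgrid <- exp(seq(log(1), log(12), length.out = 6))
  for (seed in 1:4) {
    ex <- small_scene(seed = seed, n_rows = 5, n_source_cols = 5,
                      n_timepoints = 60, sigma_choices = sgrid[3:4])
    s <- ex$scans[[1]]
    y <- s$target$values[1, ]
    fit <- fit_cf_grid(ex$mesh, ex$source_roi, s$source, y, sgrid)
    ref <- brute_force_cf(ex$mesh, ex$source_roi, s$source, y, sgrid)
    expect_identical(fit$center, ref$center)
    expect_identical(fit$sigma_mm, ref$sigma_mm)
    expect_equal(fit$beta, ref$beta, tolerance = 1e-10)
    expect_equal(fit$ve, ref$ve, tolerance = 1e-10)
  }
})

test_that("pure-noise targets stay below the retention threshold on average", {
  sc <- synthetic_scene_config(n_rows = 20, n_source_cols = 20,
                               n_target_cols = 1, beta = 0, noise_sd = 1)
  ves <- vapply(1:8, function(k) {
    ex <- make_two_scan_experiment(sc, seed = 400 + k)
    s <- ex$scans[[1]]
    fit_cf_grid(ex$mesh, ex$source_roi, s$source, s$target$values[1, ])$ve
  }, numeric(1))
  expect_lt(mean(ves), 0.15)
})

test_that("the map decomposes into per-vertex fits and checks ROI disjointness", {
  ex <- small_scene(seed = 81, n_timepoints = 40)
  s <- ex$scans[[1]]
  fits <- fit_cf_map(ex$mesh, ex$source_roi, ex$target_roi, s$source, s$target)
  for (i in c(1, 5, nrow(fits))) {
    single <- fit_cf_grid(ex$mesh, ex$source_roi, s$source,
                          s$target$values[i, ])
    expect_identical(fits$center[i], single$center)
    expect_identical(fits$sigma_mm[i], single$sigma_mm)
    expect_equal(fits$ve[i], single$ve, tolerance = 1e-12)
  }
  expect_error(fit_cf_map(ex$mesh, ex$source_roi, ex$source_roi, s$source,
                          s$source), "overlap")
  expect_error(fit_cf_grid(ex$mesh, ex$source_roi, s$source,
                           s$target$values[1, ], c(2, 1, 3)), "ascending")
})

test_that("refining the grid around the optimum never lowers the best VE", {
  ex <- small_scene(seed = 91, n_timepoints = 60)
  s <- ex$scans[[1]]
  y <- s$target$values[1, ]
  coarse <- default_sigma_grid(length_out = 8)
  fine <- sort(unique(c(coarse, default_sigma_grid(length_out = 24))))
  ve_coarse <- fit_cf_grid(ex$mesh, ex$source_roi, s$source, y, coarse)$ve
  ve_fine <- fit_cf_grid(ex$mesh, ex$source_roi, s$source, y, fine)$ve
  expect_gte(ve_fine, ve_coarse - 1e-12)
})
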