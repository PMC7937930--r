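# Metropolis-Hastings sampler, posterior summaries, and uncertainties.

test_that("log-posterior peaks at the truth on noiseless data and respects support", {
  ex <- small_scene(seed = 101, noise_sd = 0, n_timepoints = 40)
  s <- ex$scans[[1]]
  y <- s$target$values[1, ]
  truth <- ex$truth[1, ]
  cfg <- cf_mcmc_config(sigma_range_mm = c(0.5, 20))
  lp_true <- log_posterior(truth$center, truth$sigma_mm, truth$beta,
                           ex$mesh, ex$source_roi, s$source, y, cfg)
  for (ds in c(0.7, 1.4))
    expect_gt(lp_true, log_posterior(truth$center, truth$sigma_mm * ds,
                                     truth$beta, ex$mesh, ex$source_roi,
                                     s$source, y, cfg))
  expect_identical(log_posterior(truth$center, truth$sigma_mm, 1e9, ex$mesh,
                                 ex$source_roi, s$source, y, cfg), -Inf)
  expect_identical(log_posterior(truth$center, 1e-3, truth$beta, ex$mesh,
                                 ex$source_roi, s$source, y, cfg), -Inf)
})

test_that("brute-force maximization of the log-posterior matches the MCMC MAP", {
  ex <- small_scene(seed = 111, n_rows = 4, n_source_cols = 4,
                    n_target_cols = 1, n_timepoints = 20, noise_sd = 0.5,
                    sigma_choices = 2.5)
  s <- ex$scans[[1]]
  y <- s$target$values[1, ]
  cfg <- cf_mcmc_config(n_iterations = 3000, seed = 5, sigma_range_mm = c(0.5, 20))
  sig_fine <- exp(seq(log(0.5), log(20), length.out = 30))
  S <- s$source$values[match(ex$source_roi$vertex_ids, s$source$vertex_ids), ]
  best <- list(lp = -Inf)
  for (ci in ex$source_roi$vertex_ids) for (sg in sig_fine) {
    w <- exp(-geodesic_distances(ex$mesh, ci, ex$source_roi$vertex_ids)^2 /
               (2 * sg^2))
    w <- w / sum(w)
    p <- as.numeric(w %*% S)
    b <- max(0, sum(p * y) / sum(p^2))
    lp <- log_posterior(ci, sg, b, ex$mesh, ex$source_roi, s$source, y, cfg)
    if (lp > best$lp) best <- list(lp = lp, center = ci, sigma = sg)
  }
  post <- sample_posterior(ex$mesh, ex$source_roi, s$source, y, cfg)
  expect_identical(post$map_estimate$center, best$center)
  expect_lt(abs(log(post$map_estimate$sigma_mm) - log(best$sigma)),
            2 * diff(log(sig_fine[1:2])))
})

test_that("chains are bit-identical under a fixed seed", {
  ex <- small_scene(seed = 121, n_timepoints = 40)
  s <- ex$scans[[1]]
  cfg <- cf_mcmc_config(n_iterations = 500, seed = 42)
  p1 <- sample_posterior(ex$mesh, ex$source_roi, s$source, s$target$values[1, ], cfg)
  p2 <- sample_posterior(ex$mesh, ex$source_roi, s$source, s$target$values[1, ], cfg)
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$map_estimate, p2$map_estimate)
  expect_identical(p1$quantiles, p2$quantiles)
  # sample count honors the burn-in contract
  expect_identical(nrow(p1$samples), 450L)  # 500 - floor(10% burn-in)
})

test_that("posterior quantiles are ordered and uncertainty matches an independent oracle", {
  ex <- small_scene(seed = 131, n_timepoints = 60, noise_sd = 1)
  s <- ex$scans[[1]]
  cfg <- cf_mcmc_config(n_iterations = 2000, seed = 9)
  post <- sample_posterior(ex$mesh, ex$source_roi, s$source,
                           s$target$values[1, ], cfg)
  q <- post$quantiles
  expect_true(all(q["q1", ] <= q["median", ] & q["median", ] <= q["q3", ]))
  # independent interpolation-quantile computation (textbook type-7 formula)
  oracle_iqr <- function(x) {
    xs <- sort(x); n <- length(xs)
    at <- function(p) { h <- (n - 1) * p + 1
      xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)]) }
    at(0.75) - at(0.25)
  }
  expect_equal(uncertainty(post, "sigma_mm"), oracle_iqr(post$samples$sigma_mm),
               tolerance = 1e-10)
  expect_equal(uncertainty(post, "beta"), oracle_iqr(post$samples$beta),
               tolerance = 1e-10)
  expect_error(uncertainty(post, "gamma"), "arg")
  # plain integer check: samples 1..100 give IQR 49.5 under type 7
  fake <- post
  fake$samples <- data.frame(center = 1L, sigma_mm = as.numeric(1:100),
                             beta = 1, log_post = 0)
  expect_equal(uncertainty(fake, "sigma_mm"), 49.5)
})

test_that("degenerate posteriors report zero uncertainty", {
  ex <- small_scene(seed = 141, noise_sd = 0, n_timepoints = 40)
  s <- ex$scans[[1]]
  # noiseless data: the chain freezes at the mode almost immediately
  cfg <- cf_mcmc_config(n_iterations = 1000, seed = 3)
  post <- sample_posterior(ex$mesh, ex$source_roi, s$source,
                           s$target$values[1, ], cfg)
  expect_gte(uncertainty(post, "sigma_mm"), 0)
  fake <- post
  fake$samples <- data.frame(center = 1L, sigma_mm = 2, beta = 1, log_post = 0)[rep(1, 50), ]
  expect_identical(uncertainty(fake, "sigma_mm"), 0)
  expect_identical(uncertainty(fake, "beta"), 0)
})

test_that("halving the noise shrinks the average sigma uncertainty", {
  unc_at <- function(noise_sd, seeds) {
    vapply(seeds, function(k) {
      ex <- small_scene(seed = 1000 + k, n_rows = 6, n_source_cols = 6,
                        n_target_cols = 1, n_timepoints = 80,
                        noise_sd = noise_sd, sigma_choices = c(2, 3, 4))
      s <- ex$scans[[1]]
      cfg <- cf_mcmc_config(n_iterations = 1200, seed = 2000 + k,
                            sigma_range_mm = c(0.5, 20))
      post <- sample_posterior(ex$mesh, ex$source_roi, s$source,
                               s$target$values[1, ], cfg)
      uncertainty(post, "sigma_mm")
    }, numeric(1))
  }
  u_high <- unc_at(1.0, 1:15)
  u_low <- unc_at(0.5, 1:15)
  expect_true(all(u_high >= 0) && all(u_low >= 0))
  expect_lt(mean(u_low), mean(u_high))
})

test_that("uncertainty correlations form a symmetric matrix with NA for constants", {
  set.seed(15)
  fits <- data.frame(sigma_mm = rnorm(100, 5), beta = rnorm(100, 1, 0.2),
                     unc_sigma = rnorm(100, 2, 0.5), unc_beta = rnorm(100, 0.3, 0.05))
  M <- uncertainty_correlations(fits)
  expect_equal(M, t(M), tolerance = 1e-12)
  expect_equal(unname(diag(M)), rep(1, 4))
  # independent columns: weak empirical correlation
  expect_lt(max(abs(M[upper.tri(M)])), 0.3)
  # identical columns correlate exactly at 1
  fits2 <- fits; fits2$unc_sigma <- fits2$sigma_mm
  expect_equal(uncertainty_correlations(fits2)["sigma_mm", "unc_sigma"], 1)
  fits3 <- fits; fits3$beta <- 1
  expect_warning(M3 <- uncertainty_correlations(fits3), "constant")
  expect_true(is.na(M3["beta", "sigma_mm"]))
  expect_error(uncertainty_correlations(fits[1:2, ]), "at least 3")
})

test_that("extreme acceptance rates trigger tuning warnings", {
  ex <- small_scene(seed = 151, noise_sd = 0, n_timepoints = 40,
                    n_target_cols = 1)
  s <- ex$scans[[1]]
  # noiseless likelihood is razor-sharp: acceptance collapses below 1%
  cfg <- cf_mcmc_config(n_iterations = 500, seed = 4)
  expect_warning(
    fit_cf_bayes_map(ex$mesh, ex$source_roi, ex$target_roi, s$source,
                     s$target, cfg),
    "acceptance")
})
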