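# Bayesian connective field fitting. A random-walk Metropolis-Hastings
# chain samples (center vertex, sigma, beta). The Gaussian noise variance
# is profiled out of the likelihood, giving log L = -(T/2) log RSS up to
# constants (identical in shape to marginalizing the variance under a
# Jeffreys prior). Priors: uniform over source vertices, log-uniform sigma,
# uniform beta on [0, beta_max]. Posterior spread is summarized per
# parameter as Q3 - Q1 of the post-burn-in marginal.

#' MCMC configuration for Bayesian connective field fitting
#'
#' @param n_iterations chain length (default 15000).
#' @param burn_in_fraction initial fraction discarded (default 0.10).
#' @param sigma_step Gaussian proposal step on log sigma (default 0.15).
#' @param k_ring center proposal neighborhood: uniform draw from the
#'   current vertex's k-ring on the source-ROI subgraph (default 2).
#' @param p_global probability of a global center jump (uniform over the
#'   source ROI) for mixing (default 0.05).
#' @param beta_step Gaussian proposal step for beta; `NULL` scales it to
#'   the OLS beta magnitude of the ROI-mean predictor (default).
#' @param sigma_range_mm log-uniform prior support for sigma in mm
#'   (default `c(0.3, 40)`).
#' @param beta_max upper prior bound for beta; `NULL` means 10x the OLS
#'   beta of the ROI-mean predictor (default).
#' @param estimate point estimate reported from the chain: `"map"`
#'   (highest-posterior sample, default) or `"mean"` (posterior mean).
#' @param seed RNG seed for the chain.
#' @return Named list of class `cf_mcmc_config`.
#' @export
cf_mcmc_config <- function(n_iterations = 15000L, burn_in_fraction = 0.10,
                           sigma_step = 0.15, k_ring = 2L, p_global = 0.05,
                           beta_step = NULL, sigma_range_mm = c(0.3, 40),
                           beta_max = NULL, estimate = c("map", "mean"),
                           seed = NULL) {
  if (n_iterations < 100L) stop("`n_iterations` must be >= 100")
  if (burn_in_fraction <= 0 || burn_in_fraction >= 1)
    stop("`burn_in_fraction` must lie in (0, 1)")
  if (length(sigma_range_mm) != 2L || any(sigma_range_mm <= 0) ||
      diff(sigma_range_mm) <= 0)
    stop("`sigma_range_mm` must be positive and increasing")
  if (!is.null(beta_max) && beta_max <= 0) stop("`beta_max` must be positive")
  if (p_global < 0 || p_global > 1) stop("`p_global` must lie in [0, 1]")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in_fraction = burn_in_fraction,
                 sigma_step = sigma_step, k_ring = as.integer(k_ring),
                 p_global = p_global, beta_step = beta_step,
                 sigma_range_mm = sigma_range_mm, beta_max = beta_max,
                 estimate = match.arg(estimate), seed = seed),
            class = "cf_mcmc_config")
}

# Shared precomputations for one (source ROI, source block, target) problem:
# distance matrix, Gram matrix G = S S', Sy = S y, k-ring neighbor lists.
cf_bayes_context <- function(mesh, source_roi, source_block, k_ring) {
  assert_roi_connected(mesh, source_roi)
  S <- block_subset(source_block, source_roi$vertex_ids)$values
  D <- geodesic_distance_matrix(mesh, source_roi$vertex_ids)
  sub <- igraph::induced_subgraph(mesh$graph, source_roi$vertex_ids)
  nb <- igraph::ego(sub, order = k_ring, mindist = 1L)
  neighbors <- lapply(nb, function(v) sort(as.integer(v)) - 1L)  # 0-based for C++
  G <- S %*% t(S)
  pbar <- colMeans(S)
  list(S = S, D = D, G = G, Gdiag = pmax(diag(G), 1e-12),
       pbar = pbar, pbar_ss = sum(pbar^2), pbar_sd = sd(pbar),
       neighbors = neighbors, source_ids = source_roi$vertex_ids)
}

# Data-adaptive beta scales from the OLS fit of the ROI-mean predictor.
beta_scales <- function(ctx, y, config) {
  beta_ols <- abs(sum(ctx$pbar * y) / ctx$pbar_ss)
  if (!is.finite(beta_ols) || beta_ols == 0)
    beta_ols <- sd(y) / max(ctx$pbar_sd, 1e-12)
  beta_max <- if (is.null(config$beta_max)) 10 * beta_ols else config$beta_max
  beta_step <- if (is.null(config$beta_step)) 0.3 * beta_ols else config$beta_step
  list(beta_max = beta_max, beta_step = max(beta_step, 1e-12))
}

#' Log-posterior of a connective-field parameter triple
#'
#' Profiled-noise Gaussian log-likelihood `-(T/2) log RSS` plus log-priors
#' (uniform center, log-uniform sigma, uniform beta on `[0, beta_max]`),
#' up to an additive constant. Returns `-Inf` outside the prior support.
#'
#' @param center candidate center vertex id (in the source ROI).
#' @param sigma_mm,beta candidate kernel width (mm) and amplitude.
#' @param mesh,source_roi,source_block the source-region model inputs.
#' @param target_series zero-mean target series.
#' @param config a [cf_mcmc_config()] supplying the prior bounds.
#' @return Log-posterior density (unnormalized).
#' @export
log_posterior <- function(center, sigma_mm, beta, mesh, source_roi,
                          source_block, target_series,
                          config = cf_mcmc_config()) {
  if (any(!is.finite(target_series))) stop("target series contains non-finite values")
  ctx <- cf_bayes_context(mesh, source_roi, source_block, config$k_ring)
  S <- ctx$S
  sc <- beta_scales(ctx, target_series, config)
  if (sigma_mm < config$sigma_range_mm[1] || sigma_mm > config$sigma_range_mm[2] ||
      beta < 0 || beta > sc$beta_max || !center %in% source_roi$vertex_ids)
    return(-Inf)
  k <- cf_kernel(mesh, source_roi, center, sigma_mm)
  p <- as.numeric(k$weights %*% S)
  rss <- sum((target_series - beta * p)^2)
  rss <- max(rss, 1e-12 * sum(target_series^2))
  -0.5 * length(target_series) * log(rss) - log(sigma_mm)
}

#' Sample the connective-field posterior by Metropolis-Hastings
#'
#' One chain of `n_iterations` sweeps (center, log sigma, beta updated in
#' turn); the first `burn_in_fraction` is discarded and marginals are
#' summarized on the remainder. Reproducible under a fixed seed. The center
#' proposal mixes a uniform k-ring step with occasional global jumps; its
#' asymmetry at ROI boundaries carries the Hastings correction.
#'
#' @inheritParams log_posterior
#' @param config a [cf_mcmc_config()].
#' @return Object of class `cf_posterior`: `samples` (post-burn-in
#'   data.frame of `center`, `sigma_mm`, `beta`, `log_post`),
#'   `map_estimate` (a `cf_fit` at the point estimate, with VE),
#'   `quantiles` (Q1/median/Q3 per parameter), `uncertainty` (Q3 - Q1),
#'   `acceptance_rate` (per update type), and the config.
#' @export
sample_posterior <- function(mesh, source_roi, source_block, target_series,
                             config = cf_mcmc_config()) {
  stopifnot(inherits(config, "cf_mcmc_config"))
  if (any(!is.finite(target_series))) stop("target series contains non-finite values")
  ctx <- cf_bayes_context(mesh, source_roi, source_block, config$k_ring)
  post <- sample_posterior_ctx(ctx, target_series, config)
  post
}

# Core sampler working from a prebuilt context (reused across targets).
sample_posterior_ctx <- function(ctx, y, config) {
  if (length(y) != ncol(ctx$S))
    stop("target series length does not match the source block")
  sc <- beta_scales(ctx, y, config)
  Sy <- as.numeric(ctx$S %*% y)
  yty <- sum(y^2)
  # initialize at the best single-vertex correlate, mid-prior sigma, its OLS beta
  r0 <- abs(Sy) / sqrt(ctx$Gdiag)
  c0 <- which.max(r0)
  sigma0 <- exp(mean(log(config$sigma_range_mm)))
  w0 <- exp(-ctx$D[, c0]^2 / (2 * sigma0^2)); w0 <- w0 / sum(w0)
  beta0 <- min(max(sum(w0 * Sy) / max(sum(w0 * (ctx$G %*% w0)), 1e-12), 1e-6),
               sc$beta_max)
  if (!is.null(config$seed)) set.seed(config$seed)
  ch <- .cf_mcmc_cpp(ctx$D, ctx$G, Sy, yty, length(y), ctx$neighbors,
                     config$n_iterations, c0 - 1L, sigma0, beta0,
                     config$sigma_range_mm[1], config$sigma_range_mm[2],
                     sc$beta_max, config$sigma_step, sc$beta_step,
                     config$p_global)
  acc <- attr(ch, "acceptance")
  n_burn <- floor(config$n_iterations * config$burn_in_fraction)
  keep <- ch[(n_burn + 1L):nrow(ch), , drop = FALSE]
  centers <- ctx$source_ids[keep[, 1] + 1L]
  if (config$estimate == "map") {
    i_map <- which.max(keep[, 4])
    est <- list(center = centers[i_map], sigma_mm = keep[i_map, 2],
                beta = keep[i_map, 3])
  } else {
    est <- list(center = mode_center(centers),
                sigma_mm = mean(keep[, 2]), beta = mean(keep[, 3]))
  }
  w <- exp(-ctx$D[, match(est$center, ctx$source_ids)]^2 / (2 * est$sigma_mm^2))
  w <- w / sum(w)
  p <- as.numeric(w %*% ctx$S)
  rss <- yty - 2 * est$beta * sum(p * y) + est$beta^2 * sum(p^2)
  map_fit <- structure(list(center = est$center, sigma_mm = est$sigma_mm,
                            beta = est$beta,
                            ve = if (yty > 0) 1 - rss / yty else NA_real_),
                       class = "cf_fit")
  qs <- cbind(sigma_mm = quantile_type7(keep[, 2], c(0.25, 0.5, 0.75)),
              beta = quantile_type7(keep[, 3], c(0.25, 0.5, 0.75)))
  rownames(qs) <- c("q1", "median", "q3")
  samples <- list(center = centers, sigma_mm = keep[, 2], beta = keep[, 3],
                  log_post = keep[, 4])
  class(samples) <- "data.frame"
  attr(samples, "row.names") <- .set_row_names(length(centers))
  structure(list(samples = samples, map_estimate = map_fit, quantiles = qs,
                 uncertainty = qs["q3", ] - qs["q1", ],
                 acceptance_rate = acc, config = config),
            class = "cf_posterior")
}

# Type-7 (linear interpolation) quantiles without the S3 dispatch overhead;
# numerically identical to stats::quantile(type = 7).
quantile_type7 <- function(x, probs) {
  xs <- sort.int(x, method = "quick")
  h <- (length(xs) - 1) * probs + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

mode_center <- function(centers) {
  tab <- table(centers)
  as.integer(names(tab)[which.max(tab)])
}

#' @export
print.cf_posterior <- function(x, ...) {
  cat(sprintf(paste0("cf_posterior: %d samples | MAP center %d, sigma %.3f mm, ",
                     "beta %.4g, VE %.3f\n  unc(sigma) %.3f mm, unc(beta) %.4g, ",
                     "acceptance c/s/b = %.2f/%.2f/%.2f\n"),
              nrow(x$samples), x$map_estimate$center, x$map_estimate$sigma_mm,
              x$map_estimate$beta, x$map_estimate$ve,
              x$uncertainty[["sigma_mm"]], x$uncertainty[["beta"]],
              x$acceptance_rate[["center"]], x$acceptance_rate[["sigma"]],
              x$acceptance_rate[["beta"]]))
  invisible(x)
}

check_acceptance <- function(acc) {
  overall <- mean(acc)
  if (overall < 0.01)
    warning("MCMC acceptance rate ", sprintf("%.3f", overall),
            " < 1%: decrease sigma_step/beta_step or k_ring", call. = FALSE)
  if (overall > 0.95)
    warning("MCMC acceptance rate ", sprintf("%.3f", overall),
            " > 95%: increase sigma_step/beta_step for better mixing",
            call. = FALSE)
  invisible(overall)
}

#' Posterior-quantile uncertainty of one parameter
#'
#' Q3 - Q1 (interquartile range, linear-interpolation/type-7 quantiles) of
#' the post-burn-in marginal.
#'
#' @param posterior a `cf_posterior`.
#' @param parameter `"sigma_mm"` or `"beta"`.
#' @return Non-negative scalar.
#' @export
uncertainty <- function(posterior, parameter = c("sigma_mm", "beta")) {
  parameter <- match.arg(parameter)
  if (nrow(posterior$samples) == 0L) stop("posterior is empty")
  q <- quantile(posterior$samples[[parameter]], c(0.25, 0.75), type = 7)
  unname(q[2] - q[1])
}

#' Bayesian connective-field map over a target region
#'
#' Runs [sample_posterior()] per target vertex (seeds derived per vertex
#' from `config$seed`), reporting the point estimate, VE, per-parameter
#' Q3 - Q1 uncertainties and acceptance rates.
#'
#' @inheritParams fit_cf_map
#' @param config a [cf_mcmc_config()]; its `seed` reproduces the whole map.
#' @param warn_acceptance emit tuning warnings for extreme acceptance rates
#'   (default TRUE).
#' @return Data.frame of class `cf_bayes_table`: one row per target vertex
#'   with `target_vertex`, `center`, `sigma_mm`, `beta`, `ve`, `unc_sigma`,
#'   `unc_beta`, `acceptance_rate`.
#' @export
fit_cf_bayes_map <- function(mesh, source_roi, target_roi, source_block,
                             target_block, config = cf_mcmc_config(),
                             warn_acceptance = TRUE, verbose = FALSE) {
  if (length(intersect(source_roi$vertex_ids, target_roi$vertex_ids)))
    stop("source ROI '", source_roi$name, "' and target ROI '",
         target_roi$name, "' overlap")
  ctx <- cf_bayes_context(mesh, source_roi, source_block, config$k_ring)
  Yb <- block_subset(target_block, target_roi$vertex_ids)
  master <- if (is.null(config$seed)) NULL else config$seed
  n_t <- length(Yb$vertex_ids)
  cols <- list(target_vertex = Yb$vertex_ids, center = integer(n_t),
               sigma_mm = numeric(n_t), beta = numeric(n_t), ve = numeric(n_t),
               unc_sigma = numeric(n_t), unc_beta = numeric(n_t),
               acceptance_rate = numeric(n_t))
  for (i in seq_len(n_t)) {
    if (verbose && i %% 20L == 0L)
      message("fit_cf_bayes_map: ", i, "/", n_t)
    cfg_i <- config
    if (!is.null(master)) cfg_i$seed <- derive_seed(master, i)
    post <- sample_posterior_ctx(ctx, Yb$values[i, ], cfg_i)
    if (warn_acceptance) check_acceptance(post$acceptance_rate)
    cols$center[i] <- post$map_estimate$center
    cols$sigma_mm[i] <- post$map_estimate$sigma_mm
    cols$beta[i] <- post$map_estimate$beta
    cols$ve[i] <- post$map_estimate$ve
    cols$unc_sigma[i] <- unname(post$uncertainty[["sigma_mm"]])
    cols$unc_beta[i] <- unname(post$uncertainty[["beta"]])
    cols$acceptance_rate[i] <- mean(post$acceptance_rate)
  }
  out <- as.data.frame(cols)
  class(out) <- c("cf_bayes_table", "cf_fit_table", "data.frame")
  out
}

#' Correlations between Bayesian estimates and their uncertainties
#'
#' Full Pearson correlation matrix of `sigma_mm`, `beta`, `unc_sigma`,
#' `unc_beta` across a fitted target region; the off-diagonal
#' estimate-vs-uncertainty block quantifies whether uncertainty carries
#' independent information (weak correlation) or merely mirrors the
#' estimates.
#'
#' @param fits a `cf_bayes_table` from [fit_cf_bayes_map()] (needs >= 3 rows).
#' @return Symmetric 4x4 correlation matrix; entries involving a constant
#'   column are `NA` (flagged by warning), not zero.
#' @export
uncertainty_correlations <- function(fits) {
  cols <- c("sigma_mm", "beta", "unc_sigma", "unc_beta")
  if (!all(cols %in% names(fits)))
    stop("`fits` must be a cf_bayes_table with columns ",
         paste(cols, collapse = ", "))
  if (nrow(fits) < 3L) stop("need at least 3 target vertices")
  X <- as.matrix(fits[cols])
  const <- apply(X, 2, function(v) sd(v) == 0)
  if (any(const))
    warning("constant column(s): ", paste(cols[const], collapse = ", "),
            "; correlations undefined (NA)", call. = FALSE)
  suppressWarnings(cor(X))
}
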