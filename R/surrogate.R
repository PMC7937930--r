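# IAAFT surrogate null distribution for the data-driven beta threshold.
# Surrogates preserve each source series' amplitude spectrum and exact
# value distribution while destroying its specific temporal alignment;
# refitting the connective-field model with surrogate predictors (targets
# untouched) yields the null distribution of best-fit beta, whose pooled
# 95th percentile is the familywise-error-corrected retention threshold.

#' Iterative amplitude-adjusted Fourier transform surrogate
#'
#' Schreiber-Schmitz two-step iteration: enforce the original amplitude
#' spectrum by phase-preserving spectral substitution, then restore the
#' original value distribution by rank reordering; repeat until the change
#' in spectral discrepancy falls below `tol` or `max_iter` is reached. The
#' final step is the rank reordering, so the surrogate's sorted values
#' equal the original's exactly.
#'
#' @param series finite numeric vector, length >= 8, non-constant.
#' @param max_iter maximum iterations (default 1000).
#' @param tol convergence tolerance on the change of the relative RMS
#'   spectral discrepancy (default 1e-8).
#' @param seed RNG seed for the initial shuffle.
#' @return Numeric vector with attributes `iterations` and
#'   `spectral_rmse` (relative RMS amplitude-spectrum error over non-DC
#'   frequencies).
#' @export
iaaft_surrogate <- function(series, max_iter = 1000L, tol = 1e-8, seed = NULL) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 8L) stop("series too short for IAAFT (need length >= 8)")
  if (any(!is.finite(x))) stop("series contains non-finite values")
  if (sd(x) == 0) stop("constant series: amplitude spectrum is degenerate")
  if (!is.null(seed)) set.seed(seed)

  amp <- Mod(fft(x))
  ref <- sqrt(mean(amp[-1]^2))
  xs <- sort(x)
  s <- sample(x)                      # random initial temporal order
  prev_disc <- Inf
  iters <- 0L
  repeat {
    X <- fft(s)
    m <- Mod(X)
    disc <- sqrt(mean((m[-1] - amp[-1])^2)) / ref
    if (abs(prev_disc - disc) < tol || iters >= max_iter) break
    prev_disc <- disc
    iters <- iters + 1L
    phase <- X / pmax(m, 1e-300)      # unit-modulus phases
    s2 <- Re(fft(amp * phase, inverse = TRUE)) / n
    s[order(s2)] <- xs                # rank reordering: exact value distribution
  }
  attr(s, "iterations") <- iters
  attr(s, "spectral_rmse") <- spectral_rmse(s, amp)
  s
}

# Relative RMS amplitude-spectrum error over non-DC frequencies.
spectral_rmse <- function(s, amp_ref) {
  a <- Mod(fft(s))[-1]
  r <- amp_ref[-1]
  sqrt(mean((a - r)^2)) / sqrt(mean(r^2))
}

#' Surrogate copy of a whole time-series block
#'
#' One IAAFT surrogate per vertex, drawn from a single seeded RNG stream.
#'
#' @param block a `timeseries_block`.
#' @param max_iter,tol IAAFT controls, see [iaaft_surrogate()].
#' @param seed RNG seed for the whole block.
#' @return `timeseries_block` of surrogates, same vertices and TR.
#' @export
surrogate_block <- function(block, max_iter = 1000L, tol = 1e-8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- t(apply(block$values, 1, iaaft_surrogate, max_iter = max_iter, tol = tol))
  timeseries_block(vals, block$tr_s, block$vertex_ids)
}

#' Surrogate-derived null distribution of best-fit beta
#'
#' For each of `n_realizations` runs: replace every source-vertex series by
#' an IAAFT surrogate (targets unchanged), refit the connective field per
#' target vertex with the same procedure used for the real data, and
#' collect the best-fit betas. The pooled sample across target vertices
#' and realizations is the null for [fwe_beta_threshold()].
#'
#' @inheritParams fit_cf_map
#' @param fit_method `"bayes"` (default; best fit over the MCMC iterations,
#'   as for the real data) or `"grid"` (exhaustive search, faster).
#' @param config a [cf_mcmc_config()] for `"bayes"`, or a sigma grid for
#'   `"grid"`.
#' @param n_realizations surrogate draws per source vertex (default 1, as
#'   one surrogate per voxel; raise it for a tighter null).
#' @param percentile percentile of the pooled null used as threshold
#'   (default 95).
#' @param seed master seed for the surrogate stream.
#' @return Object of class `null_beta_distribution`: `null_betas` (pooled),
#'   `per_vertex` (targets x realizations matrix), `fwe_threshold`,
#'   `percentile`, `fit_method`.
#' @export
null_beta_distribution <- function(mesh, source_roi, target_roi, source_block,
                                   target_block,
                                   fit_method = c("bayes", "grid"),
                                   config = cf_mcmc_config(),
                                   n_realizations = 1L, percentile = 95,
                                   seed = NULL) {
  fit_method <- match.arg(fit_method)
  n_t <- length(target_roi$vertex_ids)
  per_vertex <- matrix(NA_real_, n_t, n_realizations)
  for (r in seq_len(n_realizations)) {
    sseed <- if (is.null(seed)) NULL else derive_seed(seed, 1000L + r)
    surr <- surrogate_block(source_block, seed = sseed)
    fits <- if (fit_method == "bayes") {
      cfg <- config
      if (!is.null(seed)) cfg$seed <- derive_seed(seed, 2000L + r)
      fit_cf_bayes_map(mesh, source_roi, target_roi, surr, target_block,
                       cfg, warn_acceptance = FALSE)
    } else {
      grid <- if (inherits(config, "cf_mcmc_config")) default_sigma_grid() else config
      fit_cf_map(mesh, source_roi, target_roi, surr, target_block, grid)
    }
    per_vertex[, r] <- fits$beta
  }
  rownames(per_vertex) <- target_roi$vertex_ids
  out <- structure(list(null_betas = as.numeric(per_vertex),
                        per_vertex = per_vertex,
                        percentile = percentile, fit_method = fit_method),
                   class = "null_beta_distribution")
  out$fwe_threshold <- fwe_beta_threshold(out, percentile)
  out
}

#' @export
print.null_beta_distribution <- function(x, ...) {
  cat(sprintf(paste0("null_beta_distribution: %d pooled null betas (%s fit), ",
                     "%gth-percentile FWE threshold = %.4g\n"),
              length(x$null_betas), x$fit_method, x$percentile,
              x$fwe_threshold))
  invisible(x)
}

#' Familywise-error-corrected beta threshold
#'
#' The stated percentile (default 95th, linear interpolation) of the pooled
#' null best-fit betas, applied uniformly to every target vertex.
#'
#' @param null a `null_beta_distribution` (or a bare numeric null sample).
#' @param percentile percentile in (0, 100).
#' @return Scalar threshold.
#' @export
fwe_beta_threshold <- function(null, percentile = 95) {
  if (percentile <= 0 || percentile > 100)
    stop("`percentile` must lie in (0, 100]")
  betas <- if (inherits(null, "null_beta_distribution")) null$null_betas else as.numeric(null)
  if (length(betas) == 0L) stop("empty null sample")
  unname(quantile(betas, percentile / 100, type = 7))
}

#' Voxel selection by variance explained and/or FWE beta threshold
#'
#' Computes the retention mask for each rule and their overlap, mirroring
#' the comparison of the two thresholding approaches. Degenerate fits with
#' near-zero kernel width can be discarded first (they carry no spatial
#' information).
#'
#' @param fits a `cf_fit_table` (columns `ve` and `beta`).
#' @param ve_min retain `ve > ve_min` (e.g. 0.15); `NULL` skips the rule.
#' @param beta_threshold retain `beta > beta_threshold` (the FWE value);
#'   `NULL` skips the rule.
#' @param discard_sigma_below drop fits with `sigma_mm` below this before
#'   thresholding (default 0: keep all).
#' @return List with logical masks `ve_mask`, `beta_mask`, `both`,
#'   `either`, `only_ve`, `only_beta` (aligned to `fits` rows; `FALSE`
#'   where discarded) and a `counts` summary.
#' @export
select_voxels <- function(fits, ve_min = NULL, beta_threshold = NULL,
                          discard_sigma_below = 0) {
  n <- nrow(fits)
  valid <- fits$sigma_mm >= discard_sigma_below
  ve_mask <- if (is.null(ve_min)) valid else valid & fits$ve > ve_min
  beta_mask <- if (is.null(beta_threshold)) valid else valid & fits$beta > beta_threshold
  out <- list(ve_mask = ve_mask, beta_mask = beta_mask,
              both = ve_mask & beta_mask, either = ve_mask | beta_mask,
              only_ve = ve_mask & !beta_mask, only_beta = beta_mask & !ve_mask)
  out$counts <- c(n = n, discarded = sum(!valid),
                  vapply(out, sum, integer(1)))
  out
}
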