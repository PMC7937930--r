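# Agreement and test-retest battery: Pearson and Fisher-Lee circular
# correlation, coefficient of variation, intraclass correlation on the
# strongest voxels, and eccentricity-binned linear fits of connective-field
# size with bootstrap confidence intervals.

#' Pearson product-moment correlation with two-sided p-value
#'
#' @param x,y finite numeric vectors, length >= 3.
#' @return `list(r, p, n)`; `r` and `p` are `NA` (with a warning) when a
#'   vector has zero variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: Pearson correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Fisher-Lee circular correlation with permutation p-value
#'
#' T-linear association for paired angles:
#' `r = sum_{i<j} sin(a_i - a_j) sin(b_i - b_j) /
#'  sqrt(sum sin^2(a_i - a_j) * sum sin^2(b_i - b_j))`.
#' Invariant to separate rotations of either variable. The p-value is a
#' two-sided permutation test (seeded), not the asymptotic approximation.
#'
#' @param angles_a,angles_b paired angles in radians, length >= 3.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return `list(r, p, n)`. Near-uniform angle samples (tiny resultant
#'   length) trigger a warning that `p` is unreliable.
#' @export
circular_corr <- function(angles_a, angles_b, n_perm = 1000L, seed = NULL) {
  a <- as.numeric(angles_a); b <- as.numeric(angles_b)
  if (length(a) != length(b)) stop("angle vectors differ in length")
  if (length(a) < 3L) stop("need at least 3 angle pairs")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite angles")
  rbar <- function(t) Mod(mean(exp(1i * t)))
  if (rbar(a) < 0.1 || rbar(b) < 0.1)
    warning("angles nearly uniform (resultant length < 0.1): permutation ",
            "p-value unreliable", call. = FALSE)
  r_obs <- fisher_lee_r(a, b)
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(n_perm, fisher_lee_r(a, sample(b)))
  p <- (1 + sum(abs(perm) >= abs(r_obs))) / (n_perm + 1)
  list(r = r_obs, p = p, n = length(a))
}

fisher_lee_r <- function(a, b) {
  # O(n) via double-angle identities:
  # sum_{i<j} sin^2(t_i - t_j) = (n^2 - (sum cos 2t)^2 - (sum sin 2t)^2) / 4
  n <- length(a)
  num <- sum(cos(a) * cos(b)) * sum(sin(a) * sin(b)) -
         sum(cos(a) * sin(b)) * sum(sin(a) * cos(b))
  den_a <- (n^2 - sum(cos(2 * a))^2 - sum(sin(2 * a))^2) / 4
  den_b <- (n^2 - sum(cos(2 * b))^2 - sum(sin(2 * b))^2) / 4
  num / sqrt(den_a * den_b)
}

#' Coefficient of variation across repeated measurements
#'
#' `sd / |mean|` with the sample (n-1) standard deviation; the
#' within-subject reproducibility measure for a parameter estimated on
#' repeated scans.
#'
#' @param values numeric vector of repeated estimates.
#' @return Scalar CV; `NA` with a warning when the mean is zero.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) {
    warning("zero mean: coefficient of variation undefined", call. = FALSE)
    return(NA_real_)
  }
  sd(values) / abs(m)
}

#' Intraclass correlation between two scans
#'
#' Two-way ANOVA decomposition over n paired measurements x 2 scans.
#' `ICC(3,1)` (two-way mixed effects, consistency, single measure) is the
#' default test-retest form; `ICC(2,1)` (two-way random, absolute
#' agreement) is selectable. The confidence interval follows the classical
#' F-distribution construction.
#'
#' @param scan1_values,scan2_values paired estimates, length >= 5.
#' @param variant `"ICC31"` (default) or `"ICC21"`.
#' @param conf_level confidence level (default 0.95).
#' @return `list(icc, ci, variant, n)`; degenerate variance decompositions
#'   yield `NA` with a warning.
#' @export
icc <- function(scan1_values, scan2_values, variant = c("ICC31", "ICC21"),
                conf_level = 0.95) {
  variant <- match.arg(variant)
  x1 <- as.numeric(scan1_values); x2 <- as.numeric(scan2_values)
  if (length(x1) != length(x2)) stop("scans differ in length")
  n <- length(x1)
  if (n < 5L) stop("need at least 5 paired values")
  if (any(!is.finite(x1)) || any(!is.finite(x2))) stop("non-finite values")
  k <- 2
  X <- cbind(x1, x2)
  row_m <- rowMeans(X); col_m <- colMeans(X); gm <- mean(X)
  MSR <- k * sum((row_m - gm)^2) / (n - 1)              # between subjects
  MSC <- n * sum((col_m - gm)^2) / (k - 1)              # between scans
  SSE <- sum((X - outer(row_m, rep(1, k)) -
              outer(rep(1, n), col_m) + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR + (k - 1) * MSE == 0) {
    warning("degenerate variance decomposition: ICC undefined", call. = FALSE)
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                variant = variant, n = n))
  }
  alpha <- 1 - conf_level
  if (variant == "ICC31") {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    if (MSE == 0) {
      ci <- c(est, est)
    } else {
      Fobs <- MSR / MSE
      FL <- Fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      FU <- Fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    }
  } else {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    if (MSE == 0) {
      ci <- c(est, est)
    } else {
      # Shrout-Fleiss approximate interval for ICC(2,1)
      Fj <- MSC / MSE
      vn <- (k - 1) * (n - 1) * ((k * est * Fj + n * (1 + (k - 1) * est) -
                                  k * est))^2
      vd <- (n - 1) * k^2 * est^2 * Fj^2 +
            (n * (1 + (k - 1) * est) - k * est)^2
      v <- vn / vd
      FL <- qf(1 - alpha / 2, n - 1, v)
      FU <- qf(1 - alpha / 2, v, n - 1)
      ci <- c(n * (MSR - FL * MSE) /
                (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR),
              n * (FU * MSR - MSE) /
                (k * MSC + (k * n - k - n) * MSE + n * FU * MSR))
    }
  }
  list(icc = unname(est), ci = sort(unname(ci)), variant = variant, n = n)
}

#' Select the strongest-fitting fraction of voxels
#'
#' Retains the `percentile`% of rows with the highest variance explained -
#' the "most active" subset on which test-retest ICC is evaluated.
#'
#' @param fits a `cf_fit_table` (column `ve`).
#' @param percentile percentage of rows to keep (default 5).
#' @return Integer row indices into `fits`, strongest first.
#' @export
top_ve_select <- function(fits, percentile = 5) {
  if (percentile <= 0 || percentile > 100)
    stop("`percentile` must lie in (0, 100]")
  n_keep <- max(1L, ceiling(nrow(fits) * percentile / 100))
  order(fits$ve, decreasing = TRUE)[seq_len(n_keep)]
}

#' Eccentricity-binned linear fit of connective-field size
#'
#' Bins eccentricity at `bin_width_deg` intervals, fits ordinary least
#' squares to the per-bin means (mean CF size against mean eccentricity of
#' each bin, so exactly linear data recover their line exactly), and
#' derives a percentile bootstrap confidence interval by resampling
#' vertices within bins.
#'
#' @param eccentricities eccentricities in degrees.
#' @param cf_sizes matching connective-field sizes in mm.
#' @param bin_width_deg bin width in degrees (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf_level confidence level of the percentile interval
#'   (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return List: `slope`, `intercept`, `slope_ci`, `intercept_ci`,
#'   `bin_centers`, `bin_means`, `bin_counts`, `n_boot`.
#' @export
binned_ecc_fit <- function(eccentricities, cf_sizes, bin_width_deg = 1,
                           n_boot = 1000L, conf_level = 0.95, seed = NULL) {
  ecc <- as.numeric(eccentricities); sz <- as.numeric(cf_sizes)
  if (length(ecc) != length(sz)) stop("inputs differ in length")
  if (any(!is.finite(ecc)) || any(!is.finite(sz))) stop("non-finite values")
  bin <- floor(ecc / bin_width_deg)
  groups <- split(seq_along(ecc), bin)
  if (length(groups) < 2L)
    stop("fewer than 2 non-empty eccentricity bins; cannot fit a line")
  ecc_means <- vapply(groups, function(i) mean(ecc[i]), numeric(1))
  means <- vapply(groups, function(i) mean(sz[i]), numeric(1))
  fit <- lm(means ~ ecc_means)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- numeric(length(groups)); by <- numeric(length(groups))
    for (g in seq_along(groups)) {
      i <- groups[[g]][sample.int(length(groups[[g]]), replace = TRUE)]
      bx[g] <- mean(ecc[i]); by[g] <- mean(sz[i])
    }
    coef(lm(by ~ bx))
  }, numeric(2))
  alpha <- 1 - conf_level
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       slope_ci = unname(quantile(boots[2, ], c(alpha / 2, 1 - alpha / 2), type = 7)),
       intercept_ci = unname(quantile(boots[1, ], c(alpha / 2, 1 - alpha / 2), type = 7)),
       bin_centers = unname((as.numeric(names(groups)) + 0.5) * bin_width_deg),
       bin_ecc_means = unname(ecc_means), bin_means = unname(means),
       bin_counts = unname(lengths(groups)), n_boot = n_boot)
}
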