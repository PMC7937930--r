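# Standard connective field model: a target vertex's series is predicted as
# a Gaussian-weighted linear combination of source-region series, the
# Gaussian defined over geodesic distance on the cortical surface. Fitting
# is an exhaustive search over every source vertex as candidate center and a
# grid of kernel widths, retaining the model with maximal variance explained.

#' Default kernel-width grid (mm)
#'
#' Logarithmically spaced coarse grid, 0.5-25 mm, 24 points.
#'
#' @param from,to,length_out grid limits in mm and number of points.
#' @return Numeric vector of sigma values in mm, ascending.
#' @export
default_sigma_grid <- function(from = 0.5, to = 25, length_out = 24L) {
  exp(seq(log(from), log(to), length.out = length_out))
}

#' Geodesic Gaussian connective-field kernel
#'
#' Raw weight at source vertex j is `exp(-d(j, center)^2 / (2 sigma^2))`
#' with d the geodesic distance; weights are normalized to unit sum
#' (default) so that beta reads as a signal amplitude scaling, or to unit
#' maximum.
#'
#' @param mesh a `cortical_mesh`.
#' @param source_roi a `cf_roi`; weights are defined over its vertices.
#' @param center center vertex id (must lie in the source ROI).
#' @param sigma_mm kernel width in mm (> 0).
#' @param normalize `"sum"` (default) or `"max"`.
#' @return Object of class `cf_kernel`: `center`, `sigma_mm`, `vertex_ids`,
#'   `weights` (aligned to `vertex_ids`).
#' @export
cf_kernel <- function(mesh, source_roi, center, sigma_mm,
                      normalize = c("sum", "max")) {
  normalize <- match.arg(normalize)
  if (sigma_mm <= 0) stop("`sigma_mm` must be positive")
  center <- as.integer(center)
  if (!center %in% source_roi$vertex_ids)
    stop("center ", center, " is not in source ROI '", source_roi$name, "'")
  d <- geodesic_distances(mesh, center, source_roi$vertex_ids)
  w <- exp(-d^2 / (2 * sigma_mm^2))
  w <- if (normalize == "sum") w / sum(w) else w / max(w)
  structure(list(center = center, sigma_mm = sigma_mm,
                 vertex_ids = source_roi$vertex_ids, weights = unname(w)),
            class = "cf_kernel")
}

#' Predicted target time course from a connective-field kernel
#'
#' `p(t) = sum_j w_j s_j(t)`: linear in the source signals.
#'
#' @param kernel a `cf_kernel`.
#' @param source_block `timeseries_block` covering the kernel's vertices.
#' @return Numeric vector, one value per timepoint.
#' @export
predict_timecourse <- function(kernel, source_block) {
  sub <- block_subset(source_block, kernel$vertex_ids)
  as.numeric(kernel$weights %*% sub$values)
}

#' No-intercept OLS amplitude and variance explained
#'
#' `beta = <p, y> / <p, p>`; `VE = 1 - RSS/TSS` with the total sum of
#' squares taken about zero (series are zero-mean by preprocessing). VE can
#' be negative for pathological predictors.
#'
#' @param predictor predicted time course (not identically zero).
#' @param target_series measured target series, same length.
#' @return `list(beta, ve)`.
#' @export
ols_beta_ve <- function(predictor, target_series) {
  if (length(predictor) != length(target_series))
    stop("predictor and target have different lengths")
  pp <- sum(predictor^2)
  if (pp == 0) stop("degenerate kernel: predictor is identically zero")
  beta <- sum(predictor * target_series) / pp
  tss <- sum(target_series^2)
  rss <- tss - 2 * beta * sum(predictor * target_series) + beta^2 * pp
  list(beta = beta, ve = if (tss > 0) 1 - rss / tss else NA_real_)
}

# Precompute, per sigma, the predictor matrix P (centers x timepoints) and
# row sums of squares, shared across target vertices. D is the source-ROI
# geodesic distance matrix and S the source series (vertices x timepoints).
cf_predictor_stack <- function(D, S, sigma_grid) {
  lapply(sigma_grid, function(s) {
    W <- exp(-D^2 / (2 * s^2))
    W <- W / rowSums(W)           # row c = unit-sum kernel centered at c
    P <- W %*% S
    list(P = P, pp = rowSums(P^2))
  })
}

#' Fit the connective field for one target series by exhaustive grid search
#'
#' Searches every source-ROI vertex as candidate center crossed with
#' `sigma_grid_mm`, retaining the model with maximal variance explained;
#' beta is the no-intercept OLS amplitude. Ties are broken toward the
#' smallest sigma, then the lowest center vertex id (deterministic).
#'
#' @param mesh a `cortical_mesh`.
#' @param source_roi a `cf_roi` (connected on the mesh).
#' @param source_block source `timeseries_block`.
#' @param target_series numeric vector, one value per timepoint.
#' @param sigma_grid_mm ascending positive kernel widths in mm.
#' @return Object of class `cf_fit`: `center`, `sigma_mm`, `beta`, `ve`.
#' @export
fit_cf_grid <- function(mesh, source_roi, source_block, target_series,
                        sigma_grid_mm = default_sigma_grid()) {
  check_sigma_grid(sigma_grid_mm)
  assert_roi_connected(mesh, source_roi)
  S <- block_subset(source_block, source_roi$vertex_ids)$values
  if (ncol(S) != length(target_series))
    stop("target series length does not match the source block")
  D <- geodesic_distance_matrix(mesh, source_roi$vertex_ids)
  stack <- cf_predictor_stack(D, S, sigma_grid_mm)
  fit_from_stack(stack, sigma_grid_mm, source_roi$vertex_ids, target_series)
}

check_sigma_grid <- function(sigma_grid_mm) {
  if (length(sigma_grid_mm) == 0L) stop("sigma grid is empty")
  if (any(sigma_grid_mm <= 0)) stop("sigma grid must be positive")
  if (is.unsorted(sigma_grid_mm, strictly = TRUE))
    stop("sigma grid must be strictly ascending")
  invisible(TRUE)
}

fit_from_stack <- function(stack, sigma_grid_mm, source_ids, y) {
  tss <- sum(y^2)
  best <- list(ve = -Inf)
  for (i in seq_along(stack)) {
    py <- as.numeric(stack[[i]]$P %*% y)
    pp <- unname(stack[[i]]$pp)
    ve <- py^2 / (pp * tss)
    j <- which.max(ve)                 # lowest index on ties
    if (ve[j] > best$ve) {             # strict: earlier (smaller) sigma wins ties
      best <- list(center = source_ids[j], sigma_mm = sigma_grid_mm[i],
                   beta = py[j] / pp[j], ve = ve[j])
    }
  }
  structure(best[c("center", "sigma_mm", "beta", "ve")], class = "cf_fit")
}

#' @export
print.cf_fit <- function(x, ...) {
  cat(sprintf("cf_fit: center %d, sigma %.3f mm, beta %.4g, VE %.3f\n",
              x$center, x$sigma_mm, x$beta, x$ve))
  invisible(x)
}

#' Fit connective fields for every vertex of a target region
#'
#' Applies [fit_cf_grid()] per target vertex, sharing the precomputed
#' predictor stack; results are independent of vertex order.
#'
#' @inheritParams fit_cf_grid
#' @param target_roi a `cf_roi` disjoint from the source ROI.
#' @param target_block target `timeseries_block`.
#' @param verbose log progress every 50 vertices.
#' @return Data.frame of class `cf_fit_table` with one row per target
#'   vertex: `target_vertex`, `center`, `sigma_mm`, `beta`, `ve`.
#' @export
fit_cf_map <- function(mesh, source_roi, target_roi, source_block,
                       target_block, sigma_grid_mm = default_sigma_grid(),
                       verbose = FALSE) {
  check_sigma_grid(sigma_grid_mm)
  if (length(intersect(source_roi$vertex_ids, target_roi$vertex_ids)))
    stop("source ROI '", source_roi$name, "' and target ROI '",
         target_roi$name, "' overlap")
  assert_roi_connected(mesh, source_roi)
  S <- block_subset(source_block, source_roi$vertex_ids)$values
  Yb <- block_subset(target_block, target_roi$vertex_ids)
  if (ncol(S) != ncol(Yb$values))
    stop("source and target blocks have different numbers of timepoints")
  D <- geodesic_distance_matrix(mesh, source_roi$vertex_ids)
  stack <- cf_predictor_stack(D, S, sigma_grid_mm)
  rows <- lapply(seq_along(Yb$vertex_ids), function(i) {
    if (verbose && i %% 50L == 0L)
      message("fit_cf_map: ", i, "/", length(Yb$vertex_ids))
    f <- fit_from_stack(stack, sigma_grid_mm, source_roi$vertex_ids,
                        Yb$values[i, ])
    data.frame(target_vertex = Yb$vertex_ids[i], center = f$center,
               sigma_mm = f$sigma_mm, beta = f$beta, ve = f$ve)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cf_fit_table", "data.frame")
  out
}

#' Write a connective-field fit table as tab-delimited text
#'
#' @param fits a `cf_fit_table` (or any data.frame of per-vertex results).
#' @param path output path.
#' @export
write_fit_table <- function(fits, path) {
  df <- as.data.frame(lapply(fits, function(col)
    if (is.double(col)) sprintf("%.12g", col) else col))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
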