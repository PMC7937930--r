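# Synthetic cortical scenes with known ground truth. The generative model is
# the connective-field model read forwards: target series are beta-scaled,
# geodesic-Gaussian-weighted sums of source series plus white Gaussian
# noise. Source signals are spatially correlated, band-limited Gaussian
# processes emulating resting-state BOLD in the 0.01-0.1 Hz band.

#' Regular visuotopic cortical patch
#'
#' Builds a regularly triangulated `n_rows x n_cols` grid patch (edge length
#' `edge_mm`) with a smooth visuotopic parameterization: eccentricity varies
#' log-linearly along rows (the cortical magnification convention) and polar
#' angle linearly along columns. pRF sizes grow linearly with eccentricity;
#' pRF variance explained is 1 everywhere (the map is exact by
#' construction).
#'
#' @param n_rows,n_cols grid dimensions (>= 2).
#' @param edge_mm grid spacing in mm (default 1.5, ~3T voxel pitch).
#' @param ecc_range_deg eccentricity range in degrees, within (0, 10.2]
#'   (the stimulus radius that a visual-field-mapping pRF map would cover).
#' @param angle_range_rad polar angle range in radians (default a
#'   quarterfield around the horizontal meridian).
#' @param seed unused source of randomness (the patch is deterministic);
#'   kept so all generators share one signature.
#' @return `list(mesh, prf)`: a `cortical_mesh` and a [prf_map()] with one
#'   row per vertex, row-major vertex order (vertex = (row-1)*n_cols + col).
#' @export
make_visuotopic_patch <- function(n_rows, n_cols, edge_mm = 1.5,
                                  ecc_range_deg = c(1, 7),
                                  angle_range_rad = c(-pi / 4, pi / 4),
                                  seed = NULL) {
  if (n_rows < 2L || n_cols < 2L) stop("need n_rows, n_cols >= 2")
  if (length(ecc_range_deg) != 2L || any(ecc_range_deg <= 0) ||
      any(ecc_range_deg > 10.2) || diff(ecc_range_deg) <= 0)
    stop("`ecc_range_deg` must be increasing and lie within (0, 10.2]")
  if (diff(angle_range_rad) <= 0 || diff(angle_range_rad) > 2 * pi)
    stop("`angle_range_rad` must be increasing, spanning at most 2*pi")

  s <- seq(0, 1, length.out = n_rows)
  ecc_rows <- exp(log(ecc_range_deg[1]) + s * diff(log(ecc_range_deg)))
  ecc_rows[c(1L, n_rows)] <- ecc_range_deg       # exact endpoints
  ang_cols <- seq(angle_range_rad[1], angle_range_rad[2], length.out = n_cols)

  idx <- function(r, c) (r - 1L) * n_cols + c
  rc <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  coords <- cbind((rc$col - 1L) * edge_mm, (rc$row - 1L) * edge_mm, 0)
  tri <- do.call(rbind, lapply(seq_len(n_rows - 1L), function(r) {
    c0 <- seq_len(n_cols - 1L)
    rbind(cbind(idx(r, c0), idx(r, c0 + 1L), idx(r + 1L, c0)),
          cbind(idx(r, c0 + 1L), idx(r + 1L, c0 + 1L), idx(r + 1L, c0)))
  }))
  mesh <- cortical_mesh(coords, tri)

  ecc <- ecc_rows[rc$row]
  ang <- ang_cols[rc$col]
  prf <- prf_map(vertex_id = seq_len(nrow(coords)),
                 x0_deg = ecc * cos(ang), y0_deg = ecc * sin(ang),
                 sigma_prf_deg = 0.5 + 0.3 * ecc, ve = 1)
  # the parameterization is exact by construction; bypass the 1-ulp jitter
  # of rederiving (ecc, angle) from (x0, y0)
  prf$ecc_deg <- ecc
  prf$polar_rad <- ang
  list(mesh = mesh, prf = prf)
}

#' Simulate resting-state-like source signals
#'
#' Zero-mean, unit-variance per-vertex Gaussian series whose pairwise
#' correlation decays with geodesic distance (squared-exponential mixing
#' kernel with length scale `spatial_corr_mm`) and whose spectral power is
#' confined to `band_hz` by a Fourier mask. An optional AR(1) coefficient
#' adds temporal autocorrelation before filtering (robustness checks).
#'
#' @param mesh a `cortical_mesh`.
#' @param roi `cf_roi` of vertices to simulate.
#' @param n_timepoints number of volumes (default 350).
#' @param tr_s sampling interval in seconds (default 2).
#' @param spatial_corr_mm correlation length scale in mm; 0 gives
#'   independent vertices (default 3).
#' @param band_hz passband `c(low, high)` in Hz, within `[0, Nyquist]`
#'   (default 0.01-0.1 Hz).
#' @param ar1 AR(1) coefficient of the innovations (default 0, white).
#' @param seed RNG seed.
#' @return A `timeseries_block` over the ROI vertices.
#' @export
simulate_source_signals <- function(mesh, roi, n_timepoints = 350L, tr_s = 2,
                                    spatial_corr_mm = 3, band_hz = c(0.01, 0.1),
                                    ar1 = 0, seed = NULL) {
  if (spatial_corr_mm < 0) stop("`spatial_corr_mm` must be >= 0")
  nyq <- 1 / (2 * tr_s)
  if (length(band_hz) != 2L || band_hz[1] < 0 || band_hz[2] <= band_hz[1])
    stop("`band_hz` must be c(low, high) with 0 <= low < high")
  if (band_hz[2] > nyq)
    stop("band upper edge ", band_hz[2], " Hz exceeds Nyquist (", nyq, " Hz)")
  if (!is.null(seed)) set.seed(seed)

  n <- length(roi$vertex_ids)
  E <- matrix(rnorm(n * n_timepoints), n, n_timepoints)
  if (ar1 != 0) {
    for (t in 2:n_timepoints) E[, t] <- ar1 * E[, t - 1L] + E[, t]
  }
  if (spatial_corr_mm > 0) {
    D <- geodesic_distance_matrix(mesh, roi$vertex_ids)
    K <- exp(-D^2 / (2 * spatial_corr_mm^2))
    E <- K %*% E
  }
  # two-sided Fourier mask keeping |f| inside the band
  f <- seq_len(n_timepoints) - 1L
  f <- pmin(f, n_timepoints - f) / (n_timepoints * tr_s)
  keep <- f >= band_hz[1] & f <= band_hz[2]
  if (!any(keep)) stop("passband contains no Fourier frequency at this length/TR")
  X <- mvfft(t(E))
  X[!keep, ] <- 0
  E <- t(Re(mvfft(X, inverse = TRUE))) / n_timepoints
  E <- E - rowMeans(E)
  E <- E / apply(E, 1, sd)
  timeseries_block(E, tr_s, roi$vertex_ids)
}

#' Ground truth for synthetic target vertices
#'
#' @param target_vertex target vertex ids.
#' @param center true connective-field center vertex (in the source ROI).
#' @param sigma_mm true kernel width in mm (> 0 wherever beta > 0; ignored
#'   for uncoupled vertices).
#' @param beta true amplitude (>= 0; 0 encodes "uncoupled", pure noise).
#' @param noise_sd additive white-noise standard deviation.
#' @param regime `"RS"` or `"VFM"` tag (bookkeeping only).
#' @param source_roi optional `cf_roi`; when given, centers are checked to
#'   lie inside it.
#' @return Data.frame of class `cf_ground_truth` with `noise_sd` and
#'   `regime` attributes.
#' @export
synthetic_ground_truth <- function(target_vertex, center, sigma_mm, beta,
                                   noise_sd, regime = c("RS", "VFM"),
                                   source_roi = NULL) {
  regime <- match.arg(regime)
  n <- length(target_vertex)
  df <- data.frame(target_vertex = as.integer(target_vertex),
                   center = as.integer(rep_len(center, n)),
                   sigma_mm = rep_len(as.numeric(sigma_mm), n),
                   beta = rep_len(as.numeric(beta), n))
  if (any(df$beta < 0)) stop("true beta must be >= 0")
  if (any(df$beta > 0 & !(df$sigma_mm > 0)))
    stop("true sigma_mm must be > 0 wherever beta > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.null(source_roi) && !all(df$center %in% source_roi$vertex_ids))
    stop("every true center must lie in the source ROI")
  attr(df, "noise_sd") <- as.numeric(noise_sd)
  attr(df, "regime") <- regime
  class(df) <- c("cf_ground_truth", "data.frame")
  df
}

#' Generate target series from the connective-field forward model
#'
#' `y_v(t) = beta_v * sum_j w_j(center_v, sigma_v) s_j(t) + noise`, with w
#' the unit-sum geodesic Gaussian kernel over the source ROI and white
#' Gaussian noise of sd `attr(truth, "noise_sd")`. `beta = 0` rows yield
#' pure noise.
#'
#' @param source_block source `timeseries_block` (the s_j).
#' @param mesh a `cortical_mesh`.
#' @param source_roi `cf_roi` the kernels live on.
#' @param truth a [synthetic_ground_truth()] table.
#' @param seed RNG seed for the noise.
#' @return Target `timeseries_block` aligned to `truth$target_vertex`.
#' @export
simulate_target_from_cf <- function(source_block, mesh, source_roi, truth,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(truth$center %in% source_roi$vertex_ids))
    stop("every true center must lie in the source ROI")
  nt <- n_timepoints(source_block)
  noise_sd <- attr(truth, "noise_sd")
  vals <- matrix(0, nrow(truth), nt)
  for (i in seq_len(nrow(truth))) {
    if (truth$beta[i] > 0) {
      k <- cf_kernel(mesh, source_roi, truth$center[i], truth$sigma_mm[i])
      vals[i, ] <- truth$beta[i] * predict_timecourse(k, source_block)
    }
    if (noise_sd > 0) vals[i, ] <- vals[i, ] + rnorm(nt, sd = noise_sd)
  }
  timeseries_block(vals, source_block$tr_s, truth$target_vertex)
}

#' Default synthetic scene configuration
#'
#' The stated world of the synthetic experiments: a 20-column source region
#' (400 vertices) and a 5-column target strip (100 vertices) separated by a
#' one-column gap on a 20-row patch; 350 volumes at TR 2 s per scan in the
#' 0.01-0.1 Hz band; unit true beta and unit noise sd, which places fitted
#' VE around the 0.15 working threshold.
#'
#' @param ... overrides for any listed element.
#' @return Named list of scene parameters.
#' @export
synthetic_scene_config <- function(...) {
  cfg <- list(
    n_rows = 20L, n_source_cols = 20L, n_target_cols = 5L, gap_cols = 1L,
    edge_mm = 1.5, ecc_range_deg = c(1, 7), angle_range_rad = c(-pi / 4, pi / 4),
    n_timepoints = 350L, tr_s = 2, spatial_corr_mm = 3,
    band_hz = c(0.01, 0.1), ar1 = 0,
    sigma_choices_mm = NULL,   # default: interior values of the fit grid
    beta = 1, noise_sd = 1)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown scene parameter(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

# Lay out source/target ROIs on a patch: source = left column block,
# target = right column block, separated by gap_cols unused columns.
scene_geometry <- function(cfg) {
  n_cols <- cfg$n_source_cols + cfg$gap_cols + cfg$n_target_cols
  patch <- make_visuotopic_patch(cfg$n_rows, n_cols, cfg$edge_mm,
                                 cfg$ecc_range_deg, cfg$angle_range_rad)
  col_of <- rep(seq_len(n_cols), times = cfg$n_rows)
  src <- which(col_of <= cfg$n_source_cols)
  tgt <- which(col_of > cfg$n_source_cols + cfg$gap_cols)
  list(mesh = patch$mesh, prf = patch$prf,
       source_roi = cf_roi("V1", src, patch$mesh),
       target_roi = cf_roi("V2", tgt, patch$mesh))
}

#' Paired-scan synthetic experiment
#'
#' Builds a visuotopic patch with disjoint source and target regions, draws
#' one ground truth (true centers uniform over the source ROI, true sigma
#' sampled from `sigma_choices_mm`, shared beta and noise sd), and
#' generates two scans as independent signal and noise realizations over
#' that identical ground truth - the synthetic counterpart of acquiring RS1
#' and RS2 in one session.
#'
#' @param config a [synthetic_scene_config()] list (or overrides for it).
#' @param seed master seed; scan-specific seeds are derived from it.
#' @return List: `mesh`, `prf`, `source_roi`, `target_roi`, `truth`, and
#'   `scans`, a length-2 list each holding `source` and `target`
#'   `timeseries_block`s.
#' @export
make_two_scan_experiment <- function(config = synthetic_scene_config(),
                                     seed = 1L) {
  cfg <- synthetic_scene_config(config)
  geo <- scene_geometry(cfg)
  set.seed(seed)
  sigma_choices <- cfg$sigma_choices_mm
  if (is.null(sigma_choices)) sigma_choices <- default_sigma_grid()[9:15]
  n_t <- length(geo$target_roi$vertex_ids)
  truth <- synthetic_ground_truth(
    target_vertex = geo$target_roi$vertex_ids,
    center = sample(geo$source_roi$vertex_ids, n_t, replace = TRUE),
    sigma_mm = sample(sigma_choices, n_t, replace = TRUE),
    beta = cfg$beta, noise_sd = cfg$noise_sd,
    regime = "RS", source_roi = geo$source_roi)
  scans <- lapply(1:2, function(k) {
    src <- simulate_source_signals(geo$mesh, geo$source_roi, cfg$n_timepoints,
                                   cfg$tr_s, cfg$spatial_corr_mm, cfg$band_hz,
                                   cfg$ar1, seed = derive_seed(seed, 10L + k))
    tgt <- simulate_target_from_cf(src, geo$mesh, geo$source_roi, truth,
                                   seed = derive_seed(seed, 20L + k))
    list(source = src, target = tgt)
  })
  c(geo, list(truth = truth, scans = scans, config = cfg, seed = seed))
}

# Deterministic substream seeds below 2^31 (R integers are 32-bit).
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1009 + 97 * as.numeric(offset)) %% 2147483647)
}

#' Write a synthetic scene as plain-text fixtures
#'
#' GIFTI surface + labels, tab-delimited series, JSON ground truth and pRF
#' map - everything needed to reload the scene through the file-based path.
#'
#' @param experiment result of [make_two_scan_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene_fixtures <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gifti_surface(experiment$mesh, file.path(dir, "patch.surf.gii"))
  write_gifti_label(experiment$source_roi$vertex_ids, file.path(dir, "V1.label.gii"))
  write_gifti_label(experiment$target_roi$vertex_ids, file.path(dir, "V2.label.gii"))
  for (k in seq_along(experiment$scans)) {
    write_series_tsv(experiment$scans[[k]]$source,
                     file.path(dir, sprintf("scan%d_source.tsv", k)))
    write_series_tsv(experiment$scans[[k]]$target,
                     file.path(dir, sprintf("scan%d_target.tsv", k)))
  }
  jsonlite::write_json(
    list(truth = as.data.frame(experiment$truth),
         noise_sd = attr(experiment$truth, "noise_sd"),
         regime = attr(experiment$truth, "regime"),
         prf = as.data.frame(experiment$prf)),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
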