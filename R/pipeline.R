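# End-to-end orchestration: simulate (or load) a scene, preprocess, fit the
# standard and Bayesian connective-field maps, derive the surrogate null
# and FWE beta threshold, back-project to visual-field coordinates, apply
# the map filters, and write every artifact as plain text with a
# provenance manifest. A single master seed feeds named substreams so any
# stage can be re-run in isolation.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (simulate the scene) or `"files"` (load
#'   surface/labels/series/pRF from disk).
#' @param scene [synthetic_scene_config()] overrides (synthetic mode).
#' @param files named list for file mode: `surface`, `labels` (named
#'   character vector with source first), `source_series`,
#'   `target_series`, `prf` (tab-delimited pRF table).
#' @param source_roi,target_roi ROI names used for fitting (file mode;
#'   defaults: first and second label).
#' @param preprocess list: `highpass_hz`, `lowpass_hz`, `butter_order`,
#'   `psc`, `enabled`.
#' @param sigma_grid_mm grid for the standard fit.
#' @param mcmc a [cf_mcmc_config()].
#' @param threshold list: `ve_min`, `fwe_percentile`, `n_realizations`,
#'   `null_fit_method`, `discard_sigma_below`.
#' @param filter list: `ve_min`, `ecc_range` for the visuotopic map filter.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return Nested named list of class `cf_run_config`, validated.
#' @export
cf_run_config <- function(mode = c("synthetic", "files"), scene = list(),
                          files = list(), source_roi = NULL, target_roi = NULL,
                          preprocess = list(), sigma_grid_mm = default_sigma_grid(),
                          mcmc = cf_mcmc_config(), threshold = list(),
                          filter = list(), seed = 1L) {
  mode <- match.arg(mode)
  pre <- utils::modifyList(list(enabled = TRUE, highpass_hz = 0.01,
                                lowpass_hz = 0.1, butter_order = 4L,
                                psc = FALSE), preprocess)
  thr <- utils::modifyList(list(ve_min = 0.15, fwe_percentile = 95,
                                n_realizations = 1L,
                                null_fit_method = "bayes",
                                discard_sigma_below = 0), threshold)
  flt <- utils::modifyList(list(ve_min = 0.15, ecc_range = c(1, 7)), filter)
  check_sigma_grid(sigma_grid_mm)
  stopifnot(inherits(mcmc, "cf_mcmc_config"))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  if (mode == "files") {
    need <- c("surface", "labels", "source_series", "target_series", "prf")
    miss <- setdiff(need, names(files))
    if (length(miss))
      stop("file mode requires `files$", paste(miss, collapse = "`, `files$"),
           "`")
  }
  structure(list(mode = mode, scene = scene, files = files,
                 source_roi = source_roi, target_roi = target_roi,
                 preprocess = pre, sigma_grid_mm = sigma_grid_mm, mcmc = mcmc,
                 threshold = thr, filter = flt, seed = as.integer(seed)),
            class = "cf_run_config")
}

load_run_inputs <- function(config) {
  if (config$mode == "synthetic") {
    cfg <- synthetic_scene_config(config$scene)
    geo <- scene_geometry(cfg)
    set.seed(config$seed)
    sigma_choices <- cfg$sigma_choices_mm
    if (is.null(sigma_choices)) sigma_choices <- default_sigma_grid()[9:15]
    n_t <- length(geo$target_roi$vertex_ids)
    truth <- synthetic_ground_truth(
      geo$target_roi$vertex_ids,
      sample(geo$source_roi$vertex_ids, n_t, replace = TRUE),
      sample(sigma_choices, n_t, replace = TRUE),
      cfg$beta, cfg$noise_sd, "RS", geo$source_roi)
    src <- simulate_source_signals(geo$mesh, geo$source_roi, cfg$n_timepoints,
                                   cfg$tr_s, cfg$spatial_corr_mm, cfg$band_hz,
                                   cfg$ar1, seed = derive_seed(config$seed, 11L))
    tgt <- simulate_target_from_cf(src, geo$mesh, geo$source_roi, truth,
                                   seed = derive_seed(config$seed, 21L))
    c(geo, list(source_block = src, target_block = tgt, truth = truth))
  } else {
    patch <- build_patch_from_files(config$files$surface, config$files$labels)
    roi_names <- names(patch$rois)
    src_name <- if (is.null(config$source_roi)) roi_names[1] else config$source_roi
    tgt_name <- if (is.null(config$target_roi)) roi_names[2] else config$target_roi
    remap_block <- function(path) {
      blk <- read_series_tsv(path)
      ids <- match(blk$vertex_ids, patch$vertex_map)
      if (anyNA(ids)) stop("series in ", path, " cover vertices outside the patch")
      timeseries_block(blk$values, blk$tr_s, ids, patch$mesh)
    }
    prf_df <- utils::read.table(config$files$prf, header = TRUE, sep = "\t")
    ids <- match(prf_df$vertex_id, patch$vertex_map)
    prf <- prf_map(ids[!is.na(ids)], prf_df$x0_deg[!is.na(ids)],
                   prf_df$y0_deg[!is.na(ids)],
                   prf_df$sigma_prf_deg[!is.na(ids)], prf_df$ve[!is.na(ids)])
    list(mesh = patch$mesh, prf = prf,
         source_roi = patch$rois[[src_name]],
         target_roi = patch$rois[[tgt_name]],
         source_block = remap_block(config$files$source_series),
         target_block = remap_block(config$files$target_series),
         truth = NULL)
  }
}

#' Run the full connective-field analysis
#'
#' Preprocess, standard grid fit, Bayesian fit with uncertainties,
#' IAAFT-surrogate null and FWE beta threshold, voxel selection,
#' visuotopic back-projection and map filter - writing each artifact to
#' `out_dir` as tab-delimited text or JSON plus a provenance manifest.
#' Two runs with identical config and seed produce byte-identical numeric
#' outputs.
#'
#' @param config a [cf_run_config()].
#' @param out_dir artifact directory (created; default a tempdir).
#' @return Invisibly, a list with every in-memory artifact (`grid_fits`,
#'   `bayes_fits`, `null_beta`, `selection`, `assignments`, `retained`,
#'   `inputs`, `out_dir`).
#' @export
run_pipeline <- function(config = cf_run_config(), out_dir = tempfile("cfrun")) {
  stopifnot(inherits(config, "cf_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- "load"
  log <- list()
  result <- tryCatch({
    inputs <- load_run_inputs(config)
    log$load <- sprintf("%d source / %d target vertices, %d timepoints",
                        length(inputs$source_roi$vertex_ids),
                        length(inputs$target_roi$vertex_ids),
                        n_timepoints(inputs$source_block))
    stage <- "preprocess"
    if (config$preprocess$enabled) {
      pp <- config$preprocess
      inputs$source_block <- preprocess_block(inputs$source_block, pp$highpass_hz,
                                              pp$lowpass_hz, pp$butter_order, pp$psc)
      inputs$target_block <- preprocess_block(inputs$target_block, pp$highpass_hz,
                                              pp$lowpass_hz, pp$butter_order, pp$psc)
    }
    stage <- "fit_grid"
    grid_fits <- fit_cf_map(inputs$mesh, inputs$source_roi, inputs$target_roi,
                            inputs$source_block, inputs$target_block,
                            config$sigma_grid_mm)
    write_fit_table(grid_fits, file.path(out_dir, "fits_grid.tsv"))
    stage <- "fit_bayes"
    mcmc <- config$mcmc
    mcmc$seed <- derive_seed(config$seed, 31L)
    bayes_fits <- fit_cf_bayes_map(inputs$mesh, inputs$source_roi,
                                   inputs$target_roi, inputs$source_block,
                                   inputs$target_block, mcmc,
                                   warn_acceptance = FALSE)
    write_fit_table(bayes_fits, file.path(out_dir, "fits_bayes.tsv"))
    stage <- "null_threshold"
    thr <- config$threshold
    null_beta <- null_beta_distribution(
      inputs$mesh, inputs$source_roi, inputs$target_roi, inputs$source_block,
      inputs$target_block, fit_method = thr$null_fit_method,
      config = if (thr$null_fit_method == "bayes") mcmc else config$sigma_grid_mm,
      n_realizations = thr$n_realizations, percentile = thr$fwe_percentile,
      seed = derive_seed(config$seed, 41L))
    jsonlite::write_json(list(percentile = null_beta$percentile,
                              fwe_threshold = null_beta$fwe_threshold,
                              fit_method = null_beta$fit_method,
                              null_betas = null_beta$null_betas),
                         file.path(out_dir, "null_beta.json"),
                         digits = NA, auto_unbox = TRUE)
    selection <- select_voxels(bayes_fits, ve_min = thr$ve_min,
                               beta_threshold = null_beta$fwe_threshold,
                               discard_sigma_below = thr$discard_sigma_below)
    write_fit_table(data.frame(target_vertex = bayes_fits$target_vertex,
                               ve_mask = selection$ve_mask,
                               beta_mask = selection$beta_mask),
                    file.path(out_dir, "masks.tsv"))
    stage <- "backproject"
    assignments <- backproject(grid_fits, inputs$prf)
    retained <- map_filter(assignments, grid_fits, config$filter$ve_min,
                           config$filter$ecc_range)
    write_fit_table(cbind(assignments,
                          data.frame(retained = as.logical(retained))),
                    file.path(out_dir, "visuotopy.tsv"))
    stage <- "manifest"
    if (!is.null(inputs$truth)) {
      recov <- mean(grid_fits$center == inputs$truth$center)
      log$recovery <- sprintf("grid center recovery %.1f%%", 100 * recov)
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("confield")),
      seed = config$seed, mode = config$mode,
      config_hash = config_hash(config),
      stages = names(log), log = log,
      selection_counts = as.list(selection$counts),
      fwe_threshold = null_beta$fwe_threshold,
      retained_count = sum(retained),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
    list(grid_fits = grid_fits, bayes_fits = bayes_fits,
         null_beta = null_beta, selection = selection,
         assignments = assignments, retained = retained,
         inputs = inputs, config = config, out_dir = out_dir)
  }, error = function(e) {
    jsonlite::write_json(list(failed_stage = stage,
                              error = conditionMessage(e),
                              partial_artifacts = list.files(out_dir)),
                         file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# Stable hash of the configuration for the provenance manifest.
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 15)),
               collapse = "\n")
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97 + 1)) %% 2147483647
}

#' Test-retest comparison of two pipeline runs
#'
#' For each connective-field parameter (back-projected eccentricity and
#' polar angle, CF size, beta): ICC restricted to the strongest-VE voxel
#' fraction, Pearson (eccentricity, sigma, beta) or Fisher-Lee circular
#' (polar angle) correlation over all shared vertices, and the mean
#' coefficient of variation across the paired estimates.
#'
#' @param run1,run2 results of [run_pipeline()] (in-memory lists) over the
#'   same mesh/ROIs, or artifact directories containing `fits_grid.tsv`
#'   and `visuotopy.tsv`.
#' @param model `"grid"` (standard fit, default) or `"bayes"`.
#' @param icc_percentile VE percentile(s) for the ICC voxel selection
#'   (default 5; pass `c(1, 5, 10, 25, 50)` for the sweep).
#' @param icc_variant ICC form, see [icc()].
#' @param seed seed for the circular-correlation permutations.
#' @return Object of class `cf_reliability_report`: per-parameter ICC (per
#'   percentile), correlations, CV, and sample sizes.
#' @export
compare_scans <- function(run1, run2, model = c("grid", "bayes"),
                          icc_percentile = 5, icc_variant = "ICC31",
                          seed = 1L) {
  model <- match.arg(model)
  g1 <- scan_tables(run1, model); g2 <- scan_tables(run2, model)
  if (!identical(g1$fits$target_vertex, g2$fits$target_vertex))
    stop("runs cover different target vertices: ",
         paste(head(symdiff_int(g1$fits$target_vertex,
                                g2$fits$target_vertex), 5), collapse = ", "))
  params <- list(
    eccentricity = list(v1 = g1$vf$ecc_deg, v2 = g2$vf$ecc_deg, circular = FALSE),
    polar_angle = list(v1 = g1$vf$polar_rad, v2 = g2$vf$polar_rad, circular = TRUE),
    cf_size = list(v1 = g1$fits$sigma_mm, v2 = g2$fits$sigma_mm, circular = FALSE),
    beta = list(v1 = g1$fits$beta, v2 = g2$fits$beta, circular = FALSE))
  ve_pool <- pmin(g1$fits$ve, g2$fits$ve)   # strong in both scans
  report <- lapply(names(params), function(nm) {
    p <- params[[nm]]
    ok <- is.finite(p$v1) & is.finite(p$v2)
    corr <- if (p$circular)
      circular_corr(p$v1[ok], p$v2[ok], seed = seed)
    else pearson_r(p$v1[ok], p$v2[ok])
    iccs <- lapply(icc_percentile, function(pct) {
      idx <- order(ve_pool, decreasing = TRUE)[
        seq_len(max(5L, ceiling(sum(ok) * pct / 100)))]
      idx <- idx[ok[idx]]
      res <- icc(p$v1[idx], p$v2[idx], variant = icc_variant)
      c(percentile = pct, icc = res$icc, ci_lo = res$ci[1], ci_hi = res$ci[2],
        n = res$n)
    })
    # CV is undefined for circular quantities (the mean can sit at zero)
    cv <- if (p$circular) NA_real_ else
      mean(vapply(which(ok), function(i)
        suppressWarnings(coefficient_of_variation(c(p$v1[i], p$v2[i]))),
        numeric(1)), na.rm = TRUE)
    list(parameter = nm, r = corr$r, p = corr$p, n = corr$n,
         circular = p$circular, icc = do.call(rbind, iccs), mean_cv = cv)
  })
  names(report) <- names(params)
  structure(list(parameters = report, model = model,
                 icc_percentile = icc_percentile, icc_variant = icc_variant),
            class = "cf_reliability_report")
}

scan_tables <- function(run, model) {
  if (is.character(run)) {
    fits <- utils::read.table(
      file.path(run, if (model == "grid") "fits_grid.tsv" else "fits_bayes.tsv"),
      header = TRUE, sep = "\t")
    vf <- utils::read.table(file.path(run, "visuotopy.tsv"),
                            header = TRUE, sep = "\t")
  } else {
    fits <- if (model == "grid") run$grid_fits else run$bayes_fits
    vf <- if (model == "grid") run$assignments
          else backproject(run$bayes_fits, run$inputs$prf)
  }
  list(fits = fits, vf = vf)
}

symdiff_int <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' @export
print.cf_reliability_report <- function(x, ...) {
  cat("Test-retest reliability (", x$model, " model, ICC ", x$icc_variant,
      ")\n", sep = "")
  for (p in x$parameters) {
    icc_main <- p$icc[1, ]
    cat(sprintf("  %-12s r = %6.3f (p = %.4g, n = %d)%s | ICC@%g%% = %6.3f [%.3f, %.3f] | mean CV = %.3f\n",
                p$parameter, p$r, p$p, p$n,
                if (p$circular) " [circular]" else "",
                icc_main[["percentile"]], icc_main[["icc"]],
                icc_main[["ci_lo"]], icc_main[["ci_hi"]], p$mean_cv))
  }
  invisible(x)
}

#' Serialize a reliability report as JSON
#'
#' @param report a `cf_reliability_report`.
#' @param path output path.
#' @export
write_reliability_report <- function(report, path) {
  jsonlite::write_json(
    list(model = report$model, icc_variant = report$icc_variant,
         parameters = lapply(report$parameters, function(p)
           list(parameter = p$parameter, r = p$r, p = p$p, n = p$n,
                circular = p$circular,
                icc = as.data.frame(p$icc), mean_cv = p$mean_cv))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
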