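# Back-projection from cortical to visual-field coordinates: each target
# vertex inherits the eccentricity and polar angle of its fitted
# connective-field center's population receptive field.

#' Back-project connective-field centers through a pRF map
#'
#' Pure deterministic lookup: target vertex -> fitted center vertex ->
#' that center's pRF (x0, y0) -> eccentricity and polar angle. Centers
#' without a pRF entry are flagged missing and excluded downstream.
#'
#' @param fits a `cf_fit_table` (column `center`).
#' @param prf a [prf_map()] covering the source region.
#' @return Data.frame of class `vf_assignment`: `target_vertex`, `center`,
#'   `ecc_deg`, `polar_rad`, `missing`.
#' @export
backproject <- function(fits, prf) {
  idx <- match(fits$center, prf$vertex_id)
  missing <- is.na(idx)
  if (any(missing))
    warning(sum(missing), " connective-field center(s) without a pRF entry; ",
            "flagged missing", call. = FALSE)
  out <- data.frame(target_vertex = fits$target_vertex, center = fits$center,
                    ecc_deg = prf$ecc_deg[idx], polar_rad = prf$polar_rad[idx],
                    missing = missing)
  class(out) <- c("vf_assignment", "data.frame")
  out
}

#' Map-level retention filter
#'
#' Retains vertices whose best fit explains more than `ve_min` of the
#' time-series variance and whose back-projected eccentricity lies inside
#' `ecc_range` (bounds inclusive) - the usual trimming of poorly fit
#' vertices and of the foveal/peripheral map edges.
#'
#' @param assignments a [backproject()] result.
#' @param fits the matching `cf_fit_table`.
#' @param ve_min variance-explained threshold (default 0.15, exclusive).
#' @param ecc_range retained eccentricity interval in degrees (default
#'   `c(1, 7)`, inclusive).
#' @return Logical retention mask aligned to `assignments` rows, with a
#'   `counts` attribute.
#' @export
map_filter <- function(assignments, fits, ve_min = 0.15, ecc_range = c(1, 7)) {
  if (nrow(assignments) != nrow(fits) ||
      !all(assignments$target_vertex == fits$target_vertex))
    stop("`assignments` and `fits` are not aligned")
  keep <- !assignments$missing &
    fits$ve > ve_min &
    assignments$ecc_deg >= ecc_range[1] & assignments$ecc_deg <= ecc_range[2]
  keep[is.na(keep)] <- FALSE
  attr(keep, "counts") <- c(n = nrow(fits), retained = sum(keep),
                            failed_ve = sum(!(fits$ve > ve_min), na.rm = TRUE),
                            out_of_ecc = sum(!(assignments$ecc_deg >= ecc_range[1] &
                                               assignments$ecc_deg <= ecc_range[2]),
                                             na.rm = TRUE))
  keep
}
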