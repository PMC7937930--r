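#' Per-vertex BOLD time-series block
#'
#' @param values numeric matrix, vertices x timepoints.
#' @param tr_s sampling interval (TR) in seconds.
#' @param vertex_ids mesh vertex ids the rows correspond to.
#' @param mesh optional `cortical_mesh` to validate alignment against.
#' @return Object of class `timeseries_block`.
#' @export
timeseries_block <- function(values, tr_s, vertex_ids, mesh = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  vertex_ids <- as.integer(vertex_ids)
  if (nrow(values) != length(vertex_ids))
    stop("rows of `values` (", nrow(values), ") must match `vertex_ids` (",
         length(vertex_ids), ")")
  if (ncol(values) < 2L) stop("need at least 2 timepoints")
  if (any(!is.finite(values))) stop("time series contain non-finite values")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("`tr_s` must be a positive scalar")
  if (!is.null(mesh) && (any(vertex_ids < 1L) || any(vertex_ids > mesh$n_vertices)))
    stop("vertex ids not on the mesh")
  structure(list(values = values, tr_s = as.numeric(tr_s),
                 vertex_ids = vertex_ids),
            class = "timeseries_block")
}

#' @export
print.timeseries_block <- function(x, ...) {
  cat(sprintf("timeseries_block: %d vertices x %d timepoints, TR = %gs\n",
              nrow(x$values), ncol(x$values), x$tr_s))
  invisible(x)
}

n_timepoints <- function(block) ncol(block$values)

block_subset <- function(block, vertex_ids) {
  idx <- match(as.integer(vertex_ids), block$vertex_ids)
  if (anyNA(idx))
    stop("vertices ", paste(head(vertex_ids[is.na(idx)], 5), collapse = ", "),
         " not present in the time-series block")
  timeseries_block(block$values[idx, , drop = FALSE], block$tr_s,
                   as.integer(vertex_ids))
}

#' Write / read a time-series block as tab-delimited text
#'
#' The first column holds vertex ids; the TR is recorded in a `# tr_s=` header
#' comment. This is the package's plain-text interchange format for
#' per-vertex series.
#'
#' @param block a `timeseries_block`.
#' @param path file path.
#' @return `write_series_tsv` returns the path invisibly; `read_series_tsv`
#'   a `timeseries_block`.
#' @export
write_series_tsv <- function(block, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_s=%.10g", block$tr_s), con)
  df <- data.frame(vertex_id = block$vertex_ids,
                   format(block$values, digits = 17, trim = TRUE, scientific = TRUE))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  tr <- as.numeric(sub("^# tr_s=", "", header))
  if (is.na(tr)) stop("missing '# tr_s=' header in ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  timeseries_block(as.matrix(df[, -1, drop = FALSE]), tr, df$vertex_id)
}

#' Population receptive field (pRF) map
#'
#' Per-vertex visual-field tuning: a 2D Gaussian centered at (x0, y0) degrees
#' with width `sigma_prf_deg`, plus the variance explained of the pRF fit.
#' Eccentricity and polar angle are derived on construction.
#'
#' @param vertex_id mesh vertex ids.
#' @param x0_deg,y0_deg visual-field position in degrees.
#' @param sigma_prf_deg pRF size in degrees (> 0).
#' @param ve variance explained of the pRF fit, in `[0, 1]`.
#' @return A data.frame of class `prf_map` with derived columns
#'   `ecc_deg` and `polar_rad` (atan2 convention, in (-pi, pi]).
#' @export
prf_map <- function(vertex_id, x0_deg, y0_deg, sigma_prf_deg, ve = 1) {
  n <- length(vertex_id)
  stopifnot(length(x0_deg) == n, length(y0_deg) == n)
  sigma_prf_deg <- rep_len(sigma_prf_deg, n)
  ve <- rep_len(ve, n)
  if (any(sigma_prf_deg <= 0)) stop("pRF sizes must be positive")
  if (any(ve < 0 | ve > 1)) stop("pRF variance explained must lie in [0, 1]")
  out <- data.frame(vertex_id = as.integer(vertex_id),
                    x0_deg = x0_deg, y0_deg = y0_deg,
                    sigma_prf_deg = sigma_prf_deg, ve = ve,
                    ecc_deg = sqrt(x0_deg^2 + y0_deg^2),
                    polar_rad = atan2(y0_deg, x0_deg))
  class(out) <- c("prf_map", "data.frame")
  out
}
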