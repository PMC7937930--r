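# Temporal preprocessing applied to per-vertex series before connective
# field fitting: discrete cosine transform high-pass (regression-out of the
# low-frequency DCT basis, the SPM convention), zero-phase 4th-order
# Butterworth low-pass, and percent-signal-change normalization.

#' Low-frequency DCT nuisance basis
#'
#' DCT-II basis functions with frequency `k / (2 N TR)` strictly below the
#' cutoff, including the constant term, plus (optionally) a linear trend
#' column: a linear drift is not exactly representable by finitely many
#' cosines, so the trend column is needed to annihilate it rather than
#' merely attenuate it.
#'
#' @param n_timepoints number of scans.
#' @param tr_s sampling interval in seconds.
#' @param cutoff_hz high-pass cutoff in Hz.
#' @param include_trend add a linear drift column (default TRUE).
#' @return Orthonormal matrix (timepoints x basis columns).
#' @export
dct_basis <- function(n_timepoints, tr_s, cutoff_hz, include_trend = TRUE) {
  N <- n_timepoints
  k_max <- ceiling(2 * N * tr_s * cutoff_hz) - 1L  # largest k with f_k < cutoff
  t <- seq_len(N) - 1L
  X <- sapply(0:max(k_max, 0L), function(k) cos(pi * (2 * t + 1) * k / (2 * N)))
  X <- matrix(X, nrow = N)
  if (include_trend) X <- cbind(X, t - mean(t))
  qr.Q(qr(X))[, seq_len(qr(X)$rank), drop = FALSE]
}

#' High-pass filter by projecting out the low-frequency DCT basis
#'
#' Removes slow drifts below `cutoff_hz` (default 0.01 Hz) from every vertex
#' series by regressing out the orthonormal nuisance basis of [dct_basis()].
#' The output is exactly orthogonal to the removed subspace and has zero
#' mean per vertex (the constant term is always removed). Projection is
#' idempotent: applying the filter twice equals applying it once.
#'
#' @param block a `timeseries_block`.
#' @param cutoff_hz high-pass cutoff in Hz (must be below Nyquist).
#' @param include_trend also remove a linear drift term (default TRUE).
#' @return Filtered `timeseries_block`.
#' @export
dct_highpass <- function(block, cutoff_hz = 0.01, include_trend = TRUE) {
  N <- n_timepoints(block)
  nyq <- 1 / (2 * block$tr_s)
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("cutoff must lie in (0, Nyquist = ", nyq, " Hz)")
  X <- dct_basis(N, block$tr_s, cutoff_hz, include_trend)
  if (ncol(X) >= N)
    stop("fewer timepoints (", N, ") than the retained DCT basis requires (",
         ncol(X), " nuisance columns)")
  Y <- t(block$values)                    # timepoints x vertices
  Yf <- Y - X %*% crossprod(X, Y)
  timeseries_block(t(Yf), block$tr_s, block$vertex_ids)
}

#' Digital Butterworth low-pass coefficients
#'
#' Designs an order-`order` low-pass Butterworth filter by bilinear transform
#' of the analog prototype with frequency prewarping, normalized to unit DC
#' gain. The analog prototype magnitude at frequency f is
#' `(1 + (f/fc)^(2 order))^(-1/2)`.
#'
#' @param order filter order (>= 1).
#' @param Wn cutoff as a fraction of Nyquist, in (0, 1).
#' @return `list(b, a)` transfer-function coefficients, `a[1] = 1`.
#' @export
butter_lowpass <- function(order, Wn) {
  if (order < 1L) stop("`order` must be >= 1")
  if (Wn <= 0 || Wn >= 1) stop("`Wn` must lie in (0, 1) (fraction of Nyquist)")
  n <- as.integer(order)
  warped <- 2 * tan(pi * Wn / 2)          # prewarped analog cutoff (fs = 1)
  k <- seq_len(n)
  p_analog <- warped * exp(1i * pi * (2 * k + n - 1) / (2 * n))
  p_z <- (2 + p_analog) / (2 - p_analog)  # bilinear: s = 2 (z-1)/(z+1)
  a <- Re(poly_from_roots(p_z))
  b <- Re(poly_from_roots(rep(-1 + 0i, n)))  # n zeros at z = -1
  gain <- sum(a) / sum(b)                 # unit gain at z = 1 (DC)
  list(b = b * gain, a = a)
}

poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
  coef
}

# Steady-state initial conditions for the direct-form-II-transposed filter,
# so the forward-backward pass starts without a step transient.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  if (nf == 1L) return(numeric(0))
  A <- rbind(-a[-1], cbind(diag(1, nf - 2, nf - 2), 0))
  if (nf == 2L) A <- matrix(-a[2], 1, 1)
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(nf - 1) - t(A), B))
}

# Zero-phase filtering: odd-padded forward-backward pass with steady-state
# initial conditions (the usual filtfilt scheme).
filtfilt1 <- function(b, a, x) {
  nf <- max(length(a), length(b))
  padlen <- 3L * nf
  if (length(x) <= padlen)
    stop("series too short for zero-phase filtering (need > ", padlen,
         " timepoints for the edge padding)")
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1L):2L], x,
           2 * x[length(x)] - x[(length(x) - 1L):(length(x) - padlen)])
  y <- .iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(.iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + length(x))]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies the digital Butterworth low-pass of [butter_lowpass()] forward
#' and backward (zero phase), so the effective magnitude response is the
#' square of the single-pass response and no phase distortion is introduced
#' that could bias connective-field fits.
#'
#' @param block a `timeseries_block`.
#' @param cutoff_hz low-pass cutoff in Hz (default 0.1, below Nyquist).
#' @param order filter order (default 4).
#' @return Filtered `timeseries_block`.
#' @export
butterworth_lowpass <- function(block, cutoff_hz = 0.1, order = 4L) {
  nyq <- 1 / (2 * block$tr_s)
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("cutoff must lie in (0, Nyquist = ", nyq, " Hz)")
  ba <- butter_lowpass(order, cutoff_hz / nyq)
  vals <- t(apply(block$values, 1, function(x) filtfilt1(ba$b, ba$a, x)))
  timeseries_block(vals, block$tr_s, block$vertex_ids)
}

#' Band-pass preprocessing cascade
#'
#' DCT high-pass first, then zero-phase Butterworth low-pass — the order
#' used for resting-state series before connective-field fitting.
#'
#' @param block a `timeseries_block`.
#' @param highpass_hz DCT high-pass cutoff (default 0.01 Hz).
#' @param lowpass_hz Butterworth low-pass cutoff (default 0.1 Hz).
#' @param butter_order Butterworth order (default 4).
#' @param psc convert to percent signal change first (default FALSE; raw
#'   scanner-unit inputs only — synthetic series are already zero-mean).
#' @return Filtered `timeseries_block`.
#' @export
preprocess_block <- function(block, highpass_hz = 0.01, lowpass_hz = 0.1,
                             butter_order = 4L, psc = FALSE) {
  if (psc) block <- percent_signal_change(block)
  block <- dct_highpass(block, highpass_hz)
  butterworth_lowpass(block, lowpass_hz, butter_order)
}

#' Percent signal change normalization
#'
#' `100 * (x - mean) / mean` per vertex, so the connective-field beta reads
#' as an amplitude scaling between comparable units.
#'
#' @param block a `timeseries_block` in raw intensity units (per-vertex mean
#'   must be nonzero; already zero-mean data should skip this step).
#' @return Normalized `timeseries_block` with exact zero mean per vertex.
#' @export
percent_signal_change <- function(block) {
  mu <- rowMeans(block$values)
  if (any(abs(mu) < 1e-10 * apply(abs(block$values), 1, max) | mu == 0))
    stop("per-vertex mean is (near) zero; input looks already centered - ",
         "skip percent_signal_change for zero-mean data")
  vals <- 100 * sweep(sweep(block$values, 1, mu, "-"), 1, mu, "/")
  timeseries_block(vals, block$tr_s, block$vertex_ids)
}
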