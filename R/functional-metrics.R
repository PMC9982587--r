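# Resting-state regional metrics from voxel-neighbourhood time series.
#
# ALFF: band-limited spectral amplitude (sum over 0.01-0.08 Hz of the
# square-root periodogram of the linearly detrended series, no taper).
# fALFF: that amplitude as a fraction of the full-spectrum amplitude
# excluding DC. ReHo: Kendall's coefficient of concordance W of the voxels'
# rank time series, with the standard tie correction.

as_timeseries_block <- function(ts) {
  if (inherits(ts, "timeseries_block")) return(ts)
  stop_("expected a `timeseries_block` (see gen_timeseries())")
}

check_block <- function(ts) {
  ts <- as_timeseries_block(ts)
  if (!is.matrix(ts$series) || !all(is.finite(ts$series)))
    stop_("time-series block must be a finite numeric matrix")
  check_number(ts$tr, "tr", positive = TRUE)
  ts
}

# one-sided amplitude spectrum of a detrended series: frequencies k/(T*tr),
# k = 1..floor(T/2), amplitude = 2|X_k|/T (sqrt of the scaled periodogram)
amplitude_spectrum <- function(x, tr) {
  n <- length(x)
  x <- stats::residuals(stats::lm.fit(cbind(1, seq_len(n)), x)) # detrend
  k <- seq_len(floor(n / 2))
  amp <- 2 * Mod(stats::fft(x)[k + 1]) / n
  list(freq = k / (n * tr), amp = amp)
}

check_band <- function(band, tr, n) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stop_("band must be (low, high) with 0 < low < high")
  nyquist <- 1 / (2 * tr)
  if (band[2] > nyquist + 1e-12)
    stop_(sprintf("band upper edge %.4g Hz exceeds the Nyquist frequency %.4g Hz",
                  band[2], nyquist))
  invisible(band)
}

#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' Sum (or mean, via `agg`) of the square-root periodogram amplitude over the
#' frequency bins inside `band`, per voxel, then averaged over the voxels of
#' the block. The series is linearly detrended first; no taper is applied.
#'
#' @param ts a `timeseries_block` (see [gen_timeseries()]).
#' @param band low/high band edges in Hz; default `c(0.01, 0.08)`.
#' @param agg aggregate amplitudes across in-band bins by `"sum"` (default)
#'   or `"mean"`; both are reported conventions and differ only by a
#'   constant for a fixed series length.
#' @return single non-negative number (region-level ALFF).
#' @export
alff <- function(ts, band = c(0.01, 0.08), agg = c("sum", "mean")) {
  ts <- check_block(ts)
  agg <- match.arg(agg)
  n <- nrow(ts$series)
  if (n < 4) stop_("need at least 4 time points")
  check_band(band, ts$tr, n)
  f <- switch(agg, sum = sum, mean = mean)
  vox <- apply(ts$series, 2L, function(x) {
    sp <- amplitude_spectrum(x, ts$tr)
    sel <- sp$freq >= band[1] & sp$freq <= band[2]
    if (!any(sel)) return(0)
    f(sp$amp[sel])
  })
  mean(vox)
}

#' Fractional ALFF (fALFF)
#'
#' Ratio of the in-band amplitude sum to the full-spectrum amplitude sum
#' (DC excluded), per voxel, averaged over voxels. Lies in `[0, 1]` and is
#' invariant to rescaling the series.
#'
#' @inheritParams alff
#' @return single number in `[0, 1]`.
#' @export
falff <- function(ts, band = c(0.01, 0.08)) {
  ts <- check_block(ts)
  n <- nrow(ts$series)
  if (n < 4) stop_("need at least 4 time points")
  check_band(band, ts$tr, n)
  vox <- apply(ts$series, 2L, function(x) {
    if (stats::sd(x) == 0)
      stop_("zero total spectral power: fALFF undefined for a constant series")
    sp <- amplitude_spectrum(x, ts$tr)
    tot <- sum(sp$amp)
    sel <- sp$freq >= band[1] & sp$freq <= band[2]
    sum(sp$amp[sel]) / tot
  })
  mean(vox)
}

#' Regional homogeneity (ReHo): Kendall's coefficient of concordance
#'
#' Kendall's W across the block's voxels treated as raters ranking the T
#' time points: `W = 12 S / (V^2 (T^3 - T) - V sum(T_j))` where `S` is the
#' sum of squared deviations of the per-timepoint rank sums from their mean
#' and `T_j = sum(t^3 - t)` over tie groups of voxel j. W is 1 when all
#' voxels rank time identically and near `1/V` for independent noise.
#'
#' @param ts a `timeseries_block` with at least 2 voxels and 2 time points.
#' @return Kendall's W in `[0, 1]`.
#' @export
reho <- function(ts) {
  ts <- check_block(ts)
  X <- ts$series
  v <- ncol(X)
  n <- nrow(X)
  if (v < 2) stop_("ReHo needs at least 2 voxels")
  if (n < 2) stop_("ReHo needs at least 2 time points")
  R <- apply(X, 2L, rank, ties.method = "average")
  tie_term <- sum(apply(X, 2L, function(x) {
    t_sizes <- table(x)
    sum(t_sizes^3 - t_sizes)
  }))
  denom <- v^2 * (n^3 - n) - v * tie_term
  if (denom <= 0)
    stop_("degenerate block: every voxel is constant, W undefined")
  Rt <- rowSums(R)
  S <- sum((Rt - mean(Rt))^2)
  12 * S / denom
}

#' Subject x region metric table from per-region time-series blocks
#'
#' Applies one of the three metrics to each region's block for each subject
#' and returns a table shaped for the effect-map stage, optionally
#' Z-standardising each subject's map across regions (the usual
#' normalisation before group analysis).
#'
#' @param blocks nested list: `blocks[[subject]][[region]]` is a
#'   `timeseries_block`.
#' @param metric `"ALFF"`, `"fALFF"` or `"ReHo"`.
#' @param band passed to [alff()]/[falff()].
#' @param z_standardize z-score each subject's regional map (default TRUE).
#' @return numeric matrix subjects x regions.
#' @export
metric_table <- function(blocks, metric = c("ALFF", "fALFF", "ReHo"),
                         band = c(0.01, 0.08), z_standardize = TRUE) {
  metric <- match.arg(metric)
  fun <- switch(metric, ALFF = function(b) alff(b, band),
                fALFF = function(b) falff(b, band), ReHo = reho)
  out <- t(vapply(blocks, function(subj) vapply(subj, fun, numeric(1)),
                  numeric(length(blocks[[1]]))))
  dimnames(out) <- list(names(blocks), names(blocks[[1]]))
  if (z_standardize) out <- t(apply(out, 1L, zscale, allow_constant = TRUE))
  out
}
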