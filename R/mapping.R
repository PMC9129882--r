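#' Voxelwise correlation and Fisher-Z map for a single regressor
#'
#' Per retained voxel, the Pearson correlation with the regressor and its
#' Fisher-transformed, degrees-of-freedom-scaled score
#' `z = atanh(r) * sqrt(n_frames - 3)`, with `|z|` capped at 40 to keep
#' volumes finite. Voxels outside the matrix's voxel set are `NA`.
#'
#' @param matrix A `ts_matrix` whose `voxel_index` carries voxel coordinates.
#' @param regressor Frame-length numeric vector (non-constant).
#' @param grid_dim Spatial grid dimensions `c(nx, ny, nz)`; inferred from
#'   the voxel set when possible, otherwise required.
#' @return A `stat_map`: list with `r` and `z` (`volume_map`s),
#'   `regressor_name`, and `n_frames`.
#' @export
voxelwise_regression <- function(matrix, regressor, grid_dim = NULL) {
  stopifnot(inherits(matrix, "ts_matrix"))
  v <- matrix$values
  n <- ncol(v)
  if (length(regressor) != n) stop("regressor length must equal n_frames")
  if (stats::sd(regressor) == 0) stop("regressor is constant")
  if (is.null(matrix$voxel_index)) stop("matrix lacks a voxel index map")
  idx <- matrix$voxel_index$indices
  if (is.null(grid_dim)) grid_dim <- apply(idx, 2, max)
  rr <- as.vector(stats::cor(t(v), regressor))
  rr[!is.finite(rr)] <- 0
  zz <- atanh(pmin(pmax(rr, -1), 1)) * sqrt(n - 3)
  zz[zz > 40] <- 40
  zz[zz < -40] <- -40
  rvol <- array(NA_real_, grid_dim)
  zvol <- array(NA_real_, grid_dim)
  lin <- idx[, 1] + grid_dim[1] * (idx[, 2] - 1) + grid_dim[1] * grid_dim[2] * (idx[, 3] - 1)
  rvol[lin] <- rr
  zvol[lin] <- zz
  structure(list(r = volume_map(rvol, "r"), z = volume_map(zvol, "Z"),
                 regressor_name = deparse(substitute(regressor))[1],
                 n_frames = n),
            class = "stat_map")
}

# 3D box-sum via cumulative sums along each axis; S[i,j,k] = sum of a over
# the clipped cube of half-width rad centered at (i,j,k)
box_sum3d <- function(a, rad) {
  d <- dim(a)
  cs <- function(m, axis) {
    ap <- aperm(m, c(axis, setdiff(1:3, axis)))
    dm <- dim(ap)
    ap <- apply(ap, c(2, 3), cumsum)
    dim(ap) <- dm
    aperm(ap, order(c(axis, setdiff(1:3, axis))))
  }
  win <- function(csum, axis) {
    n <- d[axis]
    hi <- pmin(1:n + rad, n)
    lo <- pmax(1:n - rad, 1) - 1L
    take <- function(i) switch(axis,
      csum[i, , , drop = FALSE], csum[, i, , drop = FALSE], csum[, , i, drop = FALSE])
    zero <- array(0, dim(take(1)))
    res <- array(0, d)
    for (i in 1:n) {
      upper <- take(hi[i])
      lower <- if (lo[i] >= 1) take(lo[i]) else zero
      slice <- upper - lower
      switch(axis, res[i, , ] <- slice, res[, i, ] <- slice, res[, , i] <- slice)
    }
    res
  }
  for (axis in 1:3) a <- win(cs(a, axis), axis)
  a
}

#' Neighborhood cross-correlation between two volume maps
#'
#' For every masked voxel, the Pearson correlation between the two maps over
#' the cubic neighborhood of half-width `radius_vox` (clipped at volume
#' edges, masked voxels only). Neighborhoods with fewer than 5 valid voxels
#' or zero variance in either map are skipped. Returns the mean of the local
#' correlations over contributing voxels. This local-correlation mean is
#' affine-invariant per map and symmetric in its two arguments.
#'
#' @param mapA,mapB `volume_map`s on identical grids.
#' @param mask A `volume_map`; voxels with value > 0 participate.
#' @param radius_vox Cubic neighborhood half-width in voxels; default 4.
#' @return Scalar mean local correlation.
#' @export
neighborhood_cross_correlation <- function(mapA, mapB, mask, radius_vox = 4) {
  a <- mapA$values
  b <- mapB$values
  m <- mask$values > 0
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(m)))
    stop("maps and mask must share one grid")
  if (!any(m)) stop("mask is empty")
  valid <- m & is.finite(a) & is.finite(b)
  a0 <- ifelse(valid, a, 0)
  b0 <- ifelse(valid, b, 0)
  ind <- array(as.numeric(valid), dim(a))
  n_loc <- box_sum3d(ind, radius_vox)
  sa <- box_sum3d(a0, radius_vox)
  sb <- box_sum3d(b0, radius_vox)
  saa <- box_sum3d(a0 * a0, radius_vox)
  sbb <- box_sum3d(b0 * b0, radius_vox)
  sab <- box_sum3d(a0 * b0, radius_vox)
  cov_ab <- sab - sa * sb / pmax(n_loc, 1)
  var_a <- saa - sa * sa / pmax(n_loc, 1)
  var_b <- sbb - sb * sb / pmax(n_loc, 1)
  eps <- 1e-12
  ok <- valid & n_loc >= 5 & var_a > eps & var_b > eps
  if (!any(ok)) stop("no contributing voxel: neighborhoods too small or constant")
  mean(cov_ab[ok] / sqrt(var_a[ok] * var_b[ok]))
}

#' Mean ROI time series as percent signal change
#'
#' Averages the BOLD signal over ROI voxels per frame, then normalizes to
#' percent signal change relative to the temporal mean:
#' `100 * (x - mean) / mean`. The output always has mean zero.
#'
#' @param run A `bold_run`.
#' @param roi_mask A `volume_map`; voxels with value > 0 define the ROI.
#' @return An `roi_series`: list with `timeseries` (percent units, mean 0),
#'   `roi_name`, and `tr`.
#' @export
roi_signal <- function(run, roi_mask) {
  stopifnot(inherits(run, "bold_run"), inherits(roi_mask, "volume_map"))
  keep <- which(roi_mask$values > 0)
  if (length(keep) == 0L) stop("ROI mask is empty")
  m <- matrix(run$data, ncol = run$n_frames)[keep, , drop = FALSE]
  ts <- colMeans(m)
  mu <- mean(ts)
  if (mu <= 0) stop("ROI temporal mean is non-positive; percent change undefined")
  structure(list(timeseries = 100 * (ts - mu) / mu,
                 roi_name = roi_mask$label, tr = run$tr),
            class = "roi_series")
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the series is split into segments of
#' `nperseg` points with `noverlap` points shared between consecutive
#' segments; each segment is demeaned, tapered with a periodic Hann window,
#' and its one-sided density-scaled periodogram computed; segment
#' periodograms are averaged.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length; default 100.
#' @param noverlap Overlap between segments; default `nperseg / 2`.
#' @return `data.frame(freq, psd)` with power density in units of
#'   `x^2 / Hz`.
#' @export
welch_psd <- function(x, fs, nperseg = 100, noverlap = nperseg %/% 2) {
  n <- length(x)
  if (n < nperseg) stop("series shorter than one segment (", nperseg, " points)")
  step <- nperseg - noverlap
  if (step < 1L) stop("noverlap must be smaller than nperseg")
  starts <- seq(1L, n - nperseg + 1L, by = step)
  acc <- NULL
  for (s in starts) {
    pg <- hann_periodogram(x[s:(s + nperseg - 1L)], fs)
    acc <- if (is.null(acc)) pg$psd else acc + pg$psd
  }
  data.frame(freq = hann_periodogram(x[1:nperseg], fs)$freq,
             psd = acc / length(starts))
}

#' Amplitude and spectral metrics of an ROI series
#'
#' BOLD amplitude is the population SD of the percent-signal-change series.
#' The PSD is estimated by Welch's method (Hann windows, `segment_len`
#' points per segment, `overlap` shared points, density scaling). Band
#' metrics are trapezoid integrals of `log10(psd)` over each band's
#' frequency bins; bins with power below 1e-300 are excluded from the
#' integration and counted in `n_zero_bins`.
#'
#' @param series An `roi_series`.
#' @param segment_len Welch segment length in frames; default 100.
#' @param overlap Overlapping points between segments; default 50.
#' @param bands Named list of `c(low, high)` bands in Hz; default
#'   `list(low = c(0.005, 0.05), high = c(0.05, 0.12))`.
#' @return An `roi_metrics`: list with `sd`, `psd` (data.frame), and
#'   `band_logpsd` (named numeric), plus `n_zero_bins` diagnostics.
#' @export
roi_metrics <- function(series, segment_len = 100, overlap = 50,
                        bands = list(low = c(0.005, 0.05), high = c(0.05, 0.12))) {
  stopifnot(inherits(series, "roi_series"))
  x <- series$timeseries
  fs <- 1 / series$tr
  sd_pop <- sqrt(mean((x - mean(x))^2))
  psd <- welch_psd(x, fs, nperseg = segment_len, noverlap = overlap)
  zero <- psd$psd < 1e-300
  band_logpsd <- vapply(bands, function(b) {
    keep <- !zero
    if (sum(keep & psd$freq >= b[1] - 1e-12 & psd$freq <= b[2] + 1e-12) < 2L)
      return(NA_real_)
    band_trapz(psd$freq[keep], log10(psd$psd[keep]), b[1], b[2])
  }, numeric(1))
  structure(list(sd = sd_pop, psd = psd, band_logpsd = band_logpsd,
                 n_zero_bins = sum(zero)),
            class = "roi_metrics")
}

#' Min-max scale a series to \[0, 1\]
#'
#' Linear map sending the minimum to 0 and the maximum to 1; used to
#' compare fluctuation timing across series of different amplitudes.
#'
#' @param series Non-constant numeric vector.
#' @return Scaled vector in \[0, 1\].
#' @export
minmax_scale <- function(series) {
  rng <- range(series)
  if (rng[1] == rng[2]) stop("constant input: min-max scaling undefined")
  (series - rng[1]) / (rng[2] - rng[1])
}
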