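#' Construct an EEG trace
#'
#' @param samples Numeric vector of EEG samples in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample relative to the first fMRI volume,
#'   in seconds (default 0; alignment is the caller's responsibility).
#' @return An `eeg_trace` object.
#' @export
eeg_trace <- function(samples, fs, t0 = 0) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "eeg_trace")
}

#' Read an EEG trace from a single-column CSV with JSON sidecar
#'
#' The sidecar (`<path minus extension>.json` or given explicitly) must
#' contain `fs_hz` and may contain `t0_s`.
#'
#' @param path CSV/TSV file of microvolt samples (one column, no header
#'   required; a non-numeric first line is treated as a header).
#' @param sidecar Optional explicit sidecar path.
#' @return An `eeg_trace`.
#' @export
read_eeg <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- paste0(sub("\\.[ct]sv$", "", path), ".json")
  if (!file.exists(sidecar)) stop("EEG sidecar not found: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$fs_hz)) stop("sidecar lacks fs_hz")
  lines <- readLines(path)
  if (length(lines) && is.na(suppressWarnings(as.numeric(lines[1]))))
    lines <- lines[-1]
  eeg_trace(as.numeric(lines), fs = meta$fs_hz,
            t0 = if (is.null(meta$t0_s)) 0 else meta$t0_s)
}

# one-sided Hann-window periodogram with density scaling (power per Hz);
# returns data.frame(freq, psd). Used both for per-frame EEG segments and as
# the per-segment kernel of welch_psd().
hann_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)  # periodic Hann
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  scale <- 1 / (fs * sum(w * w))
  nfreq <- floor(n / 2) + 1L
  p <- (Mod(X[seq_len(nfreq)])^2) * scale
  # one-sided: double everything except DC and (for even n) Nyquist
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nfreq] <- 1
  data.frame(freq = (seq_len(nfreq) - 1) * fs / n, psd = p * dbl)
}

# trapezoid integral of y over x restricted to [lo, hi] (inclusive edges)
band_trapz <- function(x, y, lo, hi) {
  keep <- which(x >= lo - 1e-12 & x <= hi + 1e-12)
  if (length(keep) < 2L) return(0)
  sum(diff(x[keep]) * (utils::head(y[keep], -1) + utils::tail(y[keep], -1)) / 2)
}

#' Segment EEG into per-frame burst/suppression states by band power
#'
#' For each fMRI frame, a Hann window of `window_s` seconds centered on the
#' volume's acquisition interval (midpoint `k * tr + tr/2`, relative to
#' `t0`) is extracted, its power spectral density
#' computed (single-window Welch periodogram, density scaling), and the PSD
#' integrated by trapezoid over `band`. Frames whose band power falls below
#' `power_threshold` are designated suppression (state 0); the rest are
#' bursts (state 1). Windows extending past the recording edges are clipped
#' with a warning.
#'
#' @param eeg An `eeg_trace` in microvolts.
#' @param n_frames Number of fMRI frames.
#' @param tr Repetition time in seconds.
#' @param window_s Analysis window length; default 6 s.
#' @param band Integration band in Hz; default `c(0.5, 8)`.
#' @param power_threshold Suppression threshold in microvolts squared;
#'   default 100.
#' @return A `burst_envelope`: list with `states` (0/1 per frame), `tr`, and
#'   `band_powers` (per-frame integrated power, diagnostic).
#' @export
segment_eeg <- function(eeg, n_frames, tr, window_s = 6,
                        band = c(0.5, 8), power_threshold = 100) {
  stopifnot(inherits(eeg, "eeg_trace"))
  if (eeg$fs < 2 * band[2])
    stop("sampling rate ", eeg$fs, " Hz cannot resolve the ", band[2], " Hz band edge")
  ns <- length(eeg$samples)
  clipped <- 0L
  powers <- vapply(seq_len(n_frames) - 1L, function(k) {
    center <- k * tr + tr / 2 - eeg$t0
    i0 <- max(1L, floor((center - window_s / 2) * eeg$fs) + 1L)
    i1 <- min(ns, ceiling((center + window_s / 2) * eeg$fs))
    if (i1 - i0 + 1L < round(window_s * eeg$fs)) clipped <<- clipped + 1L
    if (i1 - i0 + 1L < 4L) return(0)
    seg <- eeg$samples[i0:i1]
    pg <- hann_periodogram(seg, eeg$fs)
    band_trapz(pg$freq, pg$psd, band[1], band[2])
  }, numeric(1))
  if (clipped > 0L)
    warning(clipped, " frame window(s) clipped at the recording edges")
  burst_envelope(as.integer(powers >= power_threshold), tr = tr,
                 band_powers = powers)
}

#' Construct a burst/suppression envelope
#'
#' @param states Integer vector per fMRI frame: 1 = burst, 0 = suppression.
#' @param tr Repetition time in seconds.
#' @param band_powers Optional per-frame band power diagnostic.
#' @return A `burst_envelope` object.
#' @export
burst_envelope <- function(states, tr, band_powers = NULL) {
  states <- as.integer(states)
  if (any(!states %in% c(0L, 1L))) stop("states must be 0 or 1")
  structure(list(states = states, tr = tr, band_powers = band_powers),
            class = "burst_envelope")
}

#' Two-gamma hemodynamic response function kernel
#'
#' Samples `h(t) = g(t; a1, b1) - c * g(t; a2, b2)` (gamma densities with
#' shape a, rate b) at `t = 0, tr, 2 tr, ...` up to `duration_s`, then
#' scales the kernel to peak value 1. The defaults give the widely used
#' canonical shape: response peak near 5-6 s, undershoot near 15-16 s,
#' undershoot ratio 1/6.
#'
#' @param tr Sampling interval in seconds.
#' @param duration_s Kernel support in seconds; default 32.
#' @param params List with `a1`, `b1`, `a2`, `b2`, `c`; see
#'   [hrf_params()].
#' @return Numeric kernel vector with peak value 1.
#' @export
two_gamma_hrf <- function(tr, duration_s = 32, params = hrf_params()) {
  stopifnot(tr > 0)
  t <- seq(0, duration_s, by = tr)
  h <- stats::dgamma(t, shape = params$a1, rate = params$b1) -
    params$c * stats::dgamma(t, shape = params$a2, rate = params$b2)
  pk <- max(abs(h))
  if (pk == 0) stop("degenerate HRF kernel")
  h / max(h)
}

#' Canonical two-gamma HRF parameters
#'
#' Shape/rate pairs (`a1`/`b1` response, `a2`/`b2` undershoot) and
#' undershoot ratio `c`. Defaults: a1 = 6, b1 = 1 (peak at 5 s),
#' a2 = 16, b2 = 1 (undershoot trough near 15 s), c = 1/6.
#'
#' @param a1,b1 Response gamma shape and rate.
#' @param a2,b2 Undershoot gamma shape and rate.
#' @param c Undershoot amplitude ratio.
#' @return Parameter list.
#' @export
hrf_params <- function(a1 = 6, b1 = 1, a2 = 16, b2 = 1, c = 1 / 6) {
  list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, c = c)
}

#' Convert a burst envelope into a hemodynamic model time series
#'
#' Convolves the binary envelope (sampled at the frame rate) with the
#' two-gamma HRF kernel, truncates the causal full convolution to the frame
#' grid, then applies the same bandpass projection used for fMRI
#' preprocessing (polynomial order 0, i.e. mean removal plus in-band
#' spectral projection). The envelope is extended into the past with its
#' initial state for the kernel duration, so a constant envelope maps to a
#' constant (hence, after filtering, zero) model rather than carrying an
#' onset transient. The output has zero mean.
#'
#' @param envelope A `burst_envelope` with at least 10 frames.
#' @param band Passband in Hz; default `c(0.005, 0.12)`.
#' @param hrf Optional HRF parameter list; see [hrf_params()].
#' @return A `hemodynamic_model`: list with `timeseries` (zero mean), `tr`,
#'   `band`, and `hrf_params`.
#' @export
envelope_to_model <- function(envelope, band = c(0.005, 0.12),
                              hrf = hrf_params()) {
  stopifnot(inherits(envelope, "burst_envelope"))
  n <- length(envelope$states)
  if (n < 10L) stop("envelope must have at least 10 frames")
  k <- two_gamma_hrf(envelope$tr, params = hrf)
  pad <- length(k) - 1L
  x <- c(rep(envelope$states[1], pad), envelope$states)
  conv_full <- stats::convolve(x, rev(k), type = "open")
  y <- conv_full[pad + seq_len(n)]
  m <- ts_matrix(matrix(y, nrow = 1), tr = envelope$tr)
  filt <- detrend_bandpass(m, poly_order = 0, band = band)
  structure(list(timeseries = as.vector(filt$values), tr = envelope$tr,
                 band = band, hrf_params = hrf),
            class = "hemodynamic_model")
}

#' Lagged cross-correlation between a hemodynamic model and a PC
#'
#' Pearson correlation at integer frame lags `k` with `|k * tr| <=
#' max_lag_s`, over the overlapping segments only (no padding). Positive
#' lag means the second series (`pc`) is delayed relative to the first
#' (`model`). Ties in the maximum are resolved toward the smallest `|lag|`.
#'
#' @param model A `hemodynamic_model`, or a plain numeric vector.
#' @param pc Frame-length numeric vector (e.g. an asymmetric PC).
#' @param tr Repetition time in seconds (taken from `model` when available).
#' @param max_lag_s Maximum lag magnitude in seconds; default 30.
#' @return A `crosscorr_result`: list with `r_zero_lag`, `r_max`,
#'   `lag_at_max` (seconds), and the full `lags`/`r` profile.
#' @export
crosscorrelate <- function(model, pc, tr = NULL, max_lag_s = 30) {
  x <- if (inherits(model, "hemodynamic_model")) model$timeseries else as.numeric(model)
  if (is.null(tr)) {
    if (inherits(model, "hemodynamic_model")) tr <- model$tr
    else stop("tr must be supplied when model is a plain vector")
  }
  y <- as.numeric(pc)
  n <- length(x)
  if (length(y) != n) stop("series must have equal length")
  if (max_lag_s >= n * tr / 2) stop("max_lag_s must be below half the series duration")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: a series is constant")
  kmax <- floor(max_lag_s / tr)
  lags <- -kmax:kmax
  r <- vapply(lags, function(k) {
    if (k >= 0) xs <- x[seq_len(n - k)] else xs <- x[(1 - k):n]
    if (k >= 0) ys <- y[(1 + k):n] else ys <- y[seq_len(n + k)]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
  best <- which(r >= max(r, na.rm = TRUE) - 1e-15)
  best <- best[order(abs(lags[best]), lags[best])][1]
  structure(list(r_zero_lag = r[lags == 0], r_max = r[best],
                 lag_at_max = lags[best] * tr, lags = lags * tr, r = r),
            class = "crosscorr_result")
}

#' @export
print.crosscorr_result <- function(x, ...) {
  cat(sprintf("cross-correlation: r(0) = %.3f, max r = %.3f at lag %.2f s\n",
              x$r_zero_lag, x$r_max, x$lag_at_max))
  invisible(x)
}
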