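#' Configuration for a synthetic burst-suppression phantom
#'
#' Defaults emulate a human-like deep-anesthesia run: TR 2 s, 300 frames
#' (10 min), alternating burst/suppression epochs of mean 20 s each (so
#' suppression occupies roughly half the time and the alternation sits near
#' 0.025 Hz, inside the 0.005-0.12 Hz analysis band), 60% of cortical
#' voxels engaged, burst response amplitude 1% of baseline with 1% voxel
#' noise (SNR 1), quadratic scanner drift, and no extra hemodynamic lag.
#'
#' @param grid Spatial grid `c(nx, ny, nz)`; the cortex is a central box.
#' @param n_frames Number of frames; default 300.
#' @param tr Repetition time in seconds; default 2.
#' @param burst_dur_s `c(mean, jitter)` burst duration in seconds.
#' @param supp_dur_s `c(mean, jitter)` suppression duration in seconds.
#' @param engaged_fraction Fraction of cortex voxels carrying the response.
#' @param amplitude_pct Burst response amplitude, percent of baseline.
#' @param noise_sd_pct Voxel noise SD, percent of baseline.
#' @param drift_order Polynomial drift order; default 2.
#' @param hemo_lag_s Extra hemodynamic delay applied to engaged voxels, s.
#' @param seed Integer seed fixing all randomness.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid = c(12, 12, 6), n_frames = 300, tr = 2,
                           burst_dur_s = c(20, 10), supp_dur_s = c(20, 10),
                           engaged_fraction = 0.6, amplitude_pct = 1,
                           noise_sd_pct = 1, drift_order = 2,
                           hemo_lag_s = 0, seed = 1) {
  stopifnot(length(grid) == 3, n_frames >= 2, tr > 0,
            burst_dur_s[1] > 0, supp_dur_s[1] > 0,
            engaged_fraction >= 0, engaged_fraction <= 1)
  structure(list(grid = grid, n_frames = n_frames, tr = tr,
                 burst_dur_s = burst_dur_s, supp_dur_s = supp_dur_s,
                 engaged_fraction = engaged_fraction,
                 amplitude_pct = amplitude_pct, noise_sd_pct = noise_sd_pct,
                 drift_order = drift_order, hemo_lag_s = hemo_lag_s,
                 seed = seed),
            class = "phantom_config")
}

# deterministic sub-seed per phantom component, kept inside 32-bit range
sub_seed <- function(seed, component) {
  (as.numeric(seed) * 7919 + component * 104729) %% 2147483629
}

#' Simulate an alternating burst/suppression envelope
#'
#' Alternating renewal process: epoch durations drawn uniformly from
#' mean +/- jitter, quantized to whole frames (minimum one frame), with a
#' random starting state. Fully reproducible from the config seed.
#'
#' @param cfg A `phantom_config`; mean durations must be at least `2 * tr`.
#' @return A `burst_envelope` of `n_frames` states.
#' @export
simulate_envelope <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$burst_dur_s[1] < 2 * cfg$tr || cfg$supp_dur_s[1] < 2 * cfg$tr)
    stop("mean epoch durations must be at least 2 * tr")
  set.seed(sub_seed(cfg$seed, 1))
  if (cfg$n_frames == 0) return(burst_envelope(integer(0), tr = cfg$tr))
  state <- sample(c(0L, 1L), 1)
  states <- integer(0)
  while (length(states) < cfg$n_frames) {
    dur <- if (state == 1L) cfg$burst_dur_s else cfg$supp_dur_s
    len <- max(1L, round(stats::runif(1, dur[1] - dur[2], dur[1] + dur[2]) / cfg$tr))
    states <- c(states, rep(state, len))
    state <- 1L - state
  }
  burst_envelope(states[seq_len(cfg$n_frames)], tr = cfg$tr)
}

#' Simulate a ground-truthed burst-suppression BOLD phantom
#'
#' The cortex is a central box covering half the grid extent per axis. A
#' random `engaged_fraction` of cortical voxels carries the hemodynamic
#' burst response: the envelope convolved with the two-gamma HRF, delayed
#' by `hemo_lag_s`, peak-normalized, and scaled to `amplitude_pct` of
#' baseline. All voxels receive independent white Gaussian noise of
#' `noise_sd_pct` (matched between engaged and non-engaged voxels) and a
#' random per-voxel polynomial drift. All randomness derives from the seed.
#'
#' @param cfg A `phantom_config`.
#' @return List with `run` (a `bold_run`) and `truth` (a `phantom_truth`:
#'   `envelope`, `engaged_mask`, `cortex_mask`, `clean_signal`, `lag_s`).
#' @export
simulate_bold <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  env <- simulate_envelope(cfg)
  n <- cfg$n_frames
  d <- cfg$grid
  # central cortical box: middle half of each axis
  lo <- pmax(1L, floor(d / 4) + 1L)
  hi <- pmin(d, lo + pmax(1L, ceiling(d / 2)) - 1L)
  cortex <- array(0, d)
  cortex[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  cortex_idx <- which(cortex > 0)

  set.seed(sub_seed(cfg$seed, 2))
  n_eng <- round(cfg$engaged_fraction * length(cortex_idx))
  engaged_idx <- if (n_eng > 0) sort(sample(cortex_idx, n_eng)) else integer(0)
  engaged <- array(0, d)
  engaged[engaged_idx] <- 1

  # clean hemodynamic response: envelope * HRF, delayed by hemo_lag_s
  k <- two_gamma_hrf(cfg$tr)
  lag_frames <- cfg$hemo_lag_s / cfg$tr
  pad <- length(k) - 1L
  conv_full <- stats::convolve(c(rep(env$states[1], pad), env$states),
                               rev(k), type = "open")
  base_sig <- conv_full[pad + seq_len(n)]
  clean <- shift_series(base_sig, lag_frames)
  pk <- max(abs(clean))
  if (pk > 0) clean <- clean / pk

  baseline <- 1000
  nvox <- prod(d)
  set.seed(sub_seed(cfg$seed, 3))
  noise <- matrix(stats::rnorm(nvox * n, sd = cfg$noise_sd_pct / 100), nvox, n)
  set.seed(sub_seed(cfg$seed, 4))
  drift <- matrix(0, nvox, n)
  if (cfg$drift_order >= 1) {
    P <- legendre_basis(n, cfg$drift_order)[, -1, drop = FALSE]
    coefs <- matrix(stats::rnorm(nvox * ncol(P), sd = 0.5 / 100), nvox, ncol(P))
    drift <- coefs %*% t(P)
  }
  signal <- matrix(0, nvox, n)
  if (length(engaged_idx) > 0)
    signal[engaged_idx, ] <- matrix(clean, length(engaged_idx), n, byrow = TRUE)
  data <- baseline * (1 + cfg$amplitude_pct / 100 * signal + noise + drift)
  run <- bold_run(array(data, c(d, n)), tr = cfg$tr)
  truth <- structure(list(envelope = env,
                          engaged_mask = volume_map(engaged, "mask"),
                          cortex_mask = volume_map(cortex, "mask"),
                          clean_signal = clean, lag_s = cfg$hemo_lag_s),
                     class = "phantom_truth")
  list(run = run, truth = truth)
}

# shift a series by `lag` frames (positive = delayed), zero-padded;
# non-integer lags use linear interpolation between neighboring frames
shift_series <- function(x, lag) {
  n <- length(x)
  if (lag == 0) return(x)
  t_src <- seq_len(n) - lag
  lo <- floor(t_src)
  frac <- t_src - lo
  get <- function(i) ifelse(i >= 1 & i <= n, x[pmin(pmax(i, 1), n)], 0)
  (1 - frac) * get(lo) + frac * get(lo + 1L)
}

#' Simulate an amplitude-modulated EEG trace matching an envelope
#'
#' Band-limited (0.5-8 Hz) Gaussian noise whose integrated band power
#' tracks the envelope state: `burst_power_uv2` during bursts,
#' `supp_power_uv2` during suppressions, with 0.5 s raised-cosine
#' cross-fades between epochs. Reproducible from the seed.
#'
#' @param envelope A `burst_envelope`.
#' @param fs Sampling rate in Hz (>= 64).
#' @param burst_power_uv2 Band power during bursts; default 300.
#' @param supp_power_uv2 Band power during suppressions; default 20.
#' @param seed Integer seed.
#' @return An `eeg_trace` in microvolts (empty for a zero-length envelope).
#' @export
simulate_eeg <- function(envelope, fs = 200, burst_power_uv2 = 300,
                         supp_power_uv2 = 20, seed = 1) {
  stopifnot(inherits(envelope, "burst_envelope"), fs >= 64)
  n_frames <- length(envelope$states)
  if (n_frames == 0L) return(eeg_trace(numeric(0), fs = fs))
  ns <- round(n_frames * envelope$tr * fs)
  set.seed(sub_seed(seed, 5))
  x <- stats::rnorm(ns)
  # exact spectral band restriction to 0.5-8 Hz
  X <- stats::fft(x)
  f <- (seq_len(ns) - 1) / ns * fs
  f <- pmin(f, fs - f)   # two-sided frequency magnitude
  X[f < 0.5 | f > 8] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / ns
  x <- x / stats::sd(x)
  # per-sample target SD from the envelope, with 0.5 s raised-cosine fades
  frame_of <- pmin(floor((seq_len(ns) - 1) / fs / envelope$tr) + 1L, n_frames)
  level <- sqrt(ifelse(envelope$states[frame_of] == 1L,
                       burst_power_uv2, supp_power_uv2))
  half <- max(1L, round(0.25 * fs))
  ramp <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = 2 * half + 1))
  kern <- c(ramp, rev(ramp)[-1])
  kern <- kern / sum(kern)
  level <- conv1d_zero(level, kern)
  # renormalize fade edges where zero padding shrank the level
  norm <- conv1d_zero(rep(1, ns), kern)
  level <- level / norm
  eeg_trace(x * level, fs = fs)
}
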