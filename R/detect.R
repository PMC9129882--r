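#' Detect burst-suppression in a BOLD fMRI run
#'
#' Runs the full carpet-plot/PCA detection pipeline: temporal SNR filter
#' (tSNR >= `tsnr_min`) within the cortical mask, optional spatial
#' smoothing, joint polynomial detrend and bandpass projection, row
#' z-scoring, carpet ordering by correlation with the mean cortical signal,
#' temporal PCA by SVD, cortex-wide PC-voxel correlations with sign fixing
#' and 50-bin histograms, and classification of the run by the median-r
#' asymmetry of its most asymmetric PC against a species threshold (with
#' the rat second-PC exclusion rule when the preset carries one).
#'
#' @param run A `bold_run` (see [load_bold()] / [bold_run()]).
#' @param cortex_mask A `volume_map`; voxels > 0 are cortical.
#' @param species Species preset selecting threshold, exclusion margin and
#'   band; see [species_preset()]. Default `"human"`.
#' @param threshold,exclusion_delta,band Optional overrides of the preset.
#' @param n_pcs Number of temporal PCs to extract; default 5.
#' @param tsnr_min tSNR cutoff; default 15.
#' @param poly_order Detrend order; default 3.
#' @param smooth_fwhm_mm Optional Gaussian smoothing FWHM in mm; default 0
#'   (off).
#' @return A `bs_detect` object: list with `decision`
#'   (an `asymmetry_decision`), `pcs` (completed `pc_profile` list),
#'   `carpet` (ordered `carpet_matrix`), `voxels` (`voxel_set`), `tsnr`
#'   (`volume_map`), `counts` (voxel bookkeeping after each filter), and
#'   `config`.
#' @examples
#' ph <- simulate_bold(phantom_config(seed = 42))
#' fit <- bs_detect(ph$run, ph$truth$cortex_mask, species = "human")
#' print(fit)
#' coef(fit)
#' @export
bs_detect <- function(run, cortex_mask, species = "human",
                      threshold = NULL, exclusion_delta = NULL, band = NULL,
                      n_pcs = 5, tsnr_min = 15, poly_order = 3,
                      smooth_fwhm_mm = 0) {
  stopifnot(inherits(run, "bold_run"))
  preset <- species_preset(species)
  if (is.null(threshold)) threshold <- preset$threshold
  if (is.null(exclusion_delta)) exclusion_delta <- preset$exclusion_delta
  if (is.null(band)) band <- preset$band
  if (smooth_fwhm_mm > 0) run <- smooth_gaussian(run, smooth_fwhm_mm)
  tsnr <- compute_tsnr(run)
  voxels <- build_voxel_set(run, cortex_mask, tsnr, tsnr_min = tsnr_min)
  mat <- extract_matrix(run, voxels)
  filt <- detrend_bandpass(mat, poly_order = poly_order, band = band)
  # the bandpass projection can leave numerically constant rows in pure-noise
  # voxels only if the band is empty; z-scoring guards against it anyway
  z <- zscore_rows(filt)
  carpet <- order_by_mean_correlation(z)
  pcs <- pc_voxel_correlations(temporal_pca(z, n_components = n_pcs), z)
  decision <- classify_run(pcs, threshold = threshold,
                           exclusion_delta = exclusion_delta)
  structure(list(decision = decision, pcs = pcs, carpet = carpet,
                 voxels = voxels, tsnr = tsnr,
                 counts = list(n_masked = sum(cortex_mask$values > 0),
                               n_retained = nrow(voxels$indices)),
                 config = list(species = species, threshold = threshold,
                               exclusion_delta = exclusion_delta, band = band,
                               n_pcs = n_pcs, tsnr_min = tsnr_min,
                               poly_order = poly_order,
                               smooth_fwhm_mm = smooth_fwhm_mm, tr = run$tr)),
            class = "bs_detect")
}

#' @export
print.bs_detect <- function(x, ...) {
  cat("Burst-suppression detection (carpet-plot PCA)\n")
  cat(sprintf("  %d/%d cortical voxels retained (tSNR >= %g), TR = %g s\n",
              x$counts$n_retained, x$counts$n_masked, x$config$tsnr_min,
              x$config$tr))
  cat(sprintf("  species preset: %s (threshold %g%s), band %g-%g Hz\n",
              x$config$species, x$config$threshold,
              if (is.null(x$config$exclusion_delta)) "" else
                sprintf(", exclusion delta %g", x$config$exclusion_delta),
              x$config$band[1], x$config$band[2]))
  cat("  decision: ")
  print(x$decision)
  invisible(x)
}

#' @export
summary.bs_detect <- function(object, ...) {
  tab <- data.frame(
    pc = vapply(object$pcs, function(p) p$index, integer(1)),
    explained_variance = vapply(object$pcs, function(p) p$explained_variance_ratio, numeric(1)),
    median_r = vapply(object$pcs, function(p) p$median_r, numeric(1)),
    sign_flipped = vapply(object$pcs, function(p) p$sign_flipped, logical(1)))
  out <- list(pc_table = tab, decision = object$decision,
              counts = object$counts, config = object$config)
  class(out) <- "summary.bs_detect"
  out
}

#' @export
print.summary.bs_detect <- function(x, ...) {
  print(x$pc_table, row.names = FALSE, digits = 3)
  cat("decision: ")
  print(x$decision)
  invisible(x)
}

#' Per-PC asymmetry scores of a detection fit
#'
#' @param object A `bs_detect` fit.
#' @param ... Unused.
#' @return Named numeric vector of median cortex-wide correlations, one per
#'   PC.
#' @export
coef.bs_detect <- function(object, ...) {
  stats::setNames(vapply(object$pcs, function(p) p$median_r, numeric(1)),
                  paste0("PC", vapply(object$pcs, function(p) p$index, integer(1))))
}

#' Carpet plot and PC time courses of a detection fit
#'
#' Top panel: the ordered carpet matrix as a grayscale heatmap (rows =
#' voxels sorted by decreasing correlation with the mean cortical signal,
#' columns = frames). Bottom panel: the extracted temporal PCs, the selected
#' asymmetric PC (if any) highlighted.
#'
#' @param x A `bs_detect` fit.
#' @param ... Passed to `image()`.
#' @export
plot.bs_detect <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  v <- x$carpet$values[x$carpet$display_order, , drop = FALSE]
  lim <- max(abs(v))
  tt <- (seq_len(ncol(v)) - 1) * x$config$tr
  graphics::image(tt, seq_len(nrow(v)), t(v[rev(seq_len(nrow(v))), ]),
                  zlim = c(-lim, lim), col = grDevices::gray.colors(64),
                  xlab = "", ylab = "voxel (ordered)", main = "carpet plot", ...)
  sel <- x$decision$selected_pc
  cols <- ifelse(seq_along(x$pcs) == if (is.na(sel)) 0 else sel, "firebrick", "gray40")
  graphics::matplot(tt, sapply(x$pcs, function(p) p$timeseries), type = "l",
                    lty = 1, col = cols, xlab = "time (s)", ylab = "PC",
                    main = "temporal principal components")
  invisible(x)
}

#' Validate a detection against concurrent EEG
#'
#' Segments the EEG into burst/suppression states per fMRI frame, converts
#' the envelope into a hemodynamic model (two-gamma HRF convolution plus
#' the fMRI bandpass projection), and cross-correlates the model with the
#' detected asymmetric PC. If the fit found no asymmetric PC, the
#' cross-correlation is skipped and recorded as such.
#'
#' @param fit A `bs_detect` fit.
#' @param eeg An `eeg_trace` concurrent with the fitted run.
#' @param window_s,eeg_band,power_threshold EEG segmentation settings; see
#'   [segment_eeg()].
#' @param max_lag_s Cross-correlation lag range; default 30 s.
#' @return A `bs_eeg_validation`: list with `envelope`, `model`, `xcorr`
#'   (a `crosscorr_result` or `NULL`), and `decision`.
#' @export
bs_validate_eeg <- function(fit, eeg, window_s = 6, eeg_band = c(0.5, 8),
                            power_threshold = 100, max_lag_s = 30) {
  stopifnot(inherits(fit, "bs_detect"), inherits(eeg, "eeg_trace"))
  n <- ncol(fit$carpet$values)
  envelope <- segment_eeg(eeg, n_frames = n, tr = fit$config$tr,
                          window_s = window_s, band = eeg_band,
                          power_threshold = power_threshold)
  model <- envelope_to_model(envelope, band = fit$config$band)
  xc <- NULL
  if (fit$decision$is_burst_suppression) {
    pc <- fit$pcs[[fit$decision$selected_pc]]$timeseries
    xc <- crosscorrelate(model, pc, max_lag_s = max_lag_s)
  }
  structure(list(envelope = envelope, model = model, xcorr = xc,
                 decision = fit$decision),
            class = "bs_eeg_validation")
}

#' @export
print.bs_eeg_validation <- function(x, ...) {
  cat(sprintf("EEG validation: %d/%d frames in burst\n",
              sum(x$envelope$states), length(x$envelope$states)))
  if (is.null(x$xcorr)) {
    cat("no asymmetric PC detected; cross-correlation skipped\n")
  } else {
    print(x$xcorr)
  }
  invisible(x)
}
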