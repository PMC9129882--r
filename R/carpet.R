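#' Order carpet rows by correlation with the mean cortical signal
#'
#' Computes the mean time series over all rows and sorts rows by decreasing
#' Pearson correlation with it. The ordering is stored as a permutation view
#' (`display_order`); the underlying row storage is unchanged, so voxel
#' indexing remains valid.
#'
#' @param matrix A `ts_matrix` with at least 2 rows and 3 frames.
#' @return A `carpet_matrix`: the input plus `display_order` (integer
#'   permutation) and `mean_ts` (the mean cortical time series).
#' @export
order_by_mean_correlation <- function(matrix) {
  stopifnot(inherits(matrix, "ts_matrix"))
  v <- matrix$values
  if (nrow(v) < 2L || ncol(v) < 3L) stop("need at least 2 rows and 3 frames")
  mean_ts <- colMeans(v)
  r <- if (stats::sd(mean_ts) == 0) rep(0, nrow(v)) else
    as.vector(stats::cor(t(v), mean_ts))
  r[!is.finite(r)] <- 0
  ord <- order(-r, seq_len(nrow(v)))   # stable: ties resolved by original row
  out <- matrix
  out$display_order <- ord
  out$mean_ts <- mean_ts
  class(out) <- c("carpet_matrix", class(matrix))
  out
}

#' Temporal principal components of the carpet matrix
#'
#' Singular value decomposition of the row-z-scored voxel-by-frame matrix.
#' The temporal PCs are the right singular vectors (unit Euclidean norm),
#' ordered by decreasing singular value; explained variance ratios are
#' squared singular values normalized to sum 1.
#'
#' @param matrix A `ts_matrix` whose rows are z-scored.
#' @param n_components Number of components to return; default 5.
#' @return A list of `pc_profile` objects, each with `index`, `timeseries`,
#'   and `explained_variance_ratio` (correlation fields are filled in by
#'   [pc_voxel_correlations()]).
#' @export
temporal_pca <- function(matrix, n_components = 5) {
  stopifnot(inherits(matrix, "ts_matrix"))
  v <- matrix$values
  rk <- min(dim(v))
  if (n_components > rk) stop("n_components exceeds min(rows, frames)")
  sv <- svd(v, nu = 0, nv = n_components)
  evr <- sv$d^2 / sum(sv$d^2)
  n_avail <- sum(sv$d > sv$d[1] * 1e-12)
  if (n_avail < n_components)
    warning("matrix rank ", n_avail, " < n_components; returning ", n_avail,
            " components")
  k <- min(n_components, n_avail)
  lapply(seq_len(k), function(i) {
    structure(list(index = i, timeseries = sv$v[, i],
                   explained_variance_ratio = evr[i],
                   voxel_r = NULL, median_r = NULL, histogram = NULL,
                   sign_flipped = FALSE),
              class = "pc_profile")
  })
}

# histogram over 50 equal bins on [-1,1]; internal bins right-open, the last
# bin right-closed so r = 1 lands in bin 50
r_histogram <- function(r, n_bins = 50) {
  idx <- floor((r + 1) / (2 / n_bins)) + 1L
  idx[idx > n_bins] <- n_bins
  idx[idx < 1L] <- 1L
  tabulate(idx, nbins = n_bins)
}

#' Correlate PCs with all retained voxels and score asymmetry
#'
#' For each PC, computes the Pearson correlation with every voxel row. If
#' the median correlation is negative, the PC and its correlations are
#' sign-flipped so PC polarity matches the majority of voxels. The median of
#' the (possibly flipped) correlations is the PC's asymmetry score, and a
#' 50-bin histogram of correlations over \[-1, 1\] is attached.
#'
#' @param pcs List of `pc_profile` from [temporal_pca()].
#' @param matrix The `ts_matrix` the PCs were computed from.
#' @return The completed list of `pc_profile` objects.
#' @export
pc_voxel_correlations <- function(pcs, matrix) {
  stopifnot(inherits(matrix, "ts_matrix"))
  v <- matrix$values
  lapply(pcs, function(pc) {
    r <- as.vector(stats::cor(t(v), pc$timeseries))
    r[!is.finite(r)] <- 0
    if (stats::median(r) < 0) {
      pc$timeseries <- -pc$timeseries
      r <- -r
      pc$sign_flipped <- TRUE
    }
    pc$voxel_r <- r
    pc$median_r <- stats::median(r)
    pc$histogram <- r_histogram(r)
    pc
  })
}

#' Classify a run as burst-suppression from its PC asymmetry scores
#'
#' A run is flagged when the largest median cortex-wide correlation exceeds
#' the (species-specific) threshold and, if `exclusion_delta` is set, the
#' second-largest score is not within `exclusion_delta` of the largest
#' (i.e. the gap `m1 - m2` must be at least `exclusion_delta`). A gap of
#' exactly `exclusion_delta` is accepted.
#'
#' @param pcs List of completed `pc_profile` objects.
#' @param threshold Median-r threshold (strict `>`).
#' @param exclusion_delta Optional second-PC margin; `NULL` disables the
#'   exclusion rule (the primate convention); rats use 0.15.
#' @return An `asymmetry_decision`: list with `is_burst_suppression`,
#'   `selected_pc` (PC rank or `NA`), `threshold_used`, `second_pc_margin`,
#'   `exclusion_applied`, and `reason`.
#' @export
classify_run <- function(pcs, threshold, exclusion_delta = NULL) {
  if (length(pcs) < 1L) stop("need at least one completed PC profile")
  med <- vapply(pcs, function(p) p$median_r, numeric(1))
  if (any(is.na(med))) stop("PC profiles are incomplete; run pc_voxel_correlations first")
  ord <- order(-med, seq_along(med))   # ties -> lower PC rank wins
  m1 <- med[ord[1]]
  m2 <- if (length(med) >= 2L) med[ord[2]] else -Inf
  margin <- m1 - m2
  excl <- FALSE
  if (m1 <= threshold) {
    bs <- FALSE
    reason <- sprintf("top median r %.3f <= threshold %.3f", m1, threshold)
  } else if (!is.null(exclusion_delta) && margin < exclusion_delta) {
    bs <- FALSE
    excl <- TRUE
    reason <- sprintf(
      "second PC within %.3f of the most asymmetric PC (gap %.3f < %.3f)",
      exclusion_delta, margin, exclusion_delta)
  } else {
    bs <- TRUE
    reason <- sprintf("top median r %.3f > threshold %.3f%s", m1, threshold,
                      if (is.null(exclusion_delta)) "" else
                        sprintf(", gap %.3f >= %.3f", margin, exclusion_delta))
  }
  structure(list(is_burst_suppression = bs,
                 selected_pc = if (bs) pcs[[ord[1]]]$index else NA_integer_,
                 threshold_used = threshold,
                 second_pc_margin = margin,
                 exclusion_applied = excl,
                 reason = reason),
            class = "asymmetry_decision")
}

#' @export
print.asymmetry_decision <- function(x, ...) {
  cat(if (x$is_burst_suppression) "burst-suppression" else "not burst-suppression",
      sprintf(" (%s)\n", x$reason), sep = "")
  invisible(x)
}

#' Species presets for burst-suppression detection
#'
#' Median-r threshold, second-PC exclusion margin, and bandpass band per
#' species: human (0.45, none, 0.005-0.12 Hz), macaque (0.15, none,
#' 0.005-0.12 Hz), marmoset (0.22, none, 0.005-0.12 Hz), rat (0.2, 0.15,
#' 0.008-0.15 Hz).
#'
#' @param species One of `"human"`, `"macaque"`, `"marmoset"`, `"rat"`.
#' @return List with `threshold`, `exclusion_delta` (`NULL` where unused)
#'   and `band` (Hz).
#' @export
species_preset <- function(species = c("human", "macaque", "marmoset", "rat")) {
  species <- match.arg(species)
  switch(species,
    human    = list(threshold = 0.45, exclusion_delta = NULL, band = c(0.005, 0.12)),
    macaque  = list(threshold = 0.15, exclusion_delta = NULL, band = c(0.005, 0.12)),
    marmoset = list(threshold = 0.22, exclusion_delta = NULL, band = c(0.005, 0.12)),
    rat      = list(threshold = 0.20, exclusion_delta = 0.15, band = c(0.008, 0.15)))
}
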