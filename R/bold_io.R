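#' Load a 4D BOLD run from a NIfTI file
#'
#' Reads a 4D NIfTI-1/NIfTI-2 image (plain or gzipped) into a `bold_run`
#' object. The repetition time is taken from the header (`pixdim[4]`) unless
#' `tr_override` is supplied. Voxels containing any non-finite value are
#' flagged and their series zeroed, which marks them constant so that
#' [build_voxel_set()] excludes them.
#'
#' @param path Path to a 4D NIfTI file.
#' @param tr_override Optional repetition time in seconds, overriding the
#'   header value. Required if the header TR is missing or non-positive.
#' @return A `bold_run` object: list with `data` (4D array, x,y,z,frame),
#'   `tr` (seconds), `affine` (4x4 voxel-to-world transform), `n_frames`,
#'   and `nonfinite_mask` (3D logical array of flagged voxels).
#' @export
load_bold <- function(path, tr_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D image, got ", length(d), " dimensions")
  tr <- RNifti::pixdim(img)[4]
  if (!is.null(tr_override)) {
    tr <- tr_override
  } else if (!is.finite(tr) || tr <= 0) {
    stop("header TR is ", tr, "; supply tr_override")
  }
  bold_run(array(as.numeric(img), d), tr = tr, affine = unclass(RNifti::xform(img)))
}

#' Construct a BOLD run from an in-memory array
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param tr Repetition time in seconds (> 0).
#' @param affine 4x4 voxel-to-world transform; defaults to identity with
#'   unit voxels.
#' @return A `bold_run` object (see [load_bold()]).
#' @export
bold_run <- function(data, tr, affine = diag(4)) {
  d <- dim(data)
  if (is.null(d) || length(d) != 4L) stop("data must be a 4D array")
  if (d[4] < 2L) stop("need at least 2 frames")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("tr must be a positive scalar (seconds)")
  bad <- apply(!is.finite(data), c(1, 2, 3), any)
  if (any(bad)) {
    message(sum(bad), " voxel(s) contained non-finite values; flagged and zeroed")
    data[array(rep(bad, d[4]), d)] <- 0
  }
  structure(list(data = data, tr = tr, affine = affine,
                 n_frames = d[4], nonfinite_mask = bad),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat("BOLD run: ", paste(d[1:3], collapse = " x "), " voxels x ",
      d[4], " frames, TR = ", x$tr, " s\n", sep = "")
  invisible(x)
}

#' Construct a volume map aligned to a run's spatial grid
#'
#' @param values 3D numeric array.
#' @param label Semantic label, e.g. `"tsnr"`, `"r"`, `"Z"`, `"mask"`.
#' @return A `volume_map` object.
#' @export
volume_map <- function(values, label = "map") {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  structure(list(values = values, label = label), class = "volume_map")
}

#' Write a volume map as NIfTI
#'
#' @param map A `volume_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world transform.
#' @export
write_volume <- function(map, path, affine = diag(4)) {
  img <- RNifti::asNifti(map$values)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Temporal signal-to-noise ratio map
#'
#' Per voxel, the temporal mean divided by the temporal SD (population SD,
#' denominator n). Voxels with zero temporal SD get `Inf` and are flagged
#' constant in the `constant` attribute.
#'
#' @param run A `bold_run`.
#' @return A `volume_map` labelled `"tsnr"` with attribute `constant`
#'   (3D logical array).
#' @export
compute_tsnr <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  n <- d[4]
  m <- matrix(run$data, ncol = n)      # voxel x frame
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans(m * m) - mu * mu)
  sd_pop[sd_pop < 0] <- 0              # numerical guard
  constant <- sd_pop == 0
  tsnr <- ifelse(constant, Inf, mu / sd_pop)
  out <- volume_map(array(tsnr, d[1:3]), label = "tsnr")
  attr(out, "constant") <- array(constant | run$nonfinite_mask, d[1:3])
  out
}

#' Select analyzable voxels
#'
#' Retains voxels that lie inside the cortical mask (> 0), have tSNR of at
#' least `tsnr_min` (voxels with tSNR strictly below the cutoff are omitted),
#' and are not flagged constant. Voxels are ordered in a fixed deterministic
#' scan order: x fastest, then y, then z (column-major over the array).
#'
#' @param run A `bold_run`.
#' @param cortical_mask A `volume_map`; voxels with value > 0 are in-mask.
#' @param tsnr A `volume_map` from [compute_tsnr()].
#' @param tsnr_min tSNR cutoff; default 15.
#' @return A `voxel_set`: list with `indices` (n x 3 integer matrix of voxel
#'   coordinates), `linear` (column-major linear indices) and `provenance`.
#' @export
build_voxel_set <- function(run, cortical_mask, tsnr, tsnr_min = 15) {
  stopifnot(inherits(run, "bold_run"), inherits(cortical_mask, "volume_map"),
            inherits(tsnr, "volume_map"))
  dsp <- dim(run$data)[1:3]
  if (!identical(dim(cortical_mask$values), dsp) || !identical(dim(tsnr$values), dsp))
    stop("mask and tsnr must share the run's spatial grid")
  constant <- attr(tsnr, "constant")
  if (is.null(constant)) constant <- array(FALSE, dsp)
  in_mask <- cortical_mask$values > 0
  good_tsnr <- tsnr$values >= tsnr_min & !constant
  keep <- in_mask & good_tsnr
  if (!any(keep)) {
    if (!any(in_mask)) stop("empty selection: cortical mask contains no voxels")
    if (all(constant[in_mask])) stop("empty selection: all masked voxels are constant")
    stop("empty selection: tSNR filter (>= ", tsnr_min, ") removed all masked voxels")
  }
  lin <- which(keep)                   # column-major: x fastest, then y, then z
  structure(list(indices = arrayInd(lin, dsp), linear = lin,
                 provenance = sprintf("mask>0 & tSNR>=%g & !constant (%d of %d masked)",
                                      tsnr_min, length(lin), sum(in_mask))),
            class = "voxel_set")
}

#' Extract the voxel-by-frame time-series matrix of a voxel set
#'
#' @param run A `bold_run`.
#' @param voxels A `voxel_set`.
#' @return A `ts_matrix`: list with `values` (voxel x frame matrix),
#'   `voxel_index` (the `voxel_set`) and `tr`.
#' @export
extract_matrix <- function(run, voxels) {
  stopifnot(inherits(run, "bold_run"), inherits(voxels, "voxel_set"))
  n <- run$n_frames
  nvox <- prod(dim(run$data)[1:3])
  m <- matrix(run$data, ncol = n)[voxels$linear, , drop = FALSE]
  ts_matrix(m, voxel_index = voxels, tr = run$tr)
}

#' Construct a time-series matrix
#'
#' @param values Voxel x frame numeric matrix.
#' @param voxel_index Optional `voxel_set` mapping rows to voxel coordinates.
#' @param tr Repetition time in seconds.
#' @return A `ts_matrix` object.
#' @export
ts_matrix <- function(values, voxel_index = NULL, tr = 1) {
  values <- as.matrix(values)
  if (!is.null(voxel_index) && nrow(voxel_index$indices) != nrow(values))
    stop("row count must equal |voxel_index|")
  structure(list(values = values, voxel_index = voxel_index, tr = tr),
            class = "ts_matrix")
}

# Legendre polynomials P_0..P_order evaluated on n equispaced points in [-1,1],
# by the Bonnet recurrence. Columns span the same space as raw monomials but
# are far better conditioned for the joint projection.
legendre_basis <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1L)
  P[, 1] <- 1
  if (order >= 1L) P[, 2] <- x
  if (order >= 2L) for (k in 2:order)
    P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
  P
}

# Sine/cosine regressors at the discrete Fourier frequencies j/(n*tr).
# `inside = TRUE` returns the in-band columns (band.low <= f <= band.high,
# edges inclusive with a tiny tolerance); `inside = FALSE` the out-of-band
# complement. The j = 1..floor(n/2) cos/sin pairs plus the constant span R^n.
fourier_basis <- function(n, tr, band, inside = TRUE) {
  jmax <- floor(n / 2)
  f <- (1:jmax) / (n * tr)
  tol <- 1e-12
  in_band <- f >= band[1] - tol & f <= band[2] + tol
  keep <- which(if (inside) in_band else !in_band)
  if (length(keep) == 0L) return(matrix(0, n, 0))
  k <- 0:(n - 1)
  cols <- lapply(keep, function(j) {
    ang <- 2 * pi * j * k / n
    cbind(cos(ang), sin(ang))
  })
  B <- do.call(cbind, cols)
  # at the Nyquist frequency (even n) the sine column is identically zero
  B[, colSums(B * B) > 1e-8, drop = FALSE]
}

#' Jointly detrend and bandpass-filter voxel time series
#'
#' Removes Legendre polynomial trends of degree 0..`poly_order` and all
#' discrete Fourier frequencies outside `band` in one joint least-squares
#' projection: each row is residualized against the polynomial plus
#' out-of-band sine/cosine regressors. The result is the orthogonal
#' projection onto the in-band spectral subspace intersected with the
#' polynomial complement — an exact spectral projection with no filter
#' transient, idempotent, orthogonal to every removed regressor, and with
#' zero mean in every output row.
#'
#' @param matrix A `ts_matrix`.
#' @param poly_order Highest polynomial degree to remove; default 3.
#' @param band `c(low, high)` passband in Hz; default `c(0.005, 0.12)`.
#'   Rats are conventionally analyzed at `c(0.008, 0.15)`.
#' @return A `ts_matrix` of the same shape with filtered rows.
#' @export
detrend_bandpass <- function(matrix, poly_order = 3, band = c(0.005, 0.12)) {
  stopifnot(inherits(matrix, "ts_matrix"))
  n <- ncol(matrix$values)
  nyq <- 1 / (2 * matrix$tr)
  if (!(band[1] < band[2])) stop("band low must be below band high")
  if (band[2] >= nyq) stop("band high (", band[2], " Hz) must be below Nyquist (", nyq, " Hz)")
  K <- fourier_basis(n, matrix$tr, band, inside = TRUE)
  if (ncol(K) == 0L) stop("no discrete Fourier frequency falls inside the band")
  P <- legendre_basis(n, poly_order)
  Fout <- fourier_basis(n, matrix$tr, band, inside = FALSE)
  qrR <- qr(cbind(P, Fout))
  out <- matrix
  out$values <- t(qr.resid(qrR, t(matrix$values)))
  dimnames(out$values) <- dimnames(matrix$values)
  out
}

# zero-padded 1D convolution of vector x with symmetric kernel k (odd length)
conv1d_zero <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  xp <- c(numeric(r), x, numeric(r))
  out <- stats::convolve(xp, rev(k), type = "filter")
  out
}

# Gaussian kernel with sd sigma (voxel units), truncated at 4 sigma
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Spatially smooth each frame with a 3D Gaussian kernel
#'
#' Separable per-axis convolution; sigma per axis is
#' `fwhm_mm / (2 sqrt(2 log 2))` converted to voxel units via the affine's
#' column norms. Boundary handling is constant-zero padding. `fwhm_mm = 0`
#' returns the input unchanged.
#'
#' @param run A `bold_run`.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm.
#' @param mask Optional `volume_map`; if given, voxels outside the mask are
#'   zeroed before smoothing.
#' @return A `bold_run` with smoothed data.
#' @export
smooth_gaussian <- function(run, fwhm_mm, mask = NULL) {
  stopifnot(inherits(run, "bold_run"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(run)
  voxdim <- sqrt(colSums(run$affine[1:3, 1:3]^2))
  if (any(voxdim <= 0)) stop("voxel sizes not derivable from affine")
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxdim
  kernels <- lapply(sigma_vox, gauss_kernel)
  d <- dim(run$data)
  out <- run$data
  if (!is.null(mask)) out <- out * array(rep(mask$values > 0, d[4]), d)
  for (fr in seq_len(d[4])) {
    v <- out[, , , fr]
    v <- apply(v, c(2, 3), conv1d_zero, k = kernels[[1]])
    v <- aperm(apply(v, c(1, 3), conv1d_zero, k = kernels[[2]]), c(2, 1, 3))
    v <- aperm(apply(v, c(1, 2), conv1d_zero, k = kernels[[3]]), c(2, 3, 1))
    out[, , , fr] <- v
  }
  run$data <- out
  run
}

#' Z-score each voxel time series
#'
#' Normalizes every row to mean 0 and population SD 1 (denominator n).
#'
#' @param matrix A `ts_matrix` with no constant rows.
#' @return A `ts_matrix` of z-scored rows.
#' @export
zscore_rows <- function(matrix) {
  stopifnot(inherits(matrix, "ts_matrix"))
  v <- matrix$values
  mu <- rowMeans(v)
  sd_pop <- sqrt(rowMeans(v * v) - mu * mu)
  if (any(sd_pop <= 0 | !is.finite(sd_pop)))
    stop("constant row encountered: z-scoring undefined (row ",
         which(sd_pop <= 0 | !is.finite(sd_pop))[1], ")")
  out <- matrix
  out$values <- (v - mu) / sd_pop
  out
}
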