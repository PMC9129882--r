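#' Write a frame-indexed series as two-column TSV
#'
#' The exchange format for PCs, regressors and envelopes: column 1 is the
#' 0-based frame index, column 2 the value.
#'
#' @param x Numeric vector (or `burst_envelope` / `hemodynamic_model`).
#' @param path Output path.
#' @export
write_series_tsv <- function(x, path) {
  if (inherits(x, "burst_envelope")) x <- x$states
  if (inherits(x, "hemodynamic_model")) x <- x$timeseries
  utils::write.table(data.frame(frame_index = seq_along(x) - 1L, value = x),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column TSV series
#'
#' @param path Path written by [write_series_tsv()] (header optional).
#' @return Numeric vector in frame order.
#' @export
read_series_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (ncol(df) < 2L) stop("expected two columns (frame_index, value)")
  df[[2]][order(df[[1]])]
}
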