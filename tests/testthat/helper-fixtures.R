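# shared fixture builders: everything is generated in code, no stored data

# small bold_run with known voxel series; data dims 4x4x3, n frames
tiny_run <- function(n_frames = 50, seed = 7, tr = 2) {
  set.seed(seed)
  a <- array(100 + rnorm(4 * 4 * 3 * n_frames), c(4, 4, 3, n_frames))
  bold_run(a, tr = tr)
}

full_mask <- function(dims) volume_map(array(1, dims), "mask")

# random z-scored ts_matrix (rows mean 0, pop sd 1)
random_zmatrix <- function(nrow, ncol, seed = 1, tr = 2) {
  set.seed(seed)
  m <- matrix(rnorm(nrow * ncol), nrow, ncol)
  zscore_rows(ts_matrix(m, tr = tr))
}

# Pearson AUROC of score separating a binary truth (rank/Wilcoxon form)
auroc <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# direct per-neighborhood loop oracle for neighborhood cross-correlation
ncc_loop_oracle <- function(a, b, mask, rad) {
  d <- dim(a)
  vals <- c()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] <= 0) next
    xs <- max(1, i - rad):min(d[1], i + rad)
    ys <- max(1, j - rad):min(d[2], j + rad)
    zs <- max(1, k - rad):min(d[3], k + rad)
    sub_m <- mask[xs, ys, zs] > 0
    av <- a[xs, ys, zs][sub_m]
    bv <- b[xs, ys, zs][sub_m]
    if (length(av) < 5 || sd(av) == 0 || sd(bv) == 0) next
    vals <- c(vals, cor(av, bv))
  }
  mean(vals)
}
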