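test_that("voxelwise regression matches a per-voxel loop oracle", {
  set.seed(12)
  n <- 60
  reg <- as.vector(envelope_to_model(
    simulate_envelope(phantom_config(n_frames = n, seed = 3)))$timeseries)
  idx <- as.matrix(expand.grid(1:5, 1:4, 1:1))
  vs <- structure(list(indices = idx, linear = seq_len(nrow(idx)),
                       provenance = "test"), class = "voxel_set")
  m <- ts_matrix(matrix(rnorm(20 * n), 20, n), voxel_index = vs, tr = 2)
  sm <- voxelwise_regression(m, reg, grid_dim = c(5, 4, 1))
  for (v in seq_len(20)) {
    r_oracle <- cor(m$values[v, ], reg)
    expect_equal(sm$r$values[idx[v, 1], idx[v, 2], idx[v, 3]], r_oracle,
                 tolerance = 1e-12)
    expect_equal(sm$z$values[idx[v, 1], idx[v, 2], idx[v, 3]],
                 min(max(atanh(r_oracle) * sqrt(n - 3), -40), 40),
                 tolerance = 1e-12)
  }
})

test_that("voxelwise regression handles perfect, null, and degenerate cases", {
  n <- 50
  reg <- sin(seq_len(n))
  # orthogonalize a second row against the regressor
  orth <- residuals(lm(cos(seq_len(n) * 2) ~ reg))
  idx <- cbind(1:3, 1, 1)
  vs <- structure(list(indices = idx, linear = 1:3, provenance = "test"),
                  class = "voxel_set")
  m <- ts_matrix(rbind(reg, orth, rnorm(n)), voxel_index = vs, tr = 2)
  sm <- voxelwise_regression(m, reg, grid_dim = c(3, 1, 1))
  expect_equal(sm$r$values[1, 1, 1], 1, tolerance = 1e-12)
  expect_equal(sm$z$values[1, 1, 1], 40)        # documented cap
  expect_equal(sm$r$values[2, 1, 1], 0, tolerance = 1e-10)
  expect_equal(sm$z$values[2, 1, 1], 0, tolerance = 1e-8)
  expect_error(voxelwise_regression(m, rep(1, n)), "constant")
  # voxels outside the set are NA
  big <- voxelwise_regression(m, reg, grid_dim = c(3, 2, 1))
  expect_true(is.na(big$r$values[1, 2, 1]))
})

test_that("shared path: r-map equals the PC's voxel correlations for that PC", {
  ph <- simulate_bold(phantom_config(seed = 6))
  fit <- bs_detect(ph$run, ph$truth$cortex_mask, species = "macaque")
  pc1 <- fit$pcs[[1]]
  sm <- voxelwise_regression(fit$carpet, pc1$timeseries,
                             grid_dim = dim(ph$run$data)[1:3])
  idx <- fit$voxels$indices
  rmap_vals <- sm$r$values[idx]
  expect_equal(rmap_vals, pc1$voxel_r, tolerance = 1e-12)
})

test_that("neighborhood cross-correlation matches a loop oracle and its invariances", {
  set.seed(77)
  d <- c(12, 12, 8)
  a <- array(rnorm(prod(d)), d)
  b <- 0.5 * a + array(rnorm(prod(d)), d)
  mask <- array(0, d); mask[3:10, 3:10, 2:7] <- 1
  A <- volume_map(a, "r"); B <- volume_map(b, "r"); M <- volume_map(mask, "mask")

  got <- neighborhood_cross_correlation(A, B, M, radius_vox = 2)
  oracle <- ncc_loop_oracle(a, b, mask, 2)
  expect_equal(got, oracle, tolerance = 1e-10)

  # self-similarity and affine invariance
  expect_equal(neighborhood_cross_correlation(A, A, M, 2), 1, tolerance = 1e-10)
  B2 <- volume_map(2 * a + 7, "r")
  expect_equal(neighborhood_cross_correlation(A, B2, M, 2), 1, tolerance = 1e-10)

  # symmetry
  expect_equal(neighborhood_cross_correlation(A, B, M, 2),
               neighborhood_cross_correlation(B, A, M, 2), tolerance = 1e-12)

  # empty mask rejected
  expect_error(neighborhood_cross_correlation(A, B, volume_map(array(0, d), "mask")),
               "empty")
})

test_that("two independent random maps have near-zero neighborhood correlation", {
  set.seed(99)
  d <- c(20, 20, 20)
  A <- volume_map(array(rnorm(prod(d)), d), "r")
  B <- volume_map(array(rnorm(prod(d)), d), "r")
  M <- volume_map(array(1, d), "mask")
  got <- neighborhood_cross_correlation(A, B, M, radius_vox = 4)
  expect_lt(abs(got), 0.05)
})

test_that("ROI signal is percent change about the temporal mean", {
  # two frames (90, 110), mean 100 -> (-10, +10)%
  a <- array(0, c(2, 2, 1, 2)); a[, , , 1] <- 90; a[, , , 2] <- 110
  run <- bold_run(a, tr = 2)
  roi <- volume_map(array(1, c(2, 2, 1)), "roi")
  rs <- roi_signal(run, roi)
  expect_equal(rs$timeseries, c(-10, 10), tolerance = 1e-12)
  expect_lt(abs(mean(rs$timeseries)), 1e-9)

  # constant ROI -> zeros; doubling units changes nothing
  ac <- array(200, c(2, 2, 1, 5))
  expect_equal(roi_signal(bold_run(ac, tr = 2), roi)$timeseries, rep(0, 5))
  rs2 <- roi_signal(bold_run(2 * a, tr = 2), roi)
  expect_equal(rs2$timeseries, rs$timeseries, tolerance = 1e-12)

  # degenerate inputs
  expect_error(roi_signal(run, volume_map(array(0, c(2, 2, 1)), "roi")), "empty")
  neg <- bold_run(a - 200, tr = 2)
  expect_error(roi_signal(neg, roi), "non-positive")
})

test_that("Welch PSD satisfies Parseval and locates a sine peak", {
  tr <- 2; n <- 400
  f0 <- 0.03                     # in-band frequency
  x <- sin(2 * pi * f0 * (0:(n - 1)) * tr)
  psd <- welch_psd(x, fs = 1 / tr, nperseg = 100, noverlap = 50)
  expect_equal(psd$freq[which.max(psd$psd)], f0, tolerance = 0.006)
  # rectangle-rule integral of the PSD ~ variance (Parseval within 5%)
  total <- sum(psd$psd) * diff(psd$freq[1:2])
  expect_equal(total, var(x) * (n - 1) / n, tolerance = 0.05)
})

test_that("ROI metrics: SD definition, band log-PSD, degenerate input", {
  set.seed(55)
  rs <- structure(list(timeseries = rnorm(400), roi_name = "test", tr = 2),
                  class = "roi_series")
  rs$timeseries <- rs$timeseries - mean(rs$timeseries)
  met <- roi_metrics(rs)
  expect_equal(met$sd, sqrt(mean(rs$timeseries^2)), tolerance = 1e-12)
  expect_equal(met$sd, 1, tolerance = 0.1)
  expect_named(met$band_logpsd, c("low", "high"))
  expect_true(all(met$psd$psd >= 0))
  expect_true(all(diff(met$psd$freq) > 0))

  # all-zero series: SD 0, log integration flagged undefined
  z <- structure(list(timeseries = rep(0, 200), roi_name = "z", tr = 2),
                 class = "roi_series")
  mz <- roi_metrics(z)
  expect_equal(mz$sd, 0)
  expect_true(all(is.na(mz$band_logpsd)))
  expect_gt(mz$n_zero_bins, 0)

  # series shorter than one segment errors
  s <- structure(list(timeseries = rnorm(50), roi_name = "s", tr = 2),
                 class = "roi_series")
  expect_error(roi_metrics(s), "shorter")
})

test_that("min-max scaling maps to [0,1] with the documented symmetries", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.3, 0.8, 1)
  expect_equal(minmax_scale(x), x)
  set.seed(2)
  y <- rnorm(50)
  expect_equal(minmax_scale(-y), 1 - minmax_scale(y), tolerance = 1e-12)
  expect_error(minmax_scale(rep(3, 5)), "constant")
  # SD round trip: scaling then inverse rescaling preserves the SD
  s <- minmax_scale(y) * diff(range(y)) + min(y)
  expect_equal(sd(s), sd(y), tolerance = 1e-10)
})

test_that("engaged-region seed map recovers the engagement mask (AUROC)", {
  cfg <- phantom_config(seed = 17, noise_sd_pct = 1, amplitude_pct = 1)
  ph <- simulate_bold(cfg)
  fit <- bs_detect(ph$run, ph$truth$cortex_mask, species = "human")
  seed_roi <- volume_map(ph$truth$engaged_mask$values, "engaged")
  rs <- roi_signal(ph$run, seed_roi)
  reg <- detrend_bandpass(ts_matrix(rbind(rs$timeseries), tr = cfg$tr))$values[1, ]
  sm <- voxelwise_regression(fit$carpet, reg, grid_dim = cfg$grid)
  idx <- fit$voxels$indices
  scores <- sm$r$values[idx]
  truth <- ph$truth$engaged_mask$values[idx] > 0
  expect_gt(auroc(scores, truth), 0.95)
})
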