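test_that("amplitude and FWHM match closed forms", {
  # symmetric triangle: peak 1.0 at index 31, base half-width 5 samples
  tri <- numeric(60)
  tri[26:36] <- 1 - abs(-5:5) / 5
  f <- feat_simple(wave_from_samples(tri))
  expect_equal(unname(f["a"]), 1.0)
  expect_equal(unname(f["w"]), 5.0)
  # Gaussian pulse: FWHM = 2*sqrt(2*log(2))*sigma, within 0.05 samples for
  # sigma >= 2 (linear-interpolation accuracy)
  for (sigma in seq(2, 6, by = 0.5)) {
    g <- exp(-((1:60 - 31) / sigma)^2 / 2)
    f <- feat_simple(wave_from_samples(g))
    expect_equal(unname(f["a"]), 1.0)
    expect_lt(abs(unname(f["w"]) - 2 * sqrt(2 * log(2)) * sigma), 0.05)
  }
  # all-negative waveform is excluded
  expect_null(feat_simple(wave_from_samples(-(1:60) / 10)))
  # missing half-crossing on one side is excluded
  ramp_up <- (1:60) / 60
  expect_null(feat_simple(wave_from_samples(ramp_up)))
})

test_that("fundamental points implement the first-zero-crossing exclusion rule", {
  # strictly negative fd: no crossing, undefined
  expect_false(fundamental_points(wave_from_samples(-(1:60) * 0.1))$defined)
  # monotone rising ramp (fd constant > 0): undefined
  expect_false(fundamental_points(wave_from_samples((1:60) * 0.1))$defined)
  # zero waveform: undefined
  expect_false(fundamental_points(wave_from_samples(numeric(60)))$defined)
  # fd ~ sin: P1 found where the dense scan finds the first sign change
  s <- -cos(2 * pi * (1:60) / 30)          # fd proportional to sin
  w <- wave_from_samples(s)
  pts <- fundamental_points(w)
  expect_true(pts$defined)
  oracle <- NA_integer_
  for (i in 2:60) {
    if (sign(w$fd[i]) != sign(w$fd[i - 1])) { oracle <- i; break }
  }
  expect_identical(pts$P1, oracle)
  # realistic waveforms: all six points inside the window
  for (w in generator_waveforms(seed = 11)[1:8]) {
    pts <- fundamental_points(w)
    expect_true(pts$defined)
    idx <- unlist(pts[c("P1", "P2", "P3", "P4", "P5", "P6")])
    expect_true(all(idx >= 1 & idx <= 60))
  }
})

test_that("f8 is the mean squared first-derivative amplitude before P1", {
  # craft a window whose fd is exactly -c on the four samples before P1 = 5
  c_ <- 0.8
  s <- numeric(60)
  s[1:5] <- -c_ * (1:5)
  s[6] <- s[4]                      # forces fd[5] = 0: sign change at i = 5
  s[7:31] <- s[6] + c_ * (1:25)     # rise to a positive peak
  s[32:60] <- s[31] * exp(-(1:29) / 6)
  w <- wave_from_samples(s)
  pts <- fundamental_points(w)
  expect_identical(pts$P1, 5L)
  f <- feat_spdf(w, pts)
  expect_equal(unname(f["f8"]), c_^2)
})

test_that("the printed FV3 definitions hold and SPDF shares the exclusion mask", {
  waves <- generator_waveforms(seed = 12)
  for (w in waves[1:10]) {
    d <- differentiate_waveform(w$samples)   # independent recomputation
    fv3 <- feat_fv3(w)
    expect_equal(unname(fv3), c(max(d$fd), max(d$sd), min(d$sd)))
    full <- feat_spdf(w)
    expect_length(full, 23L)
    expect_true(all(is.finite(full)))
    expect_identical(names(full), spdf_feature_registry()$name)
    expect_equal(full[c("f14", "f18", "f19")], fv3,
                 ignore_attr = TRUE)
    # linearity of the three extrema under positive scaling
    w2 <- wave_from_samples(2.5 * w$samples, track = w$track)
    expect_equal(unname(feat_fv3(w2)), 2.5 * unname(fv3))
  }
  # exclusion is shared: FV3 excluded iff full vector excluded
  degenerate <- wave_from_samples(-(1:60) * 0.1)
  expect_null(feat_fv3(degenerate))
  expect_null(feat_spdf(degenerate))
})

test_that("feature matrices conserve spikes: included + excluded = input", {
  waves <- generator_waveforms(seed = 13)
  # inject degenerate waveforms that the derivative-based sets must drop
  waves <- c(waves, list(wave_from_samples(-(1:60) * 0.1, "Track1"),
                         wave_from_samples((1:60) * 0.1, "Track2")))
  masks <- list()
  for (fs_name in feature_sets()) {
    fm <- feature_matrix(waves, fs_name)
    expect_identical(fm$n_input, length(waves))
    expect_identical(sum(fm$included) + sum(!fm$included), length(waves))
    expect_identical(nrow(fm$X), sum(fm$included))
    expect_identical(length(fm$labels), sum(fm$included))
    expect_true(all(is.finite(fm$X)))
    masks[[fs_name]] <- fm$included
  }
  # the raw-waveform set never excludes anything
  expect_true(all(masks$W_raw))
  expect_true(all(masks$W_2PCA))
  # FV3 and the full SPDF vector share one mask
  expect_identical(masks$SPDF_FV3, masks$SPDF_raw)
  # raw features are the identity on the aligned samples
  fm_raw <- feature_matrix(waves, "W_raw")
  expect_equal(fm_raw$X[1, ], waves[[1]]$samples, ignore_attr = TRUE)
})

test_that("feature matrix CSV round trip preserves values and labels", {
  waves <- generator_waveforms(seed = 14)
  fm <- feature_matrix(waves, "SPDF_FV3")
  path <- file.path(tempdir(), "fm.csv")
  on.exit(unlink(path))
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path, "SPDF_FV3")
  expect_equal(back$X, fm$X, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(back$labels, fm$labels)
})

test_that("PCA behaves as an orthogonal variance decomposition", {
  # data on an exact line: first component captures everything
  set.seed(21)
  t_ <- stats::rnorm(50)
  dir <- stats::rnorm(60); dir <- dir / sqrt(sum(dir^2))
  X <- outer(t_, dir)
  fit <- fit_pca(X, 2)
  expect_equal(fit$model$explained_variance_ratio[1], 1.0, tolerance = 1e-9)
  # scores are centered
  expect_equal(colMeans(fit$scores), c(PC1 = 0, PC2 = 0), tolerance = 1e-9)
  # isotropic cloud: leading ratios approximately equal
  Y <- matrix(stats::rnorm(1000 * 5), 1000, 5)
  fy <- fit_pca(Y, 5)
  expect_true(all(fy$model$explained_variance_ratio > 0.1 &
                  fy$model$explained_variance_ratio < 0.3))
  # ratio non-increasing, cumulative <= 1
  r <- fy$model$explained_variance_ratio
  expect_true(all(diff(r) <= 1e-12))
  expect_lte(sum(r), 1 + 1e-12)
  # reconstruction error is non-increasing in the number of components
  waves <- generator_waveforms(seed = 15)
  W <- do.call(rbind, lapply(waves, feat_raw))
  errs <- sapply(1:5, function(m) {
    f <- fit_pca(W, m)
    recon <- f$scores %*% t(f$model$components) +
      matrix(f$model$mean, nrow(W), ncol(W), byrow = TRUE)
    mean((W - recon)^2)
  })
  expect_true(all(diff(errs) <= 1e-9))
  expect_error(fit_pca(W[1:3, ], 3), "parameter error")
})
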