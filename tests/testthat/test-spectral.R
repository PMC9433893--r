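test_that("IQ demodulation mixes a carrier tone down to DC", {
  fs <- 40; f_mod <- 2.75
  t <- (0:1999) / fs
  rf <- cos(2 * pi * f_mod * t)
  z <- iq_demodulate(rf, fs, f_mod, 0.85)
  mid <- Mod(z[200:1800])
  expect_lt((max(mid) - min(mid)) / mean(mid), 0.01)
  expect_equal(mean(mid), 1, tolerance = 0.01)
})

test_that("an in-band tone lands at its offset frequency after mixing", {
  fs <- 40; f_mod <- 2.75; delta <- 0.4
  n <- 4096
  t <- (0:(n - 1)) / fs
  rf <- cos(2 * pi * (f_mod + delta) * t)
  z <- iq_demodulate(rf, fs, f_mod, 0.85)
  spec <- Mod(fft(z))
  freqs <- (0:(n - 1)) * fs / n
  peak <- which.max(spec)
  expect_lt(abs(freqs[peak] - delta), fs / n + 1e-9)
})

test_that("out-of-band energy is strongly attenuated", {
  fs <- 40; f_mod <- 2.75
  t <- (0:1999) / fs
  inband <- iq_demodulate(cos(2 * pi * f_mod * t), fs, f_mod, 0.85)
  outband <- iq_demodulate(cos(2 * pi * (f_mod + 3 * 0.85 * f_mod / 2) * t),
                           fs, f_mod, 0.85)
  ratio <- mean(Mod(outband[200:1800])) / mean(Mod(inband[200:1800]))
  expect_lt(ratio, 0.01)
})

test_that("IQ demodulation rejects invalid modulation settings", {
  expect_error(iq_demodulate(rnorm(100), fs = 5, f_mod = 2.5), "Nyquist|fs/2")
  expect_error(iq_demodulate(rnorm(100), fs = 40, f_mod = 2.75,
                             bandwidth = 0), "bandwidth")
})

test_that("kernel spectra of a pure complex tone match a direct DFT oracle", {
  n_ax <- 64; n_bins <- 128L
  phi <- 8 / n_bins # cycles per sample, an exact padded-DFT bin
  iq <- matrix(exp(2i * pi * phi * (0:(n_ax - 1))), n_ax, 3)
  mask <- as_mask(matrix(c(rep(FALSE, 32), TRUE, rep(FALSE, n_ax - 33)),
                         n_ax, 3))
  dz <- 0.1
  rows <- kernel_spectra(iq, mask, kernel_mm = 1.9, axial_spacing = dz,
                         n_bins = n_bins)
  expect_equal(nrow(rows), 3)
  # oracle: Hann-windowed, zero-padded DFT power of the same kernel
  k <- 19
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(k - 1)) / (k - 1))
  kern <- exp(2i * pi * phi * (24:42)) * win
  oracle <- Mod(fft(c(kern, rep(0i, n_bins - k))))^2
  oracle <- oracle[c((n_bins / 2 + 1):n_bins, 1:(n_bins / 2))]
  expect_equal(unname(rows[1, ]), oracle, tolerance = 1e-12)
  # the dominant bin sits at +phi on the shifted frequency axis
  expect_equal(which.max(rows[1, ]), n_bins / 2 + 1 + phi * n_bins)
})

test_that("kernel spectra honor masks, borders, and power scaling", {
  iq <- matrix(complex(real = rnorm(200), imaginary = rnorm(200)), 50, 4)
  dz <- 0.1
  none <- kernel_spectra(iq, as_mask(matrix(FALSE, 50, 4)), 1.9, dz)
  expect_equal(nrow(none), 0)
  # masked pixels too close to the border are dropped; all dropped -> error
  edge <- matrix(FALSE, 50, 4); edge[2, 1] <- TRUE
  expect_error(kernel_spectra(iq, as_mask(edge), 1.9, dz), "beyond")
  ok <- matrix(FALSE, 50, 4); ok[c(2, 25), 1] <- TRUE
  kept <- kernel_spectra(iq, as_mask(ok), 1.9, dz)
  expect_equal(nrow(kept), 1)
  expect_equal(attr(kept, "pixel_index")[1, ], c(25L, 1L))
  # doubling the amplitude quadruples the power
  four <- kernel_spectra(2 * iq, as_mask(ok), 1.9, dz)
  expect_equal(unname(four[1, ]), unname(4 * kept[1, ]), tolerance = 1e-12)
  expect_error(kernel_spectra(iq, as_mask(ok), 0.2, dz), "4 samples")
})

test_that("stacking normalizes per row and floors at the dynamic range", {
  px <- matrix(c(1L, 1L), 1)
  r1 <- matrix(c(2, 2, 2), 1); attr(r1, "pixel_index") <- px
  r2 <- matrix(c(2, 2, 2), 1); attr(r2, "pixel_index") <- px
  st <- stack_and_compress(r1, r2, 60)
  expect_equal(as.numeric(st), rep(0, 6)) # flat row compresses to 0 dB
  r3 <- matrix(c(1, 1e-4, 1e-8), 1); attr(r3, "pixel_index") <- px
  r4 <- matrix(c(0.5, 0.5, 0.5), 1); attr(r4, "pixel_index") <- px
  st2 <- stack_and_compress(r3, r4, 60)
  expect_equal(as.numeric(st2)[1:3], c(0, -40, -60))
  expect_true(all(as.numeric(st2) >= -60 & as.numeric(st2) <= 0))
  zero <- matrix(0, 1, 3); attr(zero, "pixel_index") <- px
  expect_error(stack_and_compress(zero, zero, 60), "all-zero")
  expect_error(stack_and_compress(matrix(1, 2, 3), r1, 60), "row counts")
})

test_that("PCA basis is orthonormal with a deterministic sign and exact
           low-rank recovery", {
  set.seed(11)
  # rank-1 data: points on a line in 6-dimensional space
  line <- outer(rnorm(30), c(3, -1, 2, 0.5, -2, 1))
  fm <- fit_pca(line + 5, p = 1)
  ve <- fm$sdev^2 / sum(fm$sdev^2)
  expect_gt(ve[1], 0.999)
  expect_gt(fm$basis[which.max(abs(fm$basis))], 0)
  # projecting the training mean gives zero
  expect_lt(max(abs(project_features(fm$mean, fm))), 1e-8)

  # planar data: p = 2 reconstructs exactly
  pts <- cbind(rnorm(20), rnorm(20)) %*% matrix(rnorm(10), 2)
  fm2 <- fit_pca(pts, p = 2)
  expect_lt(max(abs(crossprod(fm2$basis) - diag(2))), 1e-8)
  recon <- fm2$projected %*% t(fm2$basis)
  expect_lt(max(abs(recon - sweep(pts, 2, fm2$mean))), 1e-8)
  expect_error(fit_pca(pts, p = 3), "rank")
  expect_error(fit_pca(pts[1:2, ], p = 2), "rows")
})

test_that("projection is consistent with the fit and kills the orthogonal
           complement", {
  set.seed(12)
  x <- matrix(rnorm(60), 12, 5)
  fm <- fit_pca(x, p = 2)
  expect_equal(project_features(x, fm), fm$projected, tolerance = 1e-10)
  # a vector orthogonal to the basis projects to zero
  v <- rnorm(5)
  v_perp <- v - fm$basis %*% crossprod(fm$basis, v)
  expect_lt(max(abs(project_features(fm$mean + as.numeric(v_perp), fm))),
            1e-8)
  expect_error(project_features(matrix(1, 1, 4), fm), "bins")
})

test_that("the feature pipeline is deterministic", {
  g <- small_geometry()
  fs1 <- simulate_trial(small_scene(0.5), geom = g,
                        n_frames_per_wavelength = 1L, seed = 21L)
  cfg <- small_config()
  run <- function() {
    prep <- paatlas:::prepare_set(fs1, cfg)
    mask <- paatlas:::trial_mask(prep, cfg)
    paatlas:::set_spectra(prep, cfg, mask)
  }
  a <- run(); b <- run()
  expect_identical(a, b)
})
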