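test_that("DAS localizes a point source built from the forward delay model", {
  g <- small_geometry()
  src <- matrix(c(8, 1.2), 1) # axial, lateral (mm)
  rf <- point_source_rf(g, src, n_samp = 80)
  img <- das_image(channel_frame(rf, 710), g)
  peak <- which(img$pixels == max(img$pixels), arr.ind = TRUE)
  exp_row <- src[1] / g$axial_spacing + 1
  exp_col <- which.min(abs((seq_len(g$n_elements) - 16.5) * g$pitch - src[2]))
  expect_lte(abs(peak[1] - exp_row), 1)
  expect_lte(abs(peak[2] - exp_col), 1)
})

test_that("DAS is linear: zero input gives a zero image", {
  g <- small_geometry()
  img <- das_image(channel_frame(matrix(0, 60, 32), 710), g)
  expect_true(all(img$pixels == 0))
})

test_that("two symmetric equal sources produce equal peaks", {
  g <- small_geometry()
  src <- rbind(c(8, -2.1), c(8, 2.1))
  rf <- point_source_rf(g, src, n_samp = 80)
  img <- das_image(channel_frame(rf, 710), g)
  px <- img$pixels
  row <- round(8 / g$axial_spacing) + 1
  cols <- vapply(src[, 2], function(x)
    which.min(abs((seq_len(g$n_elements) - 16.5) * g$pitch - x)), integer(1))
  v1 <- max(px[row + (-1:1), cols[1] + (-1:1)])
  v2 <- max(px[row + (-1:1), cols[2] + (-1:1)])
  expect_lt(abs(v1 - v2) / max(v1, v2), 0.01)
})

test_that("beamforming rejects grids deeper than the recording", {
  g <- small_geometry()
  f <- channel_frame(matrix(1, 50, 32), 710)
  expect_error(das_image(f, g, n_rows = 200), "deeper")
  expect_no_error(das_image(f, g, n_rows = 99))
})

test_that("identical delayed channels give unit normalized coherence", {
  # constant channels are invariant under delaying, so every correlation
  # window sees identical pairs and the normalized coherence is exactly 1
  g <- small_geometry()
  f <- channel_frame(matrix(1, 60, 32), 710)
  for (img in list(slsc_image(f, g, M = 10),
                   mweighted_slsc_image(f, g, M = 10))) {
    interior <- img$pixels[5:50, ]
    expect_lt(max(abs(interior - 1)), 1e-6)
  }
})

test_that("independent white-noise channels average to zero coherence", {
  g <- small_geometry()
  set.seed(42)
  f <- channel_frame(matrix(rnorm(300 * 32), 300), 710)
  img <- slsc_image(f, g, M = 10)
  interior <- img$pixels[20:580, ]
  expect_gt(length(interior), 1000)
  expect_lt(abs(mean(interior)), 0.05)
})

test_that("lag weighting reduces to known special cases", {
  g <- small_geometry()
  fs1 <- simulate_trial(small_scene(1, noise_sd = 0.02), geom = g,
                        n_frames_per_wavelength = 1L, seed = 3L)
  f <- fs1$frames[[1]]
  # uniform weights must equal the normalized plain short-lag image
  a <- mweighted_slsc_image(f, g, M = 6, weights = rep(1, 6))
  b <- slsc_image(f, g, M = 6, normalize = TRUE)
  expect_lt(max(abs(a$pixels - b$pixels)), 1e-9)
  # M = 1 is the single-lag correlation image under any weighting
  a1 <- mweighted_slsc_image(f, g, M = 1)
  b1 <- slsc_image(f, g, M = 1)
  expect_lt(max(abs(a1$pixels - b1$pixels)), 1e-12)
})

test_that("weighted lag sum equals the weighted mean of per-lag images", {
  # per-lag correlation images recovered as successive differences of
  # unnormalized short-lag sums; triangular weighting must reproduce
  # sum(w_m * chat_m) / sum(w_m) pixel-wise
  g <- small_geometry()
  fs1 <- simulate_trial(small_scene(1, noise_sd = 0.05), geom = g,
                        n_frames_per_wavelength = 1L, seed = 4L)
  f <- fs1$frames[[1]]
  M <- 4
  sums <- lapply(seq_len(M), function(m)
    slsc_image(f, g, M = m, normalize = FALSE)$pixels)
  lag_imgs <- c(sums[1], lapply(2:M, function(m) sums[[m]] - sums[[m - 1]]))
  w <- M - seq_len(M) + 1
  expected <- Reduce(`+`, Map(`*`, lag_imgs, w)) / sum(w)
  got <- mweighted_slsc_image(f, g, M = M)$pixels
  expect_lt(max(abs(got - expected)), 1e-9)
})

test_that("coherent targets outshine diffuse noise in coherence images", {
  g <- small_geometry()
  for (seed in 1:3) {
    fs1 <- simulate_trial(small_scene(0.5), geom = g,
                          n_frames_per_wavelength = 1L, seed = seed)
    img <- mweighted_slsc_image(fs1$frames[[1]], g, M = 10)
    rows <- round(c(9, 15) / g$axial_spacing)
    target <- img$pixels[rows[1]:rows[2], ]
    background <- img$pixels[1:round(5 / g$axial_spacing), ]
    expect_gt(mean(target), mean(background))
  }
})

test_that("M outside [1, n_elements) is rejected", {
  g <- small_geometry()
  f <- channel_frame(matrix(1, 40, 32), 710)
  expect_error(slsc_image(f, g, M = 32), "n_elements")
  expect_error(slsc_image(f, g, M = 0), "n_elements")
})
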