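test_that("point-atlas estimates close over pure classes and clamp", {
  at <- point_atlas(mb = 10, hb = 0)
  set.seed(1)
  expect_true(all(concentration_distribution(0, at, 50) == 0))
  expect_true(all(concentration_distribution(10, at, 50) == 1))
  # scalar anchors Hb = 0, MB = 10, x = 6: 1/2 + (6 - 4) / 20 = 0.6
  expect_true(all(concentration_distribution(6, at, 50) == 0.6))
  # x = 15 overshoots: 1/2 + (15 - 5) / 20 = 1, clamp binds at the boundary
  expect_true(all(concentration_distribution(15, at, 50) == 1))
  expect_true(all(concentration_distribution(-3, at, 50) == 0))
})

test_that("linear mixtures are recovered exactly on a 101-point grid", {
  # brute-force oracle: direct evaluation of the Manhattan mixture formula
  mb <- 4.2; hb <- -1.3
  at <- point_atlas(mb, hb)
  oracle <- function(x) {
    v <- 0.5 + (abs(x - hb) - abs(x - mb)) / (2 * abs(hb - mb))
    min(max(v, 0), 1)
  }
  set.seed(2)
  for (cc in seq(0, 1, by = 0.01)) {
    x <- (1 - cc) * hb + cc * mb
    expect_equal(oracle(x), cc, tolerance = 1e-12)
    got <- concentration_distribution(x, at, 20)
    expect_true(all(abs(got - cc) < 1e-12))
  }
})

test_that("multivariate point atlases recover mixtures on the segment", {
  a <- c(2, -1, 0.5); b <- c(-1, 3, 0)
  at <- point_atlas(0, 1) # placeholder, rebuilt below with p = 3
  at$mb_rows <- matrix(rep(a, each = 4), 4)
  at$hb_rows <- matrix(rep(b, each = 4), 4)
  at$fm$p <- 3L
  set.seed(3)
  for (cc in c(0, 0.25, 0.5, 0.9, 1)) {
    got <- concentration_distribution((1 - cc) * b + cc * a, at, 10)
    expect_true(all(abs(got - cc) < 1e-12))
  }
})

test_that("degenerate atlas pairs are redrawn or rejected", {
  at <- point_atlas(1, 1) # zero separation everywhere
  expect_error(concentration_distribution(1, at, 10), "degenerate")
  # mixed atlas: some degenerate pairs, redraw succeeds
  at2 <- point_atlas(1, 0)
  at2$mb_rows <- matrix(c(0, 1, 1, 1, 1)) # one MB row collides with Hb
  set.seed(4)
  got <- concentration_distribution(1, at2, 500)
  expect_true(all(got == 1))
})

test_that("histogram filter keeps the most populated bin", {
  expect_equal(histogram_filter(rep(0.4, 7)), 0.4)
  expect_equal(histogram_filter(c(0.11, 0.12, 0.13, 0.95)), 0.12)
  # tie between bins 1 and 10 breaks to the lowest bin
  expect_equal(histogram_filter(c(0.05, 0.95)), 0.05)
  # boundary values: 0 falls in bin 1, 1 in bin 10
  expect_equal(histogram_filter(c(0, 0, 1)), 0)
  expect_equal(histogram_filter(c(1, 1, 0)), 1)
  expect_error(histogram_filter(numeric(0)), "empty")
})

test_that("atlas construction separates the pure classes", {
  run <- small_run()
  expect_gt(run$atlas$class_separation, 0)
  expect_equal(ncol(run$atlas$mb_rows), 1L) # p = 1 gives scalar samples
  # the classes form distinct clusters along the first component
  expect_gt(abs(mean(run$atlas$mb_rows) - mean(run$atlas$hb_rows)),
            2 * max(sd(run$atlas$mb_rows), sd(run$atlas$hb_rows)))
})

test_that("the same frameset as both classes is a degenerate atlas", {
  g <- small_geometry()
  fs1 <- simulate_trial(small_scene(1), geom = g,
                        n_frames_per_wavelength = 2L, seed = 6L)
  expect_warning(build_atlas(fs1, fs1, small_config()), "degenerate")
})

test_that("pure-class test trials map to their own concentration", {
  # study conditions (default noise): receiver noise keeps the coherence
  # mask on real-signal pixels, where the pure-class closure propagates
  # through the histogram and median filters
  run <- small_run()
  v1 <- run$maps[["c100_t2"]]$c
  v1 <- v1[!is.na(v1)]
  expect_gt(length(v1), 10)
  expect_gte(mean(v1 >= 0.9), 0.9)
  v0 <- run$maps[["c000_t2"]]$c
  v0 <- v0[!is.na(v0)]
  expect_gte(mean(v0 <= 0.1), 0.9)
})

test_that("median filtering matches a brute-force oracle and collapses
           frames", {
  md <- function(a, ka, kl, kf) paatlas:::cpp_median3(
    a, dim(a)[1], dim(a)[2], dim(a)[3], ka, kl, kf)
  # constant tensor is a fixed point
  a <- array(0.3, c(4, 5, 3))
  expect_equal(md(a, 3, 3, 31), a)
  # checkerboard with a 3x3 spatial kernel: interior pixels take the
  # majority (center-matching) value, computed by hand
  cb <- array(rep((outer(1:6, 1:6, `+`) %% 2), 2), c(6, 6, 2))
  f1 <- md(cb, 3, 3, 31)
  expect_equal(f1[2:5, 2:5, 1], cb[2:5, 2:5, 1])
  expect_equal(f1[, , 1], f1[, , 2]) # frame kernel >= n_f collapses frames
  # random tensor with NAs against an R oracle with clipped windows
  set.seed(5)
  x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  x[sample(60, 12)] <- NA
  oracle <- array(NA_real_, dim(x))
  for (i in 1:4) for (j in 1:5) for (f in 1:3) {
    w <- x[max(1, i - 1):min(4, i + 1), max(1, j - 1):min(5, j + 1),
           max(1, f - 1):min(3, f + 1)]
    oracle[i, j, f] <- median(w, na.rm = TRUE)
  }
  oracle[is.nan(oracle)] <- NA
  expect_equal(md(x, 3, 3, 3), oracle)
})

test_that("map estimation is deterministic given the seed and stays in
           [0, 1]", {
  run <- small_run()
  study <- small_study()
  m1 <- estimate_map(study[["c050_t2"]], run$atlas, seed = 77L)
  m2 <- estimate_map(study[["c050_t2"]], run$atlas, seed = 77L)
  expect_identical(m1$c, m2$c)
  for (m in run$maps) {
    v <- m$c[!is.na(m$c)]
    expect_true(all(v >= 0 & v <= 1))
    # estimated pixels live inside the trial coherence mask
    expect_true(all(m$mask$mask[!is.na(m$c)]))
  }
})

test_that("config mismatches with the atlas are rejected", {
  run <- small_run()
  study <- small_study()
  bad <- small_config(kernel_mm = 2.4)
  expect_error(estimate_map(study[["c050_t2"]], run$atlas, cfg = bad),
               "mismatch.*kernel_mm")
})
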