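#' Build a dual-wavelength atlas from pure-concentration trials
#'
#' Runs the full feature path on one pure methylene-blue trial (100% MB) and
#' one pure hemoglobin trial (0% MB): coherence beamforming, per-trial mask,
#' dual-wavelength stacked spectra, then a single PCA fitted on the pooled
#' rows of both classes so that atlas and test samples share one basis. The
#' projected pure-class rows are the regression anchors of the mixture
#' estimator.
#'
#' @param pure_mb,pure_hb [frameset()]s of the pure trials; each must contain
#'   both optical wavelengths.
#' @param cfg A [pa_config()].
#' @return An object of class `pa_atlas` with fields `fm` (the fitted
#'   [fit_pca()] basis), `mb_rows`, `hb_rows` (projected pure-class samples),
#'   and `config`.
#' @export
build_atlas <- function(pure_mb, pure_hb, cfg = pa_config()) {
  if (!inherits(cfg, "pa_config")) stop("cfg must be a pa_config",
                                        call. = FALSE)
  atlas_from_preps(prepare_set(pure_mb, cfg), prepare_set(pure_hb, cfg), cfg)
}

# atlas construction from cached beamforming results (shared with sweeps)
atlas_from_preps <- function(prep_mb, prep_hb, cfg) {
  feats <- lapply(list(hb = prep_hb, mb = prep_mb), function(prep) {
    mask <- trial_mask(prep, cfg)
    if (!any(mask$mask))
      stop("no coherent signal: the trial mask is empty", call. = FALSE)
    set_spectra(prep, cfg, mask)
  })
  if (nrow(feats$hb$rows) == 0L || nrow(feats$mb$rows) == 0L)
    stop("no coherent signal: no spectral rows extracted", call. = FALSE)
  pooled <- rbind(feats$hb$rows, feats$mb$rows)
  fm <- fit_pca(pooled, cfg$p)
  n_hb <- nrow(feats$hb$rows)
  hb_rows <- fm$projected[seq_len(n_hb), , drop = FALSE]
  mb_rows <- fm$projected[-seq_len(n_hb), , drop = FALSE]
  sep <- sum(abs(colMeans(mb_rows) - colMeans(hb_rows)))
  if (sep < 1e-8)
    warning("degenerate atlas: MB and Hb class means coincide",
            call. = FALSE)
  structure(list(fm = fm, mb_rows = mb_rows, hb_rows = hb_rows,
                 config = cfg, class_separation = sep),
            class = "pa_atlas")
}

#' @export
print.pa_atlas <- function(x, ...) {
  cat(sprintf("<pa_atlas> %d MB rows, %d Hb rows, p = %d, class separation %.3g\n",
              nrow(x$mb_rows), nrow(x$hb_rows), x$fm$p, x$class_separation))
  invisible(x)
}

# lean Eq.-style mixture core used per pixel: one MB row and one Hb row per
# draw, Manhattan distances, clamp to [0, 1]; degenerate pairs are redrawn
conc_core <- function(x, mb, hb, n, max_redraw = 100L) {
  n_mb <- nrow(mb); n_hb <- nrow(hb)
  i_mb <- sample.int(n_mb, n, replace = TRUE)
  i_hb <- sample.int(n_hb, n, replace = TRUE)
  l1 <- function(a, b) {
    d <- a - b
    if (ncol(mb) == 1L) abs(d) else rowSums(abs(d))
  }
  sep <- l1(hb[i_hb, , drop = FALSE], mb[i_mb, , drop = FALSE])
  tries <- 0L
  while (any(bad <- sep == 0)) {
    tries <- tries + 1L
    if (tries > max_redraw)
      stop("all drawn atlas pairs are degenerate (zero separation)",
           call. = FALSE)
    nb <- sum(bad)
    i_mb[bad] <- sample.int(n_mb, nb, replace = TRUE)
    i_hb[bad] <- sample.int(n_hb, nb, replace = TRUE)
    sep[bad] <- l1(hb[i_hb[bad], , drop = FALSE],
                   mb[i_mb[bad], , drop = FALSE])
  }
  xm <- matrix(x, n, length(x), byrow = TRUE)
  cp <- 0.5 + (l1(xm, hb[i_hb, , drop = FALSE]) -
               l1(xm, mb[i_mb, , drop = FALSE])) / (2 * sep)
  pmin(pmax(cp, 0), 1)
}

#' Concentration distribution of one projected test sample
#'
#' For each of `n` draws, one pure-MB and one pure-Hb atlas row are sampled
#' uniformly with replacement and the MB fraction is scored by the
#' Manhattan-distance linear-mixture estimator
#' `C' = 1/2 + (||x - Hb|| - ||x - MB||) / (2 ||Hb - MB||)`, clamped to
#' `[0, 1]`. A drawn pair with zero separation is redrawn (at most 100
#' rounds). Randomness comes from the R session RNG; seed it (or use the
#' `seed` argument of [estimate_map()]) for reproducibility.
#'
#' @param x Projected feature vector (length `p`).
#' @param atlas A [build_atlas()] result.
#' @param n Number of draws (default the atlas config's `n_draws`).
#' @return Numeric vector of `n` clamped concentration scores.
#' @export
concentration_distribution <- function(x, atlas, n = atlas$config$n_draws) {
  if (!inherits(atlas, "pa_atlas")) stop("atlas must be a pa_atlas",
                                         call. = FALSE)
  if (length(x) != atlas$fm$p)
    stop(sprintf("x must have length p = %d", atlas$fm$p), call. = FALSE)
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  conc_core(as.numeric(x), atlas$mb_rows, atlas$hb_rows, as.integer(n))
}

#' Histogram filter of a concentration distribution
#'
#' Bins the clamped scores into `n_bins` equal-width bins over `[0, 1]`
#' (right-closed bins, zeros fall in the first bin), keeps the values in the
#' most populated bin (ties go to the lowest-index bin), and returns their
#' mean.
#'
#' @param cprime Numeric vector of concentration scores in `[0, 1]`.
#' @param n_bins Number of bins (default 10).
#' @return The filtered scalar concentration.
#' @export
histogram_filter <- function(cprime, n_bins = 10L) {
  if (length(cprime) == 0L) stop("empty concentration vector", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be at least 1", call. = FALSE)
  bin <- pmax(ceiling(cprime * n_bins), 1L)
  counts <- tabulate(bin, nbins = n_bins)
  top <- which.max(counts) # which.max takes the lowest index on ties
  mean(cprime[bin == top])
}

#' Estimate a per-pixel MB-fraction map from a two-wavelength trial
#'
#' For every pixel inside the per-trial coherence mask and every
#' wavelength-paired frame, the stacked spectrum is projected onto the atlas
#' basis, scored by [concentration_distribution()], and condensed with the
#' [histogram_filter()], giving a concentration tensor
#' `[axial x lateral x frame]`. A median filter with a
#' `median_kernel_mm[1] x median_kernel_mm[2]` mm spatial kernel (rounded to
#' the nearest odd pixel count) and `median_kernel_frames` frames — clipped
#' at the borders, so a frame kernel at or above the frame count collapses
#' the tensor to a single 2-D map — produces the final map. Unmasked pixels
#' are `NA`.
#'
#' @param test A [frameset()] with both optical wavelengths.
#' @param atlas A [build_atlas()] result.
#' @param cfg Stage parameters; must match the atlas configuration on every
#'   feature-path field. Default: the atlas's own config.
#' @param seed Integer seed for the atlas draws; `NULL` leaves the session
#'   RNG untouched.
#' @param keep_frames Keep the per-frame tensor in the result?
#' @return An object of class `pa_concmap`: fields `c` (2-D map in
#'   `[0, 1]`, `NA` outside the mask), `mask`, `ground_truth`, `n_frames`,
#'   and optionally `tensor`.
#' @export
estimate_map <- function(test, atlas, cfg = atlas$config, seed = NULL,
                         keep_frames = FALSE) {
  if (!inherits(atlas, "pa_atlas")) stop("atlas must be a pa_atlas",
                                         call. = FALSE)
  estimate_from_prep(prepare_set(test, cfg), atlas, cfg, seed, keep_frames)
}

# map estimation from a cached beamforming result (shared with sweeps)
estimate_from_prep <- function(prep, atlas, cfg, seed = NULL,
                               keep_frames = FALSE) {
  check_config_match(cfg, atlas$config)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  mask <- trial_mask(prep, cfg)
  dims <- prep$img_dim
  if (!any(mask$mask)) {
    warning("empty coherence mask: returning an empty map", call. = FALSE)
    return(structure(list(c = matrix(NA_real_, dims[1], dims[2]),
                          mask = mask, ground_truth = prep$ground_truth,
                          n_frames = prep$n_pairs),
                     class = "pa_concmap"))
  }
  sp <- set_spectra(prep, cfg, mask)
  proj <- project_features(sp$rows, atlas$fm)

  tensor <- array(NA_real_, c(dims[1], dims[2], prep$n_pairs))
  mb <- atlas$mb_rows; hb <- atlas$hb_rows
  for (r in seq_len(nrow(proj))) {
    cp <- conc_core(proj[r, ], mb, hb, cfg$n_draws)
    tensor[sp$pixel_index[r, 1L], sp$pixel_index[r, 2L], sp$frame[r]] <-
      histogram_filter(cp, cfg$n_bins)
  }

  ka <- odd_kernel(cfg$median_kernel_mm[1] / prep$geometry$axial_spacing)
  kl <- odd_kernel(cfg$median_kernel_mm[2] / prep$geometry$lateral_spacing)
  kf <- cfg$median_kernel_frames
  filt <- cpp_median3(tensor, dims[1], dims[2], prep$n_pairs, ka, kl,
                      if (kf %% 2L == 0L) kf + 1L else kf)
  map2d <- if (kf >= prep$n_pairs) filt[, , 1L]
           else apply(filt, c(1L, 2L), median, na.rm = TRUE)
  map2d[!mask$mask] <- NA_real_
  structure(list(c = map2d, mask = mask, ground_truth = prep$ground_truth,
                 n_frames = prep$n_pairs,
                 tensor = if (keep_frames) tensor),
            class = "pa_concmap")
}

#' @export
print.pa_concmap <- function(x, ...) {
  v <- x$c[!is.na(x$c)]
  gt <- if (is.null(x$ground_truth)) "unlabeled"
        else sprintf("truth %.0f%%", 100 * x$ground_truth)
  cat(sprintf("<pa_concmap> %d x %d px, %d estimated, mean %.1f%% MB (%s)\n",
              nrow(x$c), ncol(x$c), length(v),
              if (length(v)) 100 * mean(v) else NA_real_, gt))
  invisible(x)
}

# mm extent -> nearest odd pixel count, minimum 1
odd_kernel <- function(px) {
  k <- max(1L, as.integer(round(px)))
  if (k %% 2L == 0L) k + 1L else k
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
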