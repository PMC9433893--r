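#' Stage parameters of the estimation pipeline
#'
#' Collects every tunable of the mask / feature / estimation stages in one
#' validated list. Defaults: cumulative lag `M = 20` with triangular lag
#' weighting, absolute coherence threshold 0.7 for per-frame masks, IQ
#' demodulation at 2.75 MHz with 85% fractional bandwidth, 1.8-mm axial
#' spectral kernel compressed to a 60-dB dynamic range, one principal
#' component, 1000 atlas draws per pixel, a 10-bin histogram filter, and a
#' 0.64 x 0.70 mm x 30-frame median filter.
#'
#' @param M Cumulative lag for coherence beamforming.
#' @param mask_mode `"absolute"` or `"db"` per-frame mask thresholding.
#' @param mask_threshold Threshold value for `mask_mode`.
#' @param f_mod IQ modulation frequency, MHz.
#' @param bandwidth IQ fractional bandwidth.
#' @param kernel_mm Axial spectral kernel length, mm.
#' @param dynamic_range Log-compression floor, dB.
#' @param p Number of principal components.
#' @param n_draws Atlas sample pairs per pixel (N in the mixture estimator).
#' @param n_bins Histogram-filter bin count.
#' @param median_kernel_mm Axial and lateral median-filter extent, mm.
#' @param median_kernel_frames Median-filter extent in frames; a value at or
#'   above the frame count collapses the per-frame tensor to a single map.
#' @param corr_kernel Axial correlation kernel in samples, or `NULL` for one
#'   acoustic wavelength at the transducer center frequency.
#' @param n_bins_fft DFT length per wavelength block.
#' @param stride Axial stride between spectral kernels, samples.
#' @param per_block Normalize each wavelength block separately?
#' @param clip_negative Clip negative lag correlations in coherence images?
#' @return An object of class `pa_config`.
#' @export
pa_config <- function(M = 20L, mask_mode = "absolute", mask_threshold = 0.7,
                      f_mod = 2.75, bandwidth = 0.85, kernel_mm = 1.8,
                      dynamic_range = 60, p = 1L, n_draws = 1000L,
                      n_bins = 10L, median_kernel_mm = c(0.64, 0.70),
                      median_kernel_frames = 30L, corr_kernel = NULL,
                      n_bins_fft = 128L, stride = 1L, per_block = FALSE,
                      clip_negative = FALSE) {
  cfg <- list(M = as.integer(M), mask_mode = mask_mode,
              mask_threshold = mask_threshold, f_mod = f_mod,
              bandwidth = bandwidth, kernel_mm = kernel_mm,
              dynamic_range = dynamic_range, p = as.integer(p),
              n_draws = as.integer(n_draws), n_bins = as.integer(n_bins),
              median_kernel_mm = median_kernel_mm,
              median_kernel_frames = as.integer(median_kernel_frames),
              corr_kernel = corr_kernel,
              n_bins_fft = as.integer(n_bins_fft), stride = as.integer(stride),
              per_block = isTRUE(per_block),
              clip_negative = isTRUE(clip_negative))
  stopifnot(cfg$M >= 1L, cfg$mask_mode %in% c("absolute", "db"),
            cfg$f_mod > 0, cfg$bandwidth > 0, cfg$kernel_mm > 0,
            cfg$dynamic_range > 0, cfg$p >= 1L, cfg$n_draws >= 1L,
            cfg$n_bins >= 1L, length(cfg$median_kernel_mm) == 2L,
            all(cfg$median_kernel_mm > 0), cfg$median_kernel_frames >= 1L,
            cfg$n_bins_fft >= 8L, cfg$stride >= 1L)
  structure(cfg, class = "pa_config")
}

#' @export
print.pa_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<pa_config> M=%d, mask %s %.3g | IQ %.3g MHz @ %.0f%% | kernel %.2g mm,",
    " %g dB, p=%d | N=%d draws, %d bins, median %.2gx%.2g mm x %d frames\n"),
    x$M, x$mask_mode, x$mask_threshold, x$f_mod, 100 * x$bandwidth,
    x$kernel_mm, x$dynamic_range, x$p, x$n_draws, x$n_bins,
    x$median_kernel_mm[1], x$median_kernel_mm[2], x$median_kernel_frames))
  invisible(x)
}

# fields that must agree between an atlas and the data projected onto it
feature_fields <- c("f_mod", "bandwidth", "kernel_mm", "dynamic_range", "p",
                    "n_bins_fft", "stride", "per_block")

check_config_match <- function(cfg, ref) {
  for (nm in feature_fields)
    if (!isTRUE(all.equal(cfg[[nm]], ref[[nm]])))
      stop(sprintf("config mismatch with atlas: field '%s' differs", nm),
           call. = FALSE)
  invisible(TRUE)
}
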