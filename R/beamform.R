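#' @rdname das_image
#' @export
beamformed_image <- function(pixels, kind = c("amplitude", "coherence"),
                             axial_spacing, lateral_spacing) {
  kind <- match.arg(kind)
  structure(list(pixels = pixels, kind = kind, axial_spacing = axial_spacing,
                 lateral_spacing = lateral_spacing),
            class = "pa_image")
}

#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("<pa_image:%s> %d x %d px (%.4g x %.4g mm/px)\n", x$kind,
              nrow(x$pixels), ncol(x$pixels), x$axial_spacing,
              x$lateral_spacing))
  invisible(x)
}

# shared grid/argument checks; returns list(elem_x, lat_x, n_rows, dz, cs)
beamform_grid <- function(frame, geom, n_rows) {
  if (!inherits(frame, "pa_frame")) stop("frame must be a pa_frame",
                                         call. = FALSE)
  if (!inherits(geom, "pa_geometry")) stop("geom must be a pa_geometry",
                                           call. = FALSE)
  if (ncol(frame$rf) != geom$n_elements)
    stop("rf column count does not match geometry", call. = FALSE)
  n_samp <- nrow(frame$rf)
  cs <- sound_speed_mm_us(geom)
  if (is.null(n_rows)) {
    # deepest grid covered by the recording: one-way delays mean a sample
    # recorded at time t comes from depth c * t, i.e. two axial rows per
    # RF sample at the default row spacing c / (2 fs)
    n_rows <- floor((n_samp - 1) * cs / geom$fs / geom$axial_spacing) + 1L
  }
  n_rows <- as.integer(n_rows)
  # on-axis one-way delay (in samples) at the deepest pixel row
  tau_max <- (n_rows - 1L) * geom$axial_spacing / cs * geom$fs
  if (tau_max > n_samp - 1L + 1e-9)
    stop("pixel grid deeper than recorded samples", call. = FALSE)
  list(elem_x = element_positions(geom), lat_x = element_positions(geom),
       n_rows = n_rows, dz = geom$axial_spacing, cs = cs)
}

# delay-and-sum RF image (pre-envelope), used by both the amplitude image
# and the IQ feature path
das_rf <- function(frame, geom, n_rows = NULL) {
  g <- beamform_grid(frame, geom, n_rows)
  cpp_das_rf(frame$rf, g$elem_x, g$lat_x, geom$fs, g$cs, g$dz, g$n_rows)
}

# analytic signal of each column via FFT (Hilbert transform)
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  mvfft(mvfft(x + 0i) * h, inverse = TRUE) / n
}

#' Beamform a photoacoustic channel-data frame
#'
#' `das_image()` forms the conventional delay-and-sum amplitude image:
#' channels are aligned with one-way (receive-only) travel-time delays —
#' photoacoustic sources emit directly, so there is no transmit delay —
#' summed, and envelope-detected along each axial line. `slsc_image()` forms
#' the short-lag spatial coherence image: the pixel value is the sum over
#' element lags `m = 1..M` of the normalized cross-correlation of delayed
#' channel pairs at lag `m`, averaged over available pairs and computed over
#' an axial correlation kernel. `mweighted_slsc_image()` weights low lags
#' more heavily (triangular weights `M - m + 1` by default) and normalizes by
#' the weight sum, which produces less disjointed coherence masks than the
#' plain short-lag sum.
#'
#' @param frame A [channel_frame()].
#' @param geom An [acquisition_geometry()].
#' @param n_rows Number of axial pixel rows; default one row per RF sample.
#'   Errors if the grid is deeper than the recorded samples.
#' @param M Cumulative lag: the largest element separation correlated.
#' @param corr_kernel Axial correlation kernel in samples; default one
#'   acoustic wavelength at the transducer center frequency
#'   (`round(fs / fc)`), minimum 2.
#' @param normalize Divide the lag sum by `M` so that a perfectly coherent
#'   target maps to 1? Default `TRUE`.
#' @param clip_negative Clip negative per-lag correlations to zero before
#'   summing? Default `FALSE` (plain summation).
#' @param weights Lag weights, length `M`; default triangular `M - m + 1`.
#' @return A `pa_image` with `kind = "amplitude"` (DAS) or
#'   `kind = "coherence"` (SLSC variants; normalized values lie in
#'   `[-1, 1]`).
#' @export
das_image <- function(frame, geom, n_rows = NULL) {
  rfimg <- das_rf(frame, geom, n_rows)
  beamformed_image(Mod(analytic_signal(rfimg)), "amplitude",
                   geom$axial_spacing, geom$lateral_spacing)
}

default_corr_kernel <- function(geom) max(2L, as.integer(round(geom$fs / geom$fc)))

#' @rdname das_image
#' @export
slsc_image <- function(frame, geom, M = 20L, corr_kernel = NULL,
                       n_rows = NULL, normalize = TRUE,
                       clip_negative = FALSE) {
  mweighted_slsc_image(frame, geom, M = M, corr_kernel = corr_kernel,
                       n_rows = n_rows, weights = rep(1, M),
                       normalize = normalize, clip_negative = clip_negative)
}

#' @rdname das_image
#' @export
mweighted_slsc_image <- function(frame, geom, M = 20L, corr_kernel = NULL,
                                 n_rows = NULL, weights = NULL,
                                 normalize = TRUE, clip_negative = FALSE) {
  M <- as.integer(M)
  if (M < 1L || M >= geom$n_elements)
    stop("M must satisfy 1 <= M < n_elements", call. = FALSE)
  if (is.null(weights)) weights <- M - seq_len(M) + 1
  if (length(weights) != M || any(weights < 0))
    stop("weights must be a non-negative vector of length M", call. = FALSE)
  if (is.null(corr_kernel)) corr_kernel <- default_corr_kernel(geom)
  corr_kernel <- as.integer(corr_kernel)
  if (corr_kernel < 2L) stop("corr_kernel must be >= 2 samples",
                             call. = FALSE)
  g <- beamform_grid(frame, geom, n_rows)
  half <- max(1L, corr_kernel %/% 2L)
  img <- cpp_slsc(frame$rf, g$elem_x, g$lat_x, geom$fs, g$cs, g$dz, g$n_rows,
                  as.numeric(weights), half, normalize, clip_negative)
  beamformed_image(img, "coherence", geom$axial_spacing,
                   geom$lateral_spacing)
}
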