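#' IQ demodulation of radiofrequency data
#'
#' Converts real RF signals to complex baseband: each column is mixed down by
#' the modulation frequency and low-pass filtered (zero-phase Butterworth) at
#' half the retained bandwidth. No decimation is applied, so the sample count
#' is preserved and the magnitude is the signal envelope. The defaults (2.75
#' MHz, 85% fractional bandwidth) select the band where the photoacoustic
#' frequency content resides rather than the nominal transducer center
#' frequency.
#'
#' @param rf Real vector or matrix `[sample x line]`.
#' @param fs Sampling frequency, MHz.
#' @param f_mod Modulation frequency, MHz; must be below Nyquist.
#' @param bandwidth Fractional bandwidth retained around `f_mod` (0, 2].
#' @return Complex matrix of the same dimensions.
#' @export
iq_demodulate <- function(rf, fs, f_mod = 2.75, bandwidth = 0.85) {
  rf <- as.matrix(rf)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (f_mod <= 0 || f_mod >= fs / 2)
    stop("f_mod must satisfy 0 < f_mod < fs/2", call. = FALSE)
  if (bandwidth <= 0 || bandwidth > 2)
    stop("bandwidth fraction must lie in (0, 2]", call. = FALSE)
  n <- nrow(rf)
  t <- (seq_len(n) - 1) / fs
  mixer <- exp(-2i * pi * f_mod * t)
  cutoff <- bandwidth * f_mod / 2
  bf <- signal::butter(4, min(cutoff / (fs / 2), 0.99), type = "low")
  out <- matrix(0i, n, ncol(rf))
  for (j in seq_len(ncol(rf))) {
    z <- rf[, j] * mixer
    out[, j] <- complex(real = signal::filtfilt(bf, Re(z)),
                        imaginary = signal::filtfilt(bf, Im(z))) * 2
  }
  out
}

#' Sliding axial-kernel power spectra at masked pixels
#'
#' For every pixel inside the coherence mask, extracts the centered axial
#' kernel of complex baseband (IQ) data from that pixel's image column,
#' applies a Hann window, and computes the power spectrum (squared magnitude
#' of the DFT, zero-padded to a fixed bin count, bins reordered so frequency
#' ascends through baseband). Kernels that would extend beyond the image are
#' dropped; an error is raised only if that removes every masked pixel.
#'
#' @param iq Complex matrix `[axial x lateral]` of demodulated data.
#' @param mask A `pa_mask` with the same dimensions.
#' @param kernel_mm Axial kernel length, mm; must span at least 4 samples.
#' @param axial_spacing Axial pixel spacing, mm.
#' @param stride Keep only masked pixels whose axial row index steps by this
#'   many samples (default 1, every masked pixel).
#' @param n_bins DFT length after zero-padding (default 128).
#' @return Numeric matrix `[kernel x bin]` of raw (linear) spectral power,
#'   with attribute `pixel_index` (`[n x 2]`, axial row / lateral column).
#' @export
kernel_spectra <- function(iq, mask, kernel_mm, axial_spacing, stride = 1L,
                           n_bins = 128L) {
  if (!inherits(mask, "pa_mask")) stop("mask must be a pa_mask", call. = FALSE)
  if (!identical(dim(iq), dim(mask$mask)))
    stop("iq and mask dimensions differ", call. = FALSE)
  k <- as.integer(round(kernel_mm / axial_spacing))
  if (k < 4L) stop("kernel_mm must span at least 4 samples", call. = FALSE)
  if (k %% 2L == 0L) k <- k + 1L
  if (n_bins < k) stop("n_bins must be at least the kernel length",
                       call. = FALSE)
  half <- (k - 1L) %/% 2L

  idx <- which(mask$mask, arr.ind = TRUE)
  empty <- matrix(numeric(0), 0L, n_bins)
  attr(empty, "pixel_index") <- matrix(integer(0), 0L, 2L)
  if (nrow(idx) == 0L) return(empty)
  if (stride > 1L) idx <- idx[(idx[, 1L] - 1L) %% stride == 0L, , drop = FALSE]
  fits <- idx[, 1L] > half & idx[, 1L] + half <= nrow(iq)
  if (!any(fits)) {
    if (nrow(idx) > 0L)
      stop("axial kernel extends beyond the image for all masked pixels",
           call. = FALSE)
    return(empty)
  }
  idx <- idx[fits, , drop = FALSE]

  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(k) - 1) / (k - 1))
  offs <- (-half):half
  # gather kernels as a [k x n_pix] complex matrix
  cols <- matrix(iq[cbind(rep(idx[, 1L], each = k) + rep(offs, nrow(idx)),
                          rep(idx[, 2L], each = k))],
                 nrow = k)
  cols <- cols * win
  padded <- rbind(cols, matrix(0i, n_bins - k, ncol(cols)))
  pw <- Mod(mvfft(padded))^2
  # reorder so bins ascend from -fs/2 to +fs/2 around the carrier
  shift <- c((n_bins %/% 2L + 1L):n_bins, 1L:(n_bins %/% 2L))
  out <- t(pw[shift, , drop = FALSE])
  attr(out, "pixel_index") <- unname(idx)
  out
}

#' Stack dual-wavelength spectra and log compress
#'
#' Concatenates the 710-nm block before the 870-nm block along the frequency
#' axis, normalizes each concatenated row to its own maximum (so the row
#' maximum is 0 dB), converts to decibels (`10 * log10`), and floors at the
#' negative dynamic range. Normalizing the concatenated row — rather than
#' each wavelength block separately — preserves the relative 710-versus-870
#' amplitude that carries the optical-absorption contrast between the
#' chromophores; set `per_block = TRUE` for independent block normalization.
#'
#' @param spec710,spec870 Raw power-spectra matrices from [kernel_spectra()]
#'   computed at the two optical wavelengths over the same masked pixels.
#' @param dynamic_range Compression floor, dB (default 60).
#' @param per_block Normalize each wavelength block to its own maximum?
#' @return A `pa_spectra` object: the compressed matrix
#'   `[row x stacked bin]`, values in `[-dynamic_range, 0]`, with the raw
#'   stacked power kept in attribute `raw` and pixel indices in
#'   `pixel_index`.
#' @export
stack_and_compress <- function(spec710, spec870, dynamic_range = 60,
                               per_block = FALSE) {
  if (nrow(spec710) != nrow(spec870))
    stop("row counts differ between wavelengths", call. = FALSE)
  p1 <- attr(spec710, "pixel_index"); p2 <- attr(spec870, "pixel_index")
  if (!is.null(p1) && !is.null(p2) && !identical(p1, p2))
    stop("pixel indices differ between wavelengths", call. = FALSE)
  if (dynamic_range <= 0) stop("dynamic_range must be positive", call. = FALSE)
  raw <- cbind(spec710, spec870)
  nb <- ncol(spec710)
  comp <- compress_rows(raw, dynamic_range,
                        blocks = if (per_block)
                          list(seq_len(nb), nb + seq_len(nb)))
  structure(comp, class = "pa_spectra", raw = raw, pixel_index = p1,
            wavelength_order = c(710, 870), dynamic_range = dynamic_range,
            n_bins_per_wavelength = nb)
}

# row-wise normalize-to-max, 10*log10, floor at -dynamic_range
compress_rows <- function(raw, dynamic_range, blocks = NULL) {
  groups <- if (is.null(blocks)) list(seq_len(ncol(raw))) else blocks
  out <- matrix(0, nrow(raw), ncol(raw))
  for (g in groups) {
    mx <- apply(raw[, g, drop = FALSE], 1L, max)
    if (any(mx <= 0)) stop("all-zero spectrum row: nothing to normalize",
                           call. = FALSE)
    out[, g] <- pmax(10 * log10(raw[, g, drop = FALSE] / mx), -dynamic_range)
  }
  attributes(out) <- attributes(raw)["dim"]
  out
}

#' Principal-component feature reduction of stacked spectra
#'
#' `fit_pca()` performs mean-centered PCA and keeps the top `p` loading
#' vectors by explained variance, with a deterministic sign convention (the
#' largest-magnitude element of each loading is positive).
#' `project_features()` maps new rows into the fitted space:
#' `(x - mean) %*% basis`.
#'
#' @param x A `pa_spectra` or numeric matrix with at least `p + 1` rows.
#' @param p Number of principal components (default 1).
#' @return `fit_pca()` returns a `pa_features` object (fields `basis`,
#'   `mean`, `projected`, `sdev`, `p`); `project_features()` a
#'   `[n x p]` matrix.
#' @export
fit_pca <- function(x, p = 1L) {
  x <- unclass_matrix(x)
  p <- as.integer(p)
  if (p < 1L) stop("p must be at least 1", call. = FALSE)
  if (nrow(x) < p + 1L) stop("need at least p + 1 rows", call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  rank <- sum(sv$d > max(dim(xc)) * .Machine$double.eps * sv$d[1])
  if (p > rank) stop(sprintf("p = %d exceeds data rank %d", p, rank),
                     call. = FALSE)
  basis <- sv$v[, seq_len(p), drop = FALSE]
  for (j in seq_len(p)) {
    i0 <- which.max(abs(basis[, j]))
    if (basis[i0, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(list(basis = basis, mean = mu, projected = xc %*% basis,
                 sdev = sv$d / sqrt(max(1L, nrow(x) - 1L)), p = p),
            class = "pa_features")
}

#' @export
print.pa_features <- function(x, ...) {
  ve <- x$sdev^2 / sum(x$sdev^2)
  cat(sprintf("<pa_features> %d bins -> %d component(s); explained variance %s\n",
              nrow(x$basis), x$p,
              paste(sprintf("%.1f%%", 100 * ve[seq_len(x$p)]),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname fit_pca
#' @param fm A fitted `pa_features` object.
#' @export
project_features <- function(x, fm) {
  x <- unclass_matrix(x)
  if (!inherits(fm, "pa_features")) stop("fm must be a pa_features",
                                         call. = FALSE)
  if (ncol(x) != nrow(fm$basis))
    stop(sprintf("x has %d bins but the basis expects %d", ncol(x),
                 nrow(fm$basis)), call. = FALSE)
  sweep(x, 2L, fm$mean) %*% fm$basis
}

unclass_matrix <- function(x) {
  if (inherits(x, "pa_spectra")) {
    a <- attributes(x)
    x <- unclass(x)
    attributes(x) <- a["dim"]
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x))
    stop("x must be a numeric matrix", call. = FALSE)
  x
}
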