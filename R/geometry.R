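#' Acquisition geometry of a linear-array photoacoustic recording
#'
#' Describes the receive array and sampling used to record raw channel data,
#' and fixes the beamforming pixel grid: axial rows are spaced at
#' `speed_of_sound / (2 * sampling_frequency)` (the spacing implied by the RF
#' sampling rate) and lateral columns at the element pitch. Defaults match a
#' 128-element linear probe with a 5.5-MHz center frequency; speed of sound is
#' configurable because plastisol and blood differ from soft tissue.
#'
#' @param n_elements Number of array elements.
#' @param pitch Element pitch in mm.
#' @param fs RF sampling frequency in MHz.
#' @param c Speed of sound in m/s.
#' @param fc Transducer center frequency in MHz.
#' @param axial_spacing Axial pixel spacing in mm; default `c / (2 * fs)`.
#' @param lateral_spacing Lateral pixel spacing in mm; default the pitch.
#' @return An object of class `pa_geometry`.
#' @examples
#' geom <- acquisition_geometry()
#' geom$axial_spacing # 1540 / (2 * 40e6) m = 0.01925 mm
#' @export
acquisition_geometry <- function(n_elements = 128L, pitch = 0.3, fs = 40,
                                 c = 1540, fc = 5.5, axial_spacing = NULL,
                                 lateral_spacing = NULL) {
  n_elements <- as.integer(n_elements)
  if (length(n_elements) != 1L || is.na(n_elements) || n_elements <= 0L)
    stop("n_elements must be a positive integer", call. = FALSE)
  for (nm in c("pitch", "fs", "c", "fc")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("%s must be a positive number", nm), call. = FALSE)
  }
  if (is.null(axial_spacing)) axial_spacing <- (c / 1000) / (2 * fs)
  if (is.null(lateral_spacing)) lateral_spacing <- pitch
  if (axial_spacing <= 0 || lateral_spacing <= 0)
    stop("pixel spacings must be positive", call. = FALSE)
  structure(list(n_elements = n_elements, pitch = pitch, fs = fs, c = c,
                 fc = fc, axial_spacing = axial_spacing,
                 lateral_spacing = lateral_spacing),
            class = "pa_geometry")
}

#' @export
print.pa_geometry <- function(x, ...) {
  cat(sprintf(
    "<pa_geometry> %d elements, pitch %.3g mm, fs %.3g MHz, c %g m/s, fc %.3g MHz\n",
    x$n_elements, x$pitch, x$fs, x$c, x$fc))
  cat(sprintf("  pixel grid: %.4g mm axial x %.4g mm lateral\n",
              x$axial_spacing, x$lateral_spacing))
  invisible(x)
}

# speed of sound in mm/us
sound_speed_mm_us <- function(geom) geom$c / 1000

# lateral element (and pixel column) positions in mm, centered on the array
element_positions <- function(geom) {
  (seq_len(geom$n_elements) - (geom$n_elements + 1) / 2) * geom$pitch
}
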