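#' A single raw photoacoustic channel-data frame
#'
#' Wraps one radiofrequency recording: a real matrix of axial samples by
#' array elements, acquired after one laser emission at one optical
#' wavelength.
#'
#' @param rf Real matrix, `[axial sample x element]`.
#' @param wavelength Optical wavelength in nm; must be 710 or 870 for the
#'   two-wavelength estimator.
#' @param trial Trial index (integer).
#' @param frame Frame index within the trial and wavelength (integer).
#' @param energy Laser pulse energy in mJ (may be `NA` if unrecorded).
#' @return An object of class `pa_frame`.
#' @export
channel_frame <- function(rf, wavelength, trial = 1L, frame = 1L,
                          energy = NA_real_) {
  if (!is.matrix(rf) || !is.numeric(rf) || nrow(rf) < 1L || ncol(rf) < 1L)
    stop("rf must be a non-empty numeric matrix [sample x element]",
         call. = FALSE)
  wavelength <- as.numeric(wavelength)
  if (!wavelength %in% c(710, 870))
    stop("optical wavelength must be 710 or 870 nm", call. = FALSE)
  structure(list(rf = rf, wavelength = wavelength,
                 trial = as.integer(trial), frame = as.integer(frame),
                 energy = as.numeric(energy)),
            class = "pa_frame")
}

#' @export
print.pa_frame <- function(x, ...) {
  cat(sprintf("<pa_frame> %d samples x %d elements, %g nm, trial %d frame %d\n",
              nrow(x$rf), ncol(x$rf), x$wavelength, x$trial, x$frame))
  invisible(x)
}

#' A set of channel-data frames sharing one acquisition geometry
#'
#' The container consumed by all downstream stages. A set used for mixture
#' estimation must hold frames at both optical wavelengths; an optional
#' ground-truth methylene-blue volume fraction carries the known mixture
#' label of a phantom trial.
#'
#' @param frames List of [channel_frame()] objects.
#' @param geometry An [acquisition_geometry()].
#' @param ground_truth Known MB volume fraction in `[0, 1]`, or `NULL`.
#' @return An object of class `pa_frameset`.
#' @export
frameset <- function(frames, geometry, ground_truth = NULL) {
  if (!inherits(geometry, "pa_geometry"))
    stop("geometry must be a pa_geometry", call. = FALSE)
  if (!is.list(frames) || length(frames) == 0L)
    stop("no frames", call. = FALSE)
  for (f in frames) {
    if (!inherits(f, "pa_frame"))
      stop("frames must be pa_frame objects", call. = FALSE)
    if (ncol(f$rf) != geometry$n_elements)
      stop(sprintf("frame has %d channels but geometry has %d elements",
                   ncol(f$rf), geometry$n_elements), call. = FALSE)
  }
  if (!is.null(ground_truth)) {
    ground_truth <- as.numeric(ground_truth)
    if (length(ground_truth) != 1L || is.na(ground_truth) ||
        ground_truth < 0 || ground_truth > 1)
      stop("ground_truth must be a fraction in [0, 1]", call. = FALSE)
  }
  structure(list(frames = frames, geometry = geometry,
                 ground_truth = ground_truth),
            class = "pa_frameset")
}

#' @export
print.pa_frameset <- function(x, ...) {
  wl <- vapply(x$frames, function(f) f$wavelength, numeric(1))
  gt <- if (is.null(x$ground_truth)) "unlabeled"
        else sprintf("ground truth %.0f%% MB", 100 * x$ground_truth)
  cat(sprintf("<pa_frameset> %d frames (%s nm), %s\n", length(x$frames),
              paste(names(table(wl)), table(wl), sep = "x", collapse = ", "),
              gt))
  print(x$geometry)
  invisible(x)
}

# frames of one optical wavelength, ordered by frame index
frames_at <- function(fs, wavelength) {
  sel <- Filter(function(f) f$wavelength == wavelength, fs$frames)
  sel[order(vapply(sel, function(f) f$frame, integer(1)))]
}

# assert both wavelengths are present; returns frame lists paired by order
paired_frames <- function(fs) {
  f710 <- frames_at(fs, 710)
  f870 <- frames_at(fs, 870)
  if (length(f710) == 0L || length(f870) == 0L)
    stop("frameset must contain frames at both 710 and 870 nm", call. = FALSE)
  n <- min(length(f710), length(f870))
  list(f710 = f710[seq_len(n)], f870 = f870[seq_len(n)], n = n)
}
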