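#' Binary coherence masks
#'
#' `make_mask()` thresholds a coherence image into a binary segmentation of
#' coherent photoacoustic signal. In `"db"` mode a pixel passes when its
#' value, normalized to the image maximum on a decibel scale
#' (`20 * log10(v / max)`), is at or above the threshold (default -3 dB). In
#' `"absolute"` mode a pixel passes when its coherence is at or above a fixed
#' value in `(0, 1]`; negative coherence never passes. `merge_masks()` takes
#' the per-pixel logical OR of several masks — the per-trial mask is the OR
#' over all frames at both wavelengths. `dice()` scores the overlap of two
#' masks as `2 |A AND B| / (|A| + |B|) * 100` percent.
#'
#' @param coh A coherence `pa_image` (from [slsc_image()] or
#'   [mweighted_slsc_image()]).
#' @param mode `"db"` or `"absolute"`.
#' @param value Threshold: dB (typically negative) in `"db"` mode, a
#'   coherence in `(0, 1]` in `"absolute"` mode.
#' @return `make_mask()` and `merge_masks()` return a `pa_mask`; `dice()` a
#'   percentage in `[0, 100]`.
#' @export
make_mask <- function(coh, mode = c("db", "absolute"), value = NULL) {
  mode <- match.arg(mode)
  if (!inherits(coh, "pa_image") || coh$kind != "coherence")
    stop("coh must be a coherence pa_image", call. = FALSE)
  p <- coh$pixels
  if (mode == "db") {
    if (is.null(value)) value <- -3
    mx <- max(p)
    if (!is.finite(mx) || mx <= 0)
      stop("coherence image has no positive values to normalize", call. = FALSE)
    rel <- matrix(-Inf, nrow(p), ncol(p))
    pos <- p > 0
    rel[pos] <- 20 * log10(p[pos] / mx)
    mask <- rel >= value
  } else {
    if (is.null(value)) value <- 0.7
    if (!is.numeric(value) || length(value) != 1L || value <= 0 || value > 1)
      stop("absolute threshold must lie in (0, 1]", call. = FALSE)
    mask <- p >= value
  }
  structure(list(mask = mask, mode = mode, value = value,
                 source_frames = 1L),
            class = "pa_mask")
}

#' @export
print.pa_mask <- function(x, ...) {
  cat(sprintf("<pa_mask> %d x %d px, %d set (%.1f%%), %s threshold %g\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$mode, x$value))
  invisible(x)
}

#' @rdname make_mask
#' @param masks List of `pa_mask` objects with identical dimensions.
#' @export
merge_masks <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("masks must be a non-empty list", call. = FALSE)
  dims <- dim(masks[[1]]$mask)
  out <- matrix(FALSE, dims[1], dims[2])
  for (m in masks) {
    if (!inherits(m, "pa_mask")) stop("inputs must be pa_mask objects",
                                      call. = FALSE)
    if (!identical(dim(m$mask), dims))
      stop("mask dimension mismatch", call. = FALSE)
    out <- out | m$mask
  }
  structure(list(mask = out, mode = masks[[1]]$mode,
                 value = masks[[1]]$value,
                 source_frames = sum(vapply(masks, function(m)
                   m$source_frames, integer(1)))),
            class = "pa_mask")
}

#' @rdname make_mask
#' @param a,b `pa_mask` objects with identical dimensions.
#' @export
dice <- function(a, b) {
  if (!inherits(a, "pa_mask") || !inherits(b, "pa_mask"))
    stop("a and b must be pa_mask objects", call. = FALSE)
  if (!identical(dim(a$mask), dim(b$mask)))
    stop("mask dimension mismatch", call. = FALSE)
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na + nb == 0L) stop("Dice undefined: both masks are empty",
                          call. = FALSE)
  200 * sum(a$mask & b$mask) / (na + nb)
}

#' Select the short-lag cutoff that best reproduces reference masks
#'
#' Beamforms every frame with lag-weighted coherence at each candidate
#' cumulative lag `M`, thresholds the images into binary masks, and scores
#' each candidate by its Dice similarity to the corresponding reference masks
#' (typically -3 dB masks of plain short-lag images at `M = 5`). The winner
#' maximizes the mean Dice; ties are broken by smaller standard deviation,
#' then by smaller `M`.
#'
#' @param frames List of [channel_frame()] objects.
#' @param geom An [acquisition_geometry()].
#' @param reference_masks List of `pa_mask`, one per frame.
#' @param M_candidates Candidate cumulative lags (default `10:30`).
#' @param mask_mode,mask_value Thresholding applied to the candidate images
#'   (default -3 dB, matching the reference masks).
#' @param ... Passed to [mweighted_slsc_image()].
#' @return List with the chosen `M` and a per-candidate summary table.
#' @export
select_M <- function(frames, geom, reference_masks, M_candidates = 10:30,
                     mask_mode = "db", mask_value = -3, ...) {
  if (length(frames) == 0L) stop("no frames", call. = FALSE)
  if (length(reference_masks) != length(frames))
    stop("need one reference mask per frame", call. = FALSE)
  M_candidates <- as.integer(M_candidates)
  scores <- lapply(M_candidates, function(M) {
    d <- vapply(seq_along(frames), function(i) {
      img <- mweighted_slsc_image(frames[[i]], geom, M = M, ...)
      dice(make_mask(img, mask_mode, mask_value), reference_masks[[i]])
    }, numeric(1))
    c(mean = mean(d), sd = if (length(d) > 1L) sd(d) else 0)
  })
  tab <- data.frame(M = M_candidates,
                    mean_dice = vapply(scores, `[[`, numeric(1), "mean"),
                    sd_dice = vapply(scores, `[[`, numeric(1), "sd"))
  ord <- order(-tab$mean_dice, tab$sd_dice, tab$M)
  list(M = tab$M[ord[1]], table = tab)
}
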