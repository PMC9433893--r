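#' Coefficient of determination about the 1:1 line
#'
#' Scores estimated concentrations against their ground-truth labels with
#' `1 - sum((C - k)^2) / sum((C - mean(C))^2)`: the residuals are taken to
#' the identity line `C = k` rather than to a fitted regression line, so a
#' perfect estimator scores 1 and the score can be negative when estimates
#' fit worse than their own mean.
#'
#' @param estimates Estimated concentrations (fractions).
#' @param labels Ground-truth fraction for each estimate.
#' @return The R^2 value (dimensionless).
#' @export
r_squared_one_to_one <- function(estimates, labels) {
  if (length(estimates) != length(labels))
    stop("estimates and labels must have equal length", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("need at least 2 distinct labels", call. = FALSE)
  denom <- sum((estimates - mean(estimates))^2)
  if (denom == 0)
    stop("R^2 undefined: all estimates are identical", call. = FALSE)
  1 - sum((estimates - labels)^2) / denom
}

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of the rank variables; ties receive mid-ranks
#' (average). Values of 1 and -1 indicate perfectly increasing and
#' decreasing monotonic trends; `|rho| >= 0.8` is treated throughout this
#' package as a strong monotonic trend.
#'
#' @param x,y Numeric vectors of equal length (at least 2), not constant.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("Spearman's rho undefined for constant input", call. = FALSE)
  cor(rx, ry)
}

#' Mean absolute error of a concentration map, in percent
#'
#' @param estimates Estimated fractions for one ground-truth label.
#' @param k The label (fraction in `[0, 1]`).
#' @return `mean(|C - k|) * 100`, in percent concentration units.
#' @export
mae <- function(estimates, k) {
  if (length(estimates) == 0L) stop("no estimates", call. = FALSE)
  100 * mean(abs(estimates - k))
}

#' Evaluation report over a collection of concentration maps
#'
#' Pools the estimated pixels of every labeled map and reports the 1:1
#' coefficient of determination over all pixels, Spearman's rho between the
#' per-label mean estimates and the labels, the per-label mean absolute
#' error, and the overall MAE (the unweighted mean of the per-label MAEs, so
#' each concentration level counts equally).
#'
#' @param maps List of `pa_concmap` objects with ground truth set.
#' @return An object of class `pa_report` with fields `r_squared`,
#'   `spearman_rho`, `mae_per_label` (named, percent), `mae_overall`
#'   (percent), `label_means`, and `n_pixels`.
#' @export
evaluation_report <- function(maps) {
  vals <- lapply(maps, function(m) {
    if (!inherits(m, "pa_concmap")) stop("maps must be pa_concmap objects",
                                         call. = FALSE)
    if (is.null(m$ground_truth)) stop("every map needs a ground-truth label",
                                      call. = FALSE)
    v <- m$c[!is.na(m$c)]
    data.frame(est = v, k = rep(m$ground_truth, length(v)))
  })
  d <- do.call(rbind, vals)
  if (nrow(d) == 0L) stop("no estimated pixels in any map", call. = FALSE)
  labels <- sort(unique(d$k))
  mae_k <- vapply(labels, function(k) mae(d$est[d$k == k], k), numeric(1))
  means_k <- vapply(labels, function(k) mean(d$est[d$k == k]), numeric(1))
  names(mae_k) <- names(means_k) <- sprintf("%.0f%%", 100 * labels)
  structure(list(
    r_squared = if (length(labels) >= 2L)
                  r_squared_one_to_one(d$est, d$k) else NA_real_,
    spearman_rho = if (length(labels) >= 2L) spearman_rho(means_k, labels)
                   else NA_real_,
    mae_per_label = mae_k,
    mae_overall = mean(mae_k),
    label_means = means_k,
    labels = labels,
    n_pixels = nrow(d)), class = "pa_report")
}

#' @export
print.pa_report <- function(x, ...) {
  cat(sprintf("<pa_report> R^2 = %.3f, rho = %.3f, overall MAE = %.2f%% (%d pixels)\n",
              x$r_squared, x$spearman_rho, x$mae_overall, x$n_pixels))
  cat("  per-label MAE (%):\n")
  print(round(x$mae_per_label, 2))
  invisible(x)
}

#' Per-frequency linearity and monotonicity of stacked spectra
#'
#' For each stacked frequency bin and each candidate log-compression dynamic
#' range, recompresses the raw spectral power and regresses the compressed
#' amplitude on the ground-truth concentration across all samples, reporting
#' the ordinary-least-squares R^2 and Spearman's rho. This locates acoustic
#' frequencies whose amplitude tracks the mixture fraction and shows how the
#' compression floor affects that relationship (compression is the identity
#' above the floor, so curves change only where clipping binds).
#'
#' @param raw_by_label Named list mapping a ground-truth fraction (the name,
#'   e.g. `"0.3"`) to a raw stacked power matrix — either the `raw` attribute
#'   of a `pa_spectra` or a plain matrix of un-normalized power rows.
#' @param dynamic_ranges Dynamic ranges to evaluate, dB.
#' @return Data frame with columns `bin`, `dynamic_range`, `r_squared`,
#'   `rho`.
#' @export
spectral_linearity_scan <- function(raw_by_label, dynamic_ranges = 60) {
  labels <- as.numeric(names(raw_by_label))
  if (length(labels) < 3L || anyNA(labels))
    stop("need raw spectra for at least 3 numeric labels", call. = FALSE)
  mats <- lapply(raw_by_label, function(x) {
    if (inherits(x, "pa_spectra")) attr(x, "raw") else as.matrix(x)
  })
  lab_vec <- rep(labels, vapply(mats, nrow, integer(1)))
  raw <- do.call(rbind, mats)
  out <- vector("list", length(dynamic_ranges))
  for (di in seq_along(dynamic_ranges)) {
    dr <- dynamic_ranges[di]
    comp <- compress_rows(raw, dr)
    stat <- vapply(seq_len(ncol(comp)), function(b) {
      a <- comp[, b]
      if (sd(a) == 0) return(c(0, NA_real_))
      c(cor(a, lab_vec)^2, spearman_rho(a, lab_vec))
    }, numeric(2))
    out[[di]] <- data.frame(bin = seq_len(ncol(comp)), dynamic_range = dr,
                            r_squared = stat[1, ], rho = stat[2, ])
  }
  do.call(rbind, out)
}
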