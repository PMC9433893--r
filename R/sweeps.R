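# choose the training sets: the first trial labeled 0 (pure Hb) and the
# first labeled 1 (pure MB); everything else is test data
split_train_test <- function(datasets) {
  gt <- vapply(datasets, function(d) {
    if (is.null(d$ground_truth)) NA_real_ else d$ground_truth
  }, numeric(1))
  if (length(unique(gt[!is.na(gt)])) < 2L)
    stop("need at least 2 distinct ground-truth labels", call. = FALSE)
  i_hb <- which(gt == 0)[1]
  i_mb <- which(gt == 1)[1]
  if (is.na(i_hb) || is.na(i_mb))
    stop("datasets must include a pure-Hb (0) and a pure-MB (1) trial",
         call. = FALSE)
  list(i_mb = i_mb, i_hb = i_hb,
       i_test = setdiff(seq_along(datasets), c(i_mb, i_hb)), labels = gt)
}

#' Sweep feature parameters and rank settings by the 1:1 fit
#'
#' Runs the full atlas-and-estimation pipeline for every combination of axial
#' kernel length, log-compression dynamic range, and principal-component
#' count, and scores each setting by the coefficient of determination of the
#' 1:1 line between pooled estimated and true concentrations
#' ([r_squared_one_to_one()]). The atlas is trained on the first pure-Hb and
#' pure-MB trials; all other sets are test data. Beamforming and IQ
#' demodulation do not depend on the swept parameters and are computed once
#' per dataset. Ties keep the first setting in grid order.
#'
#' @param datasets List of labeled [frameset()]s (ground truth set), spanning
#'   at least two labels and including pure trials of both classes.
#' @param grid Named list or data frame with columns/fields `kernel_mm`,
#'   `dynamic_range`, and `p`; a list is expanded factorially.
#' @param cfg Base [pa_config()]; swept fields are overridden per setting.
#' @param seed Seed applied before each setting so settings are comparable.
#' @return List with `table` (one row per setting, with its R^2) and `best`
#'   (the maximizing row).
#' @export
parameter_sweep <- function(datasets, grid, cfg = pa_config(), seed = 1L) {
  if (is.list(grid) && !is.data.frame(grid))
    grid <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stop("empty parameter grid", call. = FALSE)
  need <- c("kernel_mm", "dynamic_range", "p")
  if (!all(need %in% names(grid)))
    stop("grid must provide kernel_mm, dynamic_range and p", call. = FALSE)
  sp <- split_train_test(datasets)
  preps <- lapply(datasets, prepare_set, cfg = cfg)

  r2 <- vapply(seq_len(nrow(grid)), function(g) {
    cfg_g <- cfg
    cfg_g$kernel_mm <- grid$kernel_mm[g]
    cfg_g$dynamic_range <- grid$dynamic_range[g]
    cfg_g$p <- as.integer(grid$p[g])
    atlas <- atlas_from_preps(preps[[sp$i_mb]], preps[[sp$i_hb]], cfg_g)
    est <- numeric(0); lab <- numeric(0)
    for (i in sp$i_test) {
      m <- estimate_from_prep(preps[[i]], atlas, cfg_g, seed = seed)
      v <- m$c[!is.na(m$c)]
      est <- c(est, v); lab <- c(lab, rep(sp$labels[i], length(v)))
    }
    r_squared_one_to_one(est, lab)
  }, numeric(1))

  tab <- cbind(grid, r_squared = r2)
  list(table = tab, best = tab[which.max(r2), , drop = FALSE])
}

#' Sweep the coherence-mask threshold and measure estimation error
#'
#' Regenerates absolute-mode coherence masks at each threshold, rebuilds the
#' atlas and every concentration map, and reports the mean absolute error
#' pooled over all labels and frames. Coherence images and demodulated data
#' are threshold-independent and computed once. A threshold whose masks are
#' empty for the training trials (or for every test trial) is recorded as an
#' absent entry (`NA`), not an error.
#'
#' @param datasets List of labeled [frameset()]s including pure trials.
#' @param thresholds Absolute coherence thresholds (default 0.3 to 0.9 in
#'   steps of 0.02).
#' @param cfg Base [pa_config()] (its `mask_mode` is forced to absolute).
#' @param seed Seed applied before each threshold's estimation pass.
#' @return Data frame with one row per threshold: `threshold`, `mae_pct`,
#'   and `n_pixels`.
#' @export
threshold_sweep <- function(datasets, thresholds = seq(0.3, 0.9, by = 0.02),
                            cfg = pa_config(), seed = 1L) {
  if (length(thresholds) == 0L) stop("empty threshold grid", call. = FALSE)
  cfg$mask_mode <- "absolute"
  sp <- split_train_test(datasets)
  preps <- lapply(datasets, prepare_set, cfg = cfg)

  one <- function(th) {
    cfg_t <- cfg
    cfg_t$mask_threshold <- th
    atlas <- tryCatch(
      atlas_from_preps(preps[[sp$i_mb]], preps[[sp$i_hb]], cfg_t),
      error = function(e) NULL)
    if (is.null(atlas)) return(c(NA_real_, 0))
    errs <- numeric(0)
    for (i in sp$i_test) {
      m <- suppressWarnings(
        estimate_from_prep(preps[[i]], atlas, cfg_t, seed = seed))
      v <- m$c[!is.na(m$c)]
      if (length(v)) errs <- c(errs, abs(v - sp$labels[i]))
    }
    if (!length(errs)) return(c(NA_real_, 0))
    c(100 * mean(errs), length(errs))
  }
  res <- vapply(thresholds, one, numeric(2))
  data.frame(threshold = thresholds, mae_pct = res[1, ],
             n_pixels = as.integer(res[2, ]))
}
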