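# Shared fixtures. Expensive objects (the small synthetic study and its
# estimated maps) are built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# reduced acquisition geometry used throughout the tests
small_geometry <- function() {
  acquisition_geometry(n_elements = 32L, pitch = 0.3, fs = 8, fc = 4)
}

# reduced phantom scene: 6-mm chamber centered 12 mm from the array
small_scene_args <- function(...) {
  utils::modifyList(list(chamber_center = c(12, 0), chamber_diameter = 6,
                         n_sources = 12L, depth_mm = 16), list(...))
}

small_scene <- function(mb_fraction, ...) {
  do.call(phantom_scene, c(list(mb_fraction = mb_fraction),
                           small_scene_args(...)))
}

small_config <- function(...) {
  args <- utils::modifyList(list(), list(...))
  do.call(pa_config, args)
}

# wrap a logical matrix as a coherence mask
as_mask <- function(m) {
  structure(list(mask = m, mode = "absolute", value = 0.7,
                 source_frames = 1L), class = "pa_mask")
}

# independent forward-delay oracle: raw channel data for point sources with
# exact one-way delays and a Gaussian-envelope pulse, built in plain R
# (no beamforming code involved)
point_source_rf <- function(geom, sources, n_samp, amp = NULL, f0 = 2.5,
                            sigma_us = 0.35) {
  cs <- geom$c / 1000
  elem_x <- (seq_len(geom$n_elements) - (geom$n_elements + 1) / 2) *
    geom$pitch
  t_us <- (seq_len(n_samp) - 1) / geom$fs
  if (is.null(amp)) amp <- rep(1, nrow(sources))
  rf <- matrix(0, n_samp, geom$n_elements)
  for (s in seq_len(nrow(sources))) {
    tau <- sqrt(sources[s, 1]^2 + (sources[s, 2] - elem_x)^2) / cs
    dt <- outer(t_us, tau, `-`)
    rf <- rf + amp[s] * exp(-dt^2 / (2 * sigma_us^2)) * cos(2 * pi * f0 * dt)
  }
  rf
}

# the small synthetic study: 11 concentrations x 2 trials, 3 frames per
# wavelength, default noise and energy jitter
small_study <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- generate_study(
      seq(0, 1, by = 0.1), n_trials = 2L, scene_args = small_scene_args(),
      geom = small_geometry(), n_frames_per_wavelength = 3L, seed = 7L)
  .fixtures$study
}

# atlas + estimated maps + evaluation report for the small study
small_run <- function() {
  if (is.null(.fixtures$run)) {
    study <- small_study()
    cfg <- small_config()
    gt <- vapply(study, function(s) s$ground_truth, numeric(1))
    i_mb <- which(gt == 1)[1]
    i_hb <- which(gt == 0)[1]
    atlas <- build_atlas(study[[i_mb]], study[[i_hb]], cfg)
    idx <- setdiff(seq_along(study), c(i_mb, i_hb))
    maps <- lapply(idx, function(i)
      estimate_map(study[[i]], atlas, seed = 100L + i))
    names(maps) <- names(study)[idx]
    .fixtures$run <- list(atlas = atlas, maps = maps,
                          report = evaluation_report(maps))
  }
  .fixtures$run
}

# a point atlas with scalar anchors, for closed-form estimator checks
point_atlas <- function(mb, hb, n_rows = 5L, cfg = pa_config()) {
  structure(list(
    fm = structure(list(basis = matrix(1), mean = 0,
                        projected = matrix(c(rep(hb, n_rows),
                                             rep(mb, n_rows))),
                        sdev = 1, p = 1L), class = "pa_features"),
    mb_rows = matrix(rep(mb, n_rows)),
    hb_rows = matrix(rep(hb, n_rows)),
    config = cfg, class_separation = abs(mb - hb)),
    class = "pa_atlas")
}
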