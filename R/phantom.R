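#' Chromophore model for the synthetic phantom
#'
#' Stylized optical and acoustic description of one chromophore: a relative
#' effective absorption at each optical wavelength (per mm, controlling both
#' the fluence decay from the fiber tip and the emitted amplitude) and a
#' Gaussian-envelope pulse model (center frequency per optical wavelength,
#' fractional bandwidth). The defaults are synthetic: methylene blue
#' dominates the 710-nm response and hemoglobin the 870-nm response, which is
#' the contrast the two-wavelength estimator exploits; they are not claims
#' about real molar absorptivities.
#'
#' @param name `"MB"` or `"Hb"`.
#' @param absorption Named vector `c("710" = ., "870" = .)`, per mm, > 0.
#' @param pulse_center_frequency Named vector (MHz) per optical wavelength.
#' @param pulse_bandwidth Fractional bandwidth of the emitted pulse.
#' @return An object of class `pa_chromophore`.
#' @export
chromophore_model <- function(name, absorption, pulse_center_frequency,
                              pulse_bandwidth = 0.6) {
  wl <- c("710", "870")
  if (!all(wl %in% names(absorption)) ||
      !all(wl %in% names(pulse_center_frequency)))
    stop("absorption and pulse_center_frequency need entries for 710 and 870",
         call. = FALSE)
  if (any(absorption[wl] <= 0) || any(pulse_center_frequency[wl] <= 0) ||
      pulse_bandwidth <= 0)
    stop("absorption, center frequencies and bandwidth must be positive",
         call. = FALSE)
  structure(list(name = name, absorption = absorption[wl],
                 pulse_center_frequency = pulse_center_frequency[wl],
                 pulse_bandwidth = pulse_bandwidth),
            class = "pa_chromophore")
}

#' @rdname chromophore_model
#' @export
default_chromophores <- function() {
  list(mb = chromophore_model("MB",
         absorption = c("710" = 0.060, "870" = 0.015),
         pulse_center_frequency = c("710" = 2.6, "870" = 2.2)),
       hb = chromophore_model("Hb",
         absorption = c("710" = 0.020, "870" = 0.050),
         pulse_center_frequency = c("710" = 2.6, "870" = 2.2)))
}

#' Scene description of the synthetic phantom
#'
#' Emulates a fiber-illuminated absorbing chamber imaged by a linear array
#' positioned on the lateral wall: a circular chamber (default 15 mm
#' diameter, centered 20 mm from the array) filled with an MB/Hb mixture,
#' point absorbers scattered uniformly inside it, a fiber tip whose fluence
#' decays radially, per-frame laser-energy jitter (default 3.13 +/- 0.4 mJ),
#' and additive white receiver noise.
#'
#' @param mb_fraction MB volume fraction in `[0, 1]`.
#' @param chamber_center `c(axial, lateral)` position in mm.
#' @param chamber_diameter Chamber diameter, mm.
#' @param fiber_tip `c(axial, lateral)` fiber-tip position, mm; default just
#'   above the chamber center.
#' @param n_sources Number of point absorbers.
#' @param energy_mean,energy_sd Per-frame laser energy distribution, mJ
#'   (truncated at zero).
#' @param noise_sd Receiver noise standard deviation relative to the peak
#'   noise-free channel amplitude.
#' @param r0 Radial floor, mm, preventing the fluence singularity at the
#'   fiber tip.
#' @param depth_mm Imaged depth, mm; default 3 mm past the chamber bottom.
#' @return An object of class `pa_scene`.
#' @export
phantom_scene <- function(mb_fraction, chamber_center = c(20, 0),
                          chamber_diameter = 15, fiber_tip = NULL,
                          n_sources = 25L, energy_mean = 3.13,
                          energy_sd = 0.4, noise_sd = 0.05, r0 = 0.5,
                          depth_mm = NULL) {
  if (!is.numeric(mb_fraction) || mb_fraction < 0 || mb_fraction > 1)
    stop("mb_fraction must lie in [0, 1]", call. = FALSE)
  if (chamber_diameter <= 0 || n_sources < 1L || energy_mean <= 0 ||
      energy_sd < 0 || noise_sd < 0 || r0 <= 0)
    stop("invalid scene parameter", call. = FALSE)
  if (is.null(fiber_tip))
    fiber_tip <- c(chamber_center[1] - 0.4 * chamber_diameter / 2,
                   chamber_center[2])
  if (is.null(depth_mm))
    depth_mm <- chamber_center[1] + chamber_diameter / 2 + 3
  structure(list(mb_fraction = mb_fraction, chamber_center = chamber_center,
                 chamber_diameter = chamber_diameter, fiber_tip = fiber_tip,
                 n_sources = as.integer(n_sources),
                 energy_mean = energy_mean, energy_sd = energy_sd,
                 noise_sd = noise_sd, r0 = r0, depth_mm = depth_mm),
            class = "pa_scene")
}

#' Mixture volumes for a target MB fraction
#'
#' Splits a total mixture volume into its MB and Hb parts:
#' `(total * fraction, total * (1 - fraction))`. A 2-mL mixture at 60% MB
#' is 1.2 mL of MB solution and 0.8 mL of Hb.
#'
#' @param total_ml Total volume, mL (> 0).
#' @param mb_fraction MB volume fraction in `[0, 1]`.
#' @return Named numeric vector `c(mb_ml = ., hb_ml = .)`.
#' @export
mixture_volumes <- function(total_ml, mb_fraction) {
  if (!is.numeric(total_ml) || total_ml <= 0)
    stop("total_ml must be positive", call. = FALSE)
  if (!is.numeric(mb_fraction) || mb_fraction < 0 || mb_fraction > 1)
    stop("mb_fraction must lie in [0, 1]", call. = FALSE)
  c(mb_ml = total_ml * mb_fraction, hb_ml = total_ml * (1 - mb_fraction))
}

# linear mixture of the two chromophores' effective absorption at one
# optical wavelength (per mm)
mu_eff <- function(c_mb, models, wl) {
  key <- as.character(wl)
  c_mb * models$mb$absorption[[key]] + (1 - c_mb) * models$hb$absorption[[key]]
}

#' Simulate one phantom trial of two-wavelength channel data
#'
#' Scatters point absorbers uniformly in the chamber and synthesizes raw RF
#' channel data frame by frame. Per source and optical wavelength, the
#' fluence from the fiber tip is `E * exp(-mu_eff * r) / max(r, r0)^2` with
#' `mu_eff(c, wl) = c * mu_MB(wl) + (1 - c) * mu_Hb(wl)`, and the received
#' amplitude on each element is fluence times `mu_eff` divided by the
#' source-element distance, delayed by the one-way travel time. Every source
#' emits a Gaussian-envelope pulse whose center frequency interpolates
#' between the chromophore pulse models with weight `c` and is additionally
#' scaled by the effective absorption (a more strongly absorbing mixture
#' confines the excited volume and radiates higher frequencies). Per-frame
#' energies are Normal(mean, sd) truncated above zero; white noise is added
#' relative to the peak noise-free amplitude. Absorber positions are fixed
#' within a trial, so frames differ only in energy and noise.
#'
#' @param scene A [phantom_scene()].
#' @param models Chromophore pair from [default_chromophores()] (a list with
#'   fields `mb` and `hb`).
#' @param geom An [acquisition_geometry()].
#' @param n_frames_per_wavelength Frames per optical wavelength (default 10).
#' @param seed Integer seed; the same seed reproduces the trial bit-exactly.
#' @return A labeled [frameset()] (`ground_truth = scene$mb_fraction`).
#' @export
simulate_trial <- function(scene, models = default_chromophores(),
                           geom = acquisition_geometry(),
                           n_frames_per_wavelength = 10L, seed = NULL) {
  if (!inherits(scene, "pa_scene")) stop("scene must be a pa_scene",
                                         call. = FALSE)
  radius <- scene$chamber_diameter / 2
  half_ap <- (geom$n_elements - 1) / 2 * geom$pitch
  if (abs(scene$chamber_center[2]) + radius > half_ap + geom$pitch / 2 ||
      scene$chamber_center[1] + radius > scene$depth_mm)
    stop("chamber does not fit inside the imaging grid", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  nf <- as.integer(n_frames_per_wavelength)
  cs <- sound_speed_mm_us(geom)

  # absorbers: uniform over the chamber disc
  rr <- radius * sqrt(runif(scene$n_sources))
  th <- runif(scene$n_sources, 0, 2 * pi)
  src <- cbind(axial = scene$chamber_center[1] + rr * sin(th),
               lateral = scene$chamber_center[2] + rr * cos(th))

  elem_x <- element_positions(geom)
  cmb <- scene$mb_fraction
  wls <- c(710, 870)

  # pulse parameters per wavelength for an arbitrary mixture fraction
  pulse_for <- function(cc, wl) {
    key <- as.character(wl)
    mu <- mu_eff(cc, models, wl)
    mu_bar <- (models$mb$absorption[[key]] + models$hb$absorption[[key]]) / 2
    f0 <- cc * models$mb$pulse_center_frequency[[key]] +
      (1 - cc) * models$hb$pulse_center_frequency[[key]]
    fc <- f0 * (1 + 0.05 * (mu - mu_bar) / mu_bar)
    bw <- cc * models$mb$pulse_bandwidth + (1 - cc) * models$hb$pulse_bandwidth
    sigma_t <- 1 / (2 * pi * (bw * fc / 2.355)) # us
    list(mu = mu, fc = fc, sigma_t = sigma_t)
  }
  pulse_par <- lapply(wls, pulse_for, cc = cmb)
  names(pulse_par) <- wls
  # longest pulse tail over the pure endpoints (center frequency and
  # bandwidth are linear in the fraction, so the extremes sit at c = 0 or 1);
  # keeps the recording length, and hence the image grid, mixture-independent
  sigma_bound <- max(vapply(wls, function(wl)
    max(pulse_for(0, wl)$sigma_t, pulse_for(1, wl)$sigma_t), numeric(1)))

  # recording window: covers any source within the imaged depth seen from
  # any element, plus the pulse tail; fixed by scene + geometry so every
  # trial of a study shares one grid
  dmax <- sqrt(scene$depth_mm^2 + (2 * half_ap)^2)
  n_samp <- ceiling((dmax / cs + 6 * sigma_bound) * geom$fs) + 4L
  t_us <- (seq_len(n_samp) - 1) / geom$fs

  # noise-free unit-energy channel data per wavelength
  base <- lapply(wls, function(wl) {
    pp <- pulse_par[[as.character(wl)]]
    rf <- matrix(0, n_samp, geom$n_elements)
    for (s in seq_len(scene$n_sources)) {
      r_fib <- sqrt(sum((src[s, ] - scene$fiber_tip)^2))
      fluence <- exp(-pp$mu * r_fib) / max(r_fib, scene$r0)^2
      d_se <- sqrt(src[s, 1]^2 + (src[s, 2] - elem_x)^2)
      tau <- d_se / cs
      amp <- fluence * pp$mu / d_se
      dt <- outer(t_us, tau, `-`)
      rf <- rf + sweep(exp(-dt^2 / (2 * pp$sigma_t^2)) *
                         cos(2 * pi * pp$fc * dt), 2L, amp, `*`)
    }
    rf
  })
  names(base) <- wls

  energies <- numeric(2L * nf)
  for (i in seq_along(energies)) {
    e <- rnorm(1, scene$energy_mean, scene$energy_sd)
    while (e <= 0) e <- rnorm(1, scene$energy_mean, scene$energy_sd)
    energies[i] <- e
  }

  frames <- vector("list", 2L * nf)
  k <- 0L
  for (wl in wls) {
    b <- base[[as.character(wl)]]
    nsd <- scene$noise_sd * max(abs(b))
    for (i in seq_len(nf)) {
      k <- k + 1L
      rf <- b * (energies[k] / scene$energy_mean)
      if (nsd > 0) rf <- rf + matrix(rnorm(length(rf), sd = nsd), nrow(rf))
      frames[[k]] <- channel_frame(rf, wl, trial = 1L, frame = i,
                                   energy = energies[k])
    }
  }
  frameset(frames, geom, ground_truth = cmb)
}

#' Generate a full synthetic concentration study
#'
#' One simulated trial per (concentration, trial) pair; per-trial seeds are
#' drawn without replacement from the master seed, so the study is
#' deterministic and no two trials share a seed. The defaults reproduce the
#' phantom protocol this simulator emulates: 11 MB fractions from 0 to 1 in
#' steps of 0.1, 5 trials each, 10 frames per optical wavelength.
#'
#' @param concentrations MB fractions to simulate.
#' @param n_trials Trials per concentration.
#' @param scene_args Named list of overrides passed to [phantom_scene()].
#' @param models,geom,n_frames_per_wavelength Passed to [simulate_trial()].
#' @param seed Master seed.
#' @return Named list of labeled [frameset()]s with attributes
#'   `concentration` and `trial` on each element.
#' @export
generate_study <- function(concentrations = seq(0, 1, by = 0.1),
                           n_trials = 5L, scene_args = list(),
                           models = default_chromophores(),
                           geom = acquisition_geometry(),
                           n_frames_per_wavelength = 10L, seed = 1L) {
  if (length(concentrations) == 0L) stop("no concentrations", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(concentrations) * n_trials
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  stopifnot(!anyDuplicated(seeds))
  out <- vector("list", n)
  nms <- character(n)
  k <- 0L
  for (ci in seq_along(concentrations)) {
    for (tr in seq_len(n_trials)) {
      k <- k + 1L
      scene <- do.call(phantom_scene,
                       c(list(mb_fraction = concentrations[ci]), scene_args))
      fs <- simulate_trial(scene, models, geom, n_frames_per_wavelength,
                           seed = seeds[k])
      for (f in seq_along(fs$frames)) fs$frames[[f]]$trial <- as.integer(tr)
      attr(fs, "concentration") <- concentrations[ci]
      attr(fs, "trial") <- tr
      out[[k]] <- fs
      nms[k] <- sprintf("c%03.0f_t%d", 100 * concentrations[ci], tr)
    }
  }
  names(out) <- nms
  out
}
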