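# paatlas

Estimation of the local volume fraction of an exogenous photoacoustic
contrast agent — methylene blue (MB) — mixed with hemoglobin (Hb), from raw
ultrasound channel data acquired after laser emissions at two optical
wavelengths (710 and 870 nm).

Methylene blue is injected to enhance photoacoustic visualization of
vasculature, but its local accumulation must be monitored: excess
concentrations risk hemolysis and photodamage. Traditional spectral unmixing
needs many laser wavelengths per estimate, which is too slow for
interventional use. The dual-wavelength atlas method instead exploits the
*acoustic* frequency content of the photoacoustic response: because fiber
illumination produces a fluence field that decays radially, different
absorber concentrations excite differently sized volumes and radiate
different acoustic spectra. Two wavelengths are enough to separate the
MB and Hb contributions.

The package is written for researchers working with linear-array
photoacoustic systems, and includes a synthetic phantom simulator so that
every stage — and the full estimation pipeline — is testable without
experimental data.

## Method

For each trial, raw channel frames are processed as follows:

1. **Coherence masking.** Each frame is beamformed with lag-weighted
   short-lag spatial coherence (SLSC): the pixel value is
   `sum_m w_m c(m) / sum_m w_m`, where `c(m)` is the normalized
   cross-correlation of receive channels at element lag `m <= M` (default
   `M = 20`, triangular weights `w_m = M - m + 1`). Thresholding (absolute
   coherence 0.7 by default, or dB-relative) and a logical OR across all
   frames and both wavelengths give the per-trial segmentation mask.
2. **Spectral features.** Delay-and-sum beamformed lines are IQ-demodulated
   (2.75 MHz, 85% bandwidth). For every masked pixel, a 1.8-mm axial kernel
   yields a power spectrum per wavelength; the 710-nm and 870-nm spectra are
   concatenated, normalized to the row maximum, log compressed with a
   dynamic-range floor, and reduced by PCA (default: first principal
   component).
3. **Atlas regression.** A PCA atlas is built from one pure-Hb (0% MB) and
   one pure-MB (100%) trial. For a test sample `x`, `N = 1000` random
   atlas pairs `(MB_i, Hb_i)` give the concentration distribution

       C'_i = 1/2 + (||x - Hb_i||_1 - ||x - MB_i||_1) / (2 ||Hb_i - MB_i||_1)

   clamped to [0, 1]. A 10-bin histogram filter keeps the modal bin's mean,
   and a 0.64 mm x 0.70 mm x 30-frame median filter reduces the per-frame
   tensor to the final concentration map.
4. **Evaluation.** Maps are scored against ground truth with the
   coefficient of determination about the 1:1 line
   (`R^2 = 1 - sum(C - k)^2 / sum(C - mean(C))^2`), Spearman's rank
   correlation `rho` (|rho| >= 0.8 marks a strong monotonic trend), and the
   mean absolute error in % concentration.

## Worked example

```r
library(paatlas)

# a small two-wavelength phantom study: 6-mm mixture chamber imaged by a
# 32-element array, 5 MB fractions, 2 trials each, 3 frames per wavelength
geom <- acquisition_geometry(n_elements = 32, pitch = 0.3, fs = 8, fc = 4)
study <- generate_study(
  concentrations = c(0, 0.25, 0.5, 0.75, 1), n_trials = 2,
  scene_args = list(chamber_center = c(12, 0), chamber_diameter = 6,
                    n_sources = 12, depth_mm = 16),
  geom = geom, n_frames_per_wavelength = 3, seed = 7)

# train the atlas on one pure trial per class, estimate the rest
atlas <- build_atlas(study[["c100_t1"]], study[["c000_t1"]], pa_config())
atlas
#> <pa_atlas> 153 MB rows, 123 Hb rows, p = 1, class separation 160

test_ids <- setdiff(names(study), c("c100_t1", "c000_t1"))
maps <- lapply(test_ids, function(id)
  estimate_map(study[[id]], atlas, seed = 11))
maps[[which(test_ids == "c050_t1")]]
#> <pa_concmap> 229 x 32 px, 79 estimated, mean 56.0% MB (truth 50%)

evaluation_report(maps)
#> <pa_report> R^2 = 0.847, rho = 0.900, overall MAE = 8.13% (463 pixels)
#>   per-label MAE (%):
#>    0%   25%   50%   75%  100%
#>  4.95 20.36  9.48  3.92  1.92
```

The atlas print shows how many projected pure-class feature samples anchor
the regression and their separation along the first principal component.
Each concentration map reports the mean estimated MB fraction over the
masked pixels next to the trial's ground truth; the report pools all maps —
here the estimates track the true series monotonically (`rho = 0.9`) with an
8% mean absolute concentration error.

`run_pipeline(run_config(...), out_dir)` wraps the same flow end to end and
writes maps (CSV), `report.json`, and a `manifest.json` whose configuration
hash makes reruns bit-reproducible. A thin command-line wrapper lives at
`inst/cli/paatlas.R` (subcommands `simulate`, `run`, `validate`,
`estimate`), and `write_frameset()`/`read_frameset()` persist channel data
as self-describing HDF5.

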