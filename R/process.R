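# Internal per-frameset processing shared by atlas construction, map
# estimation, and the parameter/threshold sweeps. The expensive,
# threshold-independent stages (coherence beamforming and DAS + IQ
# demodulation of every frame pair) are computed once per set and cached so
# that sweeps over mask thresholds or compression settings reuse them.

# beamform + demodulate a frameset once; returns coherence images per frame
# and IQ images per wavelength-paired frame
prepare_set <- function(fs, cfg) {
  geom <- fs$geometry
  pf <- paired_frames(fs)
  coh <- lapply(c(pf$f710, pf$f870), function(f)
    mweighted_slsc_image(f, geom, M = cfg$M, corr_kernel = cfg$corr_kernel,
                         clip_negative = cfg$clip_negative))
  iq <- lapply(seq_len(pf$n), function(i) {
    list(iq710 = iq_demodulate(das_rf(pf$f710[[i]], geom), geom$fs,
                               cfg$f_mod, cfg$bandwidth),
         iq870 = iq_demodulate(das_rf(pf$f870[[i]], geom), geom$fs,
                               cfg$f_mod, cfg$bandwidth))
  })
  list(coh = coh, iq = iq, n_pairs = pf$n, geometry = geom,
       ground_truth = fs$ground_truth,
       img_dim = dim(coh[[1]]$pixels))
}

# per-trial mask: per-frame thresholding merged by logical OR
trial_mask <- function(prep, cfg, mask_threshold = cfg$mask_threshold,
                       mask_mode = cfg$mask_mode) {
  merge_masks(lapply(prep$coh, make_mask, mode = mask_mode,
                     value = mask_threshold))
}

# stacked, compressed dual-wavelength spectra for every masked pixel of
# every frame pair; rows carry pixel indices and frame-pair ids
set_spectra <- function(prep, cfg, mask) {
  dz <- prep$geometry$axial_spacing
  rows <- vector("list", prep$n_pairs)
  pix <- vector("list", prep$n_pairs)
  frm <- vector("list", prep$n_pairs)
  for (i in seq_len(prep$n_pairs)) {
    s710 <- kernel_spectra(prep$iq[[i]]$iq710, mask, cfg$kernel_mm, dz,
                           stride = cfg$stride, n_bins = cfg$n_bins_fft)
    s870 <- kernel_spectra(prep$iq[[i]]$iq870, mask, cfg$kernel_mm, dz,
                           stride = cfg$stride, n_bins = cfg$n_bins_fft)
    if (nrow(s710) == 0L) next
    st <- stack_and_compress(s710, s870, cfg$dynamic_range,
                             per_block = cfg$per_block)
    rows[[i]] <- unclass_matrix(st)
    pix[[i]] <- attr(st, "pixel_index")
    frm[[i]] <- rep.int(i, nrow(rows[[i]]))
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep))
    return(list(rows = matrix(numeric(0), 0L, 2L * cfg$n_bins_fft),
                pixel_index = matrix(integer(0), 0L, 2L),
                frame = integer(0)))
  list(rows = do.call(rbind, rows[keep]),
       pixel_index = do.call(rbind, pix[keep]),
       frame = unlist(frm[keep]))
}
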