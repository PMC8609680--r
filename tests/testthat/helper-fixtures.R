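# Small fixtures built in code.

# Compact phantom: LC/PT on slices 1-3 (pons), SN/CP on slice 4 (midbrain).
small_truth <- function(noise_sd = 10, ...) {
  phantom_truth(shape = c(64L, 64L, 4L), lc_slices = 1:3, sn_slice = 4L,
                noise_sd = noise_sd, ...)
}

# Node x time matrix of sinusoids at the given frequencies (Hz).
sinusoid_ts <- function(freqs, Tn = 195, tr = 2, phases = 0) {
  t <- (0:(Tn - 1)) * tr
  phases <- rep_len(phases, length(freqs))
  vals <- t(mapply(function(f, p) cos(2 * pi * f * t + p), freqs, phases))
  ts_matrix(matrix(vals, nrow = length(freqs)), tr)
}

# Mean CNR_LC estimate from one noisy phantom, truth ROIs.
phantom_cnr_estimate <- function(truth, seed) {
  ph <- gen_nm_phantom(truth, seed = seed)
  lc <- ph$rois[ph$rois$structure == "LC", ]
  pt <- ph$rois[ph$rois$structure == "PT", ]
  vals <- vapply(seq_len(nrow(lc)), function(k) {
    st <- roi_stats(ph$volume, lc[k, ])
    pts <- roi_stats(ph$volume, pt[pt$slice == lc$slice[k], ])
    cnr(st$mean_si, pts$mean_si, pts$sd_si)
  }, numeric(1))
  mean(vals)
}

# Search boxes around the default LC positions of a 64 x 64 phantom.
lc_search_boxes <- function() {
  list(left = c(14, 32, 13, 32), right = c(33, 51, 13, 32))
}
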