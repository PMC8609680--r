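#!/usr/bin/env Rscript
# Generate the three synthetic input kinds with known ground truth:
# a neuromelanin phantom volume (NIfTI + ROI sidecar), parcellated
# somatomotor BOLD matrices (TSV) for an OFF/ON pair of coupling levels,
# and a 57-subject cohort table (CSV).

suppressPackageStartupMessages(library(lcsync))
seed <- 1L
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)

truth <- phantom_truth(noise_sd = 10)  # SI_LC 120, SI_PT 100 -> CNR 2.0
ph <- gen_nm_phantom(truth, seed = seed)
write_volume_nifti(ph$volume, "results/inputs/phantom.nii.gz")
write_rois_csv(ph$rois, "results/inputs/phantom_rois.csv")
cat(sprintf("phantom: %s voxels, planted CNR_LC = %.2f, CNR_SN = %.2f\n",
            paste(dim(ph$volume$intensities), collapse = "x"),
            truth$true_cnr[["LC"]], truth$true_cnr[["SN"]]))

# OFF state: weak coupling; ON state: stronger coupling (levodopa raises
# somatomotor synchronization).
couplings <- c(off = 0.08, on = 0.15)
for (nm in names(couplings)) {
  # same seed for both states: the same subject observed OFF and ON
  b <- gen_oscillator_bold(oscillator_params(coupling = couplings[[nm]],
                                             obs_noise_sd = 0.1,
                                             seed = seed + 10L))
  write_ts_tsv(b, sprintf("results/inputs/bold_%s.tsv", nm))
  cat(sprintf("bold_%s: %d nodes x %d volumes (K = %.2f)\n",
              nm, nrow(b$values), ncol(b$values), couplings[[nm]]))
}

co <- gen_cohort(cohort_params(n_subjects = 57L, target_r = 0.42,
                               target_r_sync = -0.32, seed = seed + 20L))
write_cohort_csv(co, "results/inputs/cohort.csv")
cat(sprintf("cohort: %d subjects, planted partial r(CNR_LC, UPDRS rate) = 0.42\n",
            nrow(co)))
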