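# lcsync

Locus coeruleus (LC) degeneration and levodopa responsiveness in
Parkinson's disease, linked through neuromelanin-sensitive MRI (NM-MRI)
contrast and somatomotor-network phase synchronization.

The package is written for neuroimaging researchers who want a tested,
fully synthetic-data-validated implementation of this analysis chain:

- **NM-MRI quantification** — contrast-to-noise ratios with the circular-ROI
  protocol: `CNR_LC = (SI_LC − SI_PT) / SD_PT` against the pontine tegmentum
  and `CNR_SN = (SI_SN − SI_CP) / SD_CP` against the cerebral peduncle, with
  automated LC localization by maximal mean intensity, the
  slices × sides × sessions averaging scheme, and ICC(2,1) intra-rater
  reliability.
- **BOLD conditioning** — drop 10 initial volumes, linear detrend,
  tissue + Friston-24 confound regression, ideal 0.04–0.07 Hz band-pass, and
  the Jenkinson framewise-displacement (> 0.2 mm) exclusion rule.
- **Phase synchronization** — Hilbert-transform instantaneous phases
  θ_j(t), 10-point border trimming (L = 175 at the reference configuration of
  205 volumes, TR = 2 s, 33 somatomotor nodes), the Kuramoto order parameter
  r(t) = |Σ_j e^{iθ_j(t)}| / n, and its temporal mean ⟨r(t)⟩.
- **Response metrics and inference** — rates of change
  (OFF − ON) / OFF for UPDRS-III and synchronization, the ranked-rate
  response/resistance split (57 → 29/28), covariate-adjusted partial
  correlations (age, medication duration, LEDD), pooled t and chi-squared
  group comparisons, and p-value-driven stepwise multiple regression.
- **Synthetic generators** — NM-MRI phantoms with planted contrast, coupled
  phase-oscillator BOLD with controllable synchrony, and cohort tables with
  planted partial correlations, so every stage is testable against known
  ground truth without any patient data.

## Worked example

```r
library(lcsync)

## 1. A neuromelanin phantom with planted CNR = 2.0 and its quantification
truth   <- phantom_truth(noise_sd = 10)     # SI_LC 120, SI_PT 100, noise 10
phantom <- gen_nm_phantom(truth, seed = 1)
lc <- phantom$rois[phantom$rois$structure == "LC", ]
pt <- phantom$rois[phantom$rois$structure == "PT", ]
lc_stats <- do.call(rbind, lapply(seq_len(nrow(lc)), function(k) {
  s <- roi_stats(phantom$volume, lc[k, ])
  data.frame(session = 1, side = lc$side[k], slice = lc$slice[k],
             mean_si = s$mean_si)
}))
pt_stats <- do.call(rbind, lapply(seq_len(nrow(pt)), function(k) {
  s <- roi_stats(phantom$volume, pt[k, ])
  data.frame(session = 1, slice = pt$slice[k], mean_si = s$mean_si,
             sd_si = s$sd_si)
}))
aggregate_cnr_lc(lc_stats, pt_stats)
#> <cnr_result> 6 measurements, aggregate CNR = 2.1275

## 2. Synchronization of one simulated subject, OFF vs ON
bold_off <- gen_oscillator_bold(oscillator_params(coupling = 0.08, seed = 11))
bold_on  <- gen_oscillator_bold(oscillator_params(coupling = 0.15, seed = 11))
somatomotor_sync(preprocess_bold(bold_off, drop = 10)$ts)
#> <sync_result> n = 33 nodes, L = 175, <r(t)> = 0.3311
somatomotor_sync(preprocess_bold(bold_on, drop = 10)$ts)
#> <sync_result> n = 33 nodes, L = 175, <r(t)> = 0.9395

## 3. A 57-subject cohort with a planted partial correlation of 0.42
cohort <- gen_cohort(cohort_params(n_subjects = 57, target_r = 0.42, seed = 21))
report <- run_cohort_analysis(cohort)
report$correlations[5, ]
#>        x          y            covariates       r        p df
#>   cnr_lc rate_updrs age+duration_med+ledd 0.55858 1.14e-05 52
report$stepwise
#> <stepwise_result> selected: cnr_lc (beta = 0.545, p = 3.12e-06),
#>   duration_med (beta = -0.274, p = 0.0114)
```

Reading the output: the single-phantom aggregate CNR (2.13) scatters around
the planted 2.0 — the Monte-Carlo mean over many phantoms is what converges.
Synchronization rises after the (simulated) levodopa challenge, so the
synchronization rate of change is negative for responders. In the cohort,
the covariate-adjusted correlation between CNR_LC and the UPDRS-III rate of
change (planted 0.42, here estimated 0.56 on one 57-subject draw) is carried
by CNR_LC and not CNR_SN in the stepwise model — the pattern the chain is
designed to detect.

## Analysis workflow

`analysis/` contains numbered drivers that run the full chain on synthetic
inputs and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_inputs.R      # phantom + BOLD TSVs + cohort CSV
Rscript analysis/02_cnr_quantification.R   # LC localization, CNRs, ICC
Rscript analysis/03_preprocess_bold.R      # conditioning chain + FD log
Rscript analysis/04_phase_synchronization.R# OFF/ON sync + coupling sweep
Rscript analysis/05_statistics.R           # group split, correlations, stepwise
```

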