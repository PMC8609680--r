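---
title: "From neuromelanin contrast to levodopa response: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From neuromelanin contrast to levodopa response: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

The locus coeruleus (LC), the brain's main noradrenergic nucleus, degenerates
in Parkinson's disease alongside the dopaminergic substantia nigra (SN).
Because noradrenergic input modulates dopaminergic transmission, LC integrity
is a candidate determinant of how well a patient responds to levodopa.
`lcsync` implements a complete computational chain for testing that link:

1. **Imaging**: quantify LC and SN integrity from neuromelanin-sensitive MRI
   (NM-MRI) as contrast-to-noise ratios (CNR) with a circular-ROI protocol.
2. **Function**: measure somatomotor-network synchronization from parcellated
   resting-state BOLD via Hilbert instantaneous phases and the Kuramoto order
   parameter, before (OFF) and after (ON) a levodopa challenge.
3. **Response**: summarize the challenge as rates of change of the UPDRS-III
   motor score and of synchronization, split the cohort into response and
   resistance groups, and relate CNR to responsiveness with covariate-adjusted
   partial correlations and stepwise multiple regression.

Patient data of this kind are not publicly deposited, so the package ships
synthetic generators with known ground truth for all three input kinds. Every
pipeline stage is validated against that truth.

# Imaging: CNR quantification

On NM-MRI, neuromelanin-rich nuclei are hyperintense. LC integrity is
quantified per side and slice as

$$\mathrm{CNR}_{LC} = \frac{SI_{LC} - SI_{PT}}{SD_{PT}},$$

with the pontine tegmentum (PT) as reference, and SN integrity as

$$\mathrm{CNR}_{SN} = \frac{SI_{SN} - SI_{CP}}{SD_{CP}},$$

with the cerebral peduncle (CP) as reference. ROI areas follow the protocol:
2 mm² (LC), 20 mm² (PT), 10 mm² (each SN subregion: lateral, central,
medial), 30 mm² (CP). `aggregate_cnr_lc()` averages over 3 contiguous
slices × 2 sides × assessment sessions; `aggregate_cnr_sn()` averages the six
divisions (bilateral subregions, unconditionally pooled across sides).

`locate_lc()` automates the protocol's placement rule — the 2 mm² disc with
the highest mean intensity within each side's search region on each of three
contiguous slices — by exhaustive scan over pixel-centre placements.

Numerical choices:

- **Pixel membership**: a pixel belongs to an ROI iff its centre lies
  *strictly* inside the disc of radius $\sqrt{A/\pi}$ (computed in mm, so ROI
  areas are resolution independent; at the emulated 220 mm FOV / 512 matrix,
  2 mm² ≈ 11–12 pixels). Strict membership makes the brute-force test oracle
  trivial.
- **SD** uses the $n-1$ denominator, so CNR values are bit-reproducible.
- **Ties** in the exhaustive search are broken by the lexicographically
  smallest (row, column) centre — flat regions give a deterministic answer.
- **Reliability**: `icc_intra_rater()` is the two-way, absolute-agreement,
  single-measure ICC(2,1) computed from ANOVA mean squares. The one-way and
  consistency variants were considered; absolute agreement is the
  conservative choice when the two assessments should be interchangeable, and
  the form is documented so results are interpretable.

# Function: preprocessing and phase synchronization

Inputs are node × time matrices (33 somatomotor nodes, 205 volumes at
TR = 2 s in the reference configuration); spatial preprocessing
(realignment, normalization, smoothing) is assumed done upstream. The
conditioning chain is fixed in this order:

1. `drop_initial_volumes()` — first 10 volumes (205 → 195);
2. `detrend_ts()` — per-node least-squares linear detrend;
3. `regress_confounds()` — projection onto the orthogonal complement of
   tissue regressors plus the Friston-24 motion expansion (6 parameters,
   one-volume lags, and both sets squared);
4. `bandpass_ts()` — ideal rectangular DFT filter, 0.04–0.07 Hz.

The filter zeroes every Fourier component outside the band (including DC),
is zero-phase and idempotent, and has no order/ripple parameters — the
convention of the resting-state toolchains this emulates. An IIR design
would introduce unstated roll-off choices.

Motion exclusion uses the Jenkinson framewise displacement: for the relative
rigid transform between successive volumes with rotation residual
$A = R - I$ and translation $b$,

$$FD = \sqrt{\tfrac{1}{5} r^2 \operatorname{tr}(A^\top A) + b^\top b},$$

the RMS displacement over a solid sphere of radius $r = 80$ mm (the standard
radius). Subjects whose **mean** FD exceeds 0.2 mm are excluded; the summary
is configurable to the maximum, since subject-level exclusion rules are
stated ambiguously in much of the literature. A value exactly at the
threshold is kept (strict inequality).

Synchronization is then computed by `somatomotor_sync()`:

- `instantaneous_phase()` forms the analytic signal $s + i\,H[s]$ with the
  discrete Hilbert transform (one-sided DFT spectrum; half-weight Nyquist
  bin for even lengths) and takes the **four-quadrant** angle. The
  two-quadrant $\arctan(H[s]/s)$ form loses the sign of $s$ and cannot give
  a continuous phase; the four-quadrant angle is the standard intent of that
  notation. Phases are wrapped to $(-\pi, \pi]$; unwrapping happens only in
  tests.
- `trim_borders()` removes 10 points per side (195 → L = 175) to suppress
  the transform's edge effects.
- `order_parameter()` computes $r(t) = \frac{1}{n}\left|\sum_j
  e^{i\theta_j(t)}\right| \in [0, 1]$ and `mean_sync()` its temporal mean
  $\langle r(t) \rangle$, the scalar synchronization summary.

Useful exact identities tested against: $r = 1$ for identical phases, $r = 0$
for balanced antiphase sets, $r = 1/3$ for phases $\{0, 0, \pi\}$, and
$E[r^2] = 1/n$ for independent uniform phases.

# Response metrics and inference

Levodopa responsiveness is summarized by rates of change,
$(X_{OFF} - X_{ON})/X_{OFF}$, for the UPDRS-III score and for
synchronization. Synchronization typically *rises* ON, so its rate is
negative in responders — the source of the negative correlations between LC
contrast and the synchronization rate. `split_by_response()` ranks subjects
by UPDRS rate (descending) and labels the top $\lceil n/2 \rceil$ as the
response group: with odd cohorts the extra subject goes to the response side
(57 → 29/28), and ties keep stable input order. Rates are not clipped; a
worsening subject sorts into resistance naturally.

`partial_correlation()` residualizes both variables on an intercept plus
covariates and correlates the residuals — the construction whose residuals
are the quantities shown in adjusted-correlation scatter plots; the
precision-matrix route gives the same $r$ but not the plotted residuals.
The p value is two-sided from $t = r\sqrt{df/(1-r^2)}$, $df = n - 2 -
p_{cov}$.

`stepwise_regression()` follows the classic p-value-driven convention
(forward selection by smallest partial-F p value with entry at
$p \le 0.05$, backward elimination at $p > 0.10$), because the statistics
packages that popularized stepwise selection use those defaults and the
procedure is otherwise underdetermined; both thresholds are arguments.
Standardized betas are reported (predictors and response scaled to unit
variance). A cycle guard caps iterations at twice the candidate count.
Setting both thresholds to 1 retains every candidate and reproduces ordinary
least squares — a useful degenerate check. No multiple-testing correction is
applied; the report instead records the number of tests run.

`run_cohort_analysis()` composes all of this into one report: group
comparison table (pooled t tests; chi-squared for sex), the
covariate-adjusted correlation set (CNR vs OFF/ON UPDRS-III with age as
covariate; CNR and the rates of change against each other with age,
medication duration and LEDD as covariates), and the stepwise regression of
the UPDRS rate on CNR_LC, CNR_SN, age, duration and LEDD.

# The synthetic generators

**Phantoms** (`phantom_truth()`, `gen_nm_phantom()`) plant discs of known
intensity on a uniform background with i.i.d. Gaussian noise, emulating the
NM-MRI geometry (0.4297 mm in-plane pixels — 220 mm FOV at a 512 matrix —
and 3 mm slices): bright LC discs beside a PT reference on three pons
slices, SN subregion discs with a CP reference on a separate midbrain slice.
The planted CNR is exactly $(SI_{target} - SI_{ref})/\sigma_{noise}$, so
recovery is checkable without tolerance guesswork. Default planted values
$SI_{LC} = 120$, $SI_{PT} = 100$, $\sigma = 10$ put the planted CNR at 2.0,
the order of magnitude of healthy-control LC contrast. Overlapping disc
specifications are rejected at construction.

**BOLD** (`gen_oscillator_bold()`) integrates the mean-field coupled
phase-oscillator system
$\dot\theta_j = \omega_j + (K/n)\sum_k \sin(\theta_k - \theta_j)$
and observes $\sin\theta_j(t)$ plus Gaussian noise. This model was chosen
because its order parameter *is* the statistic the pipeline estimates, so
planted synchrony is exactly known in the limit; observing $\sin\theta$
rather than the phases forces the pipeline's own Hilbert step to be
exercised end to end. Natural frequencies default to uniform draws in
[0.04, 0.07] Hz, making the band-pass transparent to the signal and
isolating synchrony estimation from filter distortion. Integration is a
fixed-step explicit Euler scheme at `sampling_interval / 20` substeps —
simple, reproducible, and accurate at these frequencies (with $K = 0$ it is
exact). With the default frequency spread the synchronization transition
sits near $K \approx 0.1$; the coupling sweep in the analysis scripts
straddles it.

**Cohorts** (`gen_cohort()`) draw age, medication duration and LEDD, then
build CNR_LC and the two rates of change from shared latent Gaussian
factors, so the *partial* correlation (after removing the covariates) is
planted exactly in the population: `target_r` (default 0.42) between CNR_LC
and the UPDRS rate, `target_r_sync` (default −0.32) for the
synchronization rate. The defaults mirror effect sizes typical of this
literature. UPDRS-III ON is derived from OFF and the planted rate so the
rate reproduces exactly; infeasible draws (a rate reaching 1, an ON-state
synchronization outside [0, 1]) abort with an error rather than being
silently clipped, which would distort the planted correlation structure.
Inter-subject variability of synchronization is not constrained by
published values; the chosen spread (OFF synchronization ≈ 0.32 ± 0.04) is
a free, fixed choice. All generators take one explicit seed per call and
restore the caller's RNG state.

What the generators do **not** emulate: scanner physics, k-space artifacts,
motion-corrupted voxel data (motion enters only through parameter traces),
spatial preprocessing, haemodynamic convolution, non-sinusoidal BOLD
waveforms, and any non-Gaussian intensity structure in NM-MRI. Passing
recovery tests therefore demonstrates the correctness of the computational
chain under its stated model, not the clinical validity of the measurements
on real data.

# Problem sizes and determinism in the test suite

The validation suite exercises the study configuration (33 nodes,
205 volumes, drop 10, trim 10, L = 175) directly. Monte-Carlo sizes were
chosen so sampling error is far below the tested tolerances while the suite
stays quick: 1000 phantoms for CNR recovery (mean error below 2%),
100 phantoms for LC localization, 50 seeds per coupling value for
monotonicity of $\langle r(t)\rangle$ over $K \in \{0, 0.5, 1, 2, 4\}$,
$10^5$ draws for the $E[r^2] = 1/n$ null calibration, 1000 replicate
cohorts for partial-correlation recovery (mean within ±0.02 of 0.42), and
1000 replicates for the stepwise null-entry calibration against
$1 - (1 - p_{enter})^5$. Independent oracles (explicit-DFT analytic signal,
brute-force pixel enumeration, solid-sphere Monte-Carlo FD, `aov()`-based
ICC mean squares) are implemented separately from the code they check.

# Known limitations

- ROI placement operates on integer pixel-centre grids; sub-pixel placement
  (and hence partial-volume weighting) is not modelled.
- The ideal filter assumes the series is effectively periodic over the
  record; leakage from non-bin frequencies is the usual DFT behaviour.
- The ICC model is fixed to two sessions (intra-rater, duplicate
  assessment); multi-rater designs are out of scope.
- Stepwise selection inherits the known inferential caveats of any
  data-driven model search; reported p values are conditional on selection.
- The FD computation assumes rotation about the coordinate origin; a
  different rotation centre shifts translations in the usual way.
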