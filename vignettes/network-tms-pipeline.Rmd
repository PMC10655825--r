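---
title: "Network-specific TMS effects: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-specific TMS effects: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netstim)
```

# The analysis

netstim implements an analysis of how high-frequency repetitive TMS applied
to two nearby but functionally opposed dorsolateral prefrontal (dlPFC)
targets changes (i) local glucose metabolism, measured with FDG-PET, and
(ii) distributed functional connectivity (FC), measured with resting-state
BOLD fMRI — and how those two kinds of change relate across subjects. The
two targets are chosen per subject so that one is maximally positively and
one maximally negatively coupled to a subgenual anterior cingulate (sgACC)
seed-FC map; in practice this places one target in the default network (DN)
and one in the salience network (SAL), two networks that are anti-correlated
at rest.

The pipeline stages are:

1. **QC** — slice-based temporal SNR and frame-to-frame motion; a run is
   excluded when its tSNR falls more than two group standard deviations
   below the group mean, or when more than five relative movements exceed
   0.5 mm ("more than five" is strict: exactly five is retained). Because
   the tSNR threshold is relative, a small fraction of runs is always
   flagged; the pipeline drops flagged runs and excludes a subject only
   when an entire session becomes unusable.
2. **Denoising** — simultaneous regression of an intercept, the mean
   whole-brain signal, six rigid-body motion parameters, mean white-matter
   and ventricular signals, and the temporal derivatives of all nine
   (19 design columns), followed by zero-phase low-pass filtering below
   0.08 Hz.
3. **Targeting** — an sgACC-region seed map is computed from the baseline
   session, zeroed inside the dlPFC, and used as a map-weighted seed; the
   Fisher z correlation between that seed series and the mean series of
   every node of a 4-mm lattice of 4-mm-diameter nodes over the dlPFC is
   the targeting statistic. The most positive node is the DN target, the
   most negative the SAL target (ties break to the lowest node id).
4. **FC** — Fisher z seed maps (`z = atanh(r)`, clipped at
   `|r| = 1 - 1e-7`), 51-region pair-wise z matrices grouped by the seven
   networks (runs concatenated after per-run standardisation), and
   whole-network ROI pair z values.
5. **PET** — whole-brain intensity normalisation (WBn-suv: division by the
   arithmetic mean over the brain mask, so the mask mean is exactly 1) and
   per-subject ΔWBn-suv tables per target, region and network, with a 10 mm
   exclusion sphere around the stimulated target for network-level rows.
6. **Group statistics** — paired t tests with paired Cohen's
   `d = mean / sd` (so `t = d * sqrt(n)`), entry-wise matrix comparisons,
   and family-wise correction of unit-wise maps by a sign-flipping
   permutation null of the maximum |t|
   (`p = (1 + #{max|t|_perm >= |t|}) / (B + 1)`).
7. **Coupling** — across-subject Pearson correlation (`r`, `R^2 = r^2`,
   two-sided p with n − 2 df) between target ΔWBn-suv and the DN × SAL
   block mean Δz, plus the divergent-subgroup contrast of the five subjects
   with the smallest versus largest metabolic change.

# The synthetic cohort

Real data for this design are multi-session PET-MR acquisitions; the
package instead ships a generator whose defaults *are* the study
conditions, so every stage can be validated against known ground truth.

**Signal model.** Seven latent network series are drawn i.i.d. across
frames from a multivariate normal whose only off-diagonal entry is the
DN–SAL correlation (−0.4 at baseline). Every unit (voxel or parcel) is

```
unit(t) = 100 + loading * latent_network(t) + global(t) + noise(t)
```

with region loading 1, a unit-variance coherent global component shared by
all tissue (the component that global-signal regression is designed to
remove), and white unit noise with s.d. 0.5, giving voxel tSNR near 70. An
sgACC region in the limbic network co-loads on the DN latent (+0.8) and on
the SAL latent (−0.6): the sgACC's positive coupling to the default network
and anti-correlation with the salience network are the premise of the
targeting method, and the balanced co-loading makes the seed map equally
sensitive to both targets. The dlPFC consists of two
blocks (one DN, one SAL region); all their units are unloaded except each
subject's ground-truth target nodes, which load 0.35 (DN) / 0.32 (SAL) on
their network latent.

**Sessions.** Each subject has a baseline visit (three 120-frame BOLD runs
at TR 3 s, plus an SUV map) and two experimental visits (pre-TMS and
post-TMS BOLD sessions plus a post-TMS SUV map) under SAL-TMS and DN-TMS,
with deterministic counter-balancing (odd subjects SAL first). Post-TMS
sessions shift the DN–SAL latent correlation by a subject-specific amount
(mean +0.15 for DN-TMS, i.e. −0.4 → −0.25; +0.05 for SAL-TMS; s.d. 0.10).

**Metabolism.** SUV profiles are built in WBn space: stimulated-target
units receive the subject's injected ΔWBn-suv (mean +0.054 at the SAL
target under SAL-TMS, −0.06 at the DN target under DN-TMS; between-subject
s.d. 0.06) with a diffuse compensatory decrease elsewhere so the
whole-brain mean stays exactly 1 — which is what whole-brain normalisation
implies for a focal change. Unit-level session noise has s.d. 0.02.

**Coupling.** A shared standard-normal subject factor `g` enters both the
metabolic delta and the FC shift. The generator solves the factor weights
in closed form so that the correlation between the *measured* quantities —
target ΔWBn-suv and DN × SAL block Δz after the full denoising and
matrix pipeline — equals `coupling_rho` (default 0.7). `coupling_design()`
assembles this from three pieces:

* the population FC algebra: the post-regression correlation of any pair of
  aggregates is computed exactly from the loadings, unit counts and the
  projection onto the whole-brain/white-matter/ventricle mean series
  (motion columns and all temporal-derivative columns have no
  population-level effect on these aggregates);
* the Fisher z estimation variance of filtered series: a Bartlett sum over
  the autocorrelation of the zero-phase Butterworth filter, inflated by
  `n / (n - 19)` for the regression degrees of freedom (verified against
  Monte Carlo);
* a fixed-seed null calibration of the block-mean z estimation noise, run
  once per parameter set through the actual measurement chain and cached.

Measurement reliability bounds the attainable measured coupling: with
3 × 120 frames the bound is roughly 0.6, so at the default acquisition the
solver caps the factor weight at 1 and records the attainable value in
`design$realized_rho`. The coupling-recovery validation therefore uses a
high-reliability acquisition (3 × 1000 frames), where the designed 0.7 is
attainable and identifiable at n = 200; this is a property of the
validation experiment, fixed by the closed-form design, not a tuned
quantity.

# Numerical and design choices

* **Protocol arithmetic.** One inter-train interval is counted after every
  train including the last: 45 trains of 40 pulses at 20 Hz with a 28 s ITI
  give 1800 pulses in exactly 22.5 min, the published totals; no other
  convention reproduces them.
* **Filter realisation.** The 0.08 Hz low-pass is a 4th-order Butterworth
  applied forward and backward (zero phase) with odd-reflection padding;
  series are demeaned first and the mean restored, so DC is preserved
  exactly. A 0.2 Hz sinusoid at TR 1 s is attenuated below 10% amplitude; a
  0.01 Hz sinusoid is preserved within 5%.
* **tSNR definition.** In-vivo QC protocols often say only "slice-based"; here a
  run's tSNR is the mean over slices of (temporal mean / temporal s.d.) of
  the slice-mean series, with slices taken from the voxel z-planes (each
  parcel is its own slice in parcel space). Zero-variance slices contribute
  +Inf and are reported.
* **Composite relative motion.** No standard composite exists; implemented as
  the Euclidean norm of the six frame-to-frame differences with rotations
  converted to arc length on a 50 mm sphere.
* **Group averaging** of FC maps is done in z space; multi-run seed maps
  are averaged per session, while region matrices concatenate runs after
  per-run standardisation.
* **Smoothing.** A mask-normalised separable Gaussian (6 mm FWHM) is
  available for voxel-space maps. It is not applied before node-FC
  targeting: the node lattice spacing (4 mm) is comparable to the kernel,
  and the published targeting procedure does not specify smoothing at that
  step. Parcel space never smooths (region averaging already pools).
* **Exclusion zone.** The extent of the target exclusion for network-level
  PET rows is unreported; a 10 mm-radius sphere around the stimulated
  target is used and configurable.
* **Ties and determinism.** Target argmax/argmin ties break to the lowest
  node id; subgroup sorting breaks ties by subject id; every random draw
  derives from the spec seed through fixed integer streams, so cohorts are
  byte-identical across runs.
* **Family-wise correction.** In-vivo map thresholding in this field
  typically uses cluster-level FWE from large neuroimaging suites; here
  FWE is controlled by sign-flipping permutation
  max-T at unit level — self-contained, assumption-light, and calibrated:
  under pure-null Gaussian maps (n = 16, 50 parcels, 500 permutations) the
  empirical family-wise error is ≈ 0.05.
* **Two-sided, uncorrected ROI tables.** All p values are two-sided; ROI
  tables are reported uncorrected (the convention for ROI-level
  stimulation studies), with the
  permutation-corrected map available alongside.

# What passing tests do and do not show

The generator realises the *statistical structure* the analysis assumes:
anti-correlated latent networks with designed covariance shifts, seed-map
geometry (sgACC → DN co-loading, dlPFC target nodes), focal mean-preserving
metabolic offsets, and a shared factor coupling the two modalities. It does
not model haemodynamics, temporal autocorrelation of neural signals,
scanner drift, physiological rhythms with structure (the global component
is white), PET count statistics, partial-volume effects or spatial
registration error. Passing the suite therefore demonstrates that the
*pipeline* recovers what it is supposed to recover under its own
assumptions — not that those assumptions hold in vivo.

Two deliberate deviations from the in-vivo calibration values deserve
mention. First, the identity-confirmation statistic (target-sphere series
against whole-network ROI series) comes out near z ≈ 0.7–0.9 at the
generator defaults, higher than the in-vivo means (0.28 SAL / 0.34 DN):
with the per-run z standard error implied by 120 filtered frames, a target
whose network coupling were weak enough to reproduce z ≈ 0.3 could not be
re-identified from its own data with near-certainty, and deterministic
ground-truth recovery was prioritised. Second, the measured metabolic–FC
coupling at the default acquisition is attenuated below its designed value
by FC measurement noise (see above); the design object reports both.

# Problem sizes used in validation

The validation suite runs, among others: 20-subject voxel-space target
recovery at 3 × 120 frames; 200 replicates of the 16-subject metabolic
contrast; 100 replicates of the 16-subject DN × SAL block comparison; a
200-subject coupling cohort at 3 × 1000 frames; and 1000 permutation-null
simulations at 500 permutations each. These sizes give Monte-Carlo
standard errors comfortably inside the asserted margins while keeping the
whole suite in the minutes range on a single core.

# A small worked run

```{r, eval = FALSE}
spec <- cohort_spec(n_subjects = 6, space = "parcel", rng_seed = 7)
run <- run_pipeline(pipeline_config(spec, n_permutations = 500))
print(run)       # QC, target deltas, block delta-z, coupling, subgroups
```

The `netstim_run` object holds the per-stage products (`$qc`, `$targets`,
`$fc`, `$pet`, `$stats`, `$coupling`) alongside the generated ground truth,
and `write_report()` renders the summary tables. With an `out_dir` the
staged TSV/JSON products are written with a checksum manifest, and
re-running the identical configuration and seed reproduces identical
tables.
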