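---
title: "Models, phantoms and design choices in cingfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, phantoms and design choices in cingfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cingfp)
```

`cingfp` compares the connectional organization of the cingulate cortex
across species and modalities. This vignette documents the models the
package implements, the synthetic phantoms it validates them on, and the
design decisions taken where more than one defensible choice existed. It
states no empirical claim that the test suite does not itself compute.

## 1. The analysis pipeline

The cingulate seed strip is an elongated midline region; every analysis
orders positions along it by a normalized rostro-caudal coordinate
u ∈ [0, 1]. Internally all volumes are held with array axis 1 as the
rostro-caudal axis (anterior at index 1), so seed ordering always reads one
axis; `place_seeds()` ranks ROI voxels along that axis (ties broken by the
remaining axes in fixed order) and takes single-voxel seeds at the rank
quantiles (i − ½)/n. On a straight strip this reduces to arc length; on an
arbitrary ROI shape it stays well defined, which is why rank quantiles were
chosen over Euclidean arc length.

**Tracer arm.** `projection_similarity()` correlates, across a collection
of anterograde tracer experiments, the density sampled at each seed with
the density at every brain location. The resulting seeds × voxels matrix is
decomposed by `decompose()` into spatial independent components:

1. voxels with undefined correlations (constant density across experiments)
   are dropped from the support;
2. each voxel column is centred across seeds — the convention of spatial
   ICA in fMRI practice, where voxels are the samples and the seed
   dimension carries the mixtures;
3. PCA reduces the seed dimension to the requested order and whitens;
4. fixed-point iteration with the logcosh contrast and symmetric
   decorrelation unmixes (tolerance 1e-6 on the fixed-point residual,
   at most 500 iterations per start). Non-convergent starts — which occur
   when the requested order truncates into a nearly Gaussian residual
   subspace — are retried from fresh random rotations, deterministically
   given the seed; only when five starts all stall is a convergence error
   raised, carrying the iteration count;
5. each spatial map is z-scaled over voxels and sign-oriented so its
   skewness is positive (tie: the largest-magnitude voxel made positive);
   components are ordered by explained variance.

The centring orientation in step 2 matters more than it looks. Centring
each *seed row* over voxels instead forces, on any support composed of a
few labelled structures, the mass-weighted sum of the structures' seed
profiles to zero — an exact rank deficiency that makes a three-zone
organization unrecoverable in principle. Voxel-wise centring has no such
constraint.

Because symmetric decorrelation constrains the unmixing to a rotation, the
*raw* sources are exactly orthogonal, but the z-scaled maps the user sees
acquire small mutual correlations (−μᵢμⱼ/σᵢσⱼ); `decompose()` therefore
also returns `map_mean` and `map_sd` so the orthogonality property can be
verified on the reconstructed raw sources.

**Seed assignment.** Spatial maps are oriented positive by the skewness
convention, so a *positive* seed weight means the seed's connectivity
resembles the component map and a negative weight means it anti-resembles
it. `assign_seeds()` therefore assigns each seed to its largest *signed*
weight by default. An absolute-value variant (`signed = FALSE`) exists, but
it systematically misassigns seeds in the transition gaps between zones:
any component that is positive on one zone necessarily carries negative
lobes on the others (disjoint spatial patterns are negatively correlated),
and in a gap the magnitude of a remote component's negative lobe can exceed
the fading positive weight of the local one. With signed assignment the
seed partition is a contiguous segmentation along u on the phantom; with
absolute assignment it essentially never is.

**Fingerprints.** `tracer_fingerprint()` correlates each seed's whole-brain
similarity profile with each target's, over brain voxels *excluding* the
seed strip and all target labels. The exclusion avoids self-correlation
inflation and makes entries comparable across targets; it follows that
fingerprints need some non-target brain support with informative signal,
which on the phantom is supplied by the voxelwise density noise.
`subject_fc()`/`group_fingerprint()` build the fMRI analogue: mean ROI
timeseries, linear detrend, zero-phase 4th-order Butterworth band-pass
(applied forward–backward via `signal::filtfilt`), Pearson correlation per
subject, and arithmetic averaging of raw r across subjects with the
between-subject SEM. Raw-r averaging is the default deliberately — it
matches the way group fingerprints are conventionally reported — and a
Fisher-z option is available as a flag. Band defaults: 0.01–0.25 Hz for
mouse-style scans, 0.01–0.1 Hz for human-style scans, with the Nyquist
limit enforced against the repetition time.

**Quality control.** `specificity_filter()` scores each scan by
r_homotopic (sensory seed vs its contralateral twin) and r_specificity
(sensory vs default-mode seed) and passes scans with r_homotopic > 0.1 and
r_specificity < 0.1, both strict. The correlations are computed on
*detrended but unfiltered* mean series by default. This is a deliberate
choice: under the null (a non-specific scan), r on white series of length T
is approximately Normal(0, 1/√T), so at T = 900 the 0.1 threshold sits at
z ≈ 3 and the filter is highly specific. Narrow-band filtering before the
QC correlation inflates the null variance of r by the inverse bandwidth
fraction (sd ≈ 0.08 for a 0.01–0.1 Hz band at TR = 1 s), which turns the
same fixed threshold into a coin flip for bad scans. A `band` argument
exists for users who want QC on the analysis band, with this caveat
documented here.

**Inference.** `two_way_rm_anova()` implements the classical fully
within-subject decomposition: every effect is tested against its own
interaction-with-subject stratum, and the seed-by-target interaction has
df₁ = (a−1)(b−1), df₂ = (a−1)(b−1)(n−1). Sphericity of the interaction is
quantified by the Greenhouse–Geisser epsilon from the covariance of
orthonormal interaction contrast scores, and the Huynh–Feldt epsilon
ε_HF = (n(k−1)ε_GG − 2)/((k−1)(n−1−(k−1)ε_GG)) with k−1 = (a−1)(b−1),
capped at 1 and floored at ε_GG. Rather than deciding when adjustment is
"necessary", the implementation always reports both the unadjusted and the
Huynh–Feldt-adjusted p-value and flags ε_HF < 0.75, where the adjustment
materially matters. Subjects with any missing cell are dropped listwise
(classical RM-ANOVA needs complete within-subject tables), with a message.
Epsilons require n > (a−1)(b−1); below that they are reported as `NA` with
a warning and the unadjusted p stands. The implementation is validated in
the tests against `stats::aov` error strata (F, to 1e-8) and reproduces
`car`-style GG/HF epsilons; under the null its p-values are uniform.

**Cross-species comparison.** `align_fingerprints()` interpolates each
target's profile linearly onto m evenly spaced u values within the overlap
of the two seed ranges, pairing targets through a homolog map. No axis
warping is applied: the premise under test is positional correspondence of
the rostro-caudal gradient, and warping would beg that question.
`fingerprint_similarity()` reports per-target profile Pearson r plus
overall cosine and mean-absolute-difference scores; Pearson isolates
profile *shape*, cosine mixes shape and magnitude, Manhattan measures raw
disagreement, which is why all three are kept.

## 2. What the phantoms emulate

`build_phantom_atlas()` constructs a bilateral label atlas: one midline
seed strip spanning ≥ 80% of the rostro-caudal extent, nine named target
regions per hemisphere (hippocampus, amygdala, accumbens, hypothalamus,
caudoputamen, motor2, parietal, insula, orbitofrontal), a somatosensory
label in each hemisphere and a midline default-mode label for QC.

`simulate_tracer_experiments()` draws injection positions stratified along
the strip (evenly spaced with jitter, so small collections still cover it)
plus a configurable off-strip fraction, default conditions 0.25. Each
injection deposits a local bolus along the strip (amplitude 2, Gaussian
width 0.12 in u) and delivers density strength·exp(−(u−u_c)²/2w²) to the
targets of each zone containing them, on top of background 0.05 and
truncated Gaussian noise. The default rule set has three zones of width
0.15 centred at u = 0.15, 0.5, 0.85: anterior → amygdala, accumbens,
orbitofrontal (and insula in the mouse-analogue), mid → motor2,
caudoputamen, parietal (plus insula in the human-analogue), posterior →
hippocampus, hypothalamus. The off-strip fraction is not cosmetic: with
every injection landing in exactly one zone, the three zone response
profiles are collinear (their correlation profiles sum to ≈ 0) and the
third connectional dimension carries no variance; off-strip injections
break that degeneracy, exactly as the bulk of a real cortex-wide tracer
collection does.

`simulate_rsfmri_scans()` plants a block covariance: each network owns a
unit-variance white latent; a voxel records loading·signal_sd·latent plus
white noise. Left/right labels of one region share a latent (homotopic
coupling); the sensory and default-mode networks share a negated latent
(the anticorrelation axis); a `frac_bad` fraction of scans is pure noise
and flagged as generator truth. The strip couples position-dependently:
anterior third to the limbic latent, middle third to the motor latent,
posterior third to the hippocampal latent. Secondary targets load on their
network only partially (0.6 or 0.35) with the remaining variance in a
region-private latent. The private variance is essential for a
discriminating phantom: without it, ROI averaging removes target-side noise
and Pearson correlation cancels the loading, leaving same-network targets
statistically tied.

Latents are white (no autocorrelation) by design: Pearson r then has known
sampling behaviour (sd ≈ (1−r²)/√T), which every operating-characteristic
test in the suite relies on. The phantoms do not emulate hemodynamic
response shape, motion artefacts, physiological noise spectra, spatial
autocorrelation, or registration error. A pass on the phantom therefore
demonstrates the *estimators* recover planted structure at realistic SNR —
not that preprocessing of real scans is adequate, which is out of scope.

## 3. Study-condition defaults and problem sizes

Validation conditions used by the test suite, fixed once: tracer
collections of 60 experiments at noise 0.2 per unit strength on a
40 × 60 × 30 phantom with 20 parcellation seeds, ICA orders 4–9; fMRI
cohorts of 20 subjects × 500 timepoints (TR 1 s, signal = noise = 1) on a
24 × 30 × 16 phantom with 10 seeds for recovery, and 12 + 12 subjects at
300 timepoints for the cross-species comparison; QC cohorts of 100 scans ×
900 timepoints at signal 2, noise 1, 30% bad on a 16 × 18 × 12 phantom.
These sizes keep each validation within a few minutes while leaving wide
statistical margins (e.g. planted fingerprint contrasts of ≥ 4 standard
errors). The ANOVA null-calibration uses 2000 simulated 12 × 3 × 3
datasets.

## 4. Numerical choices and degenerate inputs

* Correlations with a zero-variance column are `NA`, never 0; fingerprint
  cells drop `NA`s pairwise and track a per-cell n.
* `NA` in TSV output is the literal token `NA`; fingerprint tables are
  written with 17 significant digits and round-trip to full precision.
* Integer volumes are written as int32 NIfTI and round-trip bit-exactly;
  floating volumes as float64.
* ICA ties in the sign convention (exactly zero skewness) orient by the
  largest-magnitude voxel; assignment ties break to the lower component
  index.
* QC marks a scan with a constant seed series as failed with reason
  `"degenerate"` rather than propagating `NA` comparisons.
* Seed rank quantiles are computed with an integer numerator
  (⌈(2i−1)N/2n⌉) to avoid floating-point ceiling slips at exact multiples.
* The interaction error mean square equal to zero (all subjects identical)
  is a hard error, not an infinite F.

## 5. Known limitations

The parcellation's component count has no automatic selection — order is a
user parameter swept over 4–9, and the matching table across consecutive
orders is the tool for judging stability. Fingerprint exclusion masks are
the caller's responsibility when not using the pipeline defaults. The
comparator assumes the homolog map; it quantifies similarity given assumed
homology and cannot establish homology itself. RM-ANOVA treats species
separately; no mixed-effects alternative is provided.
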