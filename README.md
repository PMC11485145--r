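# cingfp — cross-species cingulate connectivity fingerprints

`cingfp` is an R toolkit for comparing the connectional organization of the
cingulate cortex across species and measurement modalities. The scientific
question it serves: does the rostro-caudal belt of cingulate areas interact
with the rest of the brain according to the same principles in different
brains — anterior divisions with limbic structures (amygdala, nucleus
accumbens, orbitofrontal cortex), a mid-cingulate zone with motor and
striatal structures, and a posterior/retrosplenial zone with hippocampal
areas? The package is aimed at comparative and systems neuroscientists who
have (a) collections of anterograde-tracer projection-density volumes,
(b) resting-state BOLD fMRI scans, and (c) label atlases defining a
cingulate seed strip and a set of target regions.

## What it computes

**Projection-similarity parcellation.** For seeds placed at even
(rank-quantile) intervals along the seed strip, the tracer density *d(s, e)*
recorded at seed *s* is correlated across experiments *e* with the density
at every brain location *v*:

    S(s, v) = corr_e( d(s, e), d(v, e) )

Two locations are similar when the same injections project to both. The
seeds-by-voxels matrix *S* is then decomposed by spatial ICA (fixed-point
iteration, logcosh contrast, symmetric decorrelation) at several model
orders; each component is a spatial map of voxels with similar connectional
relationships to the strip, and each seed is assigned to the component it
expresses most strongly — a data-driven parcellation of the cingulate by its
projectome.

**Connectivity fingerprints.** For a small set of seeds along the strip and
a fixed panel of target regions, the fingerprint *F(s, t)* is the
connectivity of seed *s* with target *t*: for tracer data, the correlation
of whole-brain similarity profiles (self- and target-voxels excluded); for
rs-fMRI, the Pearson correlation of band-passed mean BOLD timeseries
(0.01–0.25 Hz for mouse-style scans, 0.01–0.1 Hz for human-style scans),
averaged over subjects with ± SEM.

**Scan-level QC.** Human-style scans are kept only when functional
connectivity is *specific*: strong homotopic interhemispheric sensory
correlation (r > 0.1) and absent-or-anticorrelated sensory–default-mode
coupling (r < 0.1).

**Inference.** A two-way fully within-subject repeated-measures ANOVA
(factors seed and target) tests the seed-by-target interaction — the
statistical statement that targets distinguish cingulate seeds — with
Greenhouse–Geisser and Huynh–Feldt sphericity corrections
(F(df₁·ε, df₂·ε), df₁ = (a−1)(b−1), df₂ = (a−1)(b−1)(n−1)).

**Cross-species comparison.** Two fingerprints with different seed counts
are aligned by linear interpolation onto a common normalized rostro-caudal
axis u ∈ [0, 1] over homologous target pairs, and compared per target
(profile Pearson r) and overall (cosine similarity, mean absolute
difference).

Because the real inputs are large external downloads, the package ships a
first-class synthetic-data module: phantom bilateral atlases with an
elongated seed strip, tracer collections whose projection targets depend on
injection position along the strip, and BOLD scans with planted network
covariance (homotopic sensory coupling, a sensory-vs-default-mode
anticorrelation axis, and a configurable fraction of non-specific scans).
Every stage of the pipeline is validated end to end against these planted
truths.

## Worked example

```r
library(cingfp)

atlas <- build_phantom_atlas(grid_shape = c(40, 60, 30), n_targets = 9)
atlas
#> <label_atlas> 40x60x30 voxels, 22 labels (1 seed_roi, 18 target)

rules <- default_tracer_rules("mouse", noise_sd = 0.2)
experiments <- simulate_tracer_experiments(atlas, rules, n_experiments = 60,
                                           rng_seed = 2, frac_off_strip = 0.25)

seeds <- place_seeds(atlas, n_seeds = 20)
strip <- atlas_labels(atlas, role = "seed_roi")
brain <- which(atlas$labels > 0 & !(atlas$labels %in% strip))
sim <- projection_similarity(
  sample_density(experiments, seeds),
  sample_density(experiments, brain_locations(atlas, brain)),
  seed_u = seeds$u)

sol <- decompose(sim, n_components = 6, rng_seed = 1)
sol
#> <component_solution> 6 components over 558 voxels, 20 seeds (68 iters)
#> seeds per component: 7 4 2 0 3 4
```

The leading components recover the planted anterior/mid/posterior zones and
partition the seeds into contiguous blocks along the strip. The rs-fMRI arm
produces a group fingerprint whose rows (seeds, anterior to posterior)
express the planted gradient — anterior seeds couple to amygdala and
accumbens, mid seeds to motor and striatal targets, posterior seeds to
hippocampus:

```r
fmri_atlas <- build_phantom_atlas(c(24, 30, 16))
model <- default_bold_model(fmri_atlas, "mouse")
fc <- cohort_fingerprint(fmri_atlas, model,
                         place_seeds(fmri_atlas, n_seeds = 10),
                         target_rois(fmri_atlas),
                         n_subjects = 12, n_timepoints = 250,
                         band = c(0.01, 0.25), rng_seed = 4,
                         species = "mouse")
print(fc$fingerprint, digits = 2)
#> <fingerprint> 10 seeds x 9 targets (mouse, rsfmri), n = 12-12
#>       hippocampus amygdala accumbens hypothalamus caudoputamen motor2 ...
#>  [1,]        0.01     0.69      0.46         0.00        -0.04   0.00
#>  [4,]       -0.02     0.00     -0.01        -0.02         0.50   0.71
#>  [9,]        0.71     0.00     -0.02         0.53        -0.01   0.01

arr <- array(unlist(fc$per_subject), c(10, 9, 12))
fit <- two_way_rm_anova(aperm(arr, c(3, 1, 2)))
fit
#> Two-way repeated-measures ANOVA (n = 12, 10 x 9 levels)
#> Interaction: F(72, 792) = 183.869, p = 0 (unadjusted)
```

The seed-by-target interaction (numerator df = 72 for 10 seeds × 9 targets)
confirms that the targets distinguish the seeds. `run_demo(demo_config(), out_dir)`
chains all stages — simulation, parcellation, both fingerprint modalities,
QC, ANOVA, cross-species comparison — and writes every table to TSV with a
run log; reruns with the same seeds are byte-identical.

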