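---
title: "Systems-level decoding of seed-cortical co-activations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systems-level decoding of seed-cortical co-activations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Coordinate-based reverse-inference decoding asks: given that studies
report activation in a brain region, which psychological terms do those
studies disproportionately concern? Decoding a single region, however,
cannot distinguish the functions of the region itself from the functions
of the distributed systems it participates in. `sysdecode` implements a
systems-level extension: each seed region is decoded *jointly* with every
cortical region it is functionally coupled to at rest, the coupled
region's own decoding is subtracted, and the surviving pair-specific
terms are aggregated into topic-wise cortical system maps that can be
compared against canonical intrinsic-network partitions.

The pipeline has seven stages:

1. **Seed definition.** Probabilistic (e.g. cytoarchitectonic) seed maps
   are resampled to the analysis grid (trilinear) and thresholded at a
   probability of 0.25, read strictly (`> 0.25`).
2. **Resting-state connectivity.** Per subject, the mean BOLD series over
   the seed voxels is correlated with every in-brain voxel and mapped
   through the Fisher transform `z = atanh(r)`; the subject maps enter a
   random-effects one-sample *t* test (df = N − 1).
3. **Thresholding.** The group map is thresholded to keep the voxel-level
   family-wise error below 5%. The default is Bonferroni over in-brain
   voxels — deterministic and, for voxelwise control, conservative; a
   max-statistic sign-flipping permutation test is available
   (`fwe_threshold(..., method = "permutation")`). The test is one-sided
   (positive coupling) by default because the downstream stages consume
   *functionally coupled* regions.
4. **Connected regions.** Cortical parcels whose voxels are covered by
   the suprathreshold map with fraction ≥ 0.8 are retained — the fraction
   is of the *parcel*, not of the map — and any parcel sharing a voxel
   with any seed is excluded.
5. **Bayesian decoding.** For a region of interest, a study in the
   coordinate database is *active* if one of its reported foci lies
   within 6 mm of a region voxel centre. For each term (binarized at a
   frequency of 0.001), the empirical likelihoods
   P(activation | term) and P(activation | ¬term) give the forward
   probability P(activation | term, p) = p·P(act|term) + (1−p)·P(act|¬term)
   and the posterior P(term | activation, p) = p·P(act|term) / P(act|term, p),
   with the prior fixed at p = 0.5 so that terms with very different base
   rates are comparable. A two-way chi-square (no continuity correction)
   tests activation-term independence and Benjamini–Hochberg FDR at 0.05
   flags significant terms. The 30 terms with the highest posterior are
   selected, non-significant ones dropped post hoc, and the list filtered
   to psychological constructs via an allowlist.
6. **Systems-level decoding.** For each (seed, connected parcel) pair the
   decoder runs twice: once on the joint activation (a study must
   activate seed *and* parcel — the co-activation reading; a union-mask
   variant is available) and once on the parcel alone. The set difference
   gives the terms *specific* to the pair, the conjunction the terms
   *shared* with the region's own profile. Specific terms populate the
   system map `(seed, term) → set of parcels`.
7. **Topics and networks.** Terms are aggregated by a hard term-to-topic
   mapping (consumed from file; when loadings are supplied the argmax
   with a 0.001 floor decides). Each (seed, topic) region set is
   rasterized to voxels and compared with a seven-network partition in
   both directions: the percentage of the topic map inside each network
   and the percentage of each network inside the topic map. Label-0
   voxels are reported as an explicit "unassigned" pseudo-network so the
   first direction always sums to 100.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `seed_threshold` | 0.25 | probability cutoff for seed cores (strict `>`) |
| `fwe_alpha`, `fwe_method` | 0.05, bonferroni | voxel-level FWE control |
| `min_overlap` | 0.8 | parcel coverage needed to count as connected (`>=`) |
| `radius_mm` | 6 | focus-to-ROI activation radius (0 = strict in-mask) |
| `prior` | 0.5 | prior term probability in the Bayes step |
| `f_min` | 0.001 | term-frequency binarization cutoff |
| `k` | 30 | terms kept per decoding |
| `selection_order` | rank_then_filter | rank by posterior first, then drop non-significant and non-construct terms (`filter_then_rank` available) |
| `pair_mode` | both | joint activation = seed AND parcel (`union` available) |
| `fdr_alpha` | 0.05 | BH-FDR level |

`rank_then_filter` mirrors a workflow in which the top-30 list is formed
first and non-significant entries are excluded afterwards; it can return
fewer than 30 terms. `filter_then_rank` always returns up to `k`
surviving terms.

## What the synthetic data generator emulates

Real inputs at full scale — a large automatically parsed coordinate
database, a resting-state cohort, a 360-region multimodal parcellation,
probabilistic seed maps — are not shippable or recomputable at desk
scale. `synthetic_dataset()` builds every input at toy scale with planted
ground truth:

* **Atlas**: a 32³ voxel grid at 2 mm, the interior tiled into 40 block
  parcels (hemispheres split at the midline), each parcel assigned to one
  of 7 named networks.
* **Seeds**: three Gaussian probability bumps (peak 0.9, sd 5 mm) whose
  `> 0.25` cores are disjoint, clustered in one slab of the volume the
  way neighbouring subdivisions of one sulcus are.
* **BOLD**: N = 20 subjects, T = 400 volumes at TR = 0.8 s. Each seed
  has a latent signal carried by its core and, scaled so that the
  population correlation with the seed-mean series is 0.5, by the voxels
  of its two planted connected parcels; everything else is white noise.
* **Coordinate database**: 2000 studies, 120 terms. Each study receives
  a fixed number of background foci uniform over labelled voxels (a fixed
  count keeps background activations of disjoint regions uncorrelated; a
  Poisson count would correlate them through its variance and bias the
  co-activation null). Planted structure comes in three kinds:
  * *seed terms* (3 per seed, study prevalence 0.05): foci placed in the
    core with probability 0.8 — the classic single-region association the
    per-seed decoding stage recovers;
  * *region terms* (1 per connected parcel, prevalence 0.05): the same
    mechanism on a parcel — what the region-alone decoding recovers and
    the set difference subtracts;
  * *pair terms* (4, prevalence 0.15, planted for every seed): generated
    by a marginal-preserving comonotone coupling. For a study carrying
    the term, background foci that would activate any coupled region are
    removed and one shared uniform draw reinstates each region's
    activation at exactly its background probability. Each region's
    activation rate is unchanged — single-region decoding sees nothing —
    while the seed-parcel co-activation probability rises from the
    product of the background rates to their minimum. These terms exist
    only at the systems level, which is precisely the signal the method
    claims to isolate.
  Geometry keeps the coupling exact: connected parcels lie more than
  twice the activation radius from every seed core (so jittered literal
  foci cannot reach them) and more than the radius from every other
  connected parcel (so no coupled focus can activate a second region).
  These separation constraints are why the default grid is 32³ rather
  than smaller: on tighter grids no feasible parcel placement exists.
* **Topics**: a deterministic hard assignment of the 120 terms to 8
  topics; **allowlist**: the construct-like subset of the vocabulary
  (the majority of terms are non-construct noise, as in real parsed
  databases).

What the generator deliberately does **not** model: hemodynamic
autocorrelation, motion and physiological noise, realistic cortical
geometry and parcel shapes, term co-occurrence structure, and
database-scale vocabularies. Passing the self-tests therefore
demonstrates that the *pipeline logic and statistics* behave as designed
under known truth — not that any particular empirical decoding of real
data is correct.

## Numerical choices and degenerate inputs

* Correlations are clipped to ±(1 − 10⁻⁷) before `atanh`; zero-variance
  voxel series get a statistic of 0 and can never survive thresholding;
  a zero-variance seed series is an error.
* In the group map, zero between-subject variance with a nonzero mean
  yields a signed infinite sentinel (p = 0 under the one-sided test);
  zero mean with zero variance yields t = 0.
* Terms with a degenerate stratum (carried by all or no studies) are
  excluded from decoding results rather than given sentinel posteriors; a
  zero activation marginal makes a term uninformative (χ² = 0, p = 1).
* Ties in the top-k selection break lexicographically, making every
  output list deterministic.
* All cross-volume operations require identical grids; nothing resamples
  implicitly. Trilinear interpolation treats out-of-field voxels as 0 and
  clips probabilities to [0, 1]; label volumes only ever use
  nearest-neighbour.
* Every generator is a pure function of its parameters and RNG seed;
  per-subject BOLD streams are derived from the master seed so any
  subject subset regenerates identically.

## Design choices where the method is underdetermined

* The joint ROI for pair decoding is read as *co-activation* (a study
  must activate both members); the union-mask reading is kept as an
  option since either is defensible.
* Subject-level connectivity enters the group stage as Fisher-z of the
  Pearson correlation — symmetric and scale-free where a regression beta
  would not be.
* Random-field-theory FWE is out of scope; Bonferroni (default) and
  max-statistic sign-flipping both control the voxel-level FWE the
  method requires.
* The activation radius (6 mm) and the binarization cutoff (0.001)
  follow common meta-analytic practice; both are configurable and
  recorded in outputs.
* The posterior listing cutoff sometimes applied when reporting decoded
  terms (posterior > 0.05) is treated as a reporting filter, not part of
  the selection algorithm.

## Operating characteristics of the default fixture

On the default fixture (seed 1) the full pipeline recovers all 21
planted (seed, term) associations, emits one spurious entry in 22
(4.5%), and every planted pair coupling is specific to its pair and
absent from the region-alone list. Across other fixture seeds the
recovery varies between roughly 0.90 and 1.00 with spurious fractions at
or below 4.5% — the residual variation is chi-square sampling noise at
2000 studies, not systematic leakage. The test suite pins the default
fixture; the problem sizes used there (16³ null grids for the FWE suite,
14³ atlases for the connectivity-recovery suite, 500 and 100 replicate
simulations) were chosen so the whole suite runs in minutes on one CPU.

## Known limitations

* Voxel-level overlap percentages are computed volumetrically; surface
  vertex counting could differ near boundaries.
* The permutation FWE null is coarse below ~6 subjects (warned).
* Chi-square p-values rely on the large-sample approximation; with very
  rare co-activations (a handful of jointly active studies) the
  approximation degrades, which is why the generator's background rates
  are calibrated to keep joint counts in the tens.
* The systems map attributes a seed-associated term to every pair of
  that seed once the region-alone decoding cannot explain it; this is a
  property of the subtraction logic itself, and the synthetic truth
  counts such terms as expected for the whole system rather than as
  spurious.
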