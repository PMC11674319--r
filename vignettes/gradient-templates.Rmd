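---
title: "Connectome gradient templates: models, design choices, and what the synthetic cohorts test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome gradient templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conngrad)
```

## The problem

Gradient analyses place every cortical parcel on a small number of smooth
axes of connectivity variation (G1, G2, G3), obtained by eigendecomposing an
affinity operator built from a connectivity matrix. Because eigenvectors are
only defined up to rotation and sign within near-degenerate subspaces,
individual-level gradients must be aligned to a common *group-level
template* before any between-group comparison. Which template to use is an
open methodological question: a template mixing patients and controls, a
control-only template, or a template from an independent high-quality
normative cohort all seem defensible, and the choice affects the effect
sizes a study reports.

`conngrad` implements the full comparison pipeline: connectivity
construction, diffusion-map gradient estimation, six template strategies,
Procrustes alignment, and parcel-wise multivariate inference — together
with a synthetic cohort generator, so every stage is testable end to end
without access to restricted neuroimaging repositories.

## Pipeline and models

### Connectivity

Functional connectivity (FC) is the Pearson correlation of parcel time
series; subject matrices are Fisher r-to-z transformed (`fisher_z()`,
diagonal set to 0 since atanh(1) diverges and self-similarity is ignored by
the affinity kernels) and group-averaged elementwise. Structural
connectivity (SC) is a non-negative streamline-count-like matrix; subject
matrices are log(1+x)-transformed (zeros must be preserved and raw counts
contain zeros, so a unit offset is used), and the group SC is built by
distance-dependent consensus (`distance_consensus_group_sc()`): candidate
edges are binned into equal-count great-circle-distance bins (intra- and
inter-hemispheric separately, 10 bins each by default), and each bin
retains its K most consistently present edges, K being the rounded mean
per-subject edge count of that bin. This preserves the subject-typical
edge-length distribution that a plain frequency threshold would distort.
Ties are broken by higher mean weight and then by lower parcel-index pair,
making the consensus bit-reproducible.

### Gradients

`embed_functional()` row-thresholds the group FC to the top 10% of entries
per row (ties to the lower column index), computes the normalized-angle
affinity `1 - acos(cos_sim)/pi` (cosine similarity mapped into [0, 1],
avoiding the negative affinities a raw cosine kernel produces; a cosine
kernel with negatives floored at 0 is available as a sensitivity variant),
and runs diffusion-map embedding: density normalisation
`W_ij / (d_i^alpha d_j^alpha)` with `alpha = 0.5`, row-normalisation to a
Markov operator, eigendecomposition through the symmetric conjugate, and
scaling of eigenvector i+1 by `lambda/(1-lambda)` (the automatic
diffusion-time convention). Both `alpha` and the kernel are exposed in the
configuration. Each component's sign is fixed so its largest-magnitude
element is positive — an idempotent convention that makes templates
reproducible. Variance explained is reported as each retained eigenvalue
over the sum of all positive non-trivial eigenvalues; this denominator
choice is documented here because published variance-explained figures
rarely state theirs.

`embed_structural()` embeds each hemisphere's intra-hemispheric block
separately (no thresholding — the structural connectome is already sparse),
which respects lateralisation, then rotates the right-hemisphere gradients
onto the left via Procrustes over homologous parcels and concatenates. If
no homologue map exists, hemispheres are matched by eigenvalue order with a
warning. A consequence worth knowing: for a hemisphere-asymmetric
connectome, flipping hemispheres and re-embedding reproduces the original
gradients only up to one global orthogonal rotation (the merge is anchored
on whichever hemisphere is "left"); the package's tests verify that the
commutation is exact once that gauge is resolved.

### Templates and alignment

The six strategies of `build_template()`: (1) cases + controls of the
study cohort, (2) study controls only, (3) study cases only, (4) the
independent reference cohort, (5) strategy 1 Procrustes-rotated onto
strategy 4, (6) strategy 2 rotated onto strategy 4. Sex-specific variants
are parameterisations of the same operations (a filtered reference cohort),
not separate code paths. Procrustes alignment (`procrustes_rotate()`) uses
the closed-form SVD solution over the full orthogonal group — no centering,
no scaling, reflections allowed — so gradient magnitudes, which the group
statistics compare, are preserved exactly.

One exact mathematical property follows and is worth stating plainly:
template 5 equals template 1 times an orthogonal matrix Q, each subject's
optimal rotation onto template 5 is its rotation onto template 1 times the
same Q, and Hotelling's T² is invariant under a joint orthogonal transform
of the response. **Strategies 5 and 6 therefore yield T² maps identical to
strategies 1 and 2** in exact arithmetic. Any empirical difference between
"study template" and "study-template-aligned-to-reference" reported by
toolbox pipelines must come from operations outside this definition (e.g.
iterative or scaled alignment). Strategy 4 differs genuinely, because the
reference template is not an orthogonal transform of the study template.

### Inference

`fit_mglm()` fits, per parcel, the multivariate linear model
`Y = intercept + group + age + sex + site` with Y the three aligned
gradient values, sites one-hot encoded with a dropped reference level (the
test is invariant to which level is dropped, and constant nuisance columns
are dropped automatically so reduced designs work). The group contrast is
tested with Hotelling's T² in its single-contrast closed form,
`T2 = (c'B)' S^-1 (c'B) / (c'(X'X)^-1 c)`, mapped to
`F = T2 (nu-q+1)/(nu q)` with `(q, nu-q+1)` degrees of freedom; with a
one-dimensional response and no covariates this reduces exactly to the
squared pooled two-sample t, which the tests assert. Parcel-wise p-values
are Benjamini–Hochberg adjusted (`fdr_bh()`, threshold q < 0.05; a relaxed
0.1 variant is a configuration choice).

`spin_test()` assesses map-to-map correlations against a spatial null:
uniform random 3D rotations applied to the left-hemisphere centroids and
their sagittal mirror conjugate to the right, with values reassigned by
nearest source centroid under a greedy one-to-one matching — a true
permutation, so each hemisphere's value multiset is preserved exactly. The
p-value is two-sided with the add-one estimator; its lower bound is
1/(n_perm+1). Parcel-level spin tests are known to be mildly
anti-conservative because nearest-centroid reassignment attenuates the
null correlations.

`evaluate_template_utility()` quantifies a template's clinical usefulness:
a linear support-vector classifier (case vs control) or ridge regression
(continuous score) on the concatenated gradients plus covariates, under
stratified fivefold cross-validation repeated 100 times by default.

## The synthetic cohort generator

The generator is the package's test bed, and its defaults define the
simulated study conditions.

Geometry: `make_parcellation()` places half the parcels quasi-uniformly on
each unit hemisphere (a Fibonacci half-shell, mirrored), assigns
kmeans-patch communities (7 by default) and latitude-band hierarchy levels
(4), and records mirror homologues. Ground truth
(`make_ground_truth()`) gives each parcel three latent coordinates —
standardised smooth functions z, y, and y·z of its centroid — so the
planted gradients are spatially smooth axes with decreasing strengths
(1, 0.8, 0.6), keeping the embedding's gradient order stable.

FC subjects follow the factor model `X = A F + E`: loadings A are the
latent geometry plus per-subject jitter (SD 0.7) and a small additive site
offset (SD 0.05, 3 sites); E has SD 2. These defaults were fixed by a
one-time design analysis: they produce realistic resting-state correlation
magnitudes (off-diagonal |r| mostly 0.1–0.3) and individual variability
large enough that a planted one-SD effect is detectable without being
trivially separable. The correlation of `A F + E` is a valid correlation
matrix by construction, with no nearest-positive-semidefinite projection
needed.

The planted group effect shifts the first-axis loadings of the affected
parcels by `effect_size` latent SD units *in the loading matrix*, so it
propagates through correlation, thresholding, affinity, embedding, and
alignment — end-to-end recovery is a genuine test, not a painted-on
gradient difference. Affected parcels default to the apex of the first
latent axis (shifted further outward). This choice is deliberate:
pathology at the extreme of the principal hierarchy mirrors the
transmodal-end effects most disease-gradient studies report, and an
off-manifold shift keeps the effect spatially localised. With scattered
affected parcels the same shift leaks into latent neighbours through their
shared edges — connectivity effects are intrinsically non-local, and that
variant (available as `affected_rule = "random"`) is useful for studying
exactly this leakage, but it cannot support a localisation benchmark.
Even with the apex rule, edges joining affected to unaffected parcels
genuinely differ between groups, so a fraction of "false" discoveries at
strict ground truth is real connectivity signal; empirical
false-discovery proportions slightly above the nominal BH level are
expected behaviour, not miscalibration.

SC subjects draw each edge with probability `exp(-d/lambda)` (great-circle
distance; `lambda` calibrated at run time so the expected density is about
15%, comparable to tractography matrices) and log-normal weights whose
log-mean decreases with distance and increases with latent similarity;
case-group edges incident to affected parcels are scaled by
`exp(effect_size * 0.2)`.

The reference cohort (`simulate_reference_cohort()`) shares the latent
geometry but multiplies the series length and divides the noise *and* the
subject jitter by `quality_factor` (default 4): it emulates a large
normative dataset that is both technically cleaner and demographically more
homogeneous than a multi-site clinical study. It is control-only, with no
site offsets.

What the generator does *not* emulate: scanner artefacts, head-motion
structure (motion is an inert covariate), autocorrelated BOLD noise,
geodesic folding geometry, or realistic community-specific connectivity
motifs. Passing tests demonstrate the pipeline's correctness and its
statistical calibration under a smooth low-rank world; they do not certify
effect-size estimates on real data.

## Numerical choices and degenerate inputs

- Correlations at |r| = 1 off the diagonal (possible with short series) are
  clipped to 1 - 1e-7 before atanh, with a warning.
- Row thresholding keeps values (not a binary mask) and ranks signed
  z-values; ties go to the lower column index.
- `diffusion_map()` refuses disconnected affinity graphs (naming the
  component sizes) and k >= p; eigen-sign ambiguity is resolved by the
  largest-magnitude-positive convention, applied identically everywhere.
- `fit_mglm()` refuses rank-deficient designs (naming aliased columns),
  residual degrees of freedom below the response dimension, and singular
  residual covariances (constant responses).
- The spin test's greedy matching is implemented in C++; each permutation
  is an exact within-hemisphere permutation of the map.
- All readers validate schemas eagerly (citing row/column of the first
  non-finite entry); writers emit 17 significant digits so every artifact
  round-trips bit-exactly.
- Randomness: every generator draws from child seeds derived from a single
  integer by a fixed counter scheme, and restores the caller's RNG state,
  so any pipeline stage is independently reproducible.

## Problem sizes used by the test suite

The packaged experiments run at 100 parcels, 30 + 30 study subjects over 3
sites, and a 100-subject reference cohort — large enough that the
multivariate model has stable residual covariances and the planted effect
is in a realistic power regime, small enough to iterate quickly. Embedding
oracles are checked on random affinities up to 100 parcels; calibration
checks pool 50 null simulations; recovery checks average 20 seeded
replicates. The vertex-level (tens of thousands of nodes) regime is out of
scope.

## Known limitations

- Strategies 5/6 are exactly equivalent to 1/2 for any statistic invariant
  to orthogonal response transforms (see above); they are retained because
  the template *coordinates* differ, which matters for visualisation and
  for cross-study comparability of gradient values.
- The latent dimension is fixed at 3 to match the three retained gradients;
  the generator cannot express effects orthogonal to a three-dimensional
  manifold.
- Parcel-level spin tests inherit the mild anti-conservatism of
  nearest-centroid reassignment (at 100 parcels, about 13% of null map
  pairs fall below p = 0.05; increasing the parcel count helps only
  marginally).
- Whether subject-level structural gradients should also be embedded
  per-hemisphere is not settled usage; this package assumes yes, for
  symmetry with the group level.
```{r example}
cfg <- default_config(n_parcels = 40L, n_communities = 4L,
                      n_case = 6L, n_control = 6L, n_reference = 6L,
                      strategies = c(1L, 4L), seed = 1L)
res <- run_experiment(cfg)
res$summary
```
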