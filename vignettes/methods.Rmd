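---
title: "Models and methods: group spatial ICA and connectivity-based parcellation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: group spatial ICA and connectivity-based parcellation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnparc)
```

# Overview

`rsnparc` implements two complementary analyses of brain connectivity and
exercises both, end to end, on synthetic cohorts with planted ground truth:

1. **Resting-state network (RSN) analysis.** 4D functional series are
   temporally conditioned, decomposed by *group spatial independent
   component analysis* (ICA) into spatially independent maps with
   subject-specific time courses, scored for reliability
   (ICASSO-style resampling), filtered to functionally relevant components
   (tissue-prior correlation and low-frequency spectral power), and compared
   voxelwise between groups with permutation-corrected cluster statistics.
2. **Connectivity-based parcellation.** Seed voxels at the grey/white
   matter interface of a cortical region are characterised by their
   streamline visitation-count profiles over atlas regions; k-means with
   silhouette-guided selection of the number of clusters subdivides the
   region, and centroid profiles and per-subject seed counts are compared
   between groups.

Because no subject-level data accompany the design this package emulates,
the synthetic-data module is a first-class component: it defines the study
conditions under which every claim in the test suite is evaluated.

# The generative model for functional data

Each subject's series is a noisy linear mixture of fixed spatial networks

$$Y_s(v, t) \;=\; \sum_{k=1}^{K_{\mathrm{net}}} a_{sk}\, M_k(v)\, \tau_{sk}(t) \;+\; \varepsilon_{sv t},
\qquad \varepsilon \sim \mathcal N(0, \sigma^2),$$

where $M_k$ are Gaussian blobs placed on a coarse lattice of cells so that
pairwise spatial correlations stay below 0.2 (spatial independence by
construction), $\tau_{sk}$ are subject-specific band-limited time courses,
and $a_{sk}$ are amplitudes. Group effects are **multiplicative on
amplitude** (`groupEffect`, default 1.5 on network 1), so that Z-scored
subject maps genuinely differ between groups — an additive offset would be
removed by the Z-scoring.

Key parameter choices:

* **Grid** — 20 × 24 × 18 voxels of 3 × 3 × 4 mm at TR = 3 s, 100 volumes
  (`defaultGrid()`): a scaled-down raster with the voxel geometry of a
  typical resting-state acquisition. The full 53 × 63 × 35 grid
  (N = 116,865 voxels) is supported but not the default; the desk-scale
  grid keeps a complete cohort analysis in seconds and the whole suite in
  minutes.
* **Time courses** — white Gaussian noise band-passed to 0.01–0.08 Hz with
  a $1/f$ amplitude envelope inside the band, then standardised.
  Resting-state fluctuations have $1/f$-like spectra; the envelope
  concentrates the expected power in the 0.01–0.05 Hz range (≈ 0.9 of the
  total), which is what makes a planted network an unambiguous
  "low-frequency" component for the selection stage. A flat spectrum over
  the pass band would leave only ≈ 0.57 of the power below 0.05 Hz and a
  genuinely low-frequency network could fail the 50% rule by sampling
  noise alone.
* **Noise** — `noiseSd` is expressed in units of the peak-voxel signal
  standard deviation (maps have unit peak, time courses unit variance);
  0.5 is the reference level used by the recovery checks.
* **Tissue priors** — grey matter follows the union of network supports,
  CSF occupies a reserved lattice cell plus the boundary shell, white
  matter fills the remainder; per-voxel sums never exceed 1. Optional
  confound components live in the CSF block and fluctuate at
  0.10–0.15 Hz, exercising both rejection rules at once.
* **Effect sizes** are free parameters of the generator, not calibrated to
  any empirical cohort; the defaults were chosen once as values a
  simulation study in this field would call realistic.

What the generator does **not** emulate: hemodynamic response convolution,
spatial autocorrelation of the noise, motion artefacts beyond a scalar
covariate, MR physics (B0 inhomogeneity, eddy currents), or anatomical
realism of the tissue geometry. Passing tests therefore demonstrate the
correctness and calibration of the pipeline's algorithms under the stated
model, not performance on real scanner data.

# Group spatial ICA

The decomposition follows the three-step group scheme: (i) per-subject PCA
reduction of the temporal dimension to C components; (ii) temporal
concatenation into an M × N matrix (M = subjects × C — with 26 subjects
and C = 40, M = 1,040); (iii) Infomax unmixing of K spatial sources,
followed by back-reconstruction of per-subject maps and time courses from
the subject blocks of the group mixing matrix. `C` defaults to `K`,
matching that arithmetic. A single group-level whitening inside Infomax is
used; a second, group-stage PCA is deliberately not performed.

**Infomax.** Natural-gradient ascent of the entropy of a logistic
nonlinearity applied to the unmixed data, which favours the
super-Gaussian (spatially sparse) sources typical of network maps. The
data are whitened to K dimensions internally. Numerical choices, fixed
for reproducibility: random orthogonal initial unmixing matrix (seeded);
block updates with block size `min(N/10, 5 + sqrt(N))`; initial learning
rate `0.01 / log K`, annealed by 2% whenever the weight change grows and
halved with a restart if the weights blow up; convergence when the
squared weight change per pass drops below `1e-6`, with a cap of 512
passes and a warning (not an error) on non-convergence.

**Sign convention.** ICA is sign-ambiguous; each component is flipped so
its spatial map has nonnegative skewness, making group statistics
well-defined. Applying the convention twice is the identity.

**Z-scoring.** Spatial maps are standardised to zero mean and unit
population SD over in-mask voxels, so voxel values are comparable across
subjects. Zero-variance rows are flagged degenerate rather than divided
by zero.

# Stability (ICASSO) and cross-decomposition similarity

Infomax is restarted `nRuns` times (default 10) from different random
initial conditions on bootstrap-resampled data (rows of the concatenated
matrix drawn with replacement; the resampling unit is a design choice —
rows are the natural exchangeable unit of the concatenated matrix). All
K × nRuns maps are pooled and clustered agglomeratively on
`1 − |spatial correlation|` into K clusters. Single linkage is used:
reliably re-estimated components form tight cliques that merge first,
while chaining is confined to the diffuse pool of unstable components.
(Average linkage, cut at exactly K clusters, occasionally merged two
tight cliques because the unstable pool splits early and consumes the
cluster budget; complete linkage and k-medoids were evaluated and were
less robust.)

The per-cluster stability index is
*mean intra-cluster similarity − mean extra-cluster similarity*, in
[−1, 1]. For runs that re-estimate a component identically the intra
term is exactly 1 and the index approaches 1; it equals 1 exactly only
if the remaining components are exactly uncorrelated with it, which
finite data never quite achieve. The cluster centrotype (member with the
largest within-cluster similarity sum) is the canonical map.

Two independent decompositions of the same voxel space are compared by
the Pearson correlation of their Z maps with greedy one-to-one matching
by descending |r| (`crossCohortSimilarity`).

# Component selection

Two criteria, both configurable via `selectionCriteria()`:

* **Tissue association** — keep a component if its map correlates with
  the grey-matter prior at least `gmCorrMin = 0.15` *and* more strongly
  than with the white-matter and CSF priors. The relative (rank-based)
  part of the rule is robust to the overall correlation scale, which
  depends on blob geometry; the absolute floor guards against components
  uncorrelated with all tissue.
* **Spectral content** — keep a component if at least 50% of its
  time-course periodogram power (DC excluded, mean over subjects) lies
  in 0.01–0.05 Hz.

Matching retained components to named networks is done against
user-supplied template maps (`matchTemplates`) rather than a bundled
atlas.

# Voxelwise group statistics

Within- and between-group tests are per-voxel general linear models with
the mean subject motion as a confounding covariate: one-sample (intercept
test, one-sided for positive network activity) and two-sample (group
contrast, `nA + nB − 3` degrees of freedom, two-sided). A constant
covariate is dropped (it contributes nothing); a covariate collinear with
the group indicator is an error. Within-group maps thresholded at
p = 0.001 are intersected into the analysis mask for the between-group
comparison.

Cluster inference: suprathreshold voxels (two-sided p < 0.001) are
labelled by 6-face connectivity (a deliberate, configurable simplification
of the 18-connectivity convention of common neuroimaging software), and
cluster extents are corrected for family-wise error by a max-statistic
permutation scheme — group labels shuffled, the model refit with the
covariate, the largest suprathreshold extent recorded per permutation.
Clusters are reported significant when the extent reaches k ≥ 5 voxels
and the FWE-corrected p falls below 0.05. Permutation correction replaces
parametric random-field cluster inference by design: at desk scale and
with synthetic smoothness, random-field theory assumptions are not
defensible, while the permutation null is assumption-light and its
calibration is itself testable. The k ≥ 5 floor is not small for this
raster: one 3 × 3 × 4 mm voxel (36 mm³) equals 4.5 voxels of a standard
2 × 2 × 2 mm analysis.

Clinical correlations use a small-volume correction: within a 10-mm
sphere around each a-priori peak, the map value is correlated with the
score voxelwise; the strongest in-sphere correlation is reported with
Bonferroni correction over the in-sphere voxel count. A radius of 0
degenerates to a single-voxel test with no correction factor. Pearson
correlation is the voxelwise default; Spearman is available and is the
default for scalar-vs-scalar seed-count correlations, mirroring standard
practice for non-normal clinical measures.

# Connectivity-based parcellation

**Seeds.** A 2D Sobel filter applied per axial slice to the
(non-binarised) grey-matter probability map marks the GM/WM interface;
voxels whose gradient magnitude reaches 25% of the slice maximum (the
threshold is unstated in common descriptions of this procedure and is
configurable) and whose region probability is ≥ 0.5 become seeds. Seeds
facing the CSF — own or any 6-neighbour CSF probability above 0.5 — are
removed automatically; the manual removal this emulates is not
reproducible, an explicit cutoff is.

**Profiles.** Per-seed visitation-count volumes (from probabilistic
tractography, or from this package's Monte-Carlo toy tracker) are
downsampled by integer-factor block summation (emulating tractography
output saved at reduced resolution; the atlas is downsampled by label
majority), then summed within atlas regions. Seed-containing regions and
contralateral-hemisphere regions are excluded from the columns.

**Clustering.** Rows are L1-normalised (each profile divided by its total
count) before Euclidean k-means — normalisation removes seed-depth count
biases; raw counts and correlation distance remain available. For each
candidate k in 2–15, k-means runs with k-means++ initialisation and 20
restarts (best within-cluster sum of squares kept); the mean silhouette
scores each solution and the k with the maximum mean silhouette is
selected, ties broken toward the smaller k (parsimony). Groups are
clustered separately.

**Silhouette.** The standard dissimilarity form
$s(i) = (b_i − a_i)/\max(a_i, b_i)$ is the default, following the
canonical references; the literal similarity-ratio variant (mean
intra-cluster similarity over the maximum similarity to other clusters'
seeds, similarity $1/(1+d)$) is available behind `variant = "ratio"`.
Seeds in singleton clusters score 0; a clustering of only singletons is
an error.

**No-structure rule.** If the best mean silhouette over the k sweep stays
below 0.25 — the conventional boundary below which a silhouette profile
indicates no substantial structure — the result is flagged
`noStructure` with the chosen k undefined, rather than reporting the
argmax of a flat curve. Profile cohorts generated with `separation = 0`
land here by design.

**Group comparison.** Cluster centroids are matched across groups by
maximal centroid correlation with an optimal one-to-one (Hungarian)
assignment; surplus clusters under unequal k are reported group-unique.
Matched centroids are compared region by region with a peak-presence
threshold (0.05 on normalised profiles) and an amplitude-ratio rule
(1.5×) yielding present-in-one-group-only / increased / decreased /
unchanged — the ratio rule makes the report mirror exactly when the
groups are swapped. Per-subject seed counts per matched cluster are
compared with Welch's t test and correlated with clinical scores by
Spearman rank correlation.

# Problem sizes used by the tests

The test suite and the acceptance script run the full pipeline at the
desk scale the generator defaults to: 12-subject cohorts on the
20 × 24 × 18 grid with 100 volumes for ICA recovery and stability
(K = C = 12, 10 ICASSO runs); 40 null replicates of a 24-subject,
1,000-voxel two-group analysis with 1,000 permutations each for the
family-wise error calibration; 50 replicates per planted k ∈ {2, 3, 4}
(60 seeds × 48 regions per cohort) for the silhouette selection rate; and
exact checks on analytic slab geometries for the seed extraction. These
sizes were chosen so a complete run finishes in a few minutes while every
stochastic claim still rests on enough replicates to be meaningful.

# Known limitations

* Subject-level back-reconstructed maps are noisy at very small cohort
  sizes when C exceeds the true signal rank; group maps are much more
  reliable (this is inherent to the per-subject pseudo-inverse, not a
  defect of the bookkeeping).
* The toy streamline tracker is a geometry generator for testing the
  aggregation and clustering stages; it models neither fibre crossing nor
  diffusion-weighted signal and is not a tractography method.
* The permutation FWE correction assumes exchangeability of group labels
  given the covariate; strong covariate-group confounding would need a
  residual-permutation scheme, which is not implemented.
* The silhouette no-structure cutoff (0.25) is a convention; cohorts with
  genuine but very weak structure will be flagged as unstructured.
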