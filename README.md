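# rsnparc

Group spatial ICA of resting-state fMRI and diffusion-connectivity-based
cortical parcellation, as one tested R pipeline exercised on synthetic
cohorts with planted ground truth.

## The problem

Resting-state networks (RSNs) are sets of brain regions whose spontaneous
low-frequency (< 0.1 Hz) fluctuations are temporally coherent. Two
standard questions about them are: *do groups differ in the amplitude of
a network's fluctuations at particular voxels?* and *does the structural
connectivity of a cortical region — the profile of streamline counts from
its seed voxels to the rest of the brain — cluster differently across
groups?* `rsnparc` implements the full analysis chain for both questions
for researchers who want a reproducible, testable reference
implementation:

* **Preprocessing** — per-voxel linear detrending, FFT band-pass
  (0.01–0.08 Hz), 6-mm 3D Gaussian smoothing, flattening to time × voxel
  matrices in fixed x-fastest raster order.
* **Group spatial ICA** — per-subject PCA reduction to C components,
  temporal concatenation into an M × N matrix (M = subjects × C; 26
  subjects × 40 components gives M = 1,040), Infomax unmixing
  (natural-gradient, logistic nonlinearity), back-reconstruction of
  subject maps/time courses, Z-scoring, and a nonnegative-skewness sign
  convention. The model is `X = A S` with spatially independent rows of
  `S`.
* **Stability** — ICASSO-style resampling: repeated Infomax runs on
  bootstrapped data, cross-run clustering of maps by |spatial
  correlation|, per-component stability index in [−1, 1].
* **Component selection** — tissue-prior correlation (keep GM-like,
  reject WM/CSF-like) and spectral power fraction ≥ 50% in 0.01–0.05 Hz.
* **Voxelwise statistics** — one/two-sample GLMs with a motion covariate,
  intersection masking at p = 0.001, cluster-extent thresholding (k ≥ 5,
  6-face connectivity) with max-statistic permutation FWE correction at
  p < 0.05, and clinical correlations with a 10-mm small-volume
  correction.
* **Parcellation** — seed extraction by 2D Sobel filtering of the GM map
  at the GM/WM interface (CSF-facing seeds removed), seed × region
  visitation-count profiles (seed-containing and contralateral regions
  excluded), k-means over k = 2…15 with silhouette-selected k, Hungarian
  matching of cluster centroids across groups, and Welch/Spearman
  statistics on per-subject seed counts.
* **Synthetic data** — a first-class generator for 4D network-embedded
  image series (planted spatial maps, 1/f band-limited time courses,
  multiplicative group effects, tissue priors, CSF/high-frequency
  confounds), profile cohorts with planted cluster structure, and a
  Monte-Carlo toy streamline tracker.

Everything is S4 (`Image4D`, `ComponentSet`, `StatMap`, `ProfileMatrix`,
`ParcellationResult`) with accessors, validity checks and `show`
methods. Volumes are read and written as NIfTI-1 via RNifti.

## Worked example

Generate a 12-subject cohort with six planted networks at noise level
0.5, decompose it, assess stability, select components, and parcellate a
2-vs-4-cluster profile cohort:

```r
library(rsnparc)

co   <- makeRsfmriCohort(nSubjectsPerGroup = c(6L, 6L), nNetworks = 6L,
                         noiseSd = 0.5, seed = 11)
pre  <- lapply(co$images, detrendBandpass)
cset <- runGroupICA(pre, K = 12L, C = 12L, seed = 12)
cset <- assessStability(cset, pre, nRuns = 10L, seed = 13)
cset
#> ComponentSet: K = 12 components, 12 subjects (C = 12), 8640 voxels in mask
#>   stability index: 0.04 - 0.99

sel <- selectComponents(cset, co$truth$priors)
subset(sel, keep, c(component, gm, wm, csf, powerFraction))
#>    component   gm     wm    csf powerFraction
#> 2          2 0.38 -0.053 -0.089          0.92
#> 4          4 0.38 -0.045 -0.095          0.91
#> 6          6 0.38 -0.048 -0.092          0.92
#> 7          7 0.38 -0.039 -0.102          0.93
#> 8          8 0.38 -0.037 -0.104          0.91
#> 11        11 0.38 -0.049 -0.092          0.94
```

Exactly the six planted networks are kept: each correlates with the
grey-matter prior (0.38) far above white matter and CSF, carries > 90% of
its time-course power below 0.05 Hz, and has a stability index near 1
(the 0.04 end of the range belongs to noise components).

```r
pc   <- makeProfileCohort(plantedK = c(2L, 4L), separation = 8, seed = 14)
resA <- chooseK(pc$profiles[[1]], seed = 15, group = "controls")
resB <- chooseK(pc$profiles[[2]], seed = 16, group = "patients")
resA; resB
#> ParcellationResult (controls): k = 2 (mean silhouette 0.522)
#> ParcellationResult (patients): k = 4 (mean silhouette 0.504)

seedCountStats(resA, resB)$tests
#>   clusterA clusterB meanA meanB     t   df      p
#> 1        1        3  5.17  2.83 -2.63 9.40 0.0266
#> 2        2        1  4.83  2.50 -2.98 7.24 0.0196
```

The silhouette sweep recovers the planted cluster numbers (2 in
"controls", 4 in "patients"), and the per-subject seed counts of the two
matched clusters are significantly lower in the 4-cluster group, whose
seeds spread over more clusters — the qualitative pattern a group
difference in parcellation produces.

A full orchestrated run (`runPipeline(config)`) writes NIfTI statistic
volumes, CSV tables and a JSON report; `inst/exec/rsnparc` is a thin
command-line wrapper (`rsnparc synthgen ...`, `rsnparc profiles ...`,
`rsnparc run --config cfg.yaml`).

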