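# myeliquant

Automated quantification of myelination in human myelinating-organoid
("myelinoid") cultures from multi-channel confocal z-stacks, for labs that
assay myelin formation with high-content imaging: developmental
time-courses, pharmacological screens (e.g. BDNF, blebbistatin), disease
models, and activity-dependent myelination experiments (e.g. tetanus-toxin
block of synaptic vesicle release).

## What it computes

**Global myelin volume, normalized to axonal density.** The myelin channel
(MBP or CNP) of each 12 µm z-stack is segmented per plane with an adaptive
threshold, then passed through a shape/intensity filter cascade that
rejects cell bodies and debris:

- Filter Mask 1 removes 2D objects with fiber breadth B > 16 µm, fiber
  length L < 10 µm or area A < 45 µm², where the fiber model solves
  A = L·B, P = 2(L + B):  L = (P + √(P² − 16A))/4,  B = A/L;
- objects are shrunk by 4 px and a second mask removes shrunk objects with
  elliptical form factor < 3.7, breadth > 8 µm or intensity SD < 1000
  counts; Keep Marked Objects retains the full-extent parents of surviving
  cores;
- round blobs 8–100 µm and 4–6 µm wide (multi-scale Laplacian of Gaussian
  with ridge rejection) are enlarged by 5 px and subtracted;
- planes are connected into 3D objects (8-connectivity in-plane,
  26-connected touching across planes) and objects with volume ≤ 450 µm³
  **and** max-Feret diameter ≤ 45 µm are removed.

The site-level readout is segmented myelin volume (µm³) divided by the
integrated NF-H intensity of the thresholded axonal volume; sites are
averaged per myelinoid and optionally normalized to each batch's control
mean.

**Single-cell and population morphometrics.** Sheath counts and lengths per
cell from trace tables (CSV or unbranched SWC), percentage length
histograms, nearest-neighbor oligodendrocyte density (cells within a 100 µm
radius), Sholl analysis (circle-crossing counts plus skeleton-length total
outgrowth), and the g-ratio regression g = a + b·ln(axon diameter).

**Cluster-aware effect estimation.** Treatment effects are fold changes:
ratios of geometric means of myelinoid-level values, with percentile
confidence intervals from a bootstrap that resamples whole myelinoids
stratified by batch and group — the myelinoid is the experimental unit, and
ignoring that clustering would overstate precision. Tukey-style five-number
boxplot summaries use type-7 quartiles and 1.5·IQR whiskers.

**Synthetic ground truth.** `generate_stack()` renders seeded stacks with
capsule-shaped sheath bundles, soma/debris distractors, a correlated NF-H
axon channel and camera noise, recording voxel-level class labels and
per-object truth before noise — every stage of the pipeline is testable
without real data, and `evaluate_segmentation()` scores a run against the
truth.

## Worked example

```r
library(myeliquant)

sim <- generate_stack(sim_params(seed = 42))   # 12 x 512 x 512, 2 channels
res <- run_pipeline(sim$stack, seg_params())
res
#> myelinoid_result (acquisition site)
#>   myelin volume:        13936.8 um^3 (9 3D objects)
#>   NF-H volume:          1651.1 um^3
#>   NF-H integrated int.: 8.459e+07 counts
#>   normalized volume:    0.0001647 um^3/count

evaluate_segmentation(res, sim$truth)
#> precision 1.00, recall 1.00, volume error -7.9% vs 15138.5 um^3 truth

tab <- generate_group_data(group_sim_params(fold_change = 2.09, seed = 42))
fold_change_bootstrap(tab, reps = 2000, seed = 43)
#> fold change (geometric-mean ratio): 2.566 (95% CI 1.956 to 3.299)
#>   13 vs 13 myelinoids; 2000 bootstrap reps (seed 43), myelinoid,
#>   stratified by batch and group

gratio_fit(generate_gratio_table(seed = 42))
#> g-ratio regression: g = 0.7195 + 0.0522 ln(axon diameter)
#>   n = 124, mean g = 0.746, residual SD = 0.0457
```

The segmentation run recovers all nine rendered sheath bundles with volume
within 8% of the voxel ground truth; the two-group design (13 vs 13
myelinoids in 3 batches, true fold 2.09) yields a bootstrap interval
covering the truth; the simulated TEM table of 124 axons fits back its
generating coefficients.

A command-line wrapper is installed as `exec/myeliquant` with subcommands
`simulate`, `segment`, `morpho`, `stats` and `pipeline`, a flat YAML
configuration exposing every threshold, and a JSON run manifest written
beside all outputs.

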