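# tme3d

3D spatial analysis of the lymphoma tumor microenvironment (TME) from
light-sheet fluorescence microscopy volumes.

Cleared lymphoid tissue imaged by light-sheet microscopy yields multichannel
3D stacks in which immunolabeled cells (CD3, CD8, CD20, CD68, CD163, CD14,
CD15, FOXP3, Ki67) are resolvable as individual blobs down to ~1 mm of
depth. `tme3d` turns such volumes — or synthetic volumes with known ground
truth — into quantitative spatial statistics and group-level comparisons
across disease conditions (e.g. reactive hyperplasia RLN vs. diffuse large
B-cell lymphoma DLBCL vs. angioimmunoblastic T-cell lymphoma AITL). It is
aimed at imaging groups who want an open, testable replacement for the
commercial spot-detection / stitching / scripting chain usually used for
this analysis.

## What it computes

For typed 3D cell coordinates (in micrometres) within regions of interest
(ROIs):

* **Cell density** — typed count / ROI volume, in cells/mm³.
* **Radial neighbor profiles** — counts of neighbor-type cells in
  concentric half-open 5-µm shells out to 50 µm around each center T cell;
  under complete spatial randomness the per-center mean in shell
  `(r₁, r₂)` is `λ · 4/3 · π · (r₂³ − r₁³)`, which the tests verify.
* **Conjugation** — unordered pairs of unlike cell types with centroid
  distance strictly below 15 µm (expected count `nₐ n_b · 4/3 π · 15³ / V`
  under randomness).
* **Co-positivity** — e.g. Ki67⁺CD8⁺ fraction, via greedy one-to-one
  matching of two channels within a 5-µm radius.
* **Group comparison** — tie-corrected Kruskal–Wallis
  `H = 12/(N(N+1)) Σ R_j²/n_j − 3(N+1)`, chi-square reference, α = 0.05.

Upstream of the statistics the package provides: a synthetic light-sheet
data generator (Poisson / Thomas-cluster / anchor-attraction point
patterns; anisotropic Gaussian PSF; per-channel exponential depth
attenuation, 660/780/900 µm at 488/532/637 nm; Poisson shot noise; 0.59 µm
pixels, 2 µm plane steps, 300 µm sections tiled every 250 µm), a
scale-normalized Laplacian-of-Gaussian 3D spot detector with subvoxel
refinement, and cross-correlation z-tile registration with ramp-blend
fusion.

## A worked example

```r
library(tme3d)

cfg <- pipeline_config(seed = 7L)      # three disease presets, truth path
run_pipeline(cfg, out_dir = "tme3d-run")

tests <- read.csv("tme3d-run/tests.csv")
head(tests[order(tests$p_value),
           c("metric", "statistic_H", "p_value", "significant")], 5)
```

```
                  metric statistic_H      p_value significant
9           density:Ki67    25.84094 2.447430e-06        TRUE
4           density:CD20    25.81219 2.482866e-06        TRUE
10  conjugation:CD8-CD20    25.81219 2.482866e-06        TRUE
19 radial_mean_0_50:CD20    25.80645 2.490005e-06        TRUE
23 copositivity:Ki67/CD8    25.80645 2.490005e-06        TRUE
```

Each row compares one per-ROI statistic across the three simulated disease
groups (10 ROIs each) with the Kruskal–Wallis test. On the packaged
presets the B-cell metrics (density, CD8–CD20 conjugation, B-near-T radial
counts) separate the DLBCL-like group, FOXP3/CD163 metrics separate the
AITL-like group, CD68 and CD14 metrics stay null, and Ki67 co-positivity
differs on CD8 but not on CD20 — the structure the generator encodes. The
run directory also holds the tidy per-ROI tables (`densities.csv`,
`radial.csv`, `conjugation.csv`, `copositivity.csv`), the ground-truth
point sets, the config echo, and a manifest with md5 hashes (rerunning
with the same seed is bit-identical).

A thin CLI over the same functions is installed at
`inst/cli/tme3d.R` (subcommands `run`, `simulate`, `detect`, `stitch`,
`analyze`, `compare`).

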