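# skatemorph

Geometric-morphometric analysis of sexual shape dimorphism in skate
(Rajoidei) pectoral fins: a reusable R pipeline for biologists studying
how male fin outlines diverge from female ones, how that divergence
varies across species, and how it develops over ontogeny alongside
clasper growth.

Skate pectoral fin margins are digitized as ordered 2-D landmark
configurations (two fixed anatomical endpoints plus sliding
semilandmarks). The package implements the full chain from raw TPS files
to comparative statistics:

* **Superimposition** — generalized Procrustes analysis (translation,
  scale, rotation removed; centroid size retained as body size) with
  Procrustes-distance sliding of semilandmarks, plus tangent-space PCA.
* **Dimorphism vectors** — per species, the female→male shape-change
  vector with length *L* = √Σᵢ(mᵢ − fᵢ)² (the Procrustes distance between
  the sexes) and angle θ = arccos(v̂₁·v̂₂) to a PC-extreme baseline; plus
  a PCA of length-scaled vectors for direction-only variation.
* **Trajectory analysis** — two-point shape trajectories across maturity
  stages compared between groups by |ΔL| and θ, with residual-
  randomization permutation p-values, p = (1 + #{perm ≥ obs})/(N + 1).
* **Comparative statistics** — PGLS of dimorphism magnitude on
  size-standardized clasper length under Brownian-motion covariance
  (C = shared path lengths); sex-specific allometric ANCOVAs
  (trait ~ sex × ln DW, slopes-then-elevation hierarchy); and a
  continuous-hinge segmented regression that estimates the disc width at
  which clasper length inflects — the maturity threshold, applied as a
  strict DW > threshold rule.
* **Synthetic data** — a generator reproducing the statistical structure
  of both study designs (one male + one female outline per species on a
  simulated phylogeny; a 43-specimen ontogenetic series with two-phase
  clasper growth breaking at 84 mm), with per-stream seeding, ground-truth
  manifests, and byte-reproducible output. No specimen images or
  third-party data are required anywhere.

## Worked example

The analysis is organised as three numbered drivers under `analysis/`,
each a thin narrative script over the package functions:

```sh
Rscript analysis/01_simulate_data.R          # writes results/data/
Rscript analysis/02_interspecific_dimorphism.R
Rscript analysis/03_ontogeny_case_study.R
```

The second script aligns 42 outlines (21 species × 2 sexes), builds the
dimorphism vectors, and prints:

```
sex-separating axis: PC1 (81.6% of shape variation)
dimorphism magnitudes: strongest species (sp12, L = 0.222) is 4.2x the weakest (sp08, L = 0.053)
angles to the baseline span 31.1 deg of the 360 available — a consistent manner of shape change
PGLS of L on clasper residuals: F(1,19) = 4.16, R2 = 0.18, p = 0.0556 — no support for clasper size driving dimorphism magnitude
```

Reading: the manner of male-female shape change is consistent across
species (angles occupy a narrow band of the possible directions) while its
magnitude varies several-fold, and that magnitude is not explained by
relative clasper length — the generator's ground truth, which assigns
clasper lengths independently of dimorphism. The third script estimates
the maturity breakpoint from clasper growth and compares shape
trajectories:

```
maturity breakpoint estimated at 81.3 mm disc width (clasper growth inflection)
ontogenetic shape change: males 3.87x females (L = 0.0631 vs 0.0163; p_deltaL = 0.0001), trajectory angle 17.4 deg (p = 0.0033)
dimorphism over ontogeny: mature pairs 13.80x immature (L = 0.0474 vs 0.0034; p_deltaL = 0.0001), angle 94.9 deg (p = 0.0074)
endoskeletal ANCOVAs: 1 of 9 traits slope-dimorphic, 4 more differ in elevation
```

Here males change shape several times more than females between immature
and mature stages (the generator plants a 3× effect), and sex dimorphism
is concentrated in mature animals. All tables land under `results/` as
plain CSV/text with deterministic formatting; identical seeds give
byte-identical reports.

Every function is usable directly, e.g.:

```r
library(skatemorph)
spec <- synthetic_spec(seed = 1)
sim  <- simulate_interspecific(spec)
al   <- gpa(sim$configs, sliders = sim$sliders)
pca  <- shape_pca(al)
```

See `vignettes/skatemorph-methods.Rmd` for the models, parameter choices,
numerical decisions, and known limitations.

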