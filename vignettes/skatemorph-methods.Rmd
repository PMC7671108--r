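---
title: "Quantifying sexual shape dimorphism in skate pectoral fins: models and methods"
author: "skatemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sexual shape dimorphism in skate pectoral fins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skatemorph)
```

## The scientific problem

Male skates (Rajoidei) carry claspers — paired, cartilage-supported
intromittent organs that elongate abruptly at sexual maturation — and in
many species the male pectoral fin differs in outline shape from the
female's: a concave anterior margin, a more posteriorly placed apex, and a
rounded, expanded lobe near the posterior insertion. `skatemorph`
implements a complete quantitative workflow for this phenomenon at two
scales:

* **across species** — how consistent is the *manner* of female-to-male
  shape change, how variable is its *magnitude*, and does magnitude track
  relative clasper length once body size is removed?
* **within a species over ontogeny** — when do claspers begin their rapid
  growth, do male pectoral fins change more (and differently) than female
  fins between immature and mature stages, and does the endoskeleton show
  its own allometric dimorphism?

Fin outlines enter as ordered 2-D landmark configurations (by default 35
points along the outer fin margin: two fixed anatomical endpoints — the
anterior tip of the propterygium and the posterior fin insertion — and 33
sliding semilandmarks between them). Because semilandmarks have no
point-to-point homology along the curve, they are allowed to slide along
their local tangent during superimposition.

## Superimposition model

Generalized Procrustes analysis removes translation, scale and rotation:
each configuration is centered, scaled to unit centroid size
(`CS = sqrt(sum of squared landmark distances from the centroid)`), and
rotated by the closed-form 2-D orthogonal solution onto the running
consensus; the consensus is the coordinate-wise mean re-scaled to unit
centroid size, and the loop repeats until the consensus moves less than
`tol = 1e-8` in Procrustes distance. Reflections are never allowed;
left-side fins are reflected to right-facing beforehand
(`reflect_configuration()`), which preserves landmark order and hence
homology.

**Sliding.** After the alignment converges, each semilandmark slides along
its tangent — the unit chord from its preceding to its following landmark —
by the scalar that minimizes its squared distance to the consensus (the
closed-form projection of the residual onto the tangent), with the
Procrustes-distance criterion rather than bending energy; the shapes are
re-normalized, re-aligned, and the alignment loop re-converged.

Two numerical choices here deserve explanation, because the obvious
algorithm is unstable:

* **Sliding passes are fixed in number (default 2), not iterated to a
  fixed point.** The sliding problem has a near-neutral mode in which all
  semilandmarks, and the consensus with them, creep together along the
  outline: iterating slide-against-consensus to convergence contracts at
  roughly 0.99 per iteration while the shapes slowly lose the very signal
  being measured, and the landing point depends on input order. A small
  fixed number of passes captures the tangential correction (the first
  pass already recovers noise-free displacement magnitudes to well under
  1%) without admitting the creep.
* **Sliding is anchored at the digitized coordinates.** Every pass
  re-slides each configuration from its original aligned position toward
  the current consensus, so tangential displacements cannot accumulate
  across passes. With both choices the consensus is reproducible across
  input orderings to ~1e-12.

Shapes are used as-is after superimposition (tangent-space projection is
omitted); at the shape scales involved the difference is far below test
tolerances. This is a documented limitation, not a claim of equivalence.

## Shape vectors, angles, and the scaled-vector PCA

Dimorphism for a species is the vector between its female and male shapes
in the common aligned frame, oriented **female to male** throughout. Its
length
`L = sqrt(sum over all 2k coordinates of squared differences)`
is exactly the Procrustes distance between the endpoints, and measures the
magnitude of dimorphism. The *manner* of shape change is compared through
angles: `theta = arccos` of the dot product of unit-normalized vectors, in
the full dimensionality of the data.

Angles are measured against a common baseline: the shape-change vector
between the predicted shapes at the minimum and maximum observed scores of
a principal component (`baseline_vector()`), by convention PC 2 when the
sex-separating axis is known, or the axis chosen by `sex_axis()` — the PC
with the largest standardized female-male score separation — when it must
be found from the data. PCA loadings carry a deterministic sign convention
(largest-magnitude component positive, ties broken toward the lowest
index), so the baseline orientation is reproducible; because flipping the
baseline maps every angle to its supplement `180 - theta`, the per-species
table reports both, along with the total range of each.

With one specimen per sex per species there is no within-species variance
to test against, so interspecific lengths and angles are reported
descriptively. The scaled-vector PCA divides every vector by its length
before the decomposition, displaying variation in *direction* only.

## Trajectory analysis over ontogeny

In the single-species design, maturity classes make two-point trajectories:
each group's (e.g. each sex's) shape path from its stage-1 mean to its
stage-2 mean. `trajectory_statistics()` reports the two path lengths, their
absolute difference `delta_L` and ratio, and the angle `theta` between the
two direction vectors. Significance comes from residual randomization
(`permutation_test()`): fit the no-interaction reduced model (grand mean +
group effect + stage effect) to the flattened shapes, permute whole
specimen residual vectors across all specimens with a seeded generator, add
them back onto the reduced-model fitted values, recompute both statistics,
and count `p = (1 + #permuted >= observed) / (n_perm + 1)` — one-sided,
large values extreme, with the observed value included so p is never zero.
A raw label-shuffling scheme (`scheme = "labels"`) is kept for sensitivity
analysis. The entire permutation stream is controlled by one integer seed
and recorded in the result, making every p-value bit-reproducible.

**Known limitation.** The `delta_L` test is well calibrated (type-I error
~0.05-0.07 in the calibration suite). The `theta` p-value is calibrated
only when the trajectories are clearly nonzero: under a weak-signal null
the stage effect refitted to permuted data absorbs resampled residual
noise, which shrinks the permuted angles below the observed near-90° value
and makes the angle test anticonservative. This behavior is intrinsic to
the residual-randomization angle statistic; interpret `p_theta` only
alongside clearly significant trajectory magnitudes.

## Comparative statistics

**Size standardization.** Clasper lengths are standardized as ordinary
least-squares residuals of log clasper length on log pectoral centroid
size. An option to use phylogenetic residuals instead is deliberately out
of scope for the standardization step; the choice is flagged in the
function documentation.

**PGLS.** Dimorphism magnitude is regressed on the clasper residuals with
error covariance proportional to shared phylogenetic path lengths under
Brownian motion (`C = ape::vcv(tree)`), the minimal covariance model when
none is stated; no Pagel's lambda estimation is attempted. Estimation uses
the whitened normal equations via the Cholesky factor of `C`; the slope is
tested by F against the GLS intercept-only model, with
`R2 = 1 - RSS/TSS` (both GLS-weighted). On a star phylogeny the fit
reduces exactly to OLS, and the implementation matches `nlme::gls` with a
Brownian correlation to machine precision in the test suite. Species
without clasper data are dropped with a logged warning, never imputed.

**Allometric ANCOVA.** For each endoskeletal trait the model
`trait ~ sex + log_dw + sex:log_dw` is fitted and the interaction F-tested
at `alpha = 0.05`; only when slopes cannot be distinguished is the additive
model refitted and the sex main effect reported as `p_sex` — the standard
slopes-then-elevation hierarchy. Raw per-trait p-values are reported, with
no multiplicity correction across the nine traits, matching the reporting
convention of the analysis this package operationalizes.

**Maturity breakpoint.** The clasper-growth inflection is estimated by
continuous two-segment (hinge) least squares: candidates are the midpoints
between consecutive sorted unique disc widths *and* the interior observed
widths themselves (so a hinge lying exactly on a sampled size is
representable), each needing at least three points strictly on either
side; the SSE-minimizing candidate wins, ties toward the smaller value.
Maturity is then a strict rule: disc width **greater than** the threshold
is mature. The same cutoff is applied to females, where preserved
specimens offer no independent maturity diagnostic.

## The synthetic-data generator

No landmark data are deposited with the study this package reimplements,
so the generator (`synthetic_spec()`, `simulate_*()`) stands in for the
museum-specimen images. Its defaults *are* the study conditions: 35
landmarks (33 sliding), 21 species, an ontogenetic series of 21 males and
22 females over 50.6-109.5 mm disc width, a clasper-growth hinge at 84 mm
(shallow slope 0.05, steep slope 1.2, noise 0.5 mm), male maturation shape
change three times the female change, and per-species dimorphism
magnitudes `seq(0.05, 0.25)` — a five-fold range whose endpoints match the
two-species recovery benchmark. Each output draws from its own RNG stream
split deterministically from one master seed, so generating one file never
perturbs another, and every dataset is byte-reproducible.

Key design choices:

* **Template outline.** A unit half-disc with k points at exactly equal
  arc length stands in for the fin margin — the equal spacing is this
  package's choice, not an assertion about how the original outlines were
  digitized.
* **Deformation fields are pointwise-normal with similarity-orthogonal
  weights.** The dimorphism field u displaces each landmark along the
  outline's outward normal with a single-harmonic weight profile
  (`sin 2*theta`: a smooth anterior concavity and posterior lobe
  expansion, the qualitative anatomy of male fins); the weights are
  projected orthogonal to the translation/rotation/scale directions. Both
  properties matter: similarity components would be silently removed by
  superimposition, and tangential components would be eaten by sliding. A
  magnitude-d displacement therefore survives the full pipeline as a
  Procrustes-scale change of (almost exactly) d. At the largest default
  magnitude (d = 0.25) the displacement is big enough to rotate outline
  chords, and sliding legitimately removes ~10% of it — a real geometric
  effect, visible in the recovery tests, not an implementation artifact.
  Narrow Gaussian bumps were rejected because their steep gradients lose
  12-20% even at moderate magnitudes.
* **Species shape evolution is isotropic Brownian motion directly on the
  landmark coordinates** (rate 1e-4 per unit tree depth), with a
  brute-force self-intersection guard. Isotropy spreads interspecific
  variance thinly across all shape axes, so — unlike in the empirical
  system, where interspecific variation dominates PC 1 — the
  sex-differentiating axis here is usually PC 1 with a large variance
  share. The pipeline therefore finds the baseline axis by sex-score
  separation rather than assuming PC 2. Passing tests on these data shows
  the machinery recovers what the generator put in; it does not show that
  real fin data meet the model's assumptions.
* **Dimorphism magnitudes are arranged on the tree like an evolving
  trait**: the supplied magnitude set is assigned to species by
  rank-matching a Brownian draw, so the PGLS error model sees
  approximately the covariance it assumes. With uniformly spaced (rather
  than Gaussian) magnitude values the match is approximate, and the PGLS
  p-value on fully synthetic runs retains mild excess mass near zero; the
  calibration tests therefore use exact Gaussian Brownian simulations,
  where type-I error is within the expected envelope.
* **Digitizing noise** is iid Gaussian per coordinate, default sd 0.005 in
  units of the template radius (~0.5% of the outline scale, a realistic
  digitizing error). Real digitizing error is autocorrelated along the
  outline and the generator does not emulate that.
* **Ontogeny.** All specimens share an allometric deformation growing with
  log disc width (scale 0.01 per log-unit, along a field orthogonal to u);
  specimens above the breakpoint add a maturation deformation along u
  proportional to disc width beyond it, three times stronger in males.
  Immature males and females are therefore identical up to noise — the
  generator's dimorphism is entirely maturation-driven, which is why the
  synthetic mature/immature dimorphism ratio is far larger than an
  empirical one would be.

## Problem sizes and tolerances

The test suite and acceptance checks run at deliberately modest sizes
chosen to give stable Monte-Carlo estimates: 200 replicates for
calibration bands (type-I error asserted within [0.02, 0.09] at alpha =
0.05), 100-200 replicates for power properties, 999 permutations inside
simulated tests (the analysis default is 10,000, the convention of the
permutation procedure it follows), 50-leaf trees for PGLS calibration, and
20-species samples for recovery properties. Recovery of the trajectory
length ratio is asserted on the median of five replicate designs because a
single 43-specimen draw sets each cell's maturation exposure with ~15%
sampling variability. Numerical tolerances follow the property being
checked: 1e-12 for algebraic identities, 1e-6 against brute-force grid
oracles, 1e-9 for linear-model equalities.

## Known limitations

* Procrustes-distance sliding only; bending energy is reserved as a future
  criterion switch.
* 2-D outlines only; no missing-landmark estimation.
* The angle permutation test's weak-signal anticonservativeness, above.
* The generator's isotropic Brownian shape evolution cannot reproduce the
  empirical ordering of interspecific vs sex axes in the PCA.
* Single-axis baselines: angles are measured to one PC axis at a time.
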