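---
title: "Quantifying Elongate dendritic phytoliths: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Elongate dendritic phytoliths: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of what it computes and why the
pieces are built the way they are. It complements the reference pages: those
say *what* each function returns, this explains the underlying model, the
parameters that matter, and the decisions taken where the methodology was
genuinely open.

## The measurement model

An Elongate dendritic phytolith is an elongated silica body from a grass
inflorescence carrying branched processes along its two long margins. The
package treats a phytolith as a closed triangle surface mesh with
coordinates in micrometres and derives three kinds of information from it.

**Geometry.** The mesh is first oriented by a PCA of its surface vertices,
so that axis 1 is the ~length, axis 2 the ~width and axis 3 the ~height.
PCA on raw vertices assumes vertex density is roughly even over the
surface; when it is not (e.g. adaptively decimated meshes),
`orient_mesh(resample_surface_n = )` switches to uniform area-weighted
surface samples. Size and shape traits are then elementary: volume by the
divergence theorem on watertight meshes (voxel volume `count * pitch^3`
otherwise), convex hull volume from a quickhull construction, solidity and
sphericity as the usual normalized ratios, extents and coordinate SDs along
the oriented axes. Elongation and flatness are defined as `1 - width/length`
and `1 - height/width`, both in `[0, 1)` with 0 meaning equant; plain ratios
are an equally defensible convention, and the complement was chosen so that
"more elongate" means a larger number.

**The core body.** Branching traits need a reference "trunk". The core body
is defined operationally: voxelize the solid at pitch `p`, apply a
morphological opening with a Euclidean ball of radius `r_open`, keep the
largest connected component, and surface it by marching tetrahedra. Opening
is the standard operator that removes protrusions thinner than about
`2 * r_open` while leaving the main body intact; it is parameterized
precisely so its effect can be studied. The original workflow this package
reimplements did not publish its core-body construction, so this definition
is this package's own, and core sensitivity to `r_open` should be checked on
new material.

Two caveats follow directly from the definition. First, the opening erodes
any surface feature whose curvature radius is below `r_open`, including the
sharp long margins of very flat bodies; geodesic distances then start from a
slightly receded core and branch lengths are inflated. Keep `r_open` below
the margin curvature radius (half-width² / half-height, for an elliptical
cross-section) when possible. Second, the core is deliberately *not*
re-oriented: its extents are measured in the whole phytolith's frame so that
`CoreMaxWidth` is directly comparable with `MaxWidth`.

**Topology.** The branching architecture is summarized by the geodesic
distance field `f` from every mesh vertex to the core (multi-source Dijkstra
on the edge graph, edge weight = Euclidean length; sources are vertices
inside the core or within `eps` of it, default one voxel pitch). Sweeping a
threshold from `max f` down to zero and tracking connected components of the
superlevel sets gives the 0-dimensional persistence barcode: a component is
born at a branch tip and dies where it merges into an older component (elder
rule; equal births resolved toward the lower vertex index so results are
deterministic). The essential component — born at the global maximum, dying
at 0 — is the phytolith's longest process and is counted as a branch.

From the barcode: `DendriticNumber`, `AverageDendriticLength` and
`DendriticTotalLength` use all bars with persistence at least `min_persist`
(default 1 µm — the same floor as the CC curve — which suppresses
voxel-scale noise bars that appear as small bumps on the reconstructed
surface). `DendriticDensity` divides the count by `CoremaxLength`; the
normalizing length is a package choice (branches per µm of core length) and
is exposed as an argument. Sub-branches (bars with death > 0) count as
branches in their own right: the barcode is taken as *the* branch summary.

The CC curve counts components of `{f > d}` at d = 20, 19, …, 1 µm
(`CC_1` … `CC_20`), i.e. branches *longer than* d — the inequality is strict
so exact ties are excluded. Counting is done independently of the barcode,
by labelling the thresholded subgraph at each level; the test suite
cross-validates the two implementations against each other and against a
brute-force oracle. One subtlety: CC curves are monotone non-decreasing for
fields whose branches merge next to the core (below the 1 µm floor), which
is the geometry this pipeline produces; it is *not* a theorem for arbitrary
scalar fields, where a saddle above the floor can merge two branches and
decrease the count. Real phytoliths with sub-branching above 1 µm can
exhibit this.

Whole-cohort branching similarity uses the exact bottleneck distance between
barcodes (L∞ matching with erasure to the diagonal at cost persistence/2).
Feasibility at a candidate radius is decided by bipartite matching; by the
Mendelsohn–Dulmage theorem it suffices that each diagram's "required" points
(persistence/2 above the radius) can be saturated separately, which keeps
the matching graphs small. The distance matrix is embedded by classical MDS
(double-centring + eigendecomposition), keeping the top 20 axes with
positive eigenvalues, zero-padded when fewer exist, signs fixed by
non-negative skewness. Bottleneck distances are generally non-Euclidean, so
some eigenvalues are negative; the embedding error they induce is reported
as a stress value in the pipeline manifest.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `pitch` | 0.5 | µm | voxel edge; must keep ≥ 4 voxels across the thinnest axis |
| `r_open` | 2.0 | µm | opening ball radius; removes branches thinner than ~4 µm |
| `eps` | `pitch` | µm | geodesic source tolerance around the core |
| `min_persist` | 1.0 | µm | persistence floor for a bar to count as a branch |
| `corr_threshold` | 0.90 | – | \|r\| above which traits are grouped and pruned |
| `n_components` | elbow | – | rotated components kept for the regressions |
| `ntree`, `mtry` | 500, ⌊√p⌋ | – | Random-Forest defaults |

Voxel volumes converge at O(pitch); halving the pitch changes volumes by
under 3% on the fixtures, and tetrahedron and voxel volumes agree within 3%
at pitch ≤ height/10. The scree "elbow" is automated as the point of maximum
perpendicular distance from the chord joining the first and last
eigenvalues; when that point lies below the chord it is the first component
that adds little variance, so retention stops just before it. This makes a
3-factor simulation select k = 3, and `n_components` overrides the
automation.

## The synthetic generator

`make_phytolith_mesh()` builds a watertight mesh as the voxel union of an
elongated capsule (elliptical cross-section, ellipsoidal caps) and
cone-shaped branches placed along both long margins, surfaced by marching
tetrahedra on a signed distance field; voxel union avoids fragile boolean
mesh operations. Defaults — 25 × 8 × 6 µm core, three branches per margin,
log-normal branch lengths around 8 µm, base radius 1.2 µm, tip radius
0.6 µm, pitch 0.5 µm — give bodies at the scale of real Elongate dendritic
and margins whose curvature radius (2.25 µm) stays above the default
`r_open`, so the core body is recoverable by construction. The ground truth
records each branch's axial length from the core surface, with overlapping
branches merged (and warned about).

`simulate_cohort()` draws trait vectors as taxon mean + sample effect +
residual, all Gaussian, with planted domestication/ploidy shifts and
optional class imbalance — a parametric stand-in whose effect sizes and
variances are exactly known, which is what type-I and power checks need.
Defaults (6 lineages × 2 species × 2 subspecies, 3 samples per taxon,
20 phytoliths per sample, between:within SD of 1:2) mirror a design in which
about 20–25 usable meshes per inflorescence sample are available and
within-sample variation dominates.

What the generator does **not** emulate: real trait distributions are
neither Gaussian nor independent across traits (CC entries are integer
counts with strong serial dependence); surface ornamentation, broken or
dissolved branches, articulated silica skeletons, segmentation artefacts and
between-accession variation are absent; branches are straight cones, never
curved or re-branching. Passing tests therefore demonstrate that the
*algorithms* are correct and the *statistics* calibrated under known
conditions — not that any particular accuracy will hold on confocal
material.

## Statistical stages

The sample-level pipeline averages traits within inflorescence samples,
prunes redundant traits (connected components of the \|r\| > 0.90 graph;
the retained representative is the member most correlated with its group,
ties alphabetical; zero-variance traits are dropped with a warning), then
computes PCA with Kaiser-normalized varimax rotation (tolerance 1e-6,
regression-method scores, components ordered by post-rotation variance with
a deterministic sign). Orthogonality means communalities are preserved —
asserted to 1e-8 in the tests.

Domestication is a binary logistic model with "domesticated" as the
reference level, so a positive coefficient means higher odds of being wild.
Odds-ratio CIs are profile-likelihood by default: with few events the Wald
interval `exp(B ± 1.96 SE)` can be visibly asymmetric relative to the
likelihood, and published intervals of this kind are generally profile
intervals. Perfect separation is detected and raised as an error instead of
returning a silently divergent fit. Ploidy uses a proportional-odds
cumulative-logit model (diploid < tetraploid < hexaploid); the
intercept-only reference likelihood has a closed form, and when only two
levels are observed the model reduces (exactly) to binary logistic
regression, which is what the implementation then fits. Mixed
wild/domesticated and mixed-ploidy taxa are not modelled: each taxon must
carry a single label, a simplification that should be kept in mind when
labels are uncertain.

LDA applies the same preprocessing, then Fisher discriminants with
proportional priors; accuracy is resubstitution by default (`cv = TRUE`
gives leave-one-out) and is compared against the no-information rate with a
one-sided exact binomial test. Resubstitution accuracy is optimistically
biased, which matters for null data; the tests use the cross-validated
accuracy for null calibration for exactly that reason.

Phylogenetic signal: Pagel's λ is fitted by ML over `[0, 1]` under the GLS
model with covariance `σ²(λ C_offdiag + diag(C)) + diag(se²)`. Without
observation error the likelihood reduces, via
`V_λ = D^{1/2}(λ C̃ + (1-λ) I) D^{1/2}`, to a single symmetric
eigendecomposition per tree with O(n) evaluations per λ. The asymptotic
test against λ = 0 uses the 50:50 χ²₀/χ²₁ boundary mixture, but at
realistic tip counts the estimate sits exactly at 0 far more often than the
asymptotic one-half, so that test is conservative; `n_boot > 0` adds a
parametric-bootstrap p-value (the LR under λ = 0 is a pivot, so null
replicates are iid normal draws), which holds its nominal size and is the
recommended test. A star phylogeny leaves λ unidentifiable and is flagged
rather than estimated. The multivariate statistic `k_mult` generalizes
Blomberg's K to a trait matrix (ratio of among-species to phylogenetically
corrected variation summed over traits, scaled by its Brownian expectation,
so K ≈ 1 under Brownian motion), with significance from permuting species
across tips and the effect size Z from the permutation distribution — Z, not
the raw K or λ, is the comparable quantity across trait sets of different
dimension. An eigen-analysis of a phylogenetic-signal matrix with
trace/determinant summaries is a related published approach that this
package deliberately does not implement: its internals are not fully
specified in the sources available, and guessing them would produce
unverifiable numbers.

Classification follows a fixed protocol: classes under 20 phytoliths are
dropped; classes with more inflorescence samples than `trim_cap` lose whole
samples (largest first, seeded tie-break) whose phytoliths become
`test_other` — a stricter evaluation set of specimens never seen in
training; remaining samples are each split 60/20/20 by a seeded draw with
largest-remainder rounding, so stratification is at the inflorescence-sample
level. Forests use CART trees with the Gini criterion, 500 trees and √p
features per split — common defaults, stated because the original protocol
did not publish its hyperparameters. Evaluation reports accuracy, Cohen's κ,
the NIR and an exact one-sided binomial test (exact rather than
normal-approximate, since the interesting p-values are small at modest n).
PH coordinates are excluded from the default predictor set (geometric +
branching + CC): CC carries the same information at far lower cost, which is
also why only one of the two branching summaries enters the model at a time.

## Numerical details and degenerate inputs

- Duplicate vertices are merged at 1e-6 µm; zero-area faces and unreferenced
  vertices are dropped on load.
- Orientation requires a full-rank vertex covariance; collinear/coplanar
  inputs raise a "degenerate orientation" error naming the deficient axis.
  Axis signs use the third central moment (ties fall back to the world
  axes), and det(R) = +1 is enforced by flipping axis 3.
- Solid voxelization of watertight meshes marks voxels whose centre is
  inside (x-ray parity with jittered rays to dodge edge ties); non-watertight
  meshes fall back to an exterior flood fill, and a fill that leaks into the
  interior raises an "open surface" error with the leak count.
- The quickhull tolerance scales with the bounding box (1e-10 × extent);
  collinear and coplanar point sets are rejected explicitly.
- Bottleneck distances are exact: the answer is one of the finitely many
  point-point or point-diagonal costs, found by binary search with matching
  feasibility at each candidate.
- All generators take explicit seeds and restore the caller's RNG state, so
  identical seeds give byte-identical meshes, cohorts and trees.

## Problem sizes used by the tests

The test-suite simulations were sized to give stable Monte Carlo estimates:
50 synthetic meshes for branch-recovery rates, 200 replicates for each
type-I calibration (with 99 bootstrap/permutation draws inside each λ/K
test), 2000 replicates for the ±2 SE coverage of the planted logistic
effect (its true coverage, ~96%, sits close enough to the 95% threshold
that smaller runs are coin flips), and 20 seeded cohorts for the
generalization comparison between the test and `test_other` sets.

## Known limitations

- The core body is an operational definition; `r_open` has no published
  value and results on flat, sharp-margined material depend on it.
- Branch lengths are geodesic persistences along the reconstructed surface:
  they include the path around the branch base and small staircase effects,
  biasing lengths upward by a few percent relative to axial ground truth.
- Only 0-dimensional persistence is computed; loops and voids (rare in this
  morphotype) are invisible.
- The MDS embedding of bottleneck distances is not isometric; PH coordinates
  should be read as an approximate shape space.
- Classification accuracy on synthetic cohorts says nothing quantitative
  about accuracy on real confocal material; it validates the protocol, not
  the biology.
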