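---
title: "Topological descriptors of airway trees: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological descriptors of airway trees: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungtda)
```

## The model

COPD remodels the bronchial tree: airways narrow and drop below the CT
resolution limit, and regional air trapping distorts the trajectories of the
branches that remain visible. `lungtda` quantifies this with persistent
homology on two kinds of filtrations built from segmentation products.

**Height filtration on the centerline graph.** The tree is an embedded graph
in mm coordinates with the third axis pointing toward the head ("top" =
larger z). The depth function `f(v) = z_max − z(v)` is assigned to vertices;
every edge takes the maximum of its endpoints, so the sublevel set
`X_h = {f ≤ h}` is exactly the part of the tree above the horizontal plane at
depth `h`. As the plane slides downwards, connected components appear and
merge; the degree-0 barcode (Z/2 coefficients) records each component as a
bar. A component born anywhere other than the global top of its tree is a
branch segment that has turned to grow *upwards*: the number of finite bars
is the **upwards complexity**. The essential bar (one per connected
component of the graph) represents the whole tree, not a trajectory change,
and is excluded from the count. Directional complexity in any direction is
the same computation after rigidly rotating the tree (fixed-axis rotations
`Rz·Ry·Rx`, right-hand rule).

**Alpha filtration on point clouds.** Thickening a point set with balls of
radius `r` is modelled by the alpha complex: the subcomplex of the Delaunay
triangulation whose simplices have critical circumscribing radius at most
`r`. Degree-1 bars `(r1, r2)` on the centerline nodes are loops created when
two branches come within `2·r1` of each other and filled at `r2`; their total
length `Σ (r2 − r1)` is the **branch-to-branch proximity**. Degree-2 bars on
the voxelized lobe + airway luminal surfaces are enclosed voids; they
describe how the airways fill the lobar cavity at every scale at once, which
is what makes the descriptor informative below the nominal resolution of the
scan. All alpha values are stored in radius units (mm) — square roots of the
squared-radius convention — so that degree-1 and degree-2 bar endpoints are
physical lengths.

**Comparing scans.** Barcodes are compared by the bottleneck distance
(max-cost optimal matching, diagonal cost = persistence/2) and the
Wasserstein-2 distance (power-mean cost, same ground metric), turned into a
cohort geometry by classical MDS, and summarised by pairwise two-sample
Kolmogorov–Smirnov statistics and Pearson correlations.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `emphysema_score(threshold_hu)` | −950 HU | low-attenuation cutoff; the conventional inspiratory value. No single standard exists, so it is exposed as an argument and CLI flag. |
| `bottleneck_distance(relative_error)` | 1e-4 | accepted relative approximation error. The implementation binary-searches the finite candidate cost set with exact feasibility tests, so the returned value is exact up to floating point and satisfies any positive tolerance; the argument is kept for interface compatibility and provenance. |
| `wasserstein_distance(order)` | 2 | cost exponent. |
| `alpha_filtration(jitter_seed)` | 1 | seed of the symmetry-breaking jitter (see below). |
| `voxel_volume(spacing)` | 0.7 mm | isotropic voxel edge of thin-slice chest CT. |
| `tree_gen_params()` | see below | synthetic-tree generator conditions. |

## Numerical choices

* **Tie-breaking in the sublevel sweep.** Vertices are ordered by (value,
  node id) and every edge after any vertex of equal value; merges follow the
  elder rule with the processing rank as the deterministic tiebreak.
  Zero-persistence pairs (birth = death) are dropped everywhere — on a tree,
  every vertex that is not a local minimum of `f` is immediately paired with
  an adjacent edge of equal value, and dropping those pairs is exactly what
  makes "finite bars = upward turns" true (and, with components, equal to
  the number of local minima).
* **Essential bars.** Infinite deaths are capped before distances or total
  persistence are taken (`cap_barcode()`), by default at the maximum
  filtration value of the generating construction — the bounding-box depth
  for height filtrations. The cap is recorded in the barcode provenance.
  Whether essential classes should enter the Wasserstein comparison at all
  is a genuinely open convention; capping at a construction-intrinsic scale
  keeps the comparison total while giving the essential bar a meaningful
  (depth-of-tree) coordinate.
* **Delaunay step and degeneracies.** The Delaunay triangulation is
  delegated to qhull (via the pre-installed scipy), the standard robust
  implementation; everything downstream — critical-radius assignment
  (circumradius + Gabriel/attachment propagation), boundary-matrix
  reduction, matchings — is implemented in the package (R + Rcpp). Voxel
  grids are maximally degenerate inputs: exactly cocircular and cospherical
  quadruples abound. Three measures keep the computation correct:
  (i) rank-deficient clouds (collinear, coplanar) are detected by SVD
  (relative tolerance 1e-7) and triangulated inside their affine hull in
  the intrinsic dimension, matching the behaviour of exact-arithmetic alpha
  implementations — a jitter into 3D would instead create near-flat
  tetrahedra with essentially unbounded circumspheres;
  (ii) a deterministic seeded jitter of `max(1e-6 × bbox diagonal, 1e-4 mm)`
  is applied inside the hull before triangulation — the floor exists
  because the tie-broken circumsphere of a cocircular voxel quadruple has
  radius inversely proportional to the jitter, and a jitter much below a
  tenth of a micron leaves those configurations numerically unresolvable in
  double precision;
  (iii) filtration values are clamped during assignment so that no face
  ever exceeds a coface (the clamp is a no-op in exact arithmetic and
  removes the spurious features that misclassified near-degenerate
  attachment tests would otherwise create).
* **Exactness of distances.** Bottleneck feasibility is decided by a 0/1
  assignment problem, Wasserstein by the exact linear assignment problem on
  the diagonally padded cost matrix (`clue::solve_LSAP`); neither is
  iterative or tolerance-dependent.
* **MDS determinism.** Classical (Torgerson) scaling via double-centering
  and the top-2 eigenpairs (`stats::cmdscale`), with each axis's sign fixed
  so its largest-magnitude coordinate is positive. Embeddings are meaningful
  up to rigid motion; the sign rule only pins a representative.
* **KS variant.** Two-sided two-sample tests with the exact p-value when
  `min(n1, n2) ≤ 25` and the asymptotic approximation otherwise. Raw
  pairwise p-values are reported (each group pair on its own); Holm
  correction is available behind a flag.
* **Degenerate inputs.** Trees with fewer than 2 nodes return 0 for all
  complexity features rather than erroring, keeping cohort tables total;
  proximity of clouds with fewer than 4 distinct points is 0 with a warning
  (no 1-cycle can exist).

## What the synthetic generator emulates

`generate_airway_tree()` grows a dichotomous tree downward: branch lengths
`N(20, 2.5)` mm at the trachea decaying by 0.8 per generation, branching
angles `N(30°, 8°)`, uniform arc-length sampling at 0.35 mm by default
(clinical centerlines carry hundreds of points between branch points — the
vertex-count length proxy is only meaningful at fixed sampling density, so
the generator enforces the spacing exactly and stamps it into provenance).
Upward deflections — the ground truth for upwards complexity — are Poisson
events per branch (`upward_turn_rate`) that bend a 4-node sub-segment to
ascend before the branch resumes its descent; ordinary growth is clamped to
a minimum downward slope so that a zero-rate tree has upwards complexity
exactly 0. An event log records branch, bifurcation, per-generation node
and inserted-turn counts.

`generate_cohort()` fixes the study conditions for the four severity groups:

| group | generations | turns/branch | emphysema fraction |
|---|---|---|---|
| HNS | 7 | 0.30 | 0.03 |
| HS | 6 | 0.40 | 0.06 |
| Mild | 5 | 0.55 | 0.10 |
| Mod | 4 | 0.75 | 0.18 |

Advancing severity is modelled as fewer visible generations (airway
narrowing below the resolution limit) with more trajectory distortion per
remaining branch — a simulation hypothesis, not a clinical claim. Cohort
trees are sampled at 0.7 mm (the voxel size), uniformly across all scans.
Each participant's tree is rescaled so its inspiratory bounding-box depth is
42 mm per metre of body height (`N(1.70, 0.08)` m), tying airway-tree size
to stature; this both makes the height-normalized variants meaningful and
keeps within-group size variation at its physiological scale rather than at
the (much larger) scale of unconstrained random growth.

The expiratory phase is derived from the inspiratory tree by
`expiratory_transform()`: a uniform contraction of 0.75 about the root
(expiration costs roughly a quarter of lung height) followed by branch
buckling — a seeded sinusoidal lateral deflection of each branch segment
(amplitude 3 mm, wavelength 10 mm, tapered to zero at segment ends).
Buckling was chosen deliberately: a uniform contraction scales every
degree-1 bar linearly and therefore *lowers* proximity, and a smooth global
"crowding" field is locally just a scaling with the same effect. Buckled
branches oscillate toward and away from their neighbours, creating earlier
contacts and later fills, so expiratory proximity exceeds inspiratory
proximity by construction. Because the deflection is horizontal, the
expiratory height barcode differs from the inspiratory one only by the
contraction, which is what the Wasserstein-2 MDS embedding separates.

Phantoms (`generate_lung_phantom()`) are hollow ellipsoid shells with
embedded hollow tubes, plus a parenchyma HU volume (`N(−850, 25)`, clamped
above −940) in which an exact configured fraction of voxels is set below
−950 HU in blob-shaped pockets; a hollow-sphere option (inner radius = the
void's death radius) calibrates the degree-2 descriptor.

**What the generator does not emulate** — and hence what green tests do and
do not show: real centerlines carry segmentation noise, spurious branches
and anisotropic sampling; real lobes are not ellipsoids; real expiration is
a heterogeneous deformation, not contraction + buckling; and real cohort
effect sizes are unknown here. Passing tests demonstrate that the
*descriptors measure what they claim to measure* on inputs with known
ground truth and that the pipeline is deterministic and internally
consistent — not that any particular clinical effect size will be observed
on patient data.

## Problem sizes

The test suite and the acceptance script run everything at desk scale, as
the package's own choice of demonstration size: oracle cross-checks on 100
random trees (20–150 nodes) and point clouds of ≤ 25 points (where dense
boundary-matrix reduction is still exhaustive), 20 random diagram pairs of
30 bars for the bottleneck bound, 400-point sphere clouds, 2000-replicate
KS calibration with groups of 18 and 19, and an end-to-end cohort of 4 × 10
participants with paired phases (80 scans). The KS calibration group sizes
are those with the exact test's attainable level closest to 0.05 (0.0493),
so the measured null rejection rate is centred in its expected band.

## Known limitations

* Persistence is computed for degrees 0–2 only; degree ≥ 3, zigzag and
  vineyard variants are out of scope.
* The alpha filtration relies on a jittered double-precision Delaunay
  triangulation, not exact predicates; the jitter floor and monotonicity
  clamp make grid inputs safe in practice, but adversarial near-degenerate
  inputs could still produce bars perturbed at the jitter scale (~1e-4 mm).
* The emphysema score is computed volume-wise; some protocols average
  per-slice area percentages instead, which can differ on anisotropic
  disease distributions.
* Trees are assumed to arrive in scanner coordinates; no per-phase
  re-orientation is attempted before height filtrations.
* NIfTI origins are not round-tripped (phantom volumes are origin-0); only
  spacing is honoured.
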