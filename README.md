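# lungtda — topological radiomics for airway trees

`lungtda` computes persistent-homology descriptors of the bronchial tree and
lung cavities as seen in chest CT, for researchers studying structural lung
disease (in particular COPD stratification). Standard CT measures — airway
wall and lumen dimensions, low-attenuation area — look at airways one at a
time; the descriptors here instead condense the geometry of the *entire*
branching structure into a handful of numbers per scan, and into barcodes
that can be compared across scans.

The package operates on segmentation products, not on raw images: airway
centerline trees (SWC or CSV) and binary surface/mask volumes (NIfTI). Since
such patient data are rarely shareable, a first-class synthetic module
generates seeded airway trees, voxel phantoms and whole multi-group cohorts
with known ground truth, so that every stage of the pipeline is testable and
demonstrable without clinical data.

## The descriptors

Let `T` be the centerline tree, densely sampled (many vertices between
consecutive branch points), with the third coordinate pointing toward the
head.

* **Upwards complexity** — slide a horizontal plane down from the top of the
  scan and watch the part of `T` above the plane. With the depth function
  `f(v) = z_max − z(v)` on vertices (edges take the max of their endpoints),
  the sublevel sets `X_h = {f ≤ h}` form a nested family of graphs. Each
  finite bar `(h1, h2)` of the degree-0 persistence barcode (Z/2
  coefficients, elder rule) is one branch segment that turns to stretch
  *upwards* at depth `h1` and merges with an older component at `h2`. The
  count of finite bars is the upwards complexity; rotating the tree first
  (`directional_complexity`) measures any other direction.
* **Bronchial tree length** — the vertex count of `T` under uniform
  arc-length sampling, a proxy for total visible airway length; also the
  branch-point count (vertices with ≥ 2 children).
* **Branch-to-branch proximity** — thicken every centerline node into a ball
  of growing radius `r`. A loop that appears at radius `r1` (two branches
  touch) and fills at `r2` is a degree-1 bar `(r1, r2)` of the alpha-complex
  filtration on the node coordinates; the proximity is `Σ (r2 − r1)` in mm.
* **Void barcode** — from the binary volume of the lobe surface plus the
  airway luminal surface, take every 1-voxel as a point of R³ and compute
  the degree-2 alpha barcode: how the airways fill the cavity of the lobe,
  robust to the CT resolution limit that hides the small airways.
* **Baselines** — emphysema score (% of lung voxels below −950 HU,
  configurable) and lumen voxel count.

Barcodes are compared with the bottleneck distance (approximation contract
`|d_exact − d_approx|/d_exact < 1e-4`; the implementation is exact on the
candidate cost set) or the Wasserstein-2 distance (exact assignment
solution), embedded in 2D by classical (Torgerson) MDS, and group
differences are scored by pairwise two-sample Kolmogorov–Smirnov tests and
Pearson correlations.

## Worked example

```r
library(lungtda)
dir <- file.path(tempdir(), "demo")
man <- generate_cohort(dir, n_per_group = c(HNS = 3L, HS = 3L, Mild = 3L, Mod = 3L),
                       seed = 42)
tab  <- build_feature_table(man, dir = dir, seed = 42)
insp <- tab[tab$phase == "inspiratory", ]
insp[, c("participant_id", "group", "upwards_complexity", "tree_length",
         "branch_points", "proximity_mm")]
```

```
 participant_id group upwards_complexity tree_length branch_points proximity_mm
          HNS01   HNS                 31        1248            63    38.629558
          HNS02   HNS                 31        1228            63    52.280189
          HNS03   HNS                 35        1217            63    35.063206
           HS01    HS                 20         746            31    18.138515
           HS02    HS                 17         763            31    18.244726
           HS03    HS                 22         738            31    14.230012
         Mild01  Mild                  9         442            15     4.747708
         Mild02  Mild                  6         448            15     8.164120
         Mild03  Mild                 14         461            15     9.130750
          Mod01   Mod                 11         260             7     2.682375
          Mod02   Mod                 14         273             7     1.638284
          Mod03   Mod                 12         267             7     1.421205
```

Upwards complexity, tree length and proximity all fall as the simulated
severity rises (fewer visible generations, more distorted branches). The two
tree descriptors track each other closely across the cohort:

```r
pearson_correlation(insp, "upwards_complexity", "tree_length")
#  Pearson rho = 0.927 (p = 1.4e-05, n = 12)
ks_pairwise(insp, "tree_length")
#  group1 group2 ks   p n1 n2
#     HNS     HS  1 0.1  3  3   (all six pairs separate perfectly at this
#     ...                        toy size; p is limited by n = 3 per group)
```

and the expiratory phase — derived by contraction plus branch buckling —
has larger proximity than the inspiratory phase for every participant here
(12 of 12).

The same pipeline is scriptable from a shell via `inst/cli/lungtda`:

```sh
lungtda simulate  --out cohort --n-per-group 4,4,4,4 --seed 1
lungtda features  --manifest cohort/manifest.csv --out feat --seed 1 --diagrams diag
lungtda distances --diagrams diag --out dist --metric wasserstein2
lungtda embed     --distances dist/distances.csv --out emb --manifest cohort/manifest.csv
lungtda compare   --features feat/features.csv --feature upwards_complexity --out cmp
```

Every command takes explicit seeds, echoes its full configuration, and
reruns byte-identically.

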