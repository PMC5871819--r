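#' Scan metadata
#'
#' @param participant_id string.
#' @param group one of `"HNS"` (healthy non-smoker), `"HS"` (healthy
#'   smoker), `"Mild"` (GOLD 1), `"Mod"` (GOLD 2).
#' @param phase `"inspiratory"` or `"expiratory"`.
#' @param body_height height in metres (optional, used by
#'   [normalize_by_height()]).
#' @return a `scan_meta` object.
#' @export
scan_meta <- function(participant_id, group = c("HNS", "HS", "Mild", "Mod"),
                      phase = c("inspiratory", "expiratory"),
                      body_height = NA_real_) {
  group <- match.arg(group)
  phase <- match.arg(phase)
  if (!is.na(body_height) && body_height <= 0)
    stop("body_height must be positive (metres)")
  structure(list(participant_id = as.character(participant_id), group = group,
                 phase = phase, body_height = body_height),
            class = "scan_meta")
}

#' Upwards complexity
#'
#' The number of upward changes of trajectory of the airways: slide a
#' horizontal plane downwards from the top of the scan and count the finite
#' bars of the degree-0 barcode of the resulting nested graphs (the sublevel
#' filtration of the depth function). Each finite bar is a branch segment
#' that turns to stretch upwards and later merges, at its birth depth, with
#' a component seen earlier; the essential bar represents the whole tree and
#' is not a trajectory change. Trees with fewer than 2 nodes return 0.
#'
#' @param tree an `airway_tree`.
#' @return non-negative integer count.
#' @export
upwards_complexity <- function(tree) {
  if (nrow(tree$nodes) < 2) return(0L)
  b <- sublevel_barcode_deg0(tree, height_function(tree))
  n_bars(b, finite = TRUE)
}

#' Directional complexity
#'
#' Upwards complexity after rotating the tree by the given angles about the
#' fixed X, Y, Z axes (right-hand rule): the number of trajectory changes
#' towards the rotated "up" direction. `angles_deg = c(0,0,0)` is upwards
#' complexity; `c(180,0,0)` counts downward trajectory changes.
#'
#' @param tree an `airway_tree`.
#' @param angles_deg numeric 3-vector of rotation angles in degrees.
#' @return non-negative integer count.
#' @export
directional_complexity <- function(tree, angles_deg) {
  upwards_complexity(rotate_tree(tree, angles_deg))
}

#' Branch-to-branch proximity
#'
#' Quantifies how branches of the bronchial tree curve towards one another.
#' Every centerline node is thickened by a ball of growing radius; when two
#' branches come close enough a loop is created at radius r1 and later
#' filled in at radius r2. Each such loop is a degree-1 bar (r1, r2) of the
#' alpha filtration on the node coordinates, and the proximity is the sum of
#' r2 - r1 over all bars (the degree-1 total persistence), in mm. Fewer than
#' 4 non-degenerate points admit no 1-cycles and return 0 with a warning.
#'
#' @param tree an `airway_tree`.
#' @param jitter_seed seed for the alpha-complex symmetry-breaking jitter.
#' @return proximity in mm.
#' @export
branch_to_branch_proximity <- function(tree, jitter_seed = 1L) {
  pts <- unique(as.matrix(tree$nodes[, c("x", "y", "z")]))
  if (nrow(pts) < 4) {
    warning("fewer than 4 distinct nodes: no 1-cycles possible, proximity 0")
    return(0)
  }
  fc <- alpha_filtration(pts, jitter_seed = jitter_seed)
  total_persistence(persistence(fc, 1))
}

#' Degree-2 void barcode of a surface voxel volume
#'
#' Describes how the airways fill the cavity of the lobes: the binary
#' volume combining the lobe surface and the airway luminal surface is
#' converted to a point cloud (one point per 1-voxel) and the degree-2
#' barcode of its alpha filtration records the enclosed voids - their birth
#' and filling radii in mm.
#'
#' @param vol a binary `surface_labels` `voxel_volume`.
#' @param jitter_seed seed for the alpha-complex jitter.
#' @return a degree-2 `barcode` in `mm_radius` units.
#' @export
void_barcode <- function(vol, jitter_seed = 1L) {
  if (vol$kind != "surface_labels")
    stop("contract violation: void_barcode expects a surface_labels volume")
  pts <- voxel_to_pointcloud(vol)
  fc <- alpha_filtration(pts, jitter_seed = jitter_seed)
  persistence(fc, 2)
}

#' Emphysema score (percentage of low-attenuation lung)
#'
#' 100 x the fraction of lung-mask voxels whose attenuation is below the
#' threshold, computed volume-wise over the whole mask. The conventional
#' inspiratory cutoff of -950 HU is the default; the threshold is exposed
#' because protocols differ.
#'
#' @param hu an `hu_attenuation` `voxel_volume`.
#' @param lung_mask a binary `voxel_volume` aligned with `hu`.
#' @param threshold_hu attenuation threshold (default -950).
#' @return percentage in [0, 100].
#' @export
emphysema_score <- function(hu, lung_mask, threshold_hu = -950) {
  if (!identical(dim(hu$grid), dim(lung_mask$grid)))
    stop("contract violation: HU and lung mask grids are not aligned")
  inside <- lung_mask$grid == 1
  n <- sum(inside)
  if (n == 0) stop("contract violation: empty lung mask")
  100 * sum(hu$grid[inside] < threshold_hu) / n
}

#' Airway lumen volume (voxel count)
#'
#' The number of voxels inside the airways. The physical volume is
#' `count * prod(spacing)` cubic mm.
#'
#' @param lumen_mask a binary `voxel_volume`.
#' @return integer voxel count.
#' @export
lumen_volume <- function(lumen_mask) {
  sum(lumen_mask$grid == 1)
}

#' Normalize a feature by body height
#'
#' Divides a per-scan feature value by the participant's height in metres,
#' as done for spirometry-style normalization.
#'
#' @param value numeric feature value.
#' @param meta a `scan_meta` with `body_height` present.
#' @return value per metre.
#' @export
normalize_by_height <- function(value, meta) {
  h <- meta$body_height
  if (is.null(h) || is.na(h))
    stop("labelled data required: body height missing")
  if (h <= 0) stop("body height must be positive")
  value / h
}
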