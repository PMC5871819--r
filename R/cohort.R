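#' Height barcode of a tree
#'
#' Convenience composition: the degree-0 barcode of the sublevel filtration
#' of the depth-below-top function. Finite bars are upward trajectory
#' changes; the essential bar (one per connected component) can be capped at
#' the bounding-box depth with [cap_barcode()] for distance computations.
#'
#' @param tree an `airway_tree`.
#' @return a degree-0 `barcode` in `mm_depth` units.
#' @export
height_barcode <- function(tree) {
  sublevel_barcode_deg0(tree, height_function(tree))
}

#' Per-scan feature table from a cohort manifest
#'
#' Reads a cohort manifest (CSV or data.frame with columns participant_id,
#' group, phase, height_m, tree_path, volume_path) and computes the
#' per-scan radiomic features: upwards complexity, tree length (vertex
#' count, plus per-component counts for forests), branch points,
#' branch-to-branch proximity (mm), and - when volumes are present -
#' emphysema score and lumen voxel count, plus height-normalized variants.
#' Per-row failures are recorded in the `status` column and do not abort
#' the table.
#'
#' @param manifest data.frame or path to the manifest CSV.
#' @param dir base directory that the manifest's relative paths resolve
#'   against (defaults to the manifest's own directory).
#' @param seed master seed from which per-scan jitter seeds are derived.
#' @param emphysema_threshold HU threshold for the emphysema score.
#' @return a `data.frame` feature table, one row per (participant, phase).
#' @export
build_feature_table <- function(manifest, dir = NULL, seed = 1L,
                                emphysema_threshold = -950) {
  if (is.character(manifest)) {
    dir <- dir %||% dirname(manifest)
    manifest <- utils::read.csv(manifest)
  }
  dir <- dir %||% "."
  need <- c("participant_id", "group", "phase", "tree_path")
  if (!all(need %in% names(manifest)))
    stop("manifest parse error: need columns ", paste(need, collapse = ", "))
  bad_group <- setdiff(unique(manifest$group), c("HNS", "HS", "Mild", "Mod"))
  if (length(bad_group))
    stop("manifest parse error: unknown group label ", bad_group[1])
  key <- paste(manifest$participant_id, manifest$phase)
  if (anyDuplicated(key))
    stop("manifest parse error: duplicate (participant, phase) row: ",
         key[duplicated(key)][1])

  n <- nrow(manifest)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    mrow <- manifest[i, ]
    height <- if ("height_m" %in% names(mrow)) mrow$height_m else NA_real_
    out <- data.frame(participant_id = mrow$participant_id,
                      group = mrow$group, phase = mrow$phase,
                      height_m = height,
                      upwards_complexity = NA_integer_,
                      tree_length = NA_integer_,
                      branch_points = NA_integer_,
                      proximity_mm = NA_real_,
                      n_components = NA_integer_,
                      component_node_counts = NA_character_,
                      emphysema_pct = NA_real_,
                      lumen_voxels = NA_integer_,
                      upwards_complexity_per_m = NA_real_,
                      tree_length_per_m = NA_real_,
                      status = "ok")
    res <- try({
      tree <- read_tree(file.path(dir, mrow$tree_path))
      comp <- tree_component_ids(tree)
      out$upwards_complexity <- upwards_complexity(tree)
      out$tree_length <- tree_length(tree)
      out$branch_points <- branch_point_count(tree)
      out$proximity_mm <- suppressWarnings(
        branch_to_branch_proximity(tree, jitter_seed = derive_seed(seed, i)))
      out$n_components <- length(unique(comp))
      out$component_node_counts <- paste(sort(table(comp), decreasing = TRUE),
                                         collapse = ";")
      if (!is.na(height) && height > 0) {
        out$upwards_complexity_per_m <- out$upwards_complexity / height
        out$tree_length_per_m <- out$tree_length / height
      }
      vp <- if ("volume_path" %in% names(mrow)) mrow$volume_path else NA
      if (!is.na(vp) && nzchar(vp)) {
        hu_p <- file.path(dir, sub("_surface", "_hu", vp))
        lm_p <- file.path(dir, sub("_surface", "_lungmask", vp))
        lu_p <- file.path(dir, sub("_surface", "_lumen", vp))
        if (file.exists(hu_p) && file.exists(lm_p))
          out$emphysema_pct <- emphysema_score(
            read_volume(hu_p, "hu_attenuation"),
            read_volume(lm_p, "lung_mask"),
            threshold_hu = emphysema_threshold)
        if (file.exists(lu_p))
          out$lumen_voxels <- lumen_volume(read_volume(lu_p, "lumen_mask"))
      }
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      out$status <- paste("failed:", trimws(attr(res, "condition")$message))
    rows[[i]] <- out
  }
  do.call(rbind, rows)
}

#' Pairwise barcode distance matrix
#'
#' Computes all pairwise distances between a list of barcodes (homogeneous
#' degree and units) under the bottleneck or Wasserstein-2 metric. Each pair
#' is computed once and mirrored; the diagonal is exactly 0.
#'
#' @param barcodes list of `barcode`s; names become scan ids.
#' @param metric `"bottleneck"` or `"wasserstein2"`.
#' @param relative_error bottleneck approximation parameter.
#' @param cap if the barcodes contain essential bars, cap value passed to
#'   [cap_barcode()] (`NA` = use each barcode's own max filtration value).
#' @return symmetric numeric matrix with scan ids as dimnames and attributes
#'   `metric`/`params`.
#' @export
pairwise_distances <- function(barcodes,
                               metric = c("bottleneck", "wasserstein2"),
                               relative_error = 1e-4, cap = NA) {
  metric <- match.arg(metric)
  m <- length(barcodes)
  if (m < 1) stop("no barcodes")
  degs <- vapply(barcodes, `[[`, 0L, "degree")
  unis <- vapply(barcodes, `[[`, "", "units")
  if (length(unique(degs)) != 1 || length(unique(unis)) != 1)
    stop("contract violation: barcodes have mixed degrees or units")
  barcodes <- lapply(barcodes, function(b) {
    if (any(is.infinite(b$bars)))
      cap_barcode(b, cap = if (is.na(cap)) NULL else cap) else b
  })
  ids <- names(barcodes) %||% as.character(seq_len(m))
  D <- matrix(0, m, m, dimnames = list(ids, ids))
  if (m >= 2) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      d <- if (metric == "bottleneck")
        bottleneck_distance(barcodes[[i]], barcodes[[j]],
                            relative_error = relative_error)
      else wasserstein_distance(barcodes[[i]], barcodes[[j]], order = 2)
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "metric") <- metric
  attr(D, "params") <- list(relative_error = relative_error, cap = cap)
  D
}

#' Classical MDS embedding of a distance matrix
#'
#' Classical (Torgerson) metric multidimensional scaling: double-centering
#' of squared distances and the top-2 eigenpairs. The sign of each axis is
#' fixed so that its largest-magnitude coordinate is positive, making the
#' embedding deterministic; embeddings are meaningful up to rigid motion.
#'
#' @param d symmetric distance matrix (>= 3 scans) with id dimnames.
#' @return data.frame with columns `id`, `x`, `y`.
#' @export
mds_embed <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3)
    stop("contract violation: MDS embedding needs at least 3 scans")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  xy <- stats::cmdscale(d, k = 2)
  if (ncol(xy) < 2) xy <- cbind(xy, matrix(0, nrow(d), 2 - ncol(xy)))
  for (j in 1:2) {
    v <- xy[, j]
    if (any(v != 0) && v[which.max(abs(v))] < 0) xy[, j] <- -v
  }
  data.frame(id = rownames(d) %||% as.character(seq_len(nrow(d))),
             x = xy[, 1], y = xy[, 2], row.names = NULL)
}

#' Pairwise Kolmogorov-Smirnov group comparison
#'
#' Two-sided two-sample KS test of a feature between every pair of severity
#' groups: statistic sup |ECDF1 - ECDF2| (reported as |KS|) and p-value,
#' exact when min(n1, n2) <= 25, asymptotic otherwise. Raw pairwise p-values
#' are reported by default, matching the convention of reporting each pair
#' separately; Holm correction is available.
#'
#' @param table a feature table from [build_feature_table()] (any data.frame
#'   with a `group` column works).
#' @param feature feature column name.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return data.frame with columns group1, group2, ks, p, n1, n2.
#' @export
ks_pairwise <- function(table, feature, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (!feature %in% names(table)) stop("no feature column ", feature)
  vals <- split(table[[feature]], table$group)
  vals <- lapply(vals, function(v) v[is.finite(v)])
  small <- names(vals)[lengths(vals) < 2]
  if (length(small)) {
    warning("skipping group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    vals <- vals[lengths(vals) >= 2]
  }
  if (length(vals) < 2)
    stop("need at least 2 groups with >= 2 observations")
  grp <- names(vals)
  pairs <- utils::combn(grp, 2)
  res <- apply(pairs, 2, function(pr) {
    x <- vals[[pr[1]]]
    y <- vals[[pr[2]]]
    kt <- suppressWarnings(stats::ks.test(x, y, exact = min(length(x),
                                                            length(y)) <= 25))
    data.frame(group1 = pr[1], group2 = pr[2],
               ks = unname(kt$statistic), p = kt$p.value,
               n1 = length(x), n2 = length(y))
  })
  out <- do.call(rbind, res)
  if (p_adjust == "holm") out$p_holm <- stats::p.adjust(out$p, "holm")
  class(out) <- c("group_comparison", class(out))
  out
}

#' Pearson correlation between two feature columns
#'
#' Sample Pearson r with the two-sided t-approximation p-value, on the rows
#' where both features are finite.
#'
#' @param table a feature table.
#' @param feature_x,feature_y column names.
#' @return list with elements `rho`, `p`, `n`.
#' @export
pearson_correlation <- function(table, feature_x, feature_y) {
  x <- table[[feature_x]]
  y <- table[[feature_y]]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 paired finite values")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Write / read a distance matrix as CSV
#'
#' Square CSV with a header row and a leading id column.
#'
#' @param d distance matrix.
#' @param path CSV path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(id = rownames(d), as.data.frame(unname(d)))
  names(df) <- c("id", rownames(d))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
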