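#' Airway centerline trees
#'
#' An `airway_tree` is an embedded forest of centerline nodes in millimetre
#' coordinates: one row per node with a parent link, an optional generation
#' label (branching depth from the trachea) and an optional radius. Edges are
#' implied by the parent links. Trees are the input of all graph descriptors:
#' they are densely sampled along each branch, not reduced to branch points,
#' because the trajectory-change descriptors depend on the full centerline
#' shape.
#'
#' @param nodes a data.frame with columns `id`, `x`, `y`, `z`, `parent`
#'   (`NA` for roots) and optionally `generation` and `radius`.
#' @param provenance character vector logging source file and transforms.
#' @return a validated `airway_tree` object.
#' @export
airway_tree <- function(nodes, provenance = character()) {
  required <- c("id", "x", "y", "z", "parent")
  if (!all(required %in% names(nodes)))
    stop("nodes must have columns ", paste(required, collapse = ", "))
  if (!"generation" %in% names(nodes))
    nodes$generation <- rep(NA_integer_, nrow(nodes))
  if (!"radius" %in% names(nodes)) nodes$radius <- rep(1, nrow(nodes))
  nodes <- nodes[, c("id", "x", "y", "z", "radius", "parent", "generation")]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$generation <- as.integer(nodes$generation)
  tree <- structure(list(nodes = nodes, provenance = as.character(provenance)),
                    class = "airway_tree")
  validate_airway_tree(tree)
  tree
}

#' Validate an airway tree
#'
#' Checks the structural invariants: unique node ids, finite coordinates,
#' parent links that resolve and contain no cycles (each connected component
#' has exactly one root), and, when generation labels are present, that a
#' child's generation equals its parent's or its parent's plus one.
#'
#' @param tree an `airway_tree`.
#' @return the tree, invisibly; stops on violation.
#' @export
validate_airway_tree <- function(tree) {
  nodes <- tree$nodes
  if (anyDuplicated(nodes$id))
    stop("structural error: duplicate node id ",
         nodes$id[duplicated(nodes$id)][1])
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  if (nrow(nodes) > 0 && !all(is.finite(pos)))
    stop("structural error: non-finite node coordinates")
  idx <- match(nodes$parent, nodes$id)
  bad <- which(!is.na(nodes$parent) & is.na(idx))
  if (length(bad))
    stop("structural error: node ", nodes$id[bad[1]],
         " references missing parent ", nodes$parent[bad[1]])
  # cycle check by memoised parent traversal
  n <- nrow(nodes)
  state <- integer(n)  # 0 unseen, 1 in progress, 2 done
  for (i in seq_len(n)) {
    j <- i
    path <- integer(0)
    while (!is.na(j) && state[j] == 0L) {
      state[j] <- 1L
      path <- c(path, j)
      j <- idx[j]
    }
    if (!is.na(j) && state[j] == 1L)
      stop("structural error: cycle in parent links involving node ",
           nodes$id[j])
    state[path] <- 2L
  }
  if (any(!is.na(nodes$generation))) {
    has <- !is.na(idx)
    g <- nodes$generation
    gp <- g[idx[has]]
    gc <- g[has]
    ok <- is.na(gc) | is.na(gp) | gc == gp | gc == gp + 1L
    if (!all(ok))
      stop("structural error: generation labels must increase by 0 or 1 ",
           "along parent links (node ", nodes$id[has][which(!ok)[1]], ")")
  }
  invisible(tree)
}

#' Read an airway centerline tree
#'
#' Two dialects are supported. `swc` is the standard embedded-tree morphology
#' format: whitespace-separated records `id type x y z radius parent` with
#' `#` comment lines; the type column carries the airway generation label as
#' `generation + 1` (0 = unlabeled), since SWC has no generation field.
#' `branch_csv` is a CSV with header `node_id,x,y,z,parent_id[,generation]`.
#' Coordinates are taken verbatim in millimetres. A parent of -1 (SWC) or
#' empty/NA (CSV) marks a root; multi-root files are accepted as forests.
#'
#' @param path file to read.
#' @param dialect `"swc"` or `"branch_csv"`.
#' @return an `airway_tree`; `#` comment headers are kept in its provenance.
#' @export
read_tree <- function(path, dialect = c("swc", "branch_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "swc") {
    lines <- readLines(path)
    comments <- grep("^\\s*#", lines, value = TRUE)
    keep <- grepl("\\S", lines) & !grepl("^\\s*#", lines)
    body <- lines[keep]
    lineno <- which(keep)
    if (length(body) == 0) stop("parse error: no node records in ", path)
    fields <- strsplit(trimws(body), "\\s+")
    nf <- lengths(fields)
    if (any(nf != 7))
      stop("parse error at line ", lineno[which(nf != 7)[1]],
           ": expected 7 whitespace-separated columns")
    m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7,
                                 byrow = TRUE))
    if (anyNA(m))
      stop("parse error at line ", lineno[which(rowSums(is.na(m)) > 0)[1]],
           ": non-numeric field")
    dup <- which(duplicated(m[, 1]))
    if (length(dup))
      stop("parse error at line ", lineno[dup[1]], ": duplicate node id ",
           m[dup[1], 1])
    gen <- as.integer(m[, 2]) - 1L
    gen[gen < 0L] <- NA_integer_
    nodes <- data.frame(id = as.integer(m[, 1]), x = m[, 3], y = m[, 4],
                        z = m[, 5], radius = m[, 6],
                        parent = ifelse(m[, 7] < 0, NA, as.integer(m[, 7])),
                        generation = gen)
    airway_tree(nodes, provenance = c(paste0("read_tree swc ", basename(path)),
                                      comments))
  } else {
    df <- utils::read.csv(path)
    need <- c("node_id", "x", "y", "z", "parent_id")
    if (!all(need %in% names(df)))
      stop("parse error: branch_csv needs columns ",
           paste(need, collapse = ", "))
    dup <- which(duplicated(df$node_id))
    if (length(dup))
      stop("parse error at line ", dup[1] + 1L, ": duplicate node id ",
           df$node_id[dup[1]])
    parent <- df$parent_id
    parent[!is.na(parent) & parent < 0] <- NA
    nodes <- data.frame(id = df$node_id, x = df$x, y = df$y, z = df$z,
                        parent = parent,
                        generation = if ("generation" %in% names(df))
                          df$generation else NA_integer_)
    airway_tree(nodes, provenance = paste0("read_tree branch_csv ",
                                           basename(path)))
  }
}

#' Write an airway tree as SWC
#'
#' Emits 7-column SWC parseable by [read_tree()]; generation labels are
#' stored in the type column as `generation + 1` and comment lines recorded
#' in the tree's provenance are written back as a header.
#'
#' @param tree an `airway_tree` with at least one node.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  validate_airway_tree(tree)
  nodes <- tree$nodes
  if (nrow(nodes) == 0) stop("refusing to write a tree with no nodes")
  comments <- grep("^\\s*#", tree$provenance, value = TRUE)
  gen <- ifelse(is.na(nodes$generation), 0L, nodes$generation + 1L)
  parent <- ifelse(is.na(nodes$parent), -1L, nodes$parent)
  rec <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                 nodes$id, gen, nodes$x, nodes$y, nodes$z, nodes$radius,
                 parent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comments, rec), con)
  invisible(path)
}

#' Rotate an airway tree about the fixed laboratory axes
#'
#' Applies `R = Rz(gamma) Ry(beta) Rx(alpha)` to every node position: a
#' right-hand-rule rotation by `angles_deg[1]` about X, then `angles_deg[2]`
#' about Y, then `angles_deg[3]` about Z, all about the fixed axes. The
#' topology is unchanged and the transform is appended to the provenance.
#' The third coordinate is superior (toward the head), so sliding a plane
#' "downwards" means decreasing z.
#'
#' @param tree an `airway_tree`.
#' @param angles_deg numeric 3-vector of angles in degrees (X, Y, Z).
#' @return the rotated tree.
#' @export
rotate_tree <- function(tree, angles_deg) {
  stopifnot(length(angles_deg) == 3, all(is.finite(angles_deg)))
  a <- angles_deg * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(a[1]), sin(a[1]),
                 0, -sin(a[1]), cos(a[1])), 3, 3)
  ry <- matrix(c(cos(a[2]), 0, -sin(a[2]),
                 0, 1, 0,
                 sin(a[2]), 0, cos(a[2])), 3, 3)
  rz <- matrix(c(cos(a[3]), sin(a[3]), 0,
                 -sin(a[3]), cos(a[3]), 0,
                 0, 0, 1), 3, 3)
  rot <- rz %*% ry %*% rx
  pos <- as.matrix(tree$nodes[, c("x", "y", "z")])
  newpos <- pos %*% t(rot)
  tree$nodes$x <- newpos[, 1]
  tree$nodes$y <- newpos[, 2]
  tree$nodes$z <- newpos[, 3]
  tree$provenance <- c(tree$provenance,
                       sprintf("rotate_tree %g %g %g", angles_deg[1],
                               angles_deg[2], angles_deg[3]))
  tree
}

#' Bronchial tree length proxy
#'
#' The number of vertices in the centerline graph. With uniform arc-length
#' sampling this vertex count is proportional to, and used as a proxy for,
#' the physical length of the visible bronchial tree.
#'
#' @param tree an `airway_tree`.
#' @return integer node count.
#' @export
tree_length <- function(tree) nrow(tree$nodes)

#' Number of branch points
#'
#' Counts nodes with out-degree at least 2 (a trifurcation counts once):
#' the points where airways branch out.
#'
#' @param tree an `airway_tree`.
#' @return integer count.
#' @export
branch_point_count <- function(tree) {
  kids <- table(tree$nodes$parent[!is.na(tree$nodes$parent)])
  sum(kids >= 2)
}

#' Restrict a tree to peripheral generations
#'
#' Keeps only nodes whose generation label is at least `min_generation`;
#' parent links into removed nodes are cut, so the result is in general a
#' forest. Supports computing tree length from a given airway generation
#' onward.
#'
#' @param tree an `airway_tree` with generation labels.
#' @param min_generation non-negative integer.
#' @return the pruned `airway_tree` (possibly with zero nodes).
#' @export
prune_to_generation <- function(tree, min_generation) {
  if (all(is.na(tree$nodes$generation)))
    stop("labelled data required: tree has no generation labels")
  keep <- !is.na(tree$nodes$generation) &
    tree$nodes$generation >= min_generation
  nodes <- tree$nodes[keep, , drop = FALSE]
  nodes$parent[!(nodes$parent %in% nodes$id)] <- NA_integer_
  structure(list(nodes = nodes,
                 provenance = c(tree$provenance,
                                paste0("prune_to_generation ", min_generation))),
            class = "airway_tree")
}

# Connected-component membership of each node (by root), used for forest
# handling and per-component reporting.
tree_component_ids <- function(tree) {
  nodes <- tree$nodes
  idx <- match(nodes$parent, nodes$id)
  n <- nrow(nodes)
  comp <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    path <- integer(0)
    while (!is.na(j) && comp[j] == 0L) {
      path <- c(path, j)
      j <- idx[j]
    }
    lab <- if (is.na(j)) path[length(path)] else comp[j]
    comp[path] <- lab
  }
  comp
}

#' @export
print.airway_tree <- function(x, ...) {
  comp <- if (nrow(x$nodes)) length(unique(tree_component_ids(x))) else 0L
  cat(sprintf("airway_tree: %d nodes, %d branch points, %d component(s)\n",
              nrow(x$nodes), branch_point_count(x), comp))
  if (any(!is.na(x$nodes$generation)))
    cat(sprintf("  generations %d..%d\n", min(x$nodes$generation, na.rm = TRUE),
                max(x$nodes$generation, na.rm = TRUE)))
  invisible(x)
}
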