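#' Filtration functions on airway trees
#'
#' A filtration function assigns a real value to every vertex of a centerline
#' graph; every edge takes the maximum of its endpoint values. Sublevel sets
#' X_h (all simplices with value <= h) then form a nested family of graphs
#' whose degree-0 persistence is computed by [sublevel_barcode_deg0()].
#'
#' @param tree an `airway_tree`.
#' @param values numeric vector of vertex values, one per node (in node row
#'   order), or named by node id.
#' @param units unit label for downstream barcodes.
#' @return a `filtration_function`.
#' @export
filtration_function <- function(tree, values, units = "mm_depth") {
  n <- nrow(tree$nodes)
  if (!is.null(names(values)))
    values <- values[as.character(tree$nodes$id)]
  if (length(values) != n || anyNA(values) || !all(is.finite(values)))
    stop("contract violation: every vertex needs a finite filtration value")
  structure(list(values = stats::setNames(as.numeric(values),
                                          tree$nodes$id),
                 units = units,
                 max_value = if (n) max(values) else NA_real_),
            class = "filtration_function")
}

#' Height (depth-below-top) function
#'
#' Assigns to each vertex its vertical distance to the top of the axis-
#' aligned bounding box of the tree: f(v) = z_max - z(v). Sliding a
#' horizontal plane downwards from the top of the scan and keeping the part
#' of the tree above it is exactly the sublevel filtration of f. At least
#' one vertex has value 0 and the maximum value is the depth of the bounding
#' box, which is also the default cap for essential bars.
#'
#' @param tree an `airway_tree` with at least one node.
#' @return a `filtration_function` in `mm_depth` units.
#' @export
height_function <- function(tree) {
  z <- tree$nodes$z
  filtration_function(tree, max(z) - z, units = "mm_depth")
}

#' Degree-0 barcode of a sublevel graph filtration
#'
#' Union-find elder-rule sweep over the simplices of the centerline graph
#' sorted by filtration value, vertices before edges at ties and vertices
#' tie-broken by node id. A finite bar (h1, h2) records a connected
#' component born at level h1 (a local minimum of the function that is new
#' to X_h1) that merges at level h2 into a component born earlier; the
#' younger component dies (elder rule). Each connected component of the
#' whole graph contributes one essential bar born at its minimum value.
#' Zero-persistence pairs are dropped, so for a height function the finite
#' bars are exactly the upward trajectory changes of the airways.
#'
#' @param tree an `airway_tree`.
#' @param f a `filtration_function` on the tree's vertices.
#' @return a degree-0 `barcode`.
#' @export
sublevel_barcode_deg0 <- function(tree, f) {
  nodes <- tree$nodes
  n <- nrow(nodes)
  fv <- f$values[as.character(nodes$id)]
  if (length(fv) != n || anyNA(fv))
    stop("contract violation: filtration value missing for some vertex")
  if (n == 0)
    return(barcode(0, matrix(numeric(0), ncol = 2), f$units,
                   max_filtration = f$max_value))
  vord <- order(fv, nodes$id)
  child <- which(!is.na(nodes$parent))
  pidx <- match(nodes$parent[child], nodes$id)
  ev <- pmax(fv[child], fv[pidx])
  eord <- order(ev)

  # union-find with birth tracking; birth recorded as processing rank so the
  # elder rule is deterministic under ties
  uf <- seq_len(n)
  find <- function(i) {
    r <- i
    while (uf[r] != r) r <- uf[r]
    while (uf[i] != r) {
      nxt <- uf[i]
      uf[i] <<- r
      i <- nxt
    }
    r
  }
  birth_val <- numeric(n)
  birth_rank <- integer(n)
  rank_of <- integer(n)
  rank_of[vord] <- seq_len(n)
  birth_val <- fv
  birth_rank <- rank_of

  bb <- vector("list", length(child))
  nb <- 0L
  # merge edges in value order (all endpoint vertices have value <= edge value)
  for (e in eord) {
    a <- find(child[e])
    b <- find(pidx[e])
    if (a != b) {
      # younger component (later birth rank) dies
      if (birth_rank[a] < birth_rank[b]) {
        elder <- a; young <- b
      } else {
        elder <- b; young <- a
      }
      nb <- nb + 1L
      bb[[nb]] <- c(birth_val[young], ev[e])
      uf[young] <- elder
    }
  }
  roots <- unique(vapply(seq_len(n), find, integer(1)))
  fin <- if (nb) do.call(rbind, bb[seq_len(nb)]) else matrix(numeric(0), ncol = 2)
  ess <- cbind(birth_val[roots], Inf)
  barcode(0, rbind(fin, ess), f$units, max_filtration = f$max_value,
          provenance = "sublevel_barcode_deg0")
}
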