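# Independent oracles and fixture builders. Each oracle recomputes a quantity
# by a different algorithm (and where possible a different library) than the
# implementation it checks.

# ---- fixtures ---------------------------------------------------------------

# random tree graph with n nodes, uniform random attachment, random positions
random_tree_fixture <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA_integer_, vapply(2:n, function(i) sample.int(i - 1L, 1), 1L))
  data.frame(id = 1:n,
             x = stats::runif(n, -30, 30),
             y = stats::runif(n, -30, 30),
             z = stats::runif(n, -60, 0),
             parent = parent)
}

random_airway_tree <- function(n, seed) airway_tree(random_tree_fixture(n, seed))

# random persistence diagram: n finite bars
random_diagram <- function(n, seed, degree = 0, units = "mm_depth") {
  set.seed(seed)
  b <- stats::runif(n, 0, 10)
  d <- b + stats::rexp(n, 1 / 2)
  barcode(degree, cbind(b, d), units)
}

# polyline tree along given z profile (x spread keeps nodes distinct)
path_tree <- function(z) {
  n <- length(z)
  airway_tree(data.frame(id = 1:n, x = seq(0, 1, length.out = n), y = 0,
                         z = z, parent = c(NA, 1:(n - 1))))
}

# "N"-shaped polyline: down 10, up 5, down 10 (1 mm steps)
n_shape_tree <- function() {
  z <- c(seq(0, -10, by = -1), seq(-9, -5, by = 1), seq(-6, -15, by = -1))
  path_tree(z)
}

# ---- degree-0 sublevel oracle (component tracking with igraph) --------------

# Recomputes the degree-0 barcode of a sublevel graph filtration by brute
# force: sweep all distinct filtration levels, compute the connected
# components of every sublevel graph with igraph, track component births as
# new vertex sets appear and record a bar at every merge (elder = smaller
# birth). Returns positive-persistence finite bars plus essential bars.
oracle_sublevel_deg0 <- function(tree, fv) {
  nodes <- tree$nodes
  n <- nrow(nodes)
  f <- unname(fv[as.character(nodes$id)])
  chl <- which(!is.na(nodes$parent))
  pidx <- match(nodes$parent[chl], nodes$id)
  ev <- pmax(f[chl], f[pidx])
  levels <- sort(unique(c(f, ev)))
  active <- list()  # list of list(members = integer vertex rows, birth)
  bars <- NULL
  for (h in levels) {
    vin <- which(f <= h)
    ein <- which(ev <= h)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(chl[ein]),
                 to = as.character(pidx[ein])),
      directed = FALSE, vertices = data.frame(name = as.character(vin)))
    cm <- igraph::components(g)$membership
    newcomps <- split(as.integer(names(cm)), cm)
    nxt <- list()
    for (C in newcomps) {
      owners <- Filter(function(a) all(a$members %in% C), active)
      if (length(owners) == 0) {
        nxt[[length(nxt) + 1]] <- list(members = C, birth = h)
      } else {
        births <- vapply(owners, `[[`, 0, "birth")
        elder <- min(births)
        for (bb in births[-which.min(births)])
          bars <- rbind(bars, c(bb, h))
        nxt[[length(nxt) + 1]] <- list(members = C, birth = elder)
      }
    }
    active <- nxt
  }
  ess <- cbind(vapply(active, `[[`, 0, "birth"), Inf)
  fin <- if (is.null(bars)) matrix(numeric(0), ncol = 2)
  else bars[bars[, 2] > bars[, 1], , drop = FALSE]
  out <- rbind(fin, ess)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# strict local minima of f over the graph (vertices whose value is < all
# neighbour values), by exhaustive neighbour scan
count_local_minima <- function(tree, fv) {
  nodes <- tree$nodes
  f <- unname(fv[as.character(nodes$id)])
  idx <- match(nodes$parent, nodes$id)
  nbrs <- lapply(seq_len(nrow(nodes)), function(i) integer(0))
  for (i in which(!is.na(idx))) {
    nbrs[[i]] <- c(nbrs[[i]], idx[i])
    nbrs[[idx[i]]] <- c(nbrs[[idx[i]]], i)
  }
  sum(vapply(seq_len(nrow(nodes)), function(i)
    length(nbrs[[i]]) == 0 || all(f[i] < f[nbrs[[i]]]), TRUE))
}

# ---- naive boundary-matrix persistence oracle -------------------------------

# Dense GF(2) column reduction written independently of the package's C++
# path: repeatedly scans for an earlier column with the same low entry.
oracle_persistence <- function(fc) {
  D <- fc$intrinsic_dim
  keys <- character(0); vals <- numeric(0); dims <- integer(0)
  for (d in 0:D) {
    S <- fc$simplices[[d + 1]]
    keys <- c(keys, apply(S, 1, function(r) paste(sort(r), collapse = "-")))
    vals <- c(vals, fc$values[[d + 1]])
    dims <- c(dims, rep(d, nrow(S)))
  }
  ord <- order(vals, dims)
  keys <- keys[ord]; vals <- vals[ord]; dims <- dims[ord]
  N <- length(keys)
  pos <- stats::setNames(seq_len(N), keys)
  B <- matrix(FALSE, N, N)
  for (j in seq_len(N)) {
    if (dims[j] == 0) next
    vs <- as.integer(strsplit(keys[j], "-")[[1]])
    for (drop in seq_along(vs)) {
      fk <- paste(vs[-drop], collapse = "-")
      B[pos[[fk]], j] <- TRUE
    }
  }
  low <- function(col) if (any(col)) max(which(col)) else 0L
  lows <- integer(N)
  for (j in seq_len(N)) {
    repeat {
      l <- low(B[, j])
      if (l == 0L) break
      k <- which(lows[seq_len(j - 1L)] == l)
      if (length(k) == 0) break
      B[, j] <- xor(B[, j], B[, k[1]])
    }
    lows[j] <- low(B[, j])
  }
  out <- vector("list", D + 1)
  for (d in 0:D) out[[d + 1]] <- matrix(numeric(0), ncol = 2)
  for (j in seq_len(N)) {
    if (lows[j] > 0) {
      i <- lows[j]
      if (vals[j] > vals[i])
        out[[dims[i] + 1]] <- rbind(out[[dims[i] + 1]], c(vals[i], vals[j]))
    } else if (!j %in% lows) {
      out[[dims[j] + 1]] <- rbind(out[[dims[j] + 1]], c(vals[j], Inf))
    }
  }
  lapply(out, function(m) m[order(m[, 1], m[, 2]), , drop = FALSE])
}

sorted_bars <- function(b) {
  m <- b$bars
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# ---- bottleneck oracle (igraph bipartite matching) --------------------------

# Exact bottleneck by binary search over candidate costs, feasibility decided
# by a maximum bipartite matching (igraph) on the diagonally padded graph.
oracle_bottleneck <- function(a, b) {
  A <- a$bars; B <- b$bars
  n <- nrow(A); m <- nrow(B)
  if (n + m == 0) return(0)
  C <- if (n && m) pmax(abs(outer(A[, 1], B[, 1], "-")),
                        abs(outer(A[, 2], B[, 2], "-"))) else
                          matrix(0, n, m)
  da <- (A[, 2] - A[, 1]) / 2
  db <- (B[, 2] - B[, 1]) / 2
  cand <- sort(unique(c(0, C, da, db)))
  feasible <- function(r) {
    # left: a-bars then b-diagonals; right: b-bars then a-diagonals
    el <- NULL
    for (i in seq_len(n)) {
      for (j in seq_len(m)) if (C[i, j] <= r) el <- rbind(el, c(i, n + m + j))
      if (da[i] <= r) el <- rbind(el, c(i, n + m + m + i))
    }
    for (j in seq_len(m)) {
      if (db[j] <= r) el <- rbind(el, c(n + j, n + m + j))
      for (i in seq_len(n)) el <- rbind(el, c(n + j, n + m + m + i))
    }
    if (is.null(el)) return(n + m == 0)
    g <- igraph::make_bipartite_graph(
      types = c(rep(FALSE, n + m), rep(TRUE, m + n)),
      edges = as.vector(t(el)))
    igraph::max_bipartite_match(g)$matching_size == n + m
  }
  lo <- 1L; hi <- length(cand)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (feasible(cand[mid])) hi <- mid else lo <- mid + 1L
  }
  cand[hi]
}

# ---- Wasserstein oracle (exhaustive matching enumeration) -------------------

# Minimal order-q matching cost by recursion over all assignments of a-bars
# to distinct b-bars or the diagonal; unmatched b-bars pay their diagonal
# cost. Only for tiny diagrams.
oracle_wasserstein <- function(a, b, order = 2) {
  A <- a$bars; B <- b$bars
  n <- nrow(A); m <- nrow(B)
  C <- if (n && m) pmax(abs(outer(A[, 1], B[, 1], "-")),
                        abs(outer(A[, 2], B[, 2], "-")))^order else
                          matrix(0, n, m)
  da <- ((A[, 2] - A[, 1]) / 2)^order
  db <- ((B[, 2] - B[, 1]) / 2)^order
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) {
      best <<- min(best, acc + sum(db[!used]))
      return()
    }
    rec(i + 1L, used, acc + da[i])
    for (j in seq_len(m)) if (!used[j]) {
      used[j] <- TRUE
      rec(i + 1L, used, acc + C[i, j])
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best^(1 / order)
}
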