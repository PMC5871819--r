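#' Alpha-complex filtration of a 3D point cloud
#'
#' Builds the Delaunay-based alpha complex of a point cloud in millimetre
#' coordinates. Each simplex enters the filtration at its critical alpha
#' radius: top-dimensional Delaunay simplices at their circumradius, lower
#' faces at their own circumradius when Gabriel (smallest circumsphere empty
#' of the opposite vertices) and otherwise at the value of their smallest
#' coface. Values are stored in radius units (mm), so thickening the cloud
#' with balls of radius r yields exactly the simplices with value <= r.
#'
#' Degeneracy handling: the cloud is first deduplicated and its affine rank
#' determined (SVD, relative tolerance 1e-7); rank-deficient clouds (e.g.
#' exactly coplanar points) are triangulated inside their affine hull in the
#' intrinsic dimension, mirroring the behaviour of exact-arithmetic alpha
#' complex implementations. A deterministic seeded jitter of magnitude
#' 1e-6 x bounding-box diagonal is applied inside the hull before
#' triangulation to break cocircular/cospherical ties of grid-like clouds;
#' the seed and magnitude are recorded in the provenance.
#'
#' @param points n x 3 numeric matrix of coordinates in mm (n x 2 / n x 1
#'   accepted and treated as embedded).
#' @param jitter_seed integer seed for the symmetry-breaking jitter.
#' @return a `filtered_complex`.
#' @export
alpha_filtration <- function(points, jitter_seed = 1L) {
  pts <- as.matrix(points)
  if (ncol(pts) > 3) stop("points must have at most 3 coordinates")
  if (!all(is.finite(pts))) stop("non-finite point coordinates")
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 2)
    stop("degenerate input: fewer than 2 distinct points")

  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X, nu = 0)
  r <- sum(sv$d > max(sv$d) * 1e-7)
  r <- max(r, 1L)
  Y <- X %*% sv$v[, seq_len(r), drop = FALSE]

  bbox <- apply(Y, 2, range)
  diag_len <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  # 1e-6 x diagonal, floored at 0.1 um: voxel grids hold exactly cocircular
  # quadruples whose tie-broken circumspheres are inversely proportional to
  # the jitter, so a too-small jitter leaves them numerically unresolvable
  mag <- max(1e-6 * diag_len, 1e-4)
  Y <- Y + with_seed(jitter_seed,
                     matrix(stats::runif(n * r, -mag, mag), n, r))

  cells <- if (n <= r + 1) {
    matrix(seq_len(n), nrow = 1)
  } else {
    delaunay_simplices(Y)
  }
  raw <- alpha_complex_cpp(Y, cells)
  simplices <- lapply(raw, `[[`, "simplices")
  values <- lapply(raw, function(l) sqrt(pmax(l$value2, 0)))
  structure(list(simplices = simplices, values = values,
                 n_points = n, intrinsic_dim = length(simplices) - 1L,
                 units = "mm_radius",
                 max_filtration = max(unlist(values)),
                 jitter = list(seed = as.integer(jitter_seed),
                               magnitude = mag),
                 provenance = sprintf(
                   "alpha_filtration n=%d rank=%d jitter_seed=%d mag=%.3g",
                   n, r, as.integer(jitter_seed), mag)),
            class = "filtered_complex")
}

#' @export
print.filtered_complex <- function(x, ...) {
  cat(sprintf("filtered_complex (alpha, %s): %d points, dims 0..%d, %s simplices\n",
              x$units, x$n_points, x$intrinsic_dim,
              paste(vapply(x$simplices, nrow, 1L), collapse = "/")))
  invisible(x)
}

# Persistence pairs of the whole filtered complex: one barcode per degree.
persistence_all <- function(complex) {
  D <- complex$intrinsic_dim
  counts <- vapply(complex$simplices, nrow, 1L)
  value <- unlist(complex$values, use.names = FALSE)
  dimv <- rep(seq_len(D + 1) - 1L, counts)
  ord <- order(value, dimv)
  N <- length(value)
  pos <- integer(N)
  pos[ord] <- seq_len(N)
  pos_by_dim <- split(pos, dimv)
  pivot <- reduce_filtration_cpp(complex$simplices, unname(pos_by_dim))
  vs <- value[ord]
  ds <- dimv[ord]
  killed <- pivot[pivot > 0]
  deaths <- which(pivot > 0)
  essential <- setdiff(which(pivot == 0), killed)
  out <- vector("list", D + 1)
  for (deg in 0:D) {
    sel <- ds[killed] == deg
    fin <- cbind(vs[killed[sel]], vs[deaths[sel]])
    ess <- essential[ds[essential] == deg]
    bars <- rbind(fin, cbind(vs[ess], rep(Inf, length(ess))))
    out[[deg + 1]] <- barcode(deg, bars, complex$units,
                              max_filtration = complex$max_filtration,
                              provenance = complex$provenance)
  }
  out
}

#' Persistence barcode of a filtered complex
#'
#' Standard persistence pairing over the field of two elements by boundary-
#' matrix column reduction, simplices ordered by (filtration value,
#' dimension). Bars are sorted by (birth, death); zero-persistence pairs are
#' dropped; unpaired (essential) classes get death `Inf`.
#'
#' @param complex a `filtered_complex` from [alpha_filtration()].
#' @param degree homology degree in 0..2.
#' @return a `barcode` in the complex's scale units.
#' @export
persistence <- function(complex, degree) {
  if (!degree %in% 0:2)
    stop("unsupported degree: ", degree, " (0, 1, 2 are available)")
  if (degree > complex$intrinsic_dim)
    return(barcode(degree, matrix(numeric(0), ncol = 2), complex$units,
                   max_filtration = complex$max_filtration))
  persistence_all(complex)[[degree + 1]]
}
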