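# Pairwise L-infinity cost matrix between bars, and diagonal costs
# (persistence / 2), the standard ground metric on persistence diagrams.
diagram_costs <- function(a, b) {
  n <- nrow(a)
  m <- nrow(b)
  C <- matrix(0, n, m)
  if (n && m)
    C <- pmax(abs(outer(a[, 1], b[, 1], "-")),
              abs(outer(a[, 2], b[, 2], "-")))
  list(C = C, da = (a[, 2] - a[, 1]) / 2, db = (b[, 2] - b[, 1]) / 2)
}

check_comparable <- function(a, b) {
  if (!inherits(a, "barcode") || !inherits(b, "barcode"))
    stop("contract violation: inputs must be barcodes")
  if (a$degree != b$degree)
    stop("contract violation: barcodes have different degrees")
  if (!identical(a$units, b$units))
    stop("contract violation: mixed units (", a$units, " vs ", b$units, ")")
  if (any(is.infinite(a$bars)) || any(is.infinite(b$bars)))
    stop("essential bars present: cap them first (cap_barcode)")
}

# Is there a perfect matching of the diagonally-padded diagrams using only
# costs <= r? Solved as a 0/1 assignment problem.
bottleneck_feasible <- function(co, r, eps = 1e-12) {
  n <- length(co$da)
  m <- length(co$db)
  M <- matrix(0, n + m, n + m)
  if (n && m) M[seq_len(n), seq_len(m)] <- (co$C > r + eps) * 1
  if (n) M[seq_len(n), m + seq_len(n)] <- matrix((co$da > r + eps) * 1, n, n)
  if (m) M[n + seq_len(m), seq_len(m)] <- matrix((co$db > r + eps) * 1, m, m,
                                                 byrow = TRUE)
  sol <- clue::solve_LSAP(M)
  sum(M[cbind(seq_len(n + m), sol)]) == 0
}

#' Bottleneck distance between barcodes
#'
#' The smallest r such that the two diagrams admit a partial matching in
#' which matched bars are within L-infinity distance r and every unmatched
#' bar is within r of the diagonal (cost persistence / 2). Computed by
#' binary search over the finite set of candidate costs with a bipartite
#' feasibility test at each step, which makes the result exact up to
#' floating point; it therefore always satisfies the approximation contract
#' |d_exact - d_approx| / d_exact < relative_error. Essential bars must be
#' capped first ([cap_barcode()]).
#'
#' @param a,b `barcode`s of the same degree and units with finite bars.
#' @param relative_error accepted relative approximation error (default
#'   1e-4); recorded for provenance, the search itself is exact.
#' @return the bottleneck distance (same units as the bars).
#' @export
bottleneck_distance <- function(a, b, relative_error = 1e-4) {
  if (relative_error <= 0) stop("contract violation: relative_error must be > 0")
  check_comparable(a, b)
  co <- diagram_costs(a$bars, b$bars)
  n <- length(co$da)
  m <- length(co$db)
  if (n == 0 && m == 0) return(0)
  cand <- sort(unique(c(0, co$C, co$da, co$db)))
  lo <- 1L
  hi <- length(cand)
  while (lo < hi) {  # invariant: cand[hi] feasible or hi == max
    mid <- (lo + hi) %/% 2L
    if (bottleneck_feasible(co, cand[mid])) hi <- mid else lo <- mid + 1L
  }
  cand[hi]
}

#' Wasserstein distance between barcodes
#'
#' (min over partial matchings of sum cost^order)^(1/order) with L-infinity
#' ground cost between bars and diagonal cost persistence / 2, solved
#' exactly as a linear assignment problem on the diagonally padded cost
#' matrix. Essential bars must be capped first.
#'
#' @param a,b `barcode`s of the same degree and units with finite bars.
#' @param order cost exponent q >= 1 (default 2, the Wasserstein-2 distance).
#' @return the order-q Wasserstein distance.
#' @export
wasserstein_distance <- function(a, b, order = 2) {
  if (order < 1) stop("contract violation: order must be >= 1")
  check_comparable(a, b)
  co <- diagram_costs(a$bars, b$bars)
  n <- length(co$da)
  m <- length(co$db)
  if (n == 0 && m == 0) return(0)
  M <- matrix(0, n + m, n + m)
  if (n && m) M[seq_len(n), seq_len(m)] <- co$C^order
  if (n) M[seq_len(n), m + seq_len(n)] <- matrix(co$da^order, n, n)
  if (m) M[n + seq_len(m), seq_len(m)] <- matrix(co$db^order, m, m,
                                                 byrow = TRUE)
  sol <- clue::solve_LSAP(M)
  sum(M[cbind(seq_len(n + m), sol)])^(1 / order)
}
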