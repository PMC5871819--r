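#include <Rcpp.h>
#include <array>
#include <map>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// A simplex is keyed by its sorted vertex ids (1-based), padded with 0.
typedef std::array<int, 4> Key;

static inline Key make_key(std::vector<int> v) {
  std::sort(v.begin(), v.end());
  Key k;
  k.fill(0);
  for (size_t i = 0; i < v.size(); ++i) k[i] = v[i];
  return k;
}

// Circumcenter (in the affine hull) and squared circumradius of the simplex
// with vertex ids idx (1-based into the n x d point matrix P, column-major).
// Solves  G lambda = h,  G_ij = 2 e_i . e_j,  h_i = |e_i|^2,
// c = p0 + sum lambda_i e_i. Gaussian elimination with partial pivoting
// (k <= 3). Returns false when the simplex is numerically degenerate, in
// which case r2 is set very large so degenerate slivers enter late.
static bool circumsphere(const double *P, int n, int d,
                         const int *idx, int k1,
                         double *center, double &r2) {
  int k = k1 - 1;
  if (k == 0) {
    for (int j = 0; j < d; ++j) center[j] = P[(idx[0] - 1) + (size_t)n * j];
    r2 = 0.0;
    return true;
  }
  double E[3][3];  // edge vectors, rows
  double G[3][4];  // augmented system
  const int p0 = idx[0] - 1;
  for (int i = 0; i < k; ++i) {
    int pi = idx[i + 1] - 1;
    for (int j = 0; j < d; ++j)
      E[i][j] = P[pi + (size_t)n * j] - P[p0 + (size_t)n * j];
  }
  for (int i = 0; i < k; ++i) {
    double h = 0.0;
    for (int j = 0; j < d; ++j) h += E[i][j] * E[i][j];
    for (int l = 0; l < k; ++l) {
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += E[i][j] * E[l][j];
      G[i][l] = 2.0 * g;
    }
    G[i][k] = h;
  }
  // Gaussian elimination
  for (int col = 0; col < k; ++col) {
    int piv = col;
    for (int r = col + 1; r < k; ++r)
      if (std::fabs(G[r][col]) > std::fabs(G[piv][col])) piv = r;
    if (piv != col)
      for (int c = 0; c <= k; ++c) std::swap(G[col][c], G[piv][c]);
    if (std::fabs(G[col][col]) < 1e-300) {
      r2 = 1e300;
      return false;
    }
    for (int r = col + 1; r < k; ++r) {
      double f = G[r][col] / G[col][col];
      for (int c = col; c <= k; ++c) G[r][c] -= f * G[col][c];
    }
  }
  double lam[3];
  for (int r = k - 1; r >= 0; --r) {
    double s = G[r][k];
    for (int c = r + 1; c < k; ++c) s -= G[r][c] * lam[c];
    lam[r] = s / G[r][r];
  }
  r2 = 0.0;
  for (int j = 0; j < d; ++j) {
    double off = 0.0;
    for (int i = 0; i < k; ++i) off += lam[i] * E[i][j];
    center[j] = P[p0 + (size_t)n * j] + off;
    r2 += off * off;
  }
  return true;
}

// Alpha-complex filtration values from a triangulation.
// pts: n x d coordinates (d = intrinsic dimension, 1..3).
// cells: m x (d+1) matrix of 1-based vertex ids of the top-dimensional
// Delaunay simplices.
// Returns, per dimension 0..d, the simplex vertex matrix and the squared
// alpha value (critical squared circumradius). Vertices enter at 0.
// Algorithm: assign each top cell its squared circumradius; then for each
// dimension descending, propagate min values to facets and assign attached
// (non-Gabriel) facets the value of their smallest coface.
// [[Rcpp::export]]
List alpha_complex_cpp(NumericMatrix pts, IntegerMatrix cells) {
  const int n = pts.nrow(), d = pts.ncol();
  const int K = cells.ncol() - 1;
  if (K < 1 || K > 3) stop("top simplex dimension must be 1..3");
  const double *P = REAL(pts);

  std::map<Key, int> index[4];
  std::vector<Key> simp[4];

  // all vertices
  for (int v = 1; v <= n; ++v) {
    Key k = make_key(std::vector<int>{v});
    index[0][k] = (int)simp[0].size();
    simp[0].push_back(k);
  }
  // all faces of all cells
  const int nc = cells.nrow();
  for (int c = 0; c < nc; ++c) {
    std::vector<int> vs(K + 1);
    for (int j = 0; j <= K; ++j) vs[j] = cells(c, j);
    for (int mask = 1; mask < (1 << (K + 1)); ++mask) {
      std::vector<int> sub;
      for (int j = 0; j <= K; ++j)
        if (mask & (1 << j)) sub.push_back(vs[j]);
      int dim = (int)sub.size() - 1;
      if (dim == 0) continue;
      Key k = make_key(sub);
      if (index[dim].find(k) == index[dim].end()) {
        index[dim][k] = (int)simp[dim].size();
        simp[dim].push_back(k);
      }
    }
  }

  // circumspheres for dims 1..K
  std::vector<double> r2[4];
  std::vector<double> ctr[4];
  for (int dim = 1; dim <= K; ++dim) {
    size_t m = simp[dim].size();
    r2[dim].resize(m);
    ctr[dim].resize(m * d);
    for (size_t i = 0; i < m; ++i) {
      double rr;
      circumsphere(P, n, d, simp[dim][i].data(), dim + 1,
                   &ctr[dim][i * d], rr);
      r2[dim][i] = rr;
    }
  }

  std::vector<double> val[4];
  std::vector<double> ub[4];  // min over coface values; enforces monotonicity
  std::vector<char> assigned[4];
  for (int dim = 0; dim <= K; ++dim) {
    val[dim].assign(simp[dim].size(), 0.0);
    ub[dim].assign(simp[dim].size(), R_PosInf);
    assigned[dim].assign(simp[dim].size(), 0);
  }

  for (int dim = K; dim >= 1; --dim) {
    size_t m = simp[dim].size();
    for (size_t i = 0; i < m; ++i) {
      if (!assigned[dim][i]) {
        // own circumradius, clamped by the cofaces so the filtration stays
        // monotone even when near-degenerate simplices make the Gabriel
        // test numerically unreliable
        val[dim][i] = std::min(r2[dim][i], ub[dim][i]);
        assigned[dim][i] = 1;
      }
      if (dim == 1) continue;  // vertex values stay 0
      const Key &kv = simp[dim][i];
      for (int drop = 0; drop <= dim; ++drop) {
        std::vector<int> sub;
        sub.reserve(dim);
        for (int j = 0; j <= dim; ++j)
          if (j != drop) sub.push_back(kv[j]);
        Key fk = make_key(sub);
        int fi = index[dim - 1][fk];
        if (val[dim][i] < ub[dim - 1][fi]) ub[dim - 1][fi] = val[dim][i];
        if (assigned[dim - 1][fi]) {
          if (val[dim][i] < val[dim - 1][fi]) val[dim - 1][fi] = val[dim][i];
        } else {
          // Gabriel test: opposite vertex inside the facet's circumsphere?
          int vopp = kv[drop] - 1;
          double dist2 = 0.0;
          for (int j = 0; j < d; ++j) {
            double t = P[vopp + (size_t)n * j] - ctr[dim - 1][(size_t)fi * d + j];
            dist2 += t * t;
          }
          if (dist2 < r2[dim - 1][fi]) {  // attached
            val[dim - 1][fi] = std::min(val[dim][i], ub[dim - 1][fi]);
            assigned[dim - 1][fi] = 1;
          }
        }
      }
    }
  }

  List out(K + 1);
  for (int dim = 0; dim <= K; ++dim) {
    size_t m = simp[dim].size();
    IntegerMatrix S(m, dim + 1);
    NumericVector V(m);
    for (size_t i = 0; i < m; ++i) {
      for (int j = 0; j <= dim; ++j) S(i, j) = simp[dim][i][j];
      V[i] = val[dim][i];
    }
    out[dim] = List::create(Named("simplices") = S, Named("value2") = V);
  }
  return out;
}

// Standard persistence column reduction over Z/2.
// simp_by_dim: list (by dimension 0..D) of m x (dim+1) vertex-id matrices.
// pos_by_dim: list of integer vectors giving each simplex's 1-based position
// in the global filtration order (faces before cofaces).
// Returns pivot[j] = i if the reduced column at position j has lowest one at
// position i (j kills i), 0 if the column is zero (i.e. j creates a class).
// [[Rcpp::export]]
IntegerVector reduce_filtration_cpp(List simp_by_dim, List pos_by_dim) {
  int D = simp_by_dim.size() - 1;
  std::map<Key, int> pos_of;  // simplex -> global position
  size_t N = 0;
  for (int dim = 0; dim <= D; ++dim) {
    IntegerMatrix S = simp_by_dim[dim];
    IntegerVector Pv = pos_by_dim[dim];
    for (int i = 0; i < S.nrow(); ++i) {
      std::vector<int> vs(dim + 1);
      for (int j = 0; j <= dim; ++j) vs[j] = S(i, j);
      pos_of[make_key(vs)] = Pv[i];
      ++N;
    }
  }
  // boundary columns in global order
  std::vector<std::vector<int>> cols(N + 1);
  for (int dim = 1; dim <= D; ++dim) {
    IntegerMatrix S = simp_by_dim[dim];
    IntegerVector Pv = pos_by_dim[dim];
    for (int i = 0; i < S.nrow(); ++i) {
      std::vector<int> vs(dim + 1), bd;
      for (int j = 0; j <= dim; ++j) vs[j] = S(i, j);
      for (int drop = 0; drop <= dim; ++drop) {
        std::vector<int> sub;
        for (int j = 0; j <= dim; ++j)
          if (j != drop) sub.push_back(vs[j]);
        std::map<Key, int>::iterator it = pos_of.find(make_key(sub));
        if (it == pos_of.end()) stop("boundary facet missing from complex");
        bd.push_back(it->second);
      }
      std::sort(bd.begin(), bd.end());
      cols[Pv[i]] = bd;
    }
  }
  std::vector<int> lowinv(N + 1, 0);
  std::vector<int> tmp;
  for (size_t j = 1; j <= N; ++j) {
    std::vector<int> &col = cols[j];
    while (!col.empty()) {
      int l = col.back();
      int k = lowinv[l];
      if (k == 0) break;
      // col <- col + cols[k] (symmetric difference of sorted vectors)
      const std::vector<int> &other = cols[k];
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    other.begin(), other.end(),
                                    std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (!col.empty()) lowinv[col.back()] = (int)j;
  }
  IntegerVector pivot(N);
  for (size_t i = 1; i <= N; ++i)
    if (lowinv[i] != 0) pivot[lowinv[i] - 1] = (int)i;
  return pivot;
}
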