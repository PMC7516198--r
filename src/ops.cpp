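#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- convolution helpers (same padding, odd kernel) ----------------------
//
// Feature maps are H x W x C cubes (column-major, as R arrays). im2col lays
// out, for every output pixel (h, w), the k*k*C input window as one row so a
// convolution becomes a single GEMM done in R via %*% (BLAS). The column
// order (c, kw, kh) only has to be consistent between im2col and col2im;
// weights are learned in whatever layout this induces.

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  arma::mat cols(static_cast<size_t>(H) * W, static_cast<size_t>(k) * k * C,
                 arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int q = c * k * k + kw * k + kh;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kw - p;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + kh - p;
            if (sh < 0 || sh >= H) continue;
            cols(static_cast<size_t>(w) * H + h, q) = x(sh, sw, c);
          }
        }
      }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& cols, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int q = c * k * k + kw * k + kh;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kw - p;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + kh - p;
            if (sh < 0 || sh >= H) continue;
            x(sh, sw, c) += cols(static_cast<size_t>(w) * H + h, q);
          }
        }
      }
  return x;
}

// 2x2 max pooling; also returns the linear index (0-based, into the input
// cube) of each selected element so the backward pass can scatter gradients.

// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  arma::cube y(H2, W2, C);
  arma::cube idx(H2, W2, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        double best = -arma::datum::inf;
        long long bi = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const int sh = 2 * h + dh, sw = 2 * w + dw;
            const double v = x(sh, sw, c);
            if (v > best) {
              best = v;
              bi = sh + static_cast<long long>(H) * sw +
                   static_cast<long long>(H) * W * c;
            }
          }
        y(h, w, c) = best;
        idx(h, w, c) = static_cast<double>(bi);
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& idx, const arma::cube& g,
                            int H, int W) {
  const int C = g.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (size_t i = 0; i < idx.n_elem; ++i)
    gx(static_cast<size_t>(idx(i))) += g(i);
  return gx;
}

// ---- optimal assignment (Jonker-Volgenant potentials) --------------------
//
// Minimum-cost assignment of n rows to m >= n columns. Returns, for each
// row, the 1-based assigned column. O(n^2 m).

// [[Rcpp::export]]
IntegerVector cpp_assignment(const arma::mat& cost) {
  const int n = cost.n_rows, m = cost.n_cols;
  if (n > m) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      int j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j)
        if (!used[j]) {
          const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// ---- Voronoi cells by incremental half-plane clipping --------------------
//
// Each site's cell starts as the bounding rectangle and is clipped by the
// perpendicular bisector of the segment to every other site, visited in
// order of increasing distance; a site at distance d cannot cut the current
// polygon once (d/2)^2 exceeds the squared distance from the site to its
// farthest remaining vertex, which prunes the scan after a handful of
// neighbours. Each polygon edge remembers which site's bisector (or which
// rectangle wall) created it; edges shorter than edge_eps are treated as
// degenerate (zero-length ridges from 4+ co-circular sites) and create no
// adjacency.

struct ClipPoly {
  // vertex k, with src[k] = id of the edge arriving at vertex k from
  // vertex k-1 (cyclic). Positive ids are sites (1-based), negative are
  // rectangle walls.
  std::vector<double> x, y;
  std::vector<int> src;
};

static void clip_halfplane(ClipPoly& P, double sx, double sy, double ox,
                           double oy, int clip_id, double tol) {
  const int M = P.x.size();
  if (M == 0) return;
  // keep f(p) = (p - mid) . (o - s) <= 0  (points closer to the site)
  const double mx = 0.5 * (sx + ox), my = 0.5 * (sy + oy);
  const double dx = ox - sx, dy = oy - sy;
  std::vector<double> f(M);
  for (int i = 0; i < M; ++i)
    f[i] = (P.x[i] - mx) * dx + (P.y[i] - my) * dy;
  ClipPoly out;
  for (int k = 0; k < M; ++k) {
    const int kn = (k + 1) % M;
    const bool cin = f[k] <= tol, nin = f[kn] <= tol;
    const int s_edge = P.src[kn];
    if (cin && nin) {
      out.x.push_back(P.x[kn]); out.y.push_back(P.y[kn]);
      out.src.push_back(s_edge);
    } else if (cin && !nin) {
      const double t = f[k] / (f[k] - f[kn]);
      out.x.push_back(P.x[k] + t * (P.x[kn] - P.x[k]));
      out.y.push_back(P.y[k] + t * (P.y[kn] - P.y[k]));
      out.src.push_back(s_edge);
    } else if (!cin && nin) {
      const double t = f[k] / (f[k] - f[kn]);
      out.x.push_back(P.x[k] + t * (P.x[kn] - P.x[k]));
      out.y.push_back(P.y[k] + t * (P.y[kn] - P.y[k]));
      out.src.push_back(clip_id);  // edge running along the bisector
      out.x.push_back(P.x[kn]); out.y.push_back(P.y[kn]);
      out.src.push_back(s_edge);
    }
  }
  P = out;
}

// [[Rcpp::export]]
List cpp_voronoi_cells(const arma::mat& pts, double xmin, double ymin,
                       double xmax, double ymax, double edge_eps) {
  const int n = pts.n_rows;
  const double diag = std::hypot(xmax - xmin, ymax - ymin);
  List cells(n);
  // global ordering by distance reused per site
  for (int i = 0; i < n; ++i) {
    const double sx = pts(i, 0), sy = pts(i, 1);
    std::vector<std::pair<double, int>> ord;
    ord.reserve(n - 1);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = pts(j, 0) - sx, dy = pts(j, 1) - sy;
      ord.push_back({dx * dx + dy * dy, j});
    }
    std::sort(ord.begin(), ord.end());
    ClipPoly P;
    P.x = {xmin, xmax, xmax, xmin};
    P.y = {ymin, ymin, ymax, ymax};
    P.src = {-4, -1, -2, -3};  // edge arriving at vertex k
    double maxd2 = 0;
    for (size_t k = 0; k < P.x.size(); ++k) {
      const double dx = P.x[k] - sx, dy = P.y[k] - sy;
      maxd2 = std::max(maxd2, dx * dx + dy * dy);
    }
    for (auto& pr : ord) {
      if (pr.first >= 4.0 * maxd2) break;  // bisector cannot reach the cell
      const double tol = 1e-12 * diag * (std::sqrt(pr.first) + diag);
      clip_halfplane(P, sx, sy, pts(pr.second, 0), pts(pr.second, 1),
                     pr.second + 1, tol);
      if (P.x.empty()) break;
      maxd2 = 0;
      for (size_t k = 0; k < P.x.size(); ++k) {
        const double dx = P.x[k] - sx, dy = P.y[k] - sy;
        maxd2 = std::max(maxd2, dx * dx + dy * dy);
      }
    }
    const int M = P.x.size();
    double area = 0;
    std::set<int> nbrs;
    bool boundary = false;
    NumericMatrix verts(M, 2);
    for (int k = 0; k < M; ++k) {
      const int kp = (k + 1) % M;
      area += P.x[k] * P.y[kp] - P.x[kp] * P.y[k];
      const double el = std::hypot(P.x[kp] - P.x[k], P.y[kp] - P.y[k]);
      const int s = P.src[kp];  // edge k -> k+1 arrives at vertex k+1
      if (el > edge_eps) {
        if (s > 0) nbrs.insert(s);
        else boundary = true;
      }
      verts(k, 0) = P.x[k];
      verts(k, 1) = P.y[k];
    }
    area = 0.5 * std::fabs(area);
    IntegerVector nb(nbrs.begin(), nbrs.end());
    cells[i] = List::create(_["area"] = area, _["neighbours"] = nb,
                            _["boundary"] = boundary, _["vertices"] = verts);
  }
  return cells;
}

// ---- k-th nearest neighbour distance -------------------------------------

// [[Rcpp::export]]
NumericVector cpp_knn_dist(const arma::mat& pts, int k) {
  const int n = pts.n_rows;
  if (k >= n) stop("k must be smaller than the number of points");
  NumericVector out(n);
  std::vector<double> d2(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = pts(j, 0) - pts(i, 0), dy = pts(j, 1) - pts(i, 1);
      d2[m++] = dx * dx + dy * dy;
    }
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    out[i] = std::sqrt(d2[k - 1]);
  }
  return out;
}
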