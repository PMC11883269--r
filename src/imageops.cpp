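#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher's
// lower-envelope algorithm applied to columns then rows of the squared
// distance). Foreground pixels get the distance to the nearest background
// pixel; background pixels get 0.

static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericMatrix edt_cpp(LogicalMatrix fg) {
  const int nr = fg.nrow(), nc = fg.ncol();
  const double INF = 1e20;
  NumericMatrix d2(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) d2(i, j) = fg(i, j) ? INF : 0.0;

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = d2(i, j);
    f.resize(nr);
    d.resize(nr);
    dt1d(f, d);
    for (int i = 0; i < nr; ++i) d2(i, j) = d[i];
    f.resize(std::max(nr, nc));
    d.resize(std::max(nr, nc));
  }
  for (int i = 0; i < nr; ++i) {
    f.resize(nc);
    d.resize(nc);
    for (int j = 0; j < nc; ++j) f[j] = d2(i, j);
    dt1d(f, d);
    for (int j = 0; j < nc; ++j) d2(i, j) = std::sqrt(d[j]);
    f.resize(std::max(nr, nc));
    d.resize(std::max(nr, nc));
  }
  return d2;
}

// Marker-driven watershed by priority flooding (Meyer's algorithm without
// watershed lines): pixels are popped in order of increasing priority, FIFO
// within ties, and take the label of the neighbour that queued them.
// 8-connectivity; pixels outside `mask` are never labelled.
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerMatrix watershed_cpp(NumericMatrix priority, IntegerMatrix markers,
                            LogicalMatrix mask) {
  const int nr = priority.nrow(), nc = priority.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc || mask.nrow() != nr ||
      mask.ncol() != nc)
    stop("priority, markers and mask must have identical dimensions");
  IntegerMatrix lab(nr, nc);
  typedef std::tuple<double, long, int> Node; // (priority, order, index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long counter = 0;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      lab(i, j) = 0;
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        pq.push(Node(priority(i, j), counter++, i + j * nr));
      }
    }

  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    const int idx = std::get<2>(pq.top());
    pq.pop();
    const int i = idx % nr, j = idx / nr;
    const int li = lab(i, j);
    for (int t = 0; t < 8; ++t) {
      const int ni = i + di[t], nj = j + dj[t];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj) || lab(ni, nj) != 0) continue;
      lab(ni, nj) = li;
      pq.push(Node(priority(ni, nj), counter++, ni + nj * nr));
    }
  }
  return lab;
}

// Connected-component labelling (BFS), connectivity 4 or 8.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ci = idx % nr, cj = idx / nr;
        for (int t = 0; t < nnb; ++t) {
          const int ni = ci + di[t], nj = cj + dj[t];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  return lab;
}

// Square-window running maximum (separable two-pass), radius in pixels.
// [[Rcpp::export(name = ".box_max_cpp")]]
NumericMatrix box_max_cpp(NumericMatrix img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double mx = -1e300;
      const int lo = std::max(0, i - radius), hi = std::min(nr - 1, i + radius);
      for (int k = lo; k <= hi; ++k) mx = std::max(mx, img(k, j));
      tmp(i, j) = mx;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double mx = -1e300;
      const int lo = std::max(0, j - radius), hi = std::min(nc - 1, j + radius);
      for (int k = lo; k <= hi; ++k) mx = std::max(mx, tmp(i, k));
      out(i, j) = mx;
    }
  return out;
}
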