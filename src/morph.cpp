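#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Voxel arrays arrive in R column-major order with dim = (d1, d2, d3).
// All routines are axis-agnostic; callers own the (z, y, x) convention.

static inline int idx3(int a, int b, int c, int d1, int d2) {
  return a + d1 * (b + d2 * c);
}

// ---- connected-component labelling (BFS flood fill) -----------------------

// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector vox, IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int n = d1 * d2 * d3;
  IntegerVector lab(n, 0);
  if (!(connectivity == 6 || connectivity == 18 || connectivity == 26))
    stop("connectivity must be 6, 18 or 26");
  int cur = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int s = 0; s < n; ++s) {
    if (!vox[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int a = v % d1, rem = v / d1;
      int b = rem % d2, c = rem / d2;
      for (int dc = -1; dc <= 1; ++dc) {
        int cc = c + dc; if (cc < 0 || cc >= d3) continue;
        for (int db = -1; db <= 1; ++db) {
          int bb = b + db; if (bb < 0 || bb >= d2) continue;
          for (int da = -1; da <= 1; ++da) {
            int aa = a + da; if (aa < 0 || aa >= d1) continue;
            int man = std::abs(da) + std::abs(db) + std::abs(dc);
            if (man == 0) continue;
            if (connectivity == 6 && man > 1) continue;
            if (connectivity == 18 && man > 2) continue;
            int w = idx3(aa, bb, cc, d1, d2);
            if (vox[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- exact Euclidean distance transform (separable lower envelope) ---------

static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &z,
                  int n, double w) {
  // squared-distance transform of sampled function f along one axis,
  // sample spacing w (Felzenszwalb & Huttenlocher)
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double)q * w, vv = (double)v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * w;
    while (z[k + 1] < qq) ++k;
    double vv = (double)v[k] * w;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  // Euclidean distance (mm) from every voxel to the nearest foreground voxel.
  // Lines with no foreground use a large finite sentinel rather than +Inf:
  // infinite parabolas make the lower-envelope intersection underflow k.
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int n = d1 * d2 * d3;
  const double BIG = 1e18;
  NumericVector out(n);
  for (int s = 0; s < n; ++s) out[s] = fg[s] ? 0.0 : BIG;
  int m = std::max(d1, std::max(d2, d3));
  std::vector<double> f(m), d(m), z(m + 1);
  std::vector<int> v(m);
  // axis 1
  for (int c = 0; c < d3; ++c)
    for (int b = 0; b < d2; ++b) {
      for (int a = 0; a < d1; ++a) f[a] = out[idx3(a, b, c, d1, d2)];
      edt1d(f, d, v, z, d1, spacing[0]);
      for (int a = 0; a < d1; ++a) out[idx3(a, b, c, d1, d2)] = d[a];
    }
  // axis 2
  for (int c = 0; c < d3; ++c)
    for (int a = 0; a < d1; ++a) {
      for (int b = 0; b < d2; ++b) f[b] = out[idx3(a, b, c, d1, d2)];
      edt1d(f, d, v, z, d2, spacing[1]);
      for (int b = 0; b < d2; ++b) out[idx3(a, b, c, d1, d2)] = d[b];
    }
  // axis 3
  for (int b = 0; b < d2; ++b)
    for (int a = 0; a < d1; ++a) {
      for (int c = 0; c < d3; ++c) f[c] = out[idx3(a, b, c, d1, d2)];
      edt1d(f, d, v, z, d3, spacing[2]);
      for (int c = 0; c < d3; ++c) out[idx3(a, b, c, d1, d2)] = d[c];
    }
  for (int s = 0; s < n; ++s) out[s] = std::sqrt(out[s]);
  out.attr("dim") = dim;
  return out;
}

// ---- topology-preserving 3D thinning ---------------------------------------

// simple-point test in (26, 6) digital topology: deletion keeps both the
// object 26-topology and the background 6-topology of the 3x3x3 neighbourhood

static int n26_components(const bool nb[27]) {
  // 26-connected components of foreground among the 26 neighbours
  bool seen[27] = {false};
  int comps = 0;
  int stack[27], top;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comps;
    top = 0; stack[top++] = i; seen[i] = true;
    while (top) {
      int v = stack[--top];
      int va = v % 3, vb = (v / 3) % 3, vc = v / 9;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || !nb[j] || seen[j]) continue;
        int ja = j % 3, jb = (j / 3) % 3, jc = j / 9;
        if (std::abs(ja - va) <= 1 && std::abs(jb - vb) <= 1 && std::abs(jc - vc) <= 1) {
          seen[j] = true; stack[top++] = j;
        }
      }
    }
  }
  return comps;
}

static int n6_bg_components(const bool nb[27]) {
  // 6-connected components of background within the 18-neighbourhood that
  // touch a face neighbour of the centre
  static const int off[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  bool in18[27] = {false};
  for (int i = 0; i < 27; ++i) {
    int a = i % 3 - 1, b = (i / 3) % 3 - 1, c = i / 9 - 1;
    if (i != 13 && std::abs(a) + std::abs(b) + std::abs(c) <= 2) in18[i] = true;
  }
  bool seen[27] = {false};
  int comps = 0, stack[27], top;
  for (int k = 0; k < 6; ++k) {
    int s = off[k];
    if (nb[s] || seen[s]) continue;
    ++comps;
    top = 0; stack[top++] = s; seen[s] = true;
    while (top) {
      int v = stack[--top];
      int va = v % 3, vb = (v / 3) % 3, vc = v / 9;
      for (int j = 0; j < 27; ++j) {
        if (!in18[j] || nb[j] || seen[j]) continue;
        int ja = j % 3, jb = (j / 3) % 3, jc = j / 9;
        int man = std::abs(ja - va) + std::abs(jb - vb) + std::abs(jc - vc);
        if (man == 1) { seen[j] = true; stack[top++] = j; }
      }
    }
  }
  return comps;
}

static void fill_neighbourhood(const LogicalVector &vox, bool nb[27],
                               int a, int b, int c, int d1, int d2, int d3) {
  for (int dc = -1; dc <= 1; ++dc)
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da) {
        int i = (da + 1) + 3 * (db + 1) + 9 * (dc + 1);
        int aa = a + da, bb = b + db, cc = c + dc;
        nb[i] = (aa >= 0 && aa < d1 && bb >= 0 && bb < d2 && cc >= 0 && cc < d3)
          ? (bool)vox[idx3(aa, bb, cc, d1, d2)] : false;
      }
}

static inline bool is_simple(const bool nb[27]) {
  return n26_components(nb) == 1 && n6_bg_components(nb) == 1;
}

static inline int fg_neighbours(const bool nb[27]) {
  int k = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++k;
  return k;
}

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector vox_in, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  LogicalVector vox = clone(vox_in);
  // face-direction offsets for the 6 directional sub-iterations
  static const int dirs[6][3] = {
    {-1, 0, 0}, {1, 0, 0}, {0, -1, 0}, {0, 1, 0}, {0, 0, -1}, {0, 0, 1}
  };
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      std::vector<int> cand;
      for (int c = 0; c < d3; ++c)
        for (int b = 0; b < d2; ++b)
          for (int a = 0; a < d1; ++a) {
            int s = idx3(a, b, c, d1, d2);
            if (!vox[s]) continue;
            int aa = a + dirs[dir][0], bb = b + dirs[dir][1], cc = c + dirs[dir][2];
            bool border = !(aa >= 0 && aa < d1 && bb >= 0 && bb < d2 && cc >= 0 && cc < d3)
              || !vox[idx3(aa, bb, cc, d1, d2)];
            if (!border) continue;
            fill_neighbourhood(vox, nb, a, b, c, d1, d2, d3);
            int k = fg_neighbours(nb);
            if (k <= 1) continue;          // endpoint: keep
            if (is_simple(nb)) cand.push_back(s);
          }
      // sequential re-check so deletions inside one sub-iteration cannot
      // break topology
      for (size_t t = 0; t < cand.size(); ++t) {
        int s = cand[t];
        int a = s % d1, rem = s / d1;
        int b = rem % d2, c = rem / d2;
        fill_neighbourhood(vox, nb, a, b, c, d1, d2, d3);
        if (fg_neighbours(nb) <= 1) continue;
        if (is_simple(nb)) { vox[s] = false; changed = true; }
      }
    }
  }
  vox.attr("dim") = dim;
  return vox;
}
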