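#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum Euclidean distance between two coordinate sets (rows are points).
// [[Rcpp::export]]
double cpp_min_set_dist(const NumericMatrix& a, const NumericMatrix& b) {
  double best = R_PosInf;
  const int na = a.nrow(), nb = b.nrow();
  for (int i = 0; i < na; ++i) {
    const double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - b(j, 0), dy = yi - b(j, 1), dz = zi - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// All-pairs minimum set-to-set distances under a cutoff, for point sets
// stored as one stacked coordinate matrix with per-set row ranges
// (1-based inclusive). Pairs are pruned with per-set bounding spheres:
// min distance >= center distance - r_i - r_j.
// [[Rcpp::export]]
DataFrame cpp_set_edges(const NumericMatrix& coords,
                        const IntegerVector& start,
                        const IntegerVector& end,
                        double cutoff, bool strict) {
  const int n = start.size();
  std::vector<double> cx(n), cy(n), cz(n), rad(n);
  for (int s = 0; s < n; ++s) {
    double sx = 0, sy = 0, sz = 0;
    const int a = start[s] - 1, b = end[s] - 1;
    for (int i = a; i <= b; ++i) { sx += coords(i, 0); sy += coords(i, 1); sz += coords(i, 2); }
    const int m = b - a + 1;
    cx[s] = sx / m; cy[s] = sy / m; cz[s] = sz / m;
    double r2 = 0;
    for (int i = a; i <= b; ++i) {
      const double dx = coords(i, 0) - cx[s], dy = coords(i, 1) - cy[s], dz = coords(i, 2) - cz[s];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[s] = std::sqrt(r2);
  }
  std::vector<int> ei, ej;
  std::vector<double> ed;
  for (int s = 0; s < n; ++s) {
    for (int t = s + 1; t < n; ++t) {
      const double dx = cx[s] - cx[t], dy = cy[s] - cy[t], dz = cz[s] - cz[t];
      const double cd = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (cd - rad[s] - rad[t] > cutoff) continue;
      double best = R_PosInf;
      for (int i = start[s] - 1; i <= end[s] - 1; ++i) {
        for (int j = start[t] - 1; j <= end[t] - 1; ++j) {
          const double ddx = coords(i, 0) - coords(j, 0);
          const double ddy = coords(i, 1) - coords(j, 1);
          const double ddz = coords(i, 2) - coords(j, 2);
          const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (d2 < best) best = d2;
        }
      }
      best = std::sqrt(best);
      const bool keep = strict ? (best < cutoff) : (best <= cutoff);
      if (keep) { ei.push_back(s + 1); ej.push_back(t + 1); ed.push_back(best); }
    }
  }
  return DataFrame::create(_["i"] = ei, _["j"] = ej, _["dist"] = ed);
}

// Unpruned counterpart of cpp_set_edges: every pair is evaluated with the
// naive double loop. Kept as an independent brute-force oracle so the
// bounding-sphere pruning above can be verified against it.
// [[Rcpp::export]]
DataFrame cpp_set_edges_brute(const NumericMatrix& coords,
                              const IntegerVector& start,
                              const IntegerVector& end,
                              double cutoff, bool strict) {
  const int n = start.size();
  std::vector<int> ei, ej;
  std::vector<double> ed;
  for (int s = 0; s < n; ++s) {
    for (int t = s + 1; t < n; ++t) {
      double best = R_PosInf;
      for (int i = start[s] - 1; i <= end[s] - 1; ++i) {
        for (int j = start[t] - 1; j <= end[t] - 1; ++j) {
          const double ddx = coords(i, 0) - coords(j, 0);
          const double ddy = coords(i, 1) - coords(j, 1);
          const double ddz = coords(i, 2) - coords(j, 2);
          const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (d2 < best) best = d2;
        }
      }
      best = std::sqrt(best);
      const bool keep = strict ? (best < cutoff) : (best <= cutoff);
      if (keep) { ei.push_back(s + 1); ej.push_back(t + 1); ed.push_back(best); }
    }
  }
  return DataFrame::create(_["i"] = ei, _["j"] = ej, _["dist"] = ed);
}

// Index (1-based) of the nearest atom to each query point.
// [[Rcpp::export]]
IntegerVector cpp_nearest_atom(const NumericMatrix& points, const NumericMatrix& atoms) {
  const int np = points.nrow(), na = atoms.nrow();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf;
    int arg = 0;
    const double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    for (int a = 0; a < na; ++a) {
      const double dx = px - atoms(a, 0), dy = py - atoms(a, 1), dz = pz - atoms(a, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; arg = a; }
    }
    out[p] = arg + 1;
  }
  return out;
}
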