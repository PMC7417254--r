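#include <Rcpp.h>
using namespace Rcpp;

static const double EARTH_R_M = 6371008.8; // sphere radius, metres

static inline double hav_m(double lon1, double lat1, double lon2, double lat2) {
  const double d2r = M_PI / 180.0;
  double dlat = (lat2 - lat1) * d2r, dlon = (lon2 - lon1) * d2r;
  double a = std::sin(dlat / 2) * std::sin(dlat / 2) +
             std::cos(lat1 * d2r) * std::cos(lat2 * d2r) *
             std::sin(dlon / 2) * std::sin(dlon / 2);
  if (a > 1.0) a = 1.0;
  return 2.0 * EARTH_R_M * std::asin(std::sqrt(a));
}

// Greedy maximal-run residency clusters: a fix extends the open cluster iff
// its distance to the anchor (running centroid, or the first fix) is within
// radius_m; otherwise the cluster closes and a new one opens at that fix.
// Gaps in the fix schedule do not break a cluster. Returns 1-based start/end
// indices plus centroid and the max accepted anchor distance.
// [[Rcpp::export(name = ".cluster_scan")]]
DataFrame cluster_scan(NumericVector lon, NumericVector lat,
                       double radius_m, int min_fixes, bool centroid_anchor) {
  int n = lon.size();
  std::vector<int> s, e, cnt;
  std::vector<double> clon, clat, maxr;
  if (n == 0)
    return DataFrame::create(_["start"] = s, _["end"] = e, _["n_fixes"] = cnt,
                             _["lon"] = clon, _["lat"] = clat,
                             _["max_radius_m"] = maxr);
  int start = 0, m = 1;
  double sx = lon[0], sy = lat[0], mr = 0.0;
  for (int i = 1; i <= n; ++i) {
    bool extend = false;
    double d = 0.0;
    if (i < n) {
      double ax = centroid_anchor ? sx / m : lon[start];
      double ay = centroid_anchor ? sy / m : lat[start];
      d = hav_m(ax, ay, lon[i], lat[i]);
      extend = d <= radius_m;
    }
    if (extend) {
      sx += lon[i]; sy += lat[i]; ++m;
      if (d > mr) mr = d;
    } else {
      if (m >= min_fixes) {
        s.push_back(start + 1); e.push_back(start + m); cnt.push_back(m);
        clon.push_back(sx / m); clat.push_back(sy / m); maxr.push_back(mr);
      }
      if (i < n) { start = i; m = 1; sx = lon[i]; sy = lat[i]; mr = 0.0; }
    }
  }
  return DataFrame::create(_["start"] = s, _["end"] = e, _["n_fixes"] = cnt,
                           _["lon"] = clon, _["lat"] = clat,
                           _["max_radius_m"] = maxr);
}

// Cumulative point coverage along an ordered hull accumulation: hulls are
// convex CCW rings visited in the given order; a point is covered once it
// lies inside or on (eps-inclusive) any visited hull. Degenerate rings of
// one or two vertices cover points within eps of the point / segment.
// Returns the covered count after each hull.
// [[Rcpp::export(name = ".cover_counts")]]
IntegerVector cover_counts(List rings, NumericMatrix pts, double eps) {
  int n = pts.nrow(), H = rings.size();
  std::vector<bool> covered(n, false);
  std::vector<int> todo(n);
  for (int i = 0; i < n; ++i) todo[i] = i;
  IntegerVector out(H);
  int ncov = 0;
  for (int h = 0; h < H; ++h) {
    NumericMatrix r = rings[h];
    int v = r.nrow();
    std::vector<int> next;
    next.reserve(todo.size());
    for (size_t q = 0; q < todo.size(); ++q) {
      int i = todo[q];
      double px = pts(i, 0), py = pts(i, 1);
      bool inside;
      if (v == 1) {
        double dx = px - r(0, 0), dy = py - r(0, 1);
        inside = std::sqrt(dx * dx + dy * dy) <= eps;
      } else if (v == 2) {
        double ax = r(0, 0), ay = r(0, 1), bx = r(1, 0), by = r(1, 1);
        double abx = bx - ax, aby = by - ay, L2 = abx * abx + aby * aby;
        double t = L2 > 0 ? ((px - ax) * abx + (py - ay) * aby) / L2 : 0.0;
        if (t < 0) t = 0; if (t > 1) t = 1;
        double dx = px - (ax + t * abx), dy = py - (ay + t * aby);
        inside = std::sqrt(dx * dx + dy * dy) <= eps;
      } else {
        inside = true;
        for (int e = 0; e < v && inside; ++e) {
          int f = (e + 1) % v;
          double cr = (r(f, 0) - r(e, 0)) * (py - r(e, 1)) -
                      (r(f, 1) - r(e, 1)) * (px - r(e, 0));
          if (cr < -eps) inside = false;
        }
      }
      if (inside) { covered[i] = true; ++ncov; }
      else next.push_back(i);
    }
    todo.swap(next);
    out[h] = ncov;
  }
  return out;
}

// Exact union area of overlapping convex polygons by vertical slab sweep:
// slab boundaries are every vertex x plus every pairwise edge crossing, so
// the covered y-length is linear within a slab and the midpoint rule is
// exact. Rings must be convex (orientation free); degenerate rings are the
// caller's job to remove.
// [[Rcpp::export(name = ".union_area_sweep")]]
double union_area_sweep_cpp(List rings) {
  int H = rings.size();
  std::vector<double> ex1, ey1, ex2, ey2;
  std::vector<int> ehid;
  std::vector<double> xs;
  for (int h = 0; h < H; ++h) {
    NumericMatrix r = rings[h];
    int v = r.nrow();
    for (int e = 0; e < v; ++e) {
      int f = (e + 1) % v;
      ex1.push_back(r(e, 0)); ey1.push_back(r(e, 1));
      ex2.push_back(r(f, 0)); ey2.push_back(r(f, 1));
      ehid.push_back(h);
      xs.push_back(r(e, 0));
    }
  }
  int E = ex1.size();
  if (E == 0) return 0.0;
  // pairwise crossings between edges of different hulls
  for (int i = 0; i < E; ++i) {
    double ix_lo = std::min(ex1[i], ex2[i]), ix_hi = std::max(ex1[i], ex2[i]);
    double iy_lo = std::min(ey1[i], ey2[i]), iy_hi = std::max(ey1[i], ey2[i]);
    for (int j = i + 1; j < E; ++j) {
      if (ehid[j] == ehid[i]) continue;
      if (std::min(ex1[j], ex2[j]) > ix_hi || std::max(ex1[j], ex2[j]) < ix_lo ||
          std::min(ey1[j], ey2[j]) > iy_hi || std::max(ey1[j], ey2[j]) < iy_lo)
        continue;
      double d1x = ex2[i] - ex1[i], d1y = ey2[i] - ey1[i];
      double d2x = ex2[j] - ex1[j], d2y = ey2[j] - ey1[j];
      double den = d1x * d2y - d1y * d2x;
      if (den == 0.0) continue;
      double rx = ex1[j] - ex1[i], ry = ey1[j] - ey1[i];
      double t = (rx * d2y - ry * d2x) / den;
      double u = (rx * d1y - ry * d1x) / den;
      if (t >= 0 && t <= 1 && u >= 0 && u <= 1)
        xs.push_back(ex1[i] + t * d1x);
    }
  }
  std::sort(xs.begin(), xs.end());
  double scale = std::max(std::abs(xs.front()), std::abs(xs.back()));
  if (scale < 1.0) scale = 1.0;
  std::vector<double> xb;
  xb.push_back(xs[0]);
  for (size_t q = 1; q < xs.size(); ++q)
    if (xs[q] - xb.back() > 1e-13 * scale) xb.push_back(xs[q]);
  int S = xb.size() - 1;
  if (S < 1) return 0.0;
  // per-hull y-interval at each slab midpoint
  std::vector<double> ylo((size_t)H * S, std::numeric_limits<double>::infinity());
  std::vector<double> yhi((size_t)H * S, -std::numeric_limits<double>::infinity());
  for (int e = 0; e < E; ++e) {
    if (ex1[e] == ex2[e]) continue;
    double lo = std::min(ex1[e], ex2[e]), hi = std::max(ex1[e], ex2[e]);
    int s0 = std::lower_bound(xb.begin(), xb.end(), lo) - xb.begin();
    for (int s = std::max(0, s0 - 1); s < S; ++s) {
      double xm = 0.5 * (xb[s] + xb[s + 1]);
      if (xm <= lo) continue;
      if (xm >= hi) break;
      double yv = ey1[e] + (ey2[e] - ey1[e]) * (xm - ex1[e]) / (ex2[e] - ex1[e]);
      size_t idx = (size_t)ehid[e] * S + s;
      if (yv < ylo[idx]) ylo[idx] = yv;
      if (yv > yhi[idx]) yhi[idx] = yv;
    }
  }
  // merge intervals per slab
  double area = 0.0;
  std::vector<std::pair<double, double>> iv;
  for (int s = 0; s < S; ++s) {
    iv.clear();
    for (int h = 0; h < H; ++h) {
      size_t idx = (size_t)h * S + s;
      if (std::isfinite(ylo[idx]))
        iv.push_back(std::make_pair(ylo[idx], yhi[idx]));
    }
    if (iv.empty()) continue;
    std::sort(iv.begin(), iv.end());
    double w = xb[s + 1] - xb[s], cov = 0.0;
    double clo = iv[0].first, chi = iv[0].second;
    for (size_t q = 1; q < iv.size(); ++q) {
      if (iv[q].first <= chi) {
        if (iv[q].second > chi) chi = iv[q].second;
      } else {
        cov += chi - clo;
        clo = iv[q].first; chi = iv[q].second;
      }
    }
    cov += chi - clo;
    area += w * cov;
  }
  return area;
}

// Containment pruning for a list of convex rings sorted by descending
// area: ring i is dropped when all its vertices lie inside (eps-inclusive)
// an earlier kept ring with at least 3 vertices. Convexity makes vertex
// containment equivalent to polygon containment.
// [[Rcpp::export(name = ".prune_contained")]]
LogicalVector prune_contained_cpp(List rings, double eps) {
  int H = rings.size();
  LogicalVector keep(H, true);
  std::vector<NumericMatrix> rs(H);
  for (int h = 0; h < H; ++h) rs[h] = as<NumericMatrix>(rings[h]);
  for (int i = 1; i < H; ++i) {
    NumericMatrix ri = rs[i];
    for (int j = 0; j < i; ++j) {
      if (!keep[j]) continue;
      NumericMatrix rj = rs[j];
      int v = rj.nrow();
      if (v < 3) continue;
      bool all_in = true;
      for (int p = 0; p < ri.nrow() && all_in; ++p) {
        double px = ri(p, 0), py = ri(p, 1);
        for (int e = 0; e < v; ++e) {
          int f = (e + 1) % v;
          double cr = (rj(f, 0) - rj(e, 0)) * (py - rj(e, 1)) -
                      (rj(f, 1) - rj(e, 1)) * (px - rj(e, 0));
          if (cr < -eps) { all_in = false; break; }
        }
      }
      if (all_in) { keep[i] = false; break; }
    }
  }
  return keep;
}
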