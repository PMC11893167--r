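#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Uniform-grid spatial index over a 3D point set. Queries are exact
// (identical result, including lowest-index tie-breaking, to a brute-force
// scan): a cell is skipped only when the squared distance from the query to
// the cell's bounding box strictly exceeds the current best.
namespace {

struct PointGrid {
  const NumericMatrix& pts;
  double lo[3];
  double cell;
  int dim[3];
  std::vector<std::vector<int> > buckets;

  explicit PointGrid(const NumericMatrix& target) : pts(target) {
    const int m = target.nrow();
    double hi[3];
    for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
    for (int i = 0; i < m; ++i)
      for (int d = 0; d < 3; ++d) {
        const double v = target(i, d);
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    double ext = 0.0;
    for (int d = 0; d < 3; ++d) ext = std::max(ext, hi[d] - lo[d]);
    // aim for a few points per occupied cell
    const int ncell = std::max(1, (int)std::floor(std::cbrt((double)m / 2.0)));
    cell = std::max(ext / ncell, 1e-12);
    std::size_t total = 1;
    for (int d = 0; d < 3; ++d) {
      dim[d] = (int)std::floor((hi[d] - lo[d]) / cell) + 1;
      if (dim[d] < 1) dim[d] = 1;
      total *= (std::size_t)dim[d];
    }
    buckets.assign(total, std::vector<int>());
    for (int i = 0; i < m; ++i) buckets[cell_of(i)].push_back(i);
  }

  int clampi(double v, int d) const {
    int c = (int)std::floor((v - lo[d]) / cell);
    if (c < 0) c = 0;
    if (c >= dim[d]) c = dim[d] - 1;
    return c;
  }
  std::size_t idx(int ix, int iy, int iz) const {
    return ((std::size_t)iz * dim[1] + iy) * dim[0] + ix;
  }
  std::size_t cell_of(int i) const {
    return idx(clampi(pts(i, 0), 0), clampi(pts(i, 1), 1), clampi(pts(i, 2), 2));
  }

  double box_dist2(double x, double y, double z, int ix, int iy, int iz) const {
    double q[3] = { x, y, z };
    int c[3] = { ix, iy, iz };
    double d2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      const double a = lo[d] + c[d] * cell, b = a + cell;
      double dd = 0.0;
      if (q[d] < a) dd = a - q[d];
      else if (q[d] > b) dd = q[d] - b;
      d2 += dd * dd;
    }
    return d2;
  }

  // nearest point to (x,y,z); ties to lowest index
  void nearest(double x, double y, double z, int& best_i, double& best_d2) const {
    best_i = -1;
    best_d2 = R_PosInf;
    const int cx = clampi(x, 0), cy = clampi(y, 1), cz = clampi(z, 2);
    const int maxring = std::max(dim[0], std::max(dim[1], dim[2]));
    for (int k = 0; k <= maxring; ++k) {
      if (best_i >= 0) {
        const double bound = (double)(k - 1) * cell;
        if (bound > 0.0 && bound * bound > best_d2) break;
      }
      const int x0 = std::max(0, cx - k), x1 = std::min(dim[0] - 1, cx + k);
      const int y0 = std::max(0, cy - k), y1 = std::min(dim[1] - 1, cy + k);
      const int z0 = std::max(0, cz - k), z1 = std::min(dim[2] - 1, cz + k);
      for (int iz = z0; iz <= z1; ++iz)
        for (int iy = y0; iy <= y1; ++iy)
          for (int ix = x0; ix <= x1; ++ix) {
            const int ring = std::max(std::abs(ix - cx),
                             std::max(std::abs(iy - cy), std::abs(iz - cz)));
            if (ring != k) continue;
            if (box_dist2(x, y, z, ix, iy, iz) > best_d2) continue;
            const std::vector<int>& b = buckets[idx(ix, iy, iz)];
            for (std::size_t t = 0; t < b.size(); ++t) {
              const int i = b[t];
              const double dx = pts(i, 0) - x, dy = pts(i, 1) - y,
                           dz = pts(i, 2) - z;
              const double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best_d2 || (d2 == best_d2 && i < best_i)) {
                best_d2 = d2;
                best_i = i;
              }
            }
          }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_nearest_point(NumericMatrix query, NumericMatrix target) {
  const int nq = query.nrow();
  if (target.nrow() == 0) stop("empty target point set");
  PointGrid grid(target);
  IntegerVector id(nq);
  NumericVector dist(nq);
  for (int q = 0; q < nq; ++q) {
    int bi;
    double bd2;
    grid.nearest(query(q, 0), query(q, 1), query(q, 2), bi, bd2);
    id[q] = bi + 1;
    dist[q] = std::sqrt(bd2);
  }
  return List::create(_["index"] = id, _["distance"] = dist);
}

// Ordered-pair counts of d_ij <= r for each r in an ascending grid.
// [[Rcpp::export]]
NumericVector cpp_pair_count(NumericMatrix points, NumericVector r) {
  const int n = points.nrow(), nr = r.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = r[k] * r[k];
  std::vector<double> tally(nr + 1, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = points(i, 0) - points(j, 0),
                   dy = points(i, 1) - points(j, 1),
                   dz = points(i, 2) - points(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      // first grid index with r^2 >= d2
      const int k = std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin();
      tally[k] += 1.0;
    }
  NumericVector out(nr);
  double acc = 0.0;
  for (int k = 0; k < nr; ++k) {
    acc += tally[k];
    out[k] = 2.0 * acc; // ordered pairs
  }
  return out;
}

// For each point, is it within `radius` (inclusive) of any seed?
// [[Rcpp::export]]
LogicalVector cpp_within_radius(NumericMatrix points, NumericMatrix seeds,
                                double radius) {
  const int n = points.nrow(), s = seeds.nrow();
  if (s == 0) return LogicalVector(n, false);
  PointGrid grid(seeds);
  const double r2 = radius * radius;
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    int bi;
    double bd2;
    grid.nearest(points(i, 0), points(i, 1), points(i, 2), bi, bd2);
    out[i] = bd2 <= r2;
  }
  return out;
}

// Nearest target point inside a cone of half-angle acos(cos_half) around
// each source direction, limited to max_range. NA where no target qualifies.
// [[Rcpp::export]]
NumericVector cpp_cone_nearest(NumericMatrix src, NumericMatrix dirs,
                               NumericMatrix target, double cos_half,
                               double max_range) {
  const int n = src.nrow(), m = target.nrow();
  if (m == 0) stop("empty target point set");
  const double r2max = max_range * max_range;
  NumericVector out(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    const double sx = src(i, 0), sy = src(i, 1), sz = src(i, 2);
    const double ux = dirs(i, 0), uy = dirs(i, 1), uz = dirs(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = target(j, 0) - sx, dy = target(j, 1) - sy,
                   dz = target(j, 2) - sz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2max || d2 >= best) continue;
      const double d = std::sqrt(d2);
      if (d == 0.0) { best = 0.0; continue; }
      const double proj = (dx * ux + dy * uy + dz * uz) / d;
      if (proj >= cos_half) best = d2 < best ? d2 : best;
    }
    if (R_finite(best)) out[i] = std::sqrt(best);
  }
  return out;
}
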