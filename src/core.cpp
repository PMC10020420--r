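#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Geometric kernels for the selfish-herd model: cutoff-bounded Voronoi
// cells (domain of danger), vision-cone observables with sight blocking,
// and hard-disk overlap resolution. All lengths in units of the body
// diameter sigma.

static const double GEOM_TOL = 1e-9;

struct Pt { double x, y; };

static inline double cross2(const Pt& a, const Pt& b) { return a.x * b.y - a.y * b.x; }
static inline double dot2(const Pt& a, const Pt& b) { return a.x * b.x + a.y * b.y; }
static inline double norm2(const Pt& a) { return std::sqrt(a.x * a.x + a.y * a.y); }

// Minimum distance from point p to segment [a, b].
static double pointSegDist(const Pt& p, const Pt& a, const Pt& b) {
  Pt d = { b.x - a.x, b.y - a.y };
  double len2 = d.x * d.x + d.y * d.y;
  if (len2 < 1e-30) {
    Pt r = { p.x - a.x, p.y - a.y };
    return norm2(r);
  }
  double t = ((p.x - a.x) * d.x + (p.y - a.y) * d.y) / len2;
  t = std::max(0.0, std::min(1.0, t));
  Pt c = { a.x + t * d.x - p.x, a.y + t * d.y - p.y };
  return norm2(c);
}

// Labelled convex polygon: vertex k starts the edge with label[k]
// (-1 = bounding box, j >= 0 = bisector against generator j).
struct LabPoly {
  std::vector<Pt> v;
  std::vector<int> lab;
};

// Clip a convex polygon by the half-plane n . x <= c (inward side kept),
// labelling any newly created edge on the clip line with `clipLab`.
static void clipHalfplane(LabPoly& poly, const Pt& n, double c, int clipLab) {
  size_t m = poly.v.size();
  if (m == 0) return;
  std::vector<Pt> nv;
  std::vector<int> nl;
  nv.reserve(m + 2);
  nl.reserve(m + 2);
  std::vector<double> f(m);
  for (size_t k = 0; k < m; ++k) f[k] = dot2(n, poly.v[k]) - c;
  for (size_t k = 0; k < m; ++k) {
    size_t k2 = (k + 1) % m;
    const Pt& A = poly.v[k];
    const Pt& B = poly.v[k2];
    bool ain = f[k] <= GEOM_TOL;
    bool bin = f[k2] <= GEOM_TOL;
    if (ain) {
      if (bin) {
        nv.push_back(A); nl.push_back(poly.lab[k]);
      } else {
        double t = f[k] / (f[k] - f[k2]);
        Pt I = { A.x + t * (B.x - A.x), A.y + t * (B.y - A.y) };
        nv.push_back(A); nl.push_back(poly.lab[k]);
        nv.push_back(I); nl.push_back(clipLab);
      }
    } else if (bin) {
      double t = f[k] / (f[k] - f[k2]);
      Pt I = { A.x + t * (B.x - A.x), A.y + t * (B.y - A.y) };
      nv.push_back(I); nl.push_back(poly.lab[k]);
    }
  }
  poly.v = nv;
  poly.lab = nl;
}

// Exact area of intersection of a convex polygon (CCW, containing the
// origin) with the disk of radius r centred at the origin. Edges fully
// inside contribute triangles, portions outside contribute circular
// sectors; pieces are delimited by segment-circle intersections.
static double polyDiskArea(const LabPoly& poly, double r) {
  size_t m = poly.v.size();
  if (m < 3) return 0.0;
  double r2 = r * r;
  double area = 0.0;
  for (size_t k = 0; k < m; ++k) {
    const Pt& A = poly.v[k];
    const Pt& B = poly.v[(k + 1) % m];
    Pt d = { B.x - A.x, B.y - A.y };
    double a = d.x * d.x + d.y * d.y;
    std::vector<double> ts;
    ts.push_back(0.0);
    if (a > 1e-30) {
      double b = 2.0 * (A.x * d.x + A.y * d.y);
      double c = A.x * A.x + A.y * A.y - r2;
      double disc = b * b - 4.0 * a * c;
      if (disc > 0.0) {
        double sq = std::sqrt(disc);
        double t1 = (-b - sq) / (2.0 * a);
        double t2 = (-b + sq) / (2.0 * a);
        if (t1 > 1e-12 && t1 < 1.0 - 1e-12) ts.push_back(t1);
        if (t2 > 1e-12 && t2 < 1.0 - 1e-12) ts.push_back(t2);
      }
    }
    ts.push_back(1.0);
    std::sort(ts.begin(), ts.end());
    for (size_t s = 0; s + 1 < ts.size(); ++s) {
      double ta = ts[s], tb = ts[s + 1];
      if (tb - ta < 1e-14) continue;
      Pt P = { A.x + ta * d.x, A.y + ta * d.y };
      Pt Q = { A.x + tb * d.x, A.y + tb * d.y };
      double tm = 0.5 * (ta + tb);
      Pt M = { A.x + tm * d.x, A.y + tm * d.y };
      if (M.x * M.x + M.y * M.y <= r2) {
        area += 0.5 * cross2(P, Q);
      } else {
        double ang = std::atan2(cross2(P, Q), dot2(P, Q));
        area += 0.5 * r2 * ang;
      }
    }
  }
  return area;
}

// Cutoff-bounded Voronoi tessellation. Returns per-agent cell areas
// (Voronoi cell intersected with the disk of radius delta around the
// agent), the within-cutoff Voronoi adjacency, and nearest-neighbour
// distances.
// [[Rcpp::export(name = ".dod_cpp")]]
List dod_cpp(NumericMatrix pos, double delta) {
  int n = pos.nrow();
  NumericVector areas(n);
  LogicalMatrix adj(n, n);
  NumericVector nn(n);
  std::fill(nn.begin(), nn.end(), R_PosInf);

  // nearest-neighbour distances (exact, O(N^2))
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < nn[i]) nn[i] = d;
      if (d < nn[j]) nn[j] = d;
    }
  }

  double half = 2.5 * delta;  // bounding box comfortably beyond the cutoff
  LogicalMatrix rawAdj(n, n); // adjacency as seen from each agent's cell

  for (int i = 0; i < n; ++i) {
    LabPoly poly;
    poly.v = { { -half, -half }, { half, -half }, { half, half }, { -half, half } };
    poly.lab = { -1, -1, -1, -1 };
    // clip by perpendicular bisectors, coordinates relative to agent i
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      Pt rij = { pos(j, 0) - pos(i, 0), pos(j, 1) - pos(i, 1) };
      double d = norm2(rij);
      if (d >= 2.0 * delta) continue;  // bisector cannot reach the cutoff disk
      Pt nrm = { rij.x / d, rij.y / d };
      clipHalfplane(poly, nrm, 0.5 * d, j);
      if (poly.v.size() < 3) break;
    }
    areas[i] = polyDiskArea(poly, delta);
    // shared bisector edges intersecting the cutoff disk -> adjacency
    size_t m = poly.v.size();
    for (size_t k = 0; k < m; ++k) {
      int j = poly.lab[k];
      if (j < 0) continue;
      const Pt& A = poly.v[k];
      const Pt& B = poly.v[(k + 1) % m];
      Pt d = { B.x - A.x, B.y - A.y };
      if (norm2(d) < GEOM_TOL) continue;
      Pt origin = { 0.0, 0.0 };
      if (pointSegDist(origin, A, B) < delta - 1e-12) rawAdj(i, j) = true;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      adj(i, j) = rawAdj(i, j) && rawAdj(j, i);

  return List::create(_["areas"] = areas, _["adjacency"] = adj, _["nn_distance"] = nn);
}

// Five-sector 180-degree vision-cone observable for every agent.
// Each visible neighbour j adds sigma/|r_ij| to the sector holding the
// bearing of its centre; with `occlusion`, a neighbour is invisible when
// the sight line passes within sigma/2 of a nearer agent's centre.
// [[Rcpp::export(name = ".observe_all_cpp")]]
NumericMatrix observe_all_cpp(NumericMatrix pos, NumericVector heading,
                              bool occlusion, double half_angle,
                              int n_sectors, double sigma) {
  int n = pos.nrow();
  NumericMatrix obs(n, n_sectors);
  double width = 2.0 * half_angle / n_sectors;

  std::vector<int> order(n);
  std::vector<double> di(n);
  for (int i = 0; i < n; ++i) {
    double hx = std::cos(heading[i]), hy = std::sin(heading[i]);
    Pt pi = { pos(i, 0), pos(i, 1) };
    if (occlusion) {
      // neighbours sorted by distance: blockers of j can only be strictly
      // nearer agents, i.e. a prefix of this order
      for (int j = 0; j < n; ++j) {
        order[j] = j;
        double dx = pos(j, 0) - pi.x, dy = pos(j, 1) - pi.y;
        di[j] = std::sqrt(dx * dx + dy * dy);
      }
      std::sort(order.begin(), order.end(),
                [&](int a, int b) { return di[a] < di[b]; });
    }
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      Pt rij = { pos(j, 0) - pi.x, pos(j, 1) - pi.y };
      double d = norm2(rij);
      if (d < GEOM_TOL) stop("coincident agents in observe()");
      // bearing of j relative to i's heading, positive = left (CCW)
      double bearing = std::atan2(hx * rij.y - hy * rij.x, hx * rij.x + hy * rij.y);
      if (bearing < -half_angle - 1e-12 || bearing > half_angle + 1e-12) continue;
      if (occlusion) {
        bool blocked = false;
        Pt pj = { pos(j, 0), pos(j, 1) };
        for (int s = 0; s < n && !blocked; ++s) {
          int k = order[s];
          if (di[k] >= d) break;  // only strictly nearer agents block
          if (k == i || k == j) continue;
          Pt pk = { pos(k, 0), pos(k, 1) };
          if (pointSegDist(pk, pi, pj) < 0.5 * sigma) blocked = true;
        }
        if (blocked) continue;
      }
      // sectors ordered left (most counter-clockwise) to right; exact
      // boundaries belong to the lower-index sector
      int s = (int)std::ceil((half_angle - bearing) / width - 1e-9);
      if (s < 1) s = 1;
      if (s > n_sectors) s = n_sectors;
      obs(i, s - 1) += sigma / d;
    }
  }
  return obs;
}

// Iterative hard-disk overlap resolution: every overlapping pair is pushed
// apart symmetrically along the centre line to contact distance sigma,
// swept until the residual overlap is below tol or max_iter is reached.
// [[Rcpp::export(name = ".resolve_overlaps_cpp")]]
List resolve_overlaps_cpp(NumericMatrix pos, double sigma, double tol, int max_iter) {
  int n = pos.nrow();
  NumericMatrix p = clone(pos);
  NumericVector disp(n);
  std::vector<double> px(n), py(n);
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    double worst = 0.0;
    std::fill(px.begin(), px.end(), 0.0);
    std::fill(py.begin(), py.end(), 0.0);
    // synchronous (Jacobi) sweep: accumulate all pair pushes from the
    // current positions, then apply at once -- preserves configuration
    // symmetries and is agent-order independent
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = p(j, 0) - p(i, 0), dy = p(j, 1) - p(i, 1);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d >= sigma) continue;
        double ux, uy;
        if (d < 1e-12) {
          // coincident disks: deterministic separation direction
          double a = 2.399963229728653 * (i + 1);  // golden angle * index
          ux = std::cos(a); uy = std::sin(a);
        } else {
          ux = dx / d; uy = dy / d;
        }
        double push = 0.5 * (sigma - d);
        px[i] -= push * ux; py[i] -= push * uy;
        px[j] += push * ux; py[j] += push * uy;
        if (sigma - d > worst) worst = sigma - d;
      }
    }
    if (worst <= tol) { converged = true; break; }
    for (int i = 0; i < n; ++i) {
      p(i, 0) += px[i]; p(i, 1) += py[i];
      disp[i] += std::sqrt(px[i] * px[i] + py[i] * py[i]);
    }
  }
  return List::create(_["positions"] = p, _["converged"] = converged,
                      _["iterations"] = iter + 1, _["displacement"] = disp);
}
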