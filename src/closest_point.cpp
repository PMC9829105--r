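#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <functional>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3& a, const Vec3& b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 vadd(const Vec3& a, const Vec3& b) {
  return Vec3{a.x + b.x, a.y + b.y, a.z + b.z};
}
inline Vec3 vscale(const Vec3& a, double s) {
  return Vec3{a.x * s, a.y * s, a.z * s};
}
inline double vdot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double vnorm2(const Vec3& a) { return vdot(a, a); }

// Closest point on triangle (a,b,c) to p; Voronoi-region case analysis.
Vec3 closest_on_triangle(const Vec3& p, const Vec3& a, const Vec3& b,
                         const Vec3& c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;

  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return vadd(a, vscale(ab, v));
  }

  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return vadd(a, vscale(ac, w));
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return vadd(b, vscale(vsub(c, b), w));
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return vadd(a, vadd(vscale(ab, v), vscale(ac, w)));
}

}  // namespace

// Unsigned closest-point queries from each row of `points` to the surface
// (V, F). F is 1-based. Returns closest points, distances and 1-based face
// hit. Brute force over faces with a bounding-sphere prune per triangle;
// `warm_faces` (1-based, optional) seeds the prune bound with a candidate
// face per point — e.g. the face hit in the previous ICP iteration.
// [[Rcpp::export]]
List cpp_closest_points(const NumericMatrix& points, const NumericMatrix& V,
                        const IntegerMatrix& F,
                        const IntegerVector& warm_faces = IntegerVector()) {
  const int np = points.nrow(), nf = F.nrow();
  if (nf == 0) stop("reference mesh has no faces");
  const bool warm = warm_faces.size() == np;

  std::vector<Vec3> a(nf), b(nf), c(nf), ctr(nf);
  std::vector<double> rad(nf);
  for (int f = 0; f < nf; ++f) {
    int i = F(f, 0) - 1, j = F(f, 1) - 1, k = F(f, 2) - 1;
    a[f] = Vec3{V(i, 0), V(i, 1), V(i, 2)};
    b[f] = Vec3{V(j, 0), V(j, 1), V(j, 2)};
    c[f] = Vec3{V(k, 0), V(k, 1), V(k, 2)};
    ctr[f] = vscale(vadd(a[f], vadd(b[f], c[f])), 1.0 / 3.0);
    double r2 = std::max(vnorm2(vsub(a[f], ctr[f])),
                         std::max(vnorm2(vsub(b[f], ctr[f])),
                                  vnorm2(vsub(c[f], ctr[f]))));
    rad[f] = std::sqrt(r2);
  }

  NumericMatrix out(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  for (int p = 0; p < np; ++p) {
    Vec3 q{points(p, 0), points(p, 1), points(p, 2)};
    double best = R_PosInf;
    Vec3 bestpt{0, 0, 0};
    int bestf = 0;
    if (warm) {
      int f0 = warm_faces[p] - 1;
      if (f0 >= 0 && f0 < nf) {
        Vec3 cp = closest_on_triangle(q, a[f0], b[f0], c[f0]);
        best = vnorm2(vsub(q, cp));
        bestpt = cp;
        bestf = f0;
      }
    }
    for (int f = 0; f < nf; ++f) {
      double dctr = std::sqrt(vnorm2(vsub(q, ctr[f]))) - rad[f];
      if (dctr > 0.0 && dctr * dctr >= best) continue;
      Vec3 cp = closest_on_triangle(q, a[f], b[f], c[f]);
      double d2 = vnorm2(vsub(q, cp));
      if (d2 < best) {
        best = d2;
        bestpt = cp;
        bestf = f;
      }
    }
    out(p, 0) = bestpt.x;
    out(p, 1) = bestpt.y;
    out(p, 2) = bestpt.z;
    dist[p] = std::sqrt(best);
    face[p] = bestf + 1;
  }
  return List::create(_["points"] = out, _["dist"] = dist, _["face"] = face);
}

// Greedy shortest-edge midpoint-collapse decimation down to target_faces.
// `noise` perturbs the edge-length sort key (multiplicative, ~1e-3) so that
// replicate degradations with different seeds collapse in different orders.
// Faces that become degenerate (repeated vertices) are dropped. F is 1-based.
// [[Rcpp::export]]
List cpp_decimate(const NumericMatrix& V, const IntegerMatrix& F,
                  int target_faces, const NumericVector& noise) {
  const int nv = V.nrow();
  std::vector<double> px(nv), py(nv), pz(nv);
  for (int i = 0; i < nv; ++i) {
    px[i] = V(i, 0);
    py[i] = V(i, 1);
    pz[i] = V(i, 2);
  }
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };

  std::vector<std::array<int, 3>> faces;
  faces.reserve(F.nrow());
  for (int f = 0; f < F.nrow(); ++f)
    faces.push_back({F(f, 0) - 1, F(f, 1) - 1, F(f, 2) - 1});

  int noise_i = 0;
  const int nnoise = noise.size();
  auto next_noise = [&]() -> double {
    if (nnoise == 0) return 0.0;
    double u = noise[noise_i % nnoise];
    ++noise_i;
    return u;
  };

  int nfaces = (int)faces.size();
  while (nfaces > target_faces) {
    // collect unique live edges
    struct Edge {
      int a, b;
      double key;
    };
    std::vector<Edge> edges;
    {
      std::vector<std::pair<int, int>> raw;
      raw.reserve(faces.size() * 3);
      for (auto& fc : faces) {
        int v0 = find(fc[0]), v1 = find(fc[1]), v2 = find(fc[2]);
        if (v0 == v1 || v1 == v2 || v0 == v2) continue;
        raw.push_back({std::min(v0, v1), std::max(v0, v1)});
        raw.push_back({std::min(v1, v2), std::max(v1, v2)});
        raw.push_back({std::min(v0, v2), std::max(v0, v2)});
      }
      std::sort(raw.begin(), raw.end());
      raw.erase(std::unique(raw.begin(), raw.end()), raw.end());
      edges.reserve(raw.size());
      for (auto& e : raw) {
        double dx = px[e.first] - px[e.second];
        double dy = py[e.first] - py[e.second];
        double dz = pz[e.first] - pz[e.second];
        double len = std::sqrt(dx * dx + dy * dy + dz * dz);
        edges.push_back({e.first, e.second,
                         len * (1.0 + 1e-3 * next_noise())});
      }
    }
    if (edges.empty()) break;
    std::sort(edges.begin(), edges.end(),
              [](const Edge& l, const Edge& r) { return l.key < r.key; });

    std::vector<char> touched(nv, 0);
    int budget = (nfaces - target_faces + 1) / 2;  // ~2 faces per collapse
    int collapsed = 0;
    for (auto& e : edges) {
      if (collapsed >= budget) break;
      int ra = find(e.a), rb = find(e.b);
      if (ra == rb || touched[ra] || touched[rb]) continue;
      px[ra] = 0.5 * (px[ra] + px[rb]);
      py[ra] = 0.5 * (py[ra] + py[rb]);
      pz[ra] = 0.5 * (pz[ra] + pz[rb]);
      parent[rb] = ra;
      touched[ra] = 1;
      ++collapsed;
    }
    if (collapsed == 0) break;

    std::vector<std::array<int, 3>> kept;
    kept.reserve(faces.size());
    for (auto& fc : faces) {
      int v0 = find(fc[0]), v1 = find(fc[1]), v2 = find(fc[2]);
      if (v0 == v1 || v1 == v2 || v0 == v2) continue;
      kept.push_back({v0, v1, v2});
    }
    faces.swap(kept);
    nfaces = (int)faces.size();
  }

  // compact vertices, drop zero-area faces
  std::vector<int> remap(nv, -1);
  int nkeep = 0;
  for (auto& fc : faces)
    for (int s = 0; s < 3; ++s)
      if (remap[fc[s]] < 0) remap[fc[s]] = nkeep++;

  NumericMatrix Vo(nkeep, 3);
  for (int i = 0; i < nv; ++i) {
    if (remap[i] >= 0) {
      Vo(remap[i], 0) = px[i];
      Vo(remap[i], 1) = py[i];
      Vo(remap[i], 2) = pz[i];
    }
  }
  std::vector<std::array<int, 3>> final_faces;
  final_faces.reserve(faces.size());
  for (auto& fc : faces) {
    int i = fc[0], j = fc[1], k = fc[2];
    double ux = px[j] - px[i], uy = py[j] - py[i], uz = pz[j] - pz[i];
    double vx = px[k] - px[i], vy = py[k] - py[i], vz = pz[k] - pz[i];
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz,
           cz = ux * vy - uy * vx;
    double area = 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
    if (area <= 1e-12) continue;
    final_faces.push_back({remap[i] + 1, remap[j] + 1, remap[k] + 1});
  }
  IntegerMatrix Fo((int)final_faces.size(), 3);
  for (int f = 0; f < (int)final_faces.size(); ++f)
    for (int s = 0; s < 3; ++s) Fo(f, s) = final_faces[f][s];

  return List::create(_["vertices"] = Vo, _["faces"] = Fo);
}
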