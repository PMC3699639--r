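// GEPOL-style cavity tessellation: interlocked atomic spheres, each initially
// carrying 60 * 4^k triangular tesserae from a subdivided pentakis
// dodecahedron; tesserae whose representative point (the projected centre of
// the original triangle) falls inside another sphere are removed, and
// partially cut tesserae get their exposed area from the Gauss-Bonnet theorem
// applied to the clipped spherical polygon (geodesic edges plus
// sphere-intersection circle arcs).
// [[Rcpp::depends(RcppArmadillo)]]
#include "common.h"
#include <map>
#include <array>
#include <algorithm>
using namespace arma;

namespace {

struct Edge {
  int kind = 0;     // 0 geodesic, 1 circle arc
  vec3 u;           // circle axis (unit)
  double h = 0.0;   // plane offset: circle is {p : p.u = h}
};

struct SphPoly {
  std::vector<vec3> v;   // unit vertices
  std::vector<Edge> e;   // e[i] joins v[i] -> v[(i+1)%n]
  double extra_sub = 0;  // holes (full cut circles inside the polygon)
  bool empty = false;
};

const double PI = 3.14159265358979323846;

// winding-number point-in-polygon on the sphere (vertices only; used for the
// rare fully-interior cut circle)
bool point_in_poly(const SphPoly& P, const vec3& x) {
  int n = P.v.size();
  if (n < 3) return false;
  double tot = 0.0;
  vec3 a = normalise(P.v[0] - dot(P.v[0], x) * x);
  vec3 prev = a;
  for (int i = 1; i <= n; ++i) {
    vec3 w = P.v[i % n] - dot(P.v[i % n], x) * x;
    double nw = norm(w);
    if (nw < 1e-12) return false;
    w /= nw;
    double ang = std::atan2(dot(cross(prev, w), x), dot(prev, w));
    tot += ang;
    prev = w;
  }
  return std::fabs(tot) > PI; // ~2*pi when inside
}

// intersection of an edge with plane p.u = h, between a and b.
// returns true and the point if found; wants the crossing where the side
// changes from sa to sb.
bool edge_plane_cross(const vec3& a, const vec3& b, const Edge& ed,
                      const vec3& u, double h, bool leaving, vec3& out) {
  if (ed.kind == 0) {
    double cosO = dot(a, b);
    vec3 w = b - cosO * a;
    double nw = norm(w);
    if (nw < 1e-14) return false;
    w /= nw;
    double Omega = std::atan2(nw, cosO);
    double ca = dot(u, a), cw = dot(u, w);
    double rho = std::sqrt(ca * ca + cw * cw);
    if (rho < std::fabs(h)) return false;
    double phi0 = std::atan2(cw, ca);
    double dphi = std::acos(std::min(1.0, std::max(-1.0, h / rho)));
    double cand[2] = {phi0 + dphi, phi0 - dphi};
    bool found = false;
    double best = 1e99;
    for (double phi : cand) {
      while (phi < -PI) phi += 2 * PI;
      while (phi > PI) phi -= 2 * PI;
      if (phi <= 1e-12 || phi >= Omega - 1e-12) continue;
      // crossing direction: d(u.p)/dphi = -ca sin + cw cos
      double der = -ca * std::sin(phi) + cw * std::cos(phi);
      if ((leaving && der <= 0) || (!leaving && der >= 0)) continue;
      if (phi < best) { best = phi; found = true; }
    }
    if (!found) {
      // fall back: accept any in-range root
      for (double phi : cand) {
        while (phi < -PI) phi += 2 * PI;
        while (phi > PI) phi -= 2 * PI;
        if (phi > 1e-12 && phi < Omega - 1e-12 && phi < best) {
          best = phi; found = true;
        }
      }
    }
    if (!found) return false;
    out = a * std::cos(best) + w * std::sin(best);
    return true;
  } else {
    // circle edge around ed.u at offset ed.h, travelling clockwise
    double hc = ed.h;
    double rc = std::sqrt(std::max(0.0, 1.0 - hc * hc));
    if (rc < 1e-14) return false;
    vec3 c0 = hc * ed.u;
    vec3 e1 = a - c0;
    double n1 = norm(e1);
    if (n1 < 1e-14) return false;
    e1 /= n1;
    vec3 e2 = normalise(cross(e1, ed.u)); // clockwise tangent direction at a
    // total arc angle to b
    vec3 wb = b - c0;
    double phib = std::atan2(dot(wb, e2), dot(wb, e1));
    if (phib < 1e-12) phib += 2 * PI;
    double K = dot(u, ed.u) * hc;
    double ca = rc * dot(u, e1), cw = rc * dot(u, e2);
    double rho = std::sqrt(ca * ca + cw * cw);
    if (rho < std::fabs(h - K)) return false;
    double phi0 = std::atan2(cw, ca);
    double dphi = std::acos(std::min(1.0, std::max(-1.0, (h - K) / rho)));
    double cand[2] = {phi0 + dphi, phi0 - dphi};
    bool found = false;
    double best = 1e99;
    for (double phi : cand) {
      while (phi < 0) phi += 2 * PI;
      while (phi >= 2 * PI) phi -= 2 * PI;
      if (phi <= 1e-12 || phi >= phib - 1e-12) continue;
      double der = -ca * std::sin(phi) + cw * std::cos(phi);
      if ((leaving && der <= 0) || (!leaving && der >= 0)) continue;
      if (phi < best) { best = phi; found = true; }
    }
    if (!found) {
      for (double phi : cand) {
        while (phi < 0) phi += 2 * PI;
        while (phi >= 2 * PI) phi -= 2 * PI;
        if (phi > 1e-12 && phi < phib - 1e-12 && phi < best) {
          best = phi; found = true;
        }
      }
    }
    if (!found) return false;
    out = c0 + rc * (e1 * std::cos(best) + e2 * std::sin(best));
    return true;
  }
}

SphPoly clip_poly(const SphPoly& P, const vec3& u, double h) {
  SphPoly R;
  R.extra_sub = P.extra_sub;
  if (P.empty) { R.empty = true; return R; }
  int n = P.v.size();
  std::vector<double> side(n);
  int nin = 0;
  for (int i = 0; i < n; ++i) {
    side[i] = dot(u, P.v[i]) - h;
    if (side[i] <= 0) nin++;
  }
  if (nin == n) {
    R = P;
    // possible interior hole: the whole cut cap sits inside the polygon
    if (std::fabs(h) < 1.0 && point_in_poly(P, u))
      R.extra_sub += 2 * PI * (1.0 - h);
    return R;
  }
  if (nin == 0) { R.empty = true; return R; }

  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    bool ini = side[i] <= 0, inj = side[j] <= 0;
    if (ini) {
      R.v.push_back(P.v[i]);
      R.e.push_back(P.e[i]);
    }
    if (ini != inj) {
      vec3 X;
      if (edge_plane_cross(P.v[i], P.v[j], P.e[i], u, h, ini, X)) {
        if (ini) {
          Edge arc; arc.kind = 1; arc.u = u; arc.h = h;
          R.v.push_back(X);
          R.e.push_back(arc);
        } else {
          R.v.push_back(X);
          R.e.push_back(P.e[i]);
        }
      }
      // if the crossing is not found numerically, skip it; the polygon stays
      // consistent at the resolution of the tessellation
    }
  }
  if (R.v.size() < 2) R.empty = true;
  return R;
}

double poly_area(const SphPoly& P) {
  if (P.empty) return 0.0;
  int n = P.v.size();
  if (n < 2) return 0.0;
  double area = 2 * PI;
  // circle-arc running terms and exterior angles
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    const vec3& a = P.v[i];
    const vec3& b = P.v[j];
    const Edge& ed = P.e[i];
    if (ed.kind == 1) {
      double hc = ed.h;
      vec3 c0 = hc * ed.u;
      vec3 e1 = a - c0;
      double n1 = norm(e1);
      if (n1 > 1e-14) {
        e1 /= n1;
        vec3 e2 = normalise(cross(e1, ed.u));
        vec3 wb = b - c0;
        double phib = std::atan2(dot(wb, e2), dot(wb, e1));
        if (phib < 1e-12) phib += 2 * PI;
        area += hc * phib;
      }
    }
  }
  auto tangent_out = [&](int i) -> vec3 {
    int j = (i + 1) % n;
    const vec3& a = P.v[i];
    const vec3& b = P.v[j];
    if (P.e[i].kind == 0) {
      vec3 t = b - dot(a, b) * a;
      double nt = norm(t);
      return nt > 1e-14 ? vec3(t / nt) : vec3({0, 0, 0});
    }
    vec3 c0 = P.e[i].h * P.e[i].u;
    (void)b;
    return normalise(cross(a - c0, P.e[i].u)); // clockwise
  };
  auto tangent_in = [&](int i) -> vec3 {
    int ip = (i - 1 + n) % n;
    const vec3& a = P.v[ip];
    const vec3& b = P.v[i];
    if (P.e[ip].kind == 0) {
      vec3 t = dot(a, b) * b - a;
      double nt = norm(t);
      return nt > 1e-14 ? vec3(t / nt) : vec3({0, 0, 0});
    }
    vec3 c0 = P.e[ip].h * P.e[ip].u;
    return normalise(cross(b - c0, P.e[ip].u));
  };
  for (int i = 0; i < n; ++i) {
    vec3 ti = tangent_in(i), to = tangent_out(i);
    if (norm(ti) < 0.5 || norm(to) < 0.5) continue;
    double ang = std::atan2(dot(cross(ti, to), P.v[i]), dot(ti, to));
    area -= ang;
  }
  area -= P.extra_sub;
  return area;
}

// base pentakis-dodecahedron triangles (unit sphere), subdivided
void base_triangles(int nper, const mat& frame, std::vector<std::array<vec3, 3>>& tris) {
  double phi = (1.0 + std::sqrt(5.0)) / 2.0;
  std::vector<vec3> iv;
  double c1[3] = {0, 1, phi};
  for (int cyc = 0; cyc < 3; ++cyc)
    for (int s1 = -1; s1 <= 1; s1 += 2)
      for (int s2 = -1; s2 <= 1; s2 += 2) {
        vec3 v;
        v((0 + cyc) % 3) = c1[0];
        v((1 + cyc) % 3) = s1 * c1[1];
        v((2 + cyc) % 3) = s2 * c1[2];
        iv.push_back(normalise(v));
      }
  // icosahedron faces: mutually adjacent triples (edge length = min distance)
  double dmin = 1e9;
  for (size_t i = 0; i < iv.size(); ++i)
    for (size_t j = i + 1; j < iv.size(); ++j)
      dmin = std::min(dmin, norm(iv[i] - iv[j]));
  std::vector<std::array<int, 3>> faces;
  for (size_t i = 0; i < iv.size(); ++i)
    for (size_t j = i + 1; j < iv.size(); ++j) {
      if (norm(iv[i] - iv[j]) > dmin * 1.1) continue;
      for (size_t k = j + 1; k < iv.size(); ++k) {
        if (norm(iv[i] - iv[k]) > dmin * 1.1) continue;
        if (norm(iv[j] - iv[k]) > dmin * 1.1) continue;
        faces.push_back({(int)i, (int)j, (int)k});
      }
    }
  std::vector<vec3> fc(faces.size());
  for (size_t f = 0; f < faces.size(); ++f)
    fc[f] = normalise(iv[faces[f][0]] + iv[faces[f][1]] + iv[faces[f][2]]);

  // 60 pentakis triangles: icosa vertex + two consecutive adjacent face centres
  std::vector<std::array<vec3, 3>> base;
  for (size_t vi = 0; vi < iv.size(); ++vi) {
    std::vector<int> adj;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f][0] == (int)vi || faces[f][1] == (int)vi || faces[f][2] == (int)vi)
        adj.push_back(f);
    // order around the vertex
    vec3 zl = iv[vi];
    vec3 xl = normalise(fc[adj[0]] - dot(fc[adj[0]], zl) * zl);
    vec3 yl = cross(zl, xl);
    std::sort(adj.begin(), adj.end(), [&](int a, int b) {
      double aa = std::atan2(dot(fc[a], yl), dot(fc[a], xl));
      double ab = std::atan2(dot(fc[b], yl), dot(fc[b], xl));
      return aa < ab;
    });
    for (size_t k = 0; k < adj.size(); ++k) {
      vec3 a = iv[vi], b = fc[adj[k]], c = fc[adj[(k + 1) % adj.size()]];
      if (dot(cross(b - a, c - a), a) < 0) std::swap(b, c);
      base.push_back({a, b, c});
    }
  }
  // subdivide to the requested count
  int levels = 0;
  if (nper == 240) levels = 1;
  else if (nper == 960) levels = 2;
  else if (nper != 60) Rcpp::stop("n_per_sphere must be 60, 240 or 960");
  tris = base;
  for (int l = 0; l < levels; ++l) {
    std::vector<std::array<vec3, 3>> nt;
    for (auto& t : tris) {
      vec3 ab = normalise(t[0] + t[1]);
      vec3 bc = normalise(t[1] + t[2]);
      vec3 ca = normalise(t[2] + t[0]);
      nt.push_back({t[0], ab, ca});
      nt.push_back({ab, t[1], bc});
      nt.push_back({ca, bc, t[2]});
      nt.push_back({ab, bc, ca});
    }
    tris = nt;
  }
  for (auto& t : tris)
    for (int k = 0; k < 3; ++k) t[k] = vec3(frame * t[k]);
}

struct TessOut {
  std::vector<int> sphere, tri;
  std::vector<double> area;
  std::vector<vec3> pos;
};

// tessellate the listed spheres (0-based subset) in the context of all spheres
void tessellate_core(const mat& centers, const vec& radii,
                     const std::vector<std::array<vec3, 3>>& tris,
                     const std::vector<int>& subset, TessOut& out) {
  int nat = radii.n_elem;
  for (int s : subset) {
    double R = radii(s);
    vec3 C = centers.col(s);
    // overlapping spheres and burial check
    std::vector<std::pair<vec3, double>> cuts; // (axis u, offset h)
    bool buried = false;
    for (int o = 0; o < nat; ++o) {
      if (o == s) continue;
      vec3 dv = centers.col(o) - C;
      double d = norm(dv);
      if (d + R <= radii(o)) { buried = true; break; }
      if (d >= R + radii(o)) continue;
      double h = (d * d + R * R - radii(o) * radii(o)) / (2.0 * d * R);
      if (h >= 1.0) continue;
      if (h <= -1.0) { buried = true; break; }
      cuts.push_back({vec3(dv / d), h});
    }
    if (buried) continue;
    for (size_t t = 0; t < tris.size(); ++t) {
      vec3 rep = normalise(tris[t][0] + tris[t][1] + tris[t][2]);
      // a tessera is removed outright once its representative point (the
      // projected triangle centre, which rides rigidly with the parent atom)
      // is covered by another sphere; survivors keep their exact exposed
      // Gauss-Bonnet area.  Removal by the representative point bounds the
      // energy discontinuity at a tessellation event and avoids near-zero
      // area slivers with singular 1/sqrt(a) matrix-diagonal derivatives.
      bool removed = false;
      for (auto& c : cuts)
        if (dot(rep, c.first) > c.second - 1e-9) { removed = true; break; }
      if (removed) continue;
      SphPoly P;
      P.v = {tris[t][0], tris[t][1], tris[t][2]};
      P.e.resize(3);
      for (auto& c : cuts) {
        P = clip_poly(P, c.first, c.second);
        if (P.empty) break;
      }
      double a = P.empty ? 0.0 : poly_area(P) * R * R;
      if (a < 1e-6) continue;
      out.sphere.push_back(s + 1);
      out.tri.push_back(t + 1);
      out.area.push_back(a);
      out.pos.push_back(vec3(C + R * rep));
    }
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_tessellate(const arma::mat& centers, const arma::vec& radii,
                          int nper, const arma::mat& frame) {
  std::vector<std::array<vec3, 3>> tris;
  base_triangles(nper, frame, tris);
  std::vector<int> subset(radii.n_elem);
  for (size_t i = 0; i < subset.size(); ++i) subset[i] = i;
  TessOut out;
  tessellate_core(centers, radii, tris, subset, out);
  int nt = out.area.size();
  mat pos(3, nt);
  vec area(nt);
  ivec sphere(nt), tri(nt);
  for (int i = 0; i < nt; ++i) {
    pos.col(i) = out.pos[i];
    area(i) = out.area[i];
    sphere(i) = out.sphere[i];
    tri(i) = out.tri[i];
  }
  return Rcpp::List::create(
      Rcpp::Named("pos") = pos, Rcpp::Named("area") = area,
      Rcpp::Named("sphere") = sphere, Rcpp::Named("tri") = tri,
      Rcpp::Named("total_area") = accu(area));
}

// Numerical (central-difference) tessera-area contribution to the PCM
// gradient: the areas enter the C-PCM matrix through the diagonal
// D_ii = kdiag sqrt(4 pi / a_i) and through the tessera-size damping of the
// inter-sphere couplings; this term is (1/2f) q^T (dD/dx)|_areas q evaluated
// at fixed reference positions. Only spheres whose cut pattern can change
// with atom A are re-tessellated. Tesserae are matched across displacements
// by their (sphere, triangle) key; a tessera appearing or vanishing inside
// the stencil is a tessellation discontinuity: the step is halved up to 3
// times, then the coordinate is flagged.
// [[Rcpp::export]]
Rcpp::List cpp_area_term_gradient(const arma::mat& centers, const arma::vec& radii,
                                  int nper, const arma::mat& frame,
                                  const arma::mat& tpos_ref,
                                  const arma::vec& area_ref,
                                  const arma::ivec& tsphere, const arma::ivec& ttri,
                                  const arma::vec& q, double f, double kdiag,
                                  double h0) {
  int nat = radii.n_elem;
  int nt = area_ref.n_elem;
  std::vector<std::array<vec3, 3>> tris;
  base_triangles(nper, frame, tris);
  const double FOURPI = 4 * PI;

  std::map<std::pair<int, int>, int> qidx; // reference key -> tessera index
  for (int i = 0; i < nt; ++i) qidx[{tsphere(i), ttri(i)}] = i;

  vec g(3 * nat, fill::zeros);
  ivec flagged(3 * nat, fill::zeros);

  // (1/2f) [ sum_{i in C} q_i^2 kd_i(a) + 2 sum_{i in C} sum_{j inter} ... ]
  auto dterm = [&](const std::vector<int>& C, const std::vector<char>& inC,
                   const vec& a) {
    double s = 0.0;
    for (int i : C) {
      s += q(i) * q(i) * kdiag * std::sqrt(FOURPI / a(i));
      double wi = std::sqrt(a(i) / PI);
      for (int j = 0; j < nt; ++j) {
        if (j == i || tsphere(j) == tsphere(i)) continue;
        if (inC[j] && j < i) continue; // count changed-changed pairs once
        double wj = std::sqrt(a(j) / PI);
        double dx = tpos_ref(0, i) - tpos_ref(0, j);
        double dy = tpos_ref(1, i) - tpos_ref(1, j);
        double dz = tpos_ref(2, i) - tpos_ref(2, j);
        s += 2.0 * q(i) * q(j) /
             std::sqrt(dx * dx + dy * dy + dz * dz + wi * wj);
      }
    }
    return s / (2.0 * f);
  };

  for (int A = 0; A < nat; ++A) {
    std::vector<int> subset; // spheres whose exposure can depend on atom A
    for (int o = 0; o < nat; ++o) {
      if (o == A) { subset.push_back(o); continue; }
      double d = norm(centers.col(o) - centers.col(A));
      if (d < radii(o) + radii(A) + 4 * h0) subset.push_back(o);
    }
    std::vector<char> in_subset(nat, 0);
    for (int o : subset) in_subset[o] = 1;
    std::vector<int> C;
    std::vector<char> inC(nt, 0);
    for (int i = 0; i < nt; ++i)
      if (in_subset[tsphere(i) - 1]) { C.push_back(i); inC[i] = 1; }
    int nref_subset = C.size();

    for (int c = 0; c < 3; ++c) {
      double h = h0;
      bool done = false;
      for (int attempt = 0; attempt < 4 && !done; ++attempt, h *= 0.5) {
        mat cp = centers, cm = centers;
        cp(c, A) += h;
        cm(c, A) -= h;
        TessOut tp, tm;
        tessellate_core(cp, radii, tris, subset, tp);
        tessellate_core(cm, radii, tris, subset, tm);
        if ((int)tp.area.size() != nref_subset ||
            (int)tm.area.size() != nref_subset) continue;
        vec ap = area_ref, am = area_ref;
        bool match = true;
        for (size_t k = 0; k < tp.area.size(); ++k) {
          auto it = qidx.find({tp.sphere[k], tp.tri[k]});
          auto im = qidx.find({tm.sphere[k], tm.tri[k]});
          if (it == qidx.end() || im == qidx.end()) { match = false; break; }
          ap(it->second) = tp.area[k];
          am(im->second) = tm.area[k];
        }
        if (!match) continue;
        g(3 * A + c) = (dterm(C, inC, ap) - dterm(C, inC, am)) / (2.0 * h);
        done = true;
      }
      if (!done) flagged(3 * A + c) = 1;
    }
  }
  return Rcpp::List::create(Rcpp::Named("gradient") = g,
                            Rcpp::Named("flagged") = flagged);
}
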