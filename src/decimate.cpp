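// Topology-preserving mesh decimation by iterative shortest-edge collapse.
//
// An edge (u,v) may collapse to its midpoint only when the link condition
// holds (the common neighbors of u and v are exactly the apex vertices of
// the faces incident to the edge), which guarantees the collapse is a
// homeomorphism: component count and Euler characteristic are preserved.
// A normal-flip guard rejects collapses that would invert surviving faces.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Cand {
  double len;
  int u, v;
  long stamp;
};
struct CandCmp {
  bool operator()(const Cand& a, const Cand& b) const { return a.len > b.len; }
};

struct Mesh {
  std::vector<double> px, py, pz;
  std::vector<int> f0, f1, f2;
  std::vector<char> face_alive, vert_alive;
  std::vector<std::vector<int>> vfaces;  // incident face ids (may hold stale)
  std::vector<long> stamp;

  double elen(int u, int v) const {
    double dx = px[u] - px[v], dy = py[u] - py[v], dz = pz[u] - pz[v];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  void face_verts(int f, int out[3]) const {
    out[0] = f0[f];
    out[1] = f1[f];
    out[2] = f2[f];
  }
  void normal(int a, int b, int c, double ax, double ay, double az,
              bool move_a, double n[3]) const {
    // normal of face (a,b,c), with vertex a optionally moved to (ax,ay,az)
    double x0 = move_a ? ax : px[a], y0 = move_a ? ay : py[a],
           z0 = move_a ? az : pz[a];
    double e1x = px[b] - x0, e1y = py[b] - y0, e1z = pz[b] - z0;
    double e2x = px[c] - x0, e2y = py[c] - y0, e2z = pz[c] - z0;
    n[0] = e1y * e2z - e1z * e2y;
    n[1] = e1z * e2x - e1x * e2z;
    n[2] = e1x * e2y - e1y * e2x;
  }
};

void neighbors_of(const Mesh& m, int u, std::vector<int>& out) {
  out.clear();
  for (int f : m.vfaces[u]) {
    if (!m.face_alive[f]) continue;
    int vv[3];
    m.face_verts(f, vv);
    for (int t = 0; t < 3; t++)
      if (vv[t] != u) out.push_back(vv[t]);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

}  // namespace

// [[Rcpp::export]]
List cpp_decimate(NumericMatrix vertices, IntegerMatrix faces,
                  int target_faces) {
  int nv = vertices.nrow(), nf = faces.nrow();
  Mesh m;
  m.px.resize(nv);
  m.py.resize(nv);
  m.pz.resize(nv);
  for (int i = 0; i < nv; i++) {
    m.px[i] = vertices(i, 0);
    m.py[i] = vertices(i, 1);
    m.pz[i] = vertices(i, 2);
  }
  m.f0.resize(nf);
  m.f1.resize(nf);
  m.f2.resize(nf);
  m.face_alive.assign(nf, 1);
  m.vert_alive.assign(nv, 1);
  m.vfaces.assign(nv, {});
  m.stamp.assign(nv, 0);
  for (int f = 0; f < nf; f++) {
    m.f0[f] = faces(f, 0) - 1;
    m.f1[f] = faces(f, 1) - 1;
    m.f2[f] = faces(f, 2) - 1;
    m.vfaces[m.f0[f]].push_back(f);
    m.vfaces[m.f1[f]].push_back(f);
    m.vfaces[m.f2[f]].push_back(f);
  }

  std::priority_queue<Cand, std::vector<Cand>, CandCmp> pq;
  auto push_edge = [&](int u, int v) {
    if (u > v) std::swap(u, v);
    pq.push({m.elen(u, v), u, v, m.stamp[u] + m.stamp[v]});
  };
  for (int f = 0; f < nf; f++) {
    int vv[3];
    m.face_verts(f, vv);
    for (int t = 0; t < 3; t++) {
      int u = vv[t], v = vv[(t + 1) % 3];
      if (u < v) push_edge(u, v);
    }
  }

  int alive_faces = nf;
  bool stopped_early = false;
  std::vector<int> nu, nv_, common, edge_faces, apex;

  while (alive_faces > target_faces) {
    if (pq.empty()) {
      stopped_early = true;
      break;
    }
    Cand c = pq.top();
    pq.pop();
    int u = c.u, v = c.v;
    if (!m.vert_alive[u] || !m.vert_alive[v]) continue;
    if (c.stamp != m.stamp[u] + m.stamp[v]) continue;  // stale entry

    // faces incident to the edge, and their apex vertices
    edge_faces.clear();
    apex.clear();
    for (int f : m.vfaces[u]) {
      if (!m.face_alive[f]) continue;
      int vv[3];
      m.face_verts(f, vv);
      bool has_v = (vv[0] == v || vv[1] == v || vv[2] == v);
      if (has_v) {
        edge_faces.push_back(f);
        for (int t = 0; t < 3; t++)
          if (vv[t] != u && vv[t] != v) apex.push_back(vv[t]);
      }
    }
    if (edge_faces.empty()) continue;  // edge no longer exists

    // link condition
    neighbors_of(m, u, nu);
    neighbors_of(m, v, nv_);
    common.clear();
    std::set_intersection(nu.begin(), nu.end(), nv_.begin(), nv_.end(),
                          std::back_inserter(common));
    std::sort(apex.begin(), apex.end());
    apex.erase(std::unique(apex.begin(), apex.end()), apex.end());
    if (common != apex) continue;

    double mx = 0.5 * (m.px[u] + m.px[v]), my = 0.5 * (m.py[u] + m.py[v]),
           mz = 0.5 * (m.pz[u] + m.pz[v]);

    // normal-flip guard over surviving incident faces
    bool flip = false;
    for (int w = 0; w < 2 && !flip; w++) {
      int p = (w == 0) ? u : v;
      for (int f : m.vfaces[p]) {
        if (!m.face_alive[f]) continue;
        bool is_edge_face = false;
        for (int ef : edge_faces)
          if (ef == f) { is_edge_face = true; break; }
        if (is_edge_face) continue;
        int vv[3];
        m.face_verts(f, vv);
        // rotate so the moving vertex is first
        int a = vv[0], b = vv[1], cc = vv[2];
        if (b == p) { b = vv[2]; cc = vv[0]; a = p; }
        else if (cc == p) { b = vv[0]; cc = vv[1]; a = p; }
        double n0[3], n1[3];
        m.normal(a, b, cc, 0, 0, 0, false, n0);
        m.normal(a, b, cc, mx, my, mz, true, n1);
        double dot = n0[0] * n1[0] + n0[1] * n1[1] + n0[2] * n1[2];
        double nrm = std::sqrt(n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2]);
        if (dot <= 0 || nrm < 1e-300) { flip = true; break; }
      }
    }
    if (flip) continue;

    // perform the collapse: v merges into u at the midpoint
    m.px[u] = mx;
    m.py[u] = my;
    m.pz[u] = mz;
    for (int f : edge_faces) m.face_alive[f] = 0;
    alive_faces -= (int)edge_faces.size();
    for (int f : m.vfaces[v]) {
      if (!m.face_alive[f]) continue;
      if (m.f0[f] == v) m.f0[f] = u;
      if (m.f1[f] == v) m.f1[f] = u;
      if (m.f2[f] == v) m.f2[f] = u;
      m.vfaces[u].push_back(f);
    }
    m.vert_alive[v] = 0;
    m.stamp[u]++;
    m.stamp[v]++;
    neighbors_of(m, u, nu);
    for (int w : nu) push_edge(u, w);
  }

  // compact
  std::vector<int> vmap(nv, 0);
  int nv2 = 0;
  for (int f = 0; f < nf; f++) {
    if (!m.face_alive[f]) continue;
    int vv[3] = {m.f0[f], m.f1[f], m.f2[f]};
    for (int t = 0; t < 3; t++)
      if (!vmap[vv[t]]) vmap[vv[t]] = ++nv2;
  }
  NumericMatrix V(nv2, 3);
  for (int i = 0; i < nv; i++) {
    if (vmap[i]) {
      V(vmap[i] - 1, 0) = m.px[i];
      V(vmap[i] - 1, 1) = m.py[i];
      V(vmap[i] - 1, 2) = m.pz[i];
    }
  }
  IntegerMatrix F(alive_faces, 3);
  int fi = 0;
  for (int f = 0; f < nf; f++) {
    if (!m.face_alive[f]) continue;
    F(fi, 0) = vmap[m.f0[f]];
    F(fi, 1) = vmap[m.f1[f]];
    F(fi, 2) = vmap[m.f2[f]];
    fi++;
  }
  return List::create(_["vertices"] = V, _["faces"] = F,
                      _["stopped_early"] = stopped_early);
}
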