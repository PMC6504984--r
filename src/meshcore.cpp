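// Geometry core: iso-surface extraction (marching tetrahedra on a Kuhn
// cube subdivision), AABB-tree closest-point queries with exact
// point-to-triangle distance, mesh topology checks, column-ray
// partial-volume voxelization and separable Gaussian smoothing.
#include <Rcpp.h>
#include <functional>
#include <cstring>
#include <unordered_map>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// marching tetrahedra
// ---------------------------------------------------------------------------

// Kuhn subdivision of the unit cube into 6 tetrahedra sharing the main
// diagonal (0,0,0)-(1,1,1). Identical in every cube, hence face-to-face
// compatible between neighbouring cubes: the extracted surface is closed
// whenever the iso-surface does not touch the grid boundary.
static const int KUHN_PERMS[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
};

struct MTVertexMap {
  std::unordered_map<uint64_t, int> map;
  std::vector<double> coords; // x,y,z triplets
};

// one interpolated vertex per crossed grid edge, shared between tets
static int edge_vertex(MTVertexMap &vm, uint64_t ga, uint64_t gb,
                       const double *pa, const double *pb,
                       double va, double vb, double level) {
  uint64_t key_a = ga, key_b = gb;
  const double *qa = pa, *qb = pb;
  double wa = va, wb = vb;
  if (key_b < key_a) {
    std::swap(key_a, key_b); std::swap(qa, qb); std::swap(wa, wb);
  }
  // exact pairing: grid ids are < 2^26 (volume size is guarded upstream)
  uint64_t key = (key_a << 26) | key_b;
  auto it = vm.map.find(key);
  if (it != vm.map.end()) return it->second;
  double t = (level - wa) / (wb - wa);
  if (t < 0) t = 0; if (t > 1) t = 1;
  int id = (int)(vm.coords.size() / 3);
  vm.coords.push_back(qa[0] + t * (qb[0] - qa[0]));
  vm.coords.push_back(qa[1] + t * (qb[1] - qa[1]));
  vm.coords.push_back(qa[2] + t * (qb[2] - qa[2]));
  vm.map.emplace(key, id);
  return id;
}

static inline void push_tri(std::vector<int> &faces, MTVertexMap &vm,
                            int a, int b, int c,
                            const double *dir_from, const double *dir_to) {
  if (a == b || b == c || a == c) return; // degenerate after welding
  const double *A = &vm.coords[3 * a], *B = &vm.coords[3 * b],
               *C = &vm.coords[3 * c];
  double u[3] = {B[0]-A[0], B[1]-A[1], B[2]-A[2]};
  double v[3] = {C[0]-A[0], C[1]-A[1], C[2]-A[2]};
  double n[3] = {u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0]};
  double d[3] = {dir_to[0]-dir_from[0], dir_to[1]-dir_from[1],
                 dir_to[2]-dir_from[2]};
  double s = n[0]*d[0] + n[1]*d[1] + n[2]*d[2];
  // outward normal points from the high-value (inside) side to the low side
  if (s >= 0) { faces.push_back(a); faces.push_back(b); faces.push_back(c); }
  else        { faces.push_back(a); faces.push_back(c); faces.push_back(b); }
}

// [[Rcpp::export(name = ".mt_extract")]]
List mt_extract(NumericVector values, IntegerVector dim,
                NumericVector spacing, NumericVector origin, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((double)nx * ny * nz > 6.7e7)
    stop("volume too large for extraction (> 2^26 samples)");
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // sample points sit at voxel centers: origin + (i + 1/2) * spacing
  const double ox = origin[0] + 0.5 * sx, oy = origin[1] + 0.5 * sy,
               oz = origin[2] + 0.5 * sz;
  const double *val = values.begin();

  MTVertexMap vm;
  std::vector<int> faces;
  faces.reserve(1 << 16);

  double corner[8][3];   // geometric coords of the current cube corners
  double cval[8];
  uint64_t cgid[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          int ii = i + di, jj = j + dj, kk = k + dk;
          uint64_t g = (uint64_t)ii + (uint64_t)nx * ((uint64_t)jj + (uint64_t)ny * kk);
          cgid[c] = g;
          double v = val[g];
          cval[c] = v;
          corner[c][0] = ox + ii * sx;
          corner[c][1] = oy + jj * sy;
          corner[c][2] = oz + kk * sz;
          if (v > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          const int *perm = KUHN_PERMS[t];
          int tc[4];
          tc[0] = 0;
          tc[1] = tc[0] | (1 << perm[0]);
          tc[2] = tc[1] | (1 << perm[1]);
          tc[3] = 7;
          bool in[4];
          int n_in = 0;
          for (int m = 0; m < 4; ++m) {
            in[m] = cval[tc[m]] > level;
            if (in[m]) ++n_in;
          }
          if (n_in == 0 || n_in == 4) continue;

          int iv[4], ov[4], ni = 0, no = 0;
          for (int m = 0; m < 4; ++m) (in[m] ? iv[ni++] : ov[no++]) = tc[m];

          if (n_in == 1) {
            int a = edge_vertex(vm, cgid[iv[0]], cgid[ov[0]], corner[iv[0]],
                                corner[ov[0]], cval[iv[0]], cval[ov[0]], level);
            int b = edge_vertex(vm, cgid[iv[0]], cgid[ov[1]], corner[iv[0]],
                                corner[ov[1]], cval[iv[0]], cval[ov[1]], level);
            int c = edge_vertex(vm, cgid[iv[0]], cgid[ov[2]], corner[iv[0]],
                                corner[ov[2]], cval[iv[0]], cval[ov[2]], level);
            double to[3] = {
              (corner[ov[0]][0] + corner[ov[1]][0] + corner[ov[2]][0]) / 3.0,
              (corner[ov[0]][1] + corner[ov[1]][1] + corner[ov[2]][1]) / 3.0,
              (corner[ov[0]][2] + corner[ov[1]][2] + corner[ov[2]][2]) / 3.0};
            push_tri(faces, vm, a, b, c, corner[iv[0]], to);
          } else if (n_in == 3) {
            int a = edge_vertex(vm, cgid[iv[0]], cgid[ov[0]], corner[iv[0]],
                                corner[ov[0]], cval[iv[0]], cval[ov[0]], level);
            int b = edge_vertex(vm, cgid[iv[1]], cgid[ov[0]], corner[iv[1]],
                                corner[ov[0]], cval[iv[1]], cval[ov[0]], level);
            int c = edge_vertex(vm, cgid[iv[2]], cgid[ov[0]], corner[iv[2]],
                                corner[ov[0]], cval[iv[2]], cval[ov[0]], level);
            double from[3] = {
              (corner[iv[0]][0] + corner[iv[1]][0] + corner[iv[2]][0]) / 3.0,
              (corner[iv[0]][1] + corner[iv[1]][1] + corner[iv[2]][1]) / 3.0,
              (corner[iv[0]][2] + corner[iv[1]][2] + corner[iv[2]][2]) / 3.0};
            push_tri(faces, vm, a, b, c, from, corner[ov[0]]);
          } else { // 2 in / 2 out: quad p(i0,o0) p(i0,o1) p(i1,o1) p(i1,o0)
            int p00 = edge_vertex(vm, cgid[iv[0]], cgid[ov[0]], corner[iv[0]],
                                  corner[ov[0]], cval[iv[0]], cval[ov[0]], level);
            int p01 = edge_vertex(vm, cgid[iv[0]], cgid[ov[1]], corner[iv[0]],
                                  corner[ov[1]], cval[iv[0]], cval[ov[1]], level);
            int p11 = edge_vertex(vm, cgid[iv[1]], cgid[ov[1]], corner[iv[1]],
                                  corner[ov[1]], cval[iv[1]], cval[ov[1]], level);
            int p10 = edge_vertex(vm, cgid[iv[1]], cgid[ov[0]], corner[iv[1]],
                                  corner[ov[0]], cval[iv[1]], cval[ov[0]], level);
            double from[3] = {(corner[iv[0]][0] + corner[iv[1]][0]) / 2.0,
                              (corner[iv[0]][1] + corner[iv[1]][1]) / 2.0,
                              (corner[iv[0]][2] + corner[iv[1]][2]) / 2.0};
            double to[3] = {(corner[ov[0]][0] + corner[ov[1]][0]) / 2.0,
                            (corner[ov[0]][1] + corner[ov[1]][1]) / 2.0,
                            (corner[ov[0]][2] + corner[ov[1]][2]) / 2.0};
            push_tri(faces, vm, p00, p01, p11, from, to);
            push_tri(faces, vm, p00, p11, p10, from, to);
          }
        }
      }
    }
  }

  int nv = (int)(vm.coords.size() / 3);
  int nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int r = 0; r < nv; ++r) {
    V(r, 0) = vm.coords[3 * r];
    V(r, 1) = vm.coords[3 * r + 1];
    V(r, 2) = vm.coords[3 * r + 2];
  }
  IntegerMatrix F(nf, 3);
  for (int r = 0; r < nf; ++r) {
    F(r, 0) = faces[3 * r] + 1;
    F(r, 1) = faces[3 * r + 1] + 1;
    F(r, 2) = faces[3 * r + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// mesh topology / measures
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mesh_face_components")]]
IntegerVector mesh_face_components(IntegerMatrix F, int n_vertices) {
  std::vector<int> parent(n_vertices);
  for (int i = 0; i < n_vertices; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int a = find(F(f, 0) - 1), b = find(F(f, 1) - 1), c = find(F(f, 2) - 1);
    parent[b] = a; parent[find(c)] = find(a);
  }
  std::unordered_map<int, int> relabel;
  IntegerVector comp(nf);
  for (int f = 0; f < nf; ++f) {
    int r = find(F(f, 0) - 1);
    auto it = relabel.find(r);
    int lab;
    if (it == relabel.end()) { lab = (int)relabel.size() + 1; relabel.emplace(r, lab); }
    else lab = it->second;
    comp[f] = lab;
  }
  return comp;
}

// [[Rcpp::export(name = ".mesh_topology")]]
List mesh_topology(IntegerMatrix F, int n_vertices) {
  std::unordered_map<uint64_t, std::pair<int,int>> edges; // fwd,bwd counts
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    for (int e = 0; e < 3; ++e) {
      int a = F(f, e) - 1, b = F(f, (e + 1) % 3) - 1;
      uint64_t key; bool fwd;
      if (a < b) { key = ((uint64_t)a << 32) | (uint64_t)b; fwd = true; }
      else       { key = ((uint64_t)b << 32) | (uint64_t)a; fwd = false; }
      auto &cnt = edges[key];
      if (fwd) ++cnt.first; else ++cnt.second;
    }
  }
  int n_boundary = 0, n_bad = 0;
  for (auto &kv : edges) {
    int tot = kv.second.first + kv.second.second;
    if (tot == 1) ++n_boundary;
    else if (tot != 2 || kv.second.first != 1 || kv.second.second != 1) ++n_bad;
  }
  int nE = (int)edges.size();
  bool closed = (n_boundary == 0 && n_bad == 0);
  return List::create(_["n_edges"] = nE,
                      _["n_boundary_edges"] = n_boundary,
                      _["n_nonmanifold_edges"] = n_bad,
                      _["closed"] = closed,
                      _["euler"] = n_vertices - nE + nf);
}

// [[Rcpp::export(name = ".mesh_area_volume")]]
NumericVector mesh_area_volume(NumericMatrix V, IntegerMatrix F) {
  double area = 0.0, vol6 = 0.0;
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const double *a = &V(F(f,0)-1, 0); // column-major: careful, use explicit
    double ax = V(F(f,0)-1,0), ay = V(F(f,0)-1,1), az = V(F(f,0)-1,2);
    double bx = V(F(f,1)-1,0), by = V(F(f,1)-1,1), bz = V(F(f,1)-1,2);
    double cx = V(F(f,2)-1,0), cy = V(F(f,2)-1,1), cz = V(F(f,2)-1,2);
    (void)a;
    double ux = bx-ax, uy = by-ay, uz = bz-az;
    double vx = cx-ax, vy = cy-ay, vz = cz-az;
    double nxv = uy*vz-uz*vy, nyv = uz*vx-ux*vz, nzv = ux*vy-uy*vx;
    area += 0.5 * std::sqrt(nxv*nxv + nyv*nyv + nzv*nzv);
    vol6 += ax*(by*cz-bz*cy) - ay*(bx*cz-bz*cx) + az*(bx*cy-by*cx);
  }
  return NumericVector::create(area, vol6 / 6.0);
}

// [[Rcpp::export(name = ".face_areas")]]
NumericVector face_areas(NumericMatrix V, IntegerMatrix F) {
  int nf = F.nrow();
  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    double ax = V(F(f,0)-1,0), ay = V(F(f,0)-1,1), az = V(F(f,0)-1,2);
    double bx = V(F(f,1)-1,0), by = V(F(f,1)-1,1), bz = V(F(f,1)-1,2);
    double cx = V(F(f,2)-1,0), cy = V(F(f,2)-1,1), cz = V(F(f,2)-1,2);
    double ux = bx-ax, uy = by-ay, uz = bz-az;
    double vx = cx-ax, vy = cy-ay, vz = cz-az;
    double nxv = uy*vz-uz*vy, nyv = uz*vx-ux*vz, nzv = ux*vy-uy*vx;
    out[f] = 0.5 * std::sqrt(nxv*nxv + nyv*nyv + nzv*nzv);
  }
  return out;
}

// ---------------------------------------------------------------------------
// AABB tree over triangles, exact point-to-triangle closest point
// ---------------------------------------------------------------------------

struct Vec3 { double x, y, z; };
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

// Ericson, Real-Time Collision Detection, closest point on triangle
static Vec3 closest_on_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                                const Vec3 &c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return {a.x + v*ab.x, a.y + v*ab.y, a.z + v*ab.z};
  }
  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return {a.x + w*ac.x, a.y + w*ac.y, a.z + w*ac.z};
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return {b.x + w*(c.x-b.x), b.y + w*(c.y-b.y), b.z + w*(c.z-b.z)};
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return {a.x + ab.x*v + ac.x*w, a.y + ab.y*v + ac.y*w, a.z + ab.z*v + ac.z*w};
}

struct AABBNode {
  double lo[3], hi[3];
  int left, right;   // children, or -1 for leaf
  int start, count;  // triangle range for leaves
};

struct AABBTree {
  std::vector<AABBNode> nodes;
  std::vector<int> tri_order;
  std::vector<Vec3> A, B, C; // triangle vertices in original order
  int n_tri;
};

static int build_node(AABBTree &T, std::vector<Vec3> &cent, int start, int count) {
  AABBNode node;
  node.lo[0] = node.lo[1] = node.lo[2] = R_PosInf;
  node.hi[0] = node.hi[1] = node.hi[2] = R_NegInf;
  for (int i = start; i < start + count; ++i) {
    int t = T.tri_order[i];
    const Vec3 *vs[3] = {&T.A[t], &T.B[t], &T.C[t]};
    for (const Vec3 *v : vs) {
      node.lo[0] = std::min(node.lo[0], v->x); node.hi[0] = std::max(node.hi[0], v->x);
      node.lo[1] = std::min(node.lo[1], v->y); node.hi[1] = std::max(node.hi[1], v->y);
      node.lo[2] = std::min(node.lo[2], v->z); node.hi[2] = std::max(node.hi[2], v->z);
    }
  }
  int idx = (int)T.nodes.size();
  T.nodes.push_back(node);
  if (count <= 8) {
    T.nodes[idx].left = T.nodes[idx].right = -1;
    T.nodes[idx].start = start; T.nodes[idx].count = count;
    return idx;
  }
  int axis = 0;
  double ext[3] = {node.hi[0]-node.lo[0], node.hi[1]-node.lo[1], node.hi[2]-node.lo[2]};
  if (ext[1] > ext[axis]) axis = 1;
  if (ext[2] > ext[axis]) axis = 2;
  int mid = start + count / 2;
  std::nth_element(T.tri_order.begin() + start, T.tri_order.begin() + mid,
                   T.tri_order.begin() + start + count,
                   [&](int a, int b) {
                     double ca = axis == 0 ? cent[a].x : (axis == 1 ? cent[a].y : cent[a].z);
                     double cb = axis == 0 ? cent[b].x : (axis == 1 ? cent[b].y : cent[b].z);
                     return ca < cb;
                   });
  int l = build_node(T, cent, start, mid - start);
  int r = build_node(T, cent, mid, start + count - mid);
  T.nodes[idx].left = l; T.nodes[idx].right = r;
  T.nodes[idx].start = -1; T.nodes[idx].count = 0;
  return idx;
}

static inline double box_dist2(const AABBNode &n, const Vec3 &p) {
  double d = 0.0;
  double dx = std::max({n.lo[0] - p.x, 0.0, p.x - n.hi[0]});
  double dy = std::max({n.lo[1] - p.y, 0.0, p.y - n.hi[1]});
  double dz = std::max({n.lo[2] - p.z, 0.0, p.z - n.hi[2]});
  d = dx*dx + dy*dy + dz*dz;
  return d;
}

// [[Rcpp::export(name = ".aabb_build")]]
SEXP aabb_build(NumericMatrix V, IntegerMatrix F) {
  AABBTree *T = new AABBTree();
  int nf = F.nrow();
  if (nf < 1) { delete T; stop("cannot build a tree over an empty mesh"); }
  T->n_tri = nf;
  T->A.resize(nf); T->B.resize(nf); T->C.resize(nf);
  std::vector<Vec3> cent(nf);
  T->tri_order.resize(nf);
  for (int f = 0; f < nf; ++f) {
    T->A[f] = {V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2)};
    T->B[f] = {V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2)};
    T->C[f] = {V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2)};
    cent[f] = {(T->A[f].x + T->B[f].x + T->C[f].x) / 3.0,
               (T->A[f].y + T->B[f].y + T->C[f].y) / 3.0,
               (T->A[f].z + T->B[f].z + T->C[f].z) / 3.0};
    T->tri_order[f] = f;
  }
  T->nodes.reserve(2 * nf / 8 + 8);
  build_node(*T, cent, 0, nf);
  XPtr<AABBTree> ptr(T, true);
  return ptr;
}

// [[Rcpp::export(name = ".aabb_query")]]
List aabb_query(SEXP tree, NumericMatrix P) {
  XPtr<AABBTree> T(tree);
  int n = P.nrow();
  NumericVector dist(n);
  NumericMatrix closest(n, 3);
  IntegerVector face(n);
  std::vector<int> stack;
  stack.reserve(64);
  for (int q = 0; q < n; ++q) {
    Vec3 p = {P(q,0), P(q,1), P(q,2)};
    double best2 = R_PosInf;
    Vec3 bestp = {0,0,0};
    int bestf = -1;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back(); stack.pop_back();
      const AABBNode &node = T->nodes[ni];
      if (box_dist2(node, p) >= best2) continue;
      if (node.left < 0) {
        for (int i = node.start; i < node.start + node.count; ++i) {
          int t = T->tri_order[i];
          Vec3 c = closest_on_triangle(p, T->A[t], T->B[t], T->C[t]);
          Vec3 d = vsub(p, c);
          double d2 = vdot(d, d);
          if (d2 < best2) { best2 = d2; bestp = c; bestf = t; }
        }
      } else {
        double dl = box_dist2(T->nodes[node.left], p);
        double dr = box_dist2(T->nodes[node.right], p);
        // push farther first so nearer is processed next
        if (dl <= dr) {
          if (dr < best2) stack.push_back(node.right);
          if (dl < best2) stack.push_back(node.left);
        } else {
          if (dl < best2) stack.push_back(node.left);
          if (dr < best2) stack.push_back(node.right);
        }
      }
    }
    dist[q] = std::sqrt(best2);
    closest(q,0) = bestp.x; closest(q,1) = bestp.y; closest(q,2) = bestp.z;
    face[q] = bestf + 1;
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["face"] = face);
}

// ---------------------------------------------------------------------------
// partial-volume voxelization: per sub-column in xy, exact interval overlap
// along z (supersample^2 sub-columns per voxel)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".voxelize_occupancy")]]
NumericVector voxelize_occupancy(NumericMatrix V, IntegerMatrix F,
                                 IntegerVector dim, NumericVector spacing,
                                 NumericVector origin, int supersample) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int ss = supersample;
  const int nf = F.nrow();
  const int ncx = nx * ss, ncy = ny * ss;

  // bucket triangles by the sub-columns their xy bbox covers
  std::vector<std::vector<int>> buckets((size_t)ncx * ncy);
  const double csx = sx / ss, csy = sy / ss;
  for (int f = 0; f < nf; ++f) {
    double xs[3] = {V(F(f,0)-1,0), V(F(f,1)-1,0), V(F(f,2)-1,0)};
    double ys[3] = {V(F(f,0)-1,1), V(F(f,1)-1,1), V(F(f,2)-1,1)};
    double xmin = std::min({xs[0], xs[1], xs[2]}), xmax = std::max({xs[0], xs[1], xs[2]});
    double ymin = std::min({ys[0], ys[1], ys[2]}), ymax = std::max({ys[0], ys[1], ys[2]});
    int i0 = std::max(0, (int)std::floor((xmin - ox) / csx) - 1);
    int i1 = std::min(ncx - 1, (int)std::floor((xmax - ox) / csx) + 1);
    int j0 = std::max(0, (int)std::floor((ymin - oy) / csy) - 1);
    int j1 = std::min(ncy - 1, (int)std::floor((ymax - oy) / csy) + 1);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        buckets[(size_t)j * ncx + i].push_back(f);
  }

  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> crossings;
  // small deterministic offset keeps rays off mesh edges/vertices
  const double jitter_x = 0.5 + 1.23456789e-4, jitter_y = 0.5 + 2.3456789e-4;

  for (int cj = 0; cj < ncy; ++cj) {
    double ry = oy + (cj + jitter_y) * csy;
    for (int ci = 0; ci < ncx; ++ci) {
      double rx = ox + (ci + jitter_x) * csx;
      const std::vector<int> &cand = buckets[(size_t)cj * ncx + ci];
      if (cand.empty()) continue;
      crossings.clear();
      for (int f : cand) {
        double ax = V(F(f,0)-1,0), ay = V(F(f,0)-1,1), az = V(F(f,0)-1,2);
        double bx = V(F(f,1)-1,0), by = V(F(f,1)-1,1), bz = V(F(f,1)-1,2);
        double cx = V(F(f,2)-1,0), cy = V(F(f,2)-1,1), cz = V(F(f,2)-1,2);
        double d1 = (bx-ax)*(ry-ay) - (by-ay)*(rx-ax);
        double d2 = (cx-bx)*(ry-by) - (cy-by)*(rx-bx);
        double d3 = (ax-cx)*(ry-cy) - (ay-cy)*(rx-cx);
        bool pos = d1 > 0 && d2 > 0 && d3 > 0;
        bool neg = d1 < 0 && d2 < 0 && d3 < 0;
        if (!pos && !neg) continue;
        double s = d1 + d2 + d3;
        // barycentric interpolation of z at (rx, ry)
        double z = (d2 * az + d3 * bz + d1 * cz) / s;
        crossings.push_back(z);
      }
      if (crossings.size() < 2) continue;
      std::sort(crossings.begin(), crossings.end());
      if (crossings.size() % 2 == 1) crossings.pop_back(); // numeric guard
      int vi = ci / ss, vj = cj / ss;
      for (size_t m = 0; m + 1 < crossings.size(); m += 2) {
        double z0 = crossings[m], z1 = crossings[m + 1];
        int k0 = std::max(0, (int)std::floor((z0 - oz) / sz));
        int k1 = std::min(nz - 1, (int)std::floor((z1 - oz) / sz));
        for (int k = k0; k <= k1; ++k) {
          double lo = oz + k * sz, hi = lo + sz;
          double ov = std::min(hi, z1) - std::max(lo, z0);
          if (ov > 0)
            out[(R_xlen_t)vi + (R_xlen_t)nx * (vj + (R_xlen_t)ny * k)] += ov;
        }
      }
    }
  }
  double norm = 1.0 / (sz * ss * ss);
  for (R_xlen_t i = 0; i < out.size(); ++i) {
    out[i] *= norm;
    if (out[i] > 1.0) out[i] = 1.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// separable Gaussian blur, truncated at 4 sigma, kernel renormalized
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double> &v, int nx, int ny, int nz,
                      int axis, double sigma_vox) {
  if (sigma_vox <= 0) return;
  int radius = std::max(1, (int)std::ceil(4.0 * sigma_vox));
  std::vector<double> kern(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    kern[i + radius] = std::exp(-0.5 * (i / sigma_vox) * (i / sigma_vox));
    s += kern[i + radius];
  }
  for (double &k : kern) k /= s;
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int na = n[axis];
  R_xlen_t sa = stride[axis];
  int b = (axis + 1) % 3, c = (axis + 2) % 3;
  std::vector<double> line(na);
  for (int jc = 0; jc < n[c]; ++jc) {
    for (int jb = 0; jb < n[b]; ++jb) {
      R_xlen_t base = (R_xlen_t)jb * stride[b] + (R_xlen_t)jc * stride[c];
      for (int i = 0; i < na; ++i) line[i] = v[base + i * sa];
      for (int i = 0; i < na; ++i) {
        double acc = 0;
        int lo = std::max(0, i - radius), hi = std::min(na - 1, i + radius);
        double wsum = 0;
        for (int j = lo; j <= hi; ++j) {
          double w = kern[j - i + radius];
          acc += w * line[j];
          wsum += w;
        }
        v[base + i * sa] = acc / wsum; // renormalize at the borders
      }
    }
  }
}

// [[Rcpp::export(name = ".gaussian_blur3")]]
NumericVector gaussian_blur3(NumericVector values, IntegerVector dim,
                             NumericVector sigma_vox) {
  std::vector<double> v(values.begin(), values.end());
  blur_axis(v, dim[0], dim[1], dim[2], 0, sigma_vox[0]);
  blur_axis(v, dim[0], dim[1], dim[2], 1, sigma_vox[1]);
  blur_axis(v, dim[0], dim[1], dim[2], 2, sigma_vox[2]);
  NumericVector out(values.size());
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// exact vertex welding + degenerate-face removal (bit-identical coords)
// ---------------------------------------------------------------------------

struct CoordKey {
  uint64_t a, b, c;
  bool operator==(const CoordKey &o) const {
    return a == o.a && b == o.b && c == o.c;
  }
};
struct CoordKeyHash {
  size_t operator()(const CoordKey &k) const {
    uint64_t h = k.a * 0x9E3779B97F4A7C15ULL;
    h ^= k.b + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
    h ^= k.c + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
    return (size_t)h;
  }
};

static inline uint64_t dbits(double x) {
  uint64_t u;
  std::memcpy(&u, &x, sizeof(u));
  return u;
}

// [[Rcpp::export(name = ".weld_clean")]]
List weld_clean(NumericMatrix V, IntegerMatrix F) {
  int nv = V.nrow(), nf = F.nrow();
  std::unordered_map<CoordKey, int, CoordKeyHash> seen;
  seen.reserve(nv * 2);
  std::vector<int> remap(nv);
  std::vector<int> keep_v;
  keep_v.reserve(nv);
  for (int i = 0; i < nv; ++i) {
    CoordKey k{dbits(V(i, 0)), dbits(V(i, 1)), dbits(V(i, 2))};
    auto it = seen.find(k);
    if (it == seen.end()) {
      int id = (int)keep_v.size();
      seen.emplace(k, id);
      keep_v.push_back(i);
      remap[i] = id;
    } else {
      remap[i] = it->second;
    }
  }
  std::vector<int> faces;
  faces.reserve(3 * nf);
  for (int f = 0; f < nf; ++f) {
    int a = remap[F(f, 0) - 1], b = remap[F(f, 1) - 1], c = remap[F(f, 2) - 1];
    if (a == b || b == c || a == c) continue;
    faces.push_back(a); faces.push_back(b); faces.push_back(c);
  }
  // drop vertices no longer referenced
  int nw = (int)keep_v.size();
  std::vector<int> used(nw, 0);
  for (int id : faces) used[id] = 1;
  std::vector<int> remap2(nw, -1);
  int nfinal = 0;
  for (int i = 0; i < nw; ++i) if (used[i]) remap2[i] = nfinal++;
  NumericMatrix VV(nfinal, 3);
  for (int i = 0; i < nw; ++i) {
    if (!used[i]) continue;
    int r = remap2[i], src = keep_v[i];
    VV(r, 0) = V(src, 0); VV(r, 1) = V(src, 1); VV(r, 2) = V(src, 2);
  }
  int nff = (int)faces.size() / 3;
  IntegerMatrix FF(nff, 3);
  for (int f = 0; f < nff; ++f) {
    FF(f, 0) = remap2[faces[3 * f]] + 1;
    FF(f, 1) = remap2[faces[3 * f + 1]] + 1;
    FF(f, 2) = remap2[faces[3 * f + 2]] + 1;
  }
  return List::create(_["vertices"] = VV, _["faces"] = FF);
}
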