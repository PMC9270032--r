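// Incremental 3D Delaunay triangulation (Bowyer-Watson with an explicit
// point at infinity, so no fragile "super tetrahedron" coordinates).
// Predicates are evaluated in long double; genuinely degenerate inputs are
// expected to be jittered by the caller before retrying.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

typedef long double ld;

static inline ld orient3d_ld(const double *a, const double *b, const double *c,
                             const double *d) {
  ld adx = (ld)a[0] - d[0], ady = (ld)a[1] - d[1], adz = (ld)a[2] - d[2];
  ld bdx = (ld)b[0] - d[0], bdy = (ld)b[1] - d[1], bdz = (ld)b[2] - d[2];
  ld cdx = (ld)c[0] - d[0], cdy = (ld)c[1] - d[1], cdz = (ld)c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy) - ady * (bdx * cdz - bdz * cdx) +
         adz * (bdx * cdy - bdy * cdx);
}

// > 0 iff e lies strictly inside the circumsphere of the positively
// oriented tetrahedron (a, b, c, d).
static inline ld insphere_ld(const double *a, const double *b, const double *c,
                             const double *d, const double *e) {
  ld aex = (ld)a[0] - e[0], aey = (ld)a[1] - e[1], aez = (ld)a[2] - e[2];
  ld bex = (ld)b[0] - e[0], bey = (ld)b[1] - e[1], bez = (ld)b[2] - e[2];
  ld cex = (ld)c[0] - e[0], cey = (ld)c[1] - e[1], cez = (ld)c[2] - e[2];
  ld dex = (ld)d[0] - e[0], dey = (ld)d[1] - e[1], dez = (ld)d[2] - e[2];
  ld alift = aex * aex + aey * aey + aez * aez;
  ld blift = bex * bex + bey * bey + bez * bez;
  ld clift = cex * cex + cey * cey + cez * cez;
  ld dlift = dex * dex + dey * dey + dez * dez;
  ld ab = aex * bey - bex * aey, bc = bex * cey - cex * bey;
  ld cd = cex * dey - dex * cey, da = dex * aey - aex * dey;
  ld ac = aex * cey - cex * aey, bd = bex * dey - dex * bey;
  ld abc = aez * bc - bez * ac + cez * ab;
  ld bcd = bez * cd - cez * bd + dez * bc;
  ld cda = cez * da + dez * ac + aez * cd;
  ld dab = dez * ab + aez * bd + bez * da;
  return (dlift * abc - clift * dab) + (blift * cda - alift * bcd);
}

struct Tet {
  int v[4];   // vertex ids; v[3] == -1 marks an infinite tetrahedron
  int nb[4];  // neighbour opposite v[i]
  bool alive;
};

// face opposite vertex i of a positively oriented finite tet, oriented so
// that orient3d(face, v[i]) > 0
static const int FACE[4][3] = {{2, 1, 3}, {0, 2, 3}, {1, 0, 3}, {0, 1, 2}};

struct FaceKey {
  int a, b, c;
  bool operator==(const FaceKey &o) const {
    return a == o.a && b == o.b && c == o.c;
  }
};
struct FaceKeyHash {
  size_t operator()(const FaceKey &k) const {
    uint64_t h = 1469598103934665603ull;
    for (int x : {k.a, k.b, k.c}) {
      h ^= (uint64_t)(x + 2);
      h *= 1099511628211ull;
    }
    return (size_t)h;
  }
};
static inline FaceKey face_key(int a, int b, int c) {
  if (a > b) std::swap(a, b);
  if (b > c) std::swap(b, c);
  if (a > b) std::swap(a, b);
  return FaceKey{a, b, c};
}

class Delaunay3 {
public:
  const double *pts;  // n x 3, row-major
  int n;
  std::vector<Tet> tets;
  double inner[3];  // a point strictly inside the hull of the first 4 sites

  Delaunay3(const double *pts_, int n_) : pts(pts_), n(n_) {}
  const double *P(int i) const { return pts + 3 * i; }

  bool in_conflict(int t, const double *p) const {
    const Tet &T = tets[t];
    if (T.v[3] == -1) {
      ld o = orient3d_ld(P(T.v[0]), P(T.v[1]), P(T.v[2]), p);
      return o > 0;  // strictly outside the hull facet
    }
    return insphere_ld(P(T.v[0]), P(T.v[1]), P(T.v[2]), P(T.v[3]), p) > 0;
  }

  void init(int i0, int i1, int i2, int i3) {
    ld o = orient3d_ld(P(i0), P(i1), P(i2), P(i3));
    if (o == 0) stop("degenerate initial tetrahedron");
    if (o < 0) std::swap(i2, i3);
    for (int k = 0; k < 3; ++k)
      inner[k] = 0.25 * (P(i0)[k] + P(i1)[k] + P(i2)[k] + P(i3)[k]);
    int v[4] = {i0, i1, i2, i3};
    Tet T0;
    for (int k = 0; k < 4; ++k) T0.v[k] = v[k];
    T0.alive = true;
    tets.push_back(T0);
    // four infinite tets, one per face, stored as (a,b,c,-1) with the face
    // oriented so that points outside the hull give orient3d(a,b,c,p) > 0
    for (int i = 0; i < 4; ++i) {
      Tet TI;
      TI.v[0] = v[FACE[i][1]];  // reversed: interior on negative side
      TI.v[1] = v[FACE[i][0]];
      TI.v[2] = v[FACE[i][2]];
      TI.v[3] = -1;
      TI.alive = true;
      tets.push_back(TI);
    }
    // stitch neighbours via the generic face map
    std::unordered_map<FaceKey, std::pair<int, int>, FaceKeyHash> fmap;
    for (int t = 0; t < 5; ++t) link_faces(t, fmap);
  }

  void faces_of(const Tet &T, FaceKey fk[4]) const {
    for (int i = 0; i < 4; ++i) {
      int a = T.v[FACE[i][0]], b = T.v[FACE[i][1]], c = T.v[FACE[i][2]];
      fk[i] = face_key(a, b, c);
    }
  }

  void link_faces(int t,
                  std::unordered_map<FaceKey, std::pair<int, int>, FaceKeyHash> &fmap) {
    FaceKey fk[4];
    faces_of(tets[t], fk);
    for (int i = 0; i < 4; ++i) {
      auto it = fmap.find(fk[i]);
      if (it == fmap.end()) {
        fmap[fk[i]] = {t, i};
        tets[t].nb[i] = -1;
      } else {
        int u = it->second.first, j = it->second.second;
        tets[t].nb[i] = u;
        tets[u].nb[j] = t;
      }
    }
  }

  // locate a tetrahedron in conflict with p, walking from hint
  int locate(const double *p, int hint) {
    int cur = hint, steps = 0, maxsteps = 10 * (int)tets.size() + 100;
    while (steps++ < maxsteps) {
      if (!tets[cur].alive) break;
      const Tet &T = tets[cur];
      if (T.v[3] == -1) {
        if (in_conflict(cur, p)) return cur;
        // walk back inside across the finite face (opposite the infinite
        // vertex, which is stored at position 3)
        if (T.nb[3] < 0) break;
        cur = T.nb[3];
        continue;
      }
      int next = -1;
      for (int i = 0; i < 4; ++i) {
        const double *A = P(T.v[FACE[i][0]]);
        const double *B = P(T.v[FACE[i][1]]);
        const double *C = P(T.v[FACE[i][2]]);
        if (orient3d_ld(A, B, C, p) < 0) { next = T.nb[i]; break; }
      }
      if (next < 0) return cur;  // containing tet
      cur = next;
    }
    // robust fallback: linear scan
    for (int t = 0; t < (int)tets.size(); ++t)
      if (tets[t].alive && in_conflict(t, p)) return t;
    return -1;
  }

  void insert(int ip) {
    const double *p = P(ip);
    static int hint = 0;
    if (hint >= (int)tets.size() || !tets[hint].alive) hint = 0;
    int seed = locate(p, hint);
    if (seed < 0 || !in_conflict(seed, p))
      { // exhaustive check before giving up
        seed = -1;
        for (int t = 0; t < (int)tets.size(); ++t)
          if (tets[t].alive && in_conflict(t, p)) { seed = t; break; }
        if (seed < 0) stop("point location failed (degenerate input)");
      }
    // BFS the conflict cavity
    std::vector<int> cavity, stack{seed};
    std::vector<char> inCav(tets.size(), 0);
    inCav[seed] = 1;
    while (!stack.empty()) {
      int t = stack.back();
      stack.pop_back();
      cavity.push_back(t);
      for (int i = 0; i < 4; ++i) {
        int u = tets[t].nb[i];
        if (u < 0 || inCav[u] || !tets[u].alive) continue;
        if (in_conflict(u, p)) {
          inCav[u] = 1;
          stack.push_back(u);
        }
      }
    }
    // boundary faces: (face vertices, outside neighbour, its face index)
    struct BFace { int a, b, c, out, outIdx; };
    std::vector<BFace> bfaces;
    for (int t : cavity) {
      const Tet &T = tets[t];
      for (int i = 0; i < 4; ++i) {
        int u = T.nb[i];
        if (u >= 0 && inCav[u]) continue;
        int a = T.v[FACE[i][0]], b = T.v[FACE[i][1]], c = T.v[FACE[i][2]];
        int outIdx = -1;
        if (u >= 0) {
          FaceKey fk = face_key(a, b, c);
          FaceKey ofk[4];
          faces_of(tets[u], ofk);
          for (int j = 0; j < 4; ++j)
            if (ofk[j] == fk) { outIdx = j; break; }
        }
        bfaces.push_back(BFace{a, b, c, u, outIdx});
      }
    }
    for (int t : cavity) tets[t].alive = false;
    // create new tets joining p to each boundary face
    std::unordered_map<FaceKey, std::pair<int, int>, FaceKeyHash> fmap;
    std::vector<int> created;
    for (const BFace &f : bfaces) {
      Tet N;
      bool inf_face = (f.a == -1 || f.b == -1 || f.c == -1);
      if (!inf_face) {
        ld o = orient3d_ld(P(f.a), P(f.b), P(f.c), p);
        if (o == 0) stop("degenerate cavity face (cospherical input)");
        if (o > 0) { N.v[0] = f.a; N.v[1] = f.b; N.v[2] = f.c; }
        else       { N.v[0] = f.b; N.v[1] = f.a; N.v[2] = f.c; }
        N.v[3] = ip;
        if (ip == -1) stop("internal error");
      } else {
        // infinite new tet: face is (edge, inf); finite face becomes
        // (edge, p), oriented with the hull interior on the negative side
        int e[2], k = 0;
        for (int x : {f.a, f.b, f.c})
          if (x != -1) e[k++] = x;
        ld o = orient3d_ld(P(e[0]), P(e[1]), p, inner);
        if (o == 0) stop("degenerate hull face");
        if (o < 0) { N.v[0] = e[0]; N.v[1] = e[1]; }
        else       { N.v[0] = e[1]; N.v[1] = e[0]; }
        N.v[2] = ip;
        N.v[3] = -1;
      }
      N.alive = true;
      int tid = (int)tets.size();
      tets.push_back(N);
      created.push_back(tid);
      // reconnect to the outside neighbour across the boundary face
      FaceKey fk = face_key(f.a, f.b, f.c);
      FaceKey nfk[4];
      faces_of(tets[tid], nfk);
      for (int i = 0; i < 4; ++i) {
        if (nfk[i] == fk) {
          tets[tid].nb[i] = f.out;
          if (f.out >= 0 && f.outIdx >= 0) tets[f.out].nb[f.outIdx] = tid;
        } else {
          auto it = fmap.find(nfk[i]);
          if (it == fmap.end()) {
            fmap[nfk[i]] = {tid, i};
            tets[tid].nb[i] = -2;  // provisional
          } else {
            int u = it->second.first, j = it->second.second;
            tets[tid].nb[i] = u;
            tets[u].nb[j] = tid;
          }
        }
      }
    }
    for (int t : created)
      for (int i = 0; i < 4; ++i)
        if (tets[t].nb[i] == -2) stop("non-manifold cavity boundary");
    hint = created.empty() ? 0 : created.back();
  }
};

// [[Rcpp::export]]
IntegerMatrix delaunay3d_cpp(NumericMatrix pts, IntegerVector order) {
  int n = pts.nrow();
  if (pts.ncol() != 3) stop("points must be n x 3");
  if (n < 4) stop("need at least 4 points");
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) P[3 * i + k] = pts(i, k);

  // choose 4 affinely independent starters from the given insertion order
  std::vector<int> ord(order.begin(), order.end());
  if ((int)ord.size() != n) stop("order must be a permutation of the points");
  for (int &o : ord) {
    --o;  // R is 1-based
    if (o < 0 || o >= n) stop("order out of range");
  }
  int i0 = ord[0], i1 = -1, i2 = -1, i3 = -1;
  size_t k = 1;
  for (; k < ord.size(); ++k) {
    int j = ord[k];
    const double *a = &P[3 * i0], *b = &P[3 * j];
    ld dx = (ld)b[0] - a[0], dy = (ld)b[1] - a[1], dz = (ld)b[2] - a[2];
    if (dx * dx + dy * dy + dz * dz > 0) { i1 = j; ++k; break; }
  }
  if (i1 < 0) stop("all points coincident");
  for (; k < ord.size(); ++k) {
    int j = ord[k];
    const double *a = &P[3 * i0], *b = &P[3 * i1], *c = &P[3 * j];
    ld ux = (ld)b[0] - a[0], uy = (ld)b[1] - a[1], uz = (ld)b[2] - a[2];
    ld vx = (ld)c[0] - a[0], vy = (ld)c[1] - a[1], vz = (ld)c[2] - a[2];
    ld cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    if (cx * cx + cy * cy + cz * cz > 0) { i2 = j; ++k; break; }
  }
  if (i2 < 0) stop("all points collinear");
  for (; k < ord.size(); ++k) {
    int j = ord[k];
    if (orient3d_ld(&P[3 * i0], &P[3 * i1], &P[3 * i2], &P[3 * j]) != 0) {
      i3 = j;
      break;
    }
  }
  if (i3 < 0) stop("all points coplanar");

  Delaunay3 D(P.data(), n);
  D.init(i0, i1, i2, i3);
  std::vector<char> used(n, 0);
  used[i0] = used[i1] = used[i2] = used[i3] = 1;
  for (int j : ord) {
    if (used[j]) continue;
    used[j] = 1;
    D.insert(j);
  }

  int m = 0;
  for (const Tet &T : D.tets)
    if (T.alive && T.v[3] != -1) ++m;
  IntegerMatrix out(m, 4);
  int r = 0;
  for (const Tet &T : D.tets) {
    if (!T.alive || T.v[3] == -1) continue;
    for (int i = 0; i < 4; ++i) out(r, i) = T.v[i] + 1;  // 1-based for R
    ++r;
  }
  return out;
}
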