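// Alpha-complex filtration values (squared circumradius units) and degree-1
// persistence pairs by boundary-matrix reduction over Z/2.
//
// Filtration values follow the standard alpha-complex rule: a simplex that
// is not Gabriel with respect to a coface inherits the coface's value;
// otherwise it enters at its own squared circumradius.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <functional>

using namespace Rcpp;
typedef long double ld;

struct Key2 {
  int a, b;
  bool operator==(const Key2 &o) const { return a == o.a && b == o.b; }
};
struct Key3 {
  int a, b, c;
  bool operator==(const Key3 &o) const {
    return a == o.a && b == o.b && c == o.c;
  }
};
struct Key2Hash {
  size_t operator()(const Key2 &k) const {
    return ((uint64_t)k.a * 2654435761u) ^ ((uint64_t)k.b * 40503u << 16);
  }
};
struct Key3Hash {
  size_t operator()(const Key3 &k) const {
    uint64_t h = 1469598103934665603ull;
    for (int x : {k.a, k.b, k.c}) {
      h ^= (uint64_t)x;
      h *= 1099511628211ull;
    }
    return (size_t)h;
  }
};

static inline Key2 mk2(int a, int b) {
  if (a > b) std::swap(a, b);
  return Key2{a, b};
}
static inline Key3 mk3(int a, int b, int c) {
  if (a > b) std::swap(a, b);
  if (b > c) std::swap(b, c);
  if (a > b) std::swap(a, b);
  return Key3{a, b, c};
}

// squared circumradius and circumcentre of an edge
static void circum_edge(const double *a, const double *b, ld cc[3], ld &r2) {
  r2 = 0;
  for (int k = 0; k < 3; ++k) {
    cc[k] = ((ld)a[k] + b[k]) / 2;
    ld d = (ld)b[k] - a[k];
    r2 += d * d;
  }
  r2 /= 4;
}

// squared circumradius and circumcentre of a triangle (in its own plane)
static void circum_tri(const double *a, const double *b, const double *c,
                       ld cc[3], ld &r2) {
  ld u[3], v[3];
  for (int k = 0; k < 3; ++k) {
    u[k] = (ld)b[k] - a[k];
    v[k] = (ld)c[k] - a[k];
  }
  ld uu = 0, vv = 0, uv = 0;
  for (int k = 0; k < 3; ++k) {
    uu += u[k] * u[k];
    vv += v[k] * v[k];
    uv += u[k] * v[k];
  }
  ld det = uu * vv - uv * uv;
  if (det == 0) det = 1e-300L;  // degenerate triangle; value becomes huge
  ld s = (uu * vv - uv * vv) / (2 * det);
  ld t = (uu * vv - uv * uu) / (2 * det);
  r2 = 0;
  for (int k = 0; k < 3; ++k) {
    ld w = s * u[k] + t * v[k];
    cc[k] = a[k] + w;
    r2 += w * w;
  }
}

// squared circumradius and circumcentre of a tetrahedron
static void circum_tet(const double *a, const double *b, const double *c,
                       const double *d, ld cc[3], ld &r2) {
  ld A[3][3], rhs[3];
  const double *q[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    rhs[i] = 0;
    for (int k = 0; k < 3; ++k) {
      A[i][k] = 2 * ((ld)q[i][k] - a[k]);
      rhs[i] += ((ld)q[i][k] - a[k]) * ((ld)q[i][k] + a[k]);
    }
    rhs[i] -= 0;  // rhs = |q|^2 - |a|^2 accumulated below
  }
  // recompute rhs properly: |q|^2 - |a|^2
  for (int i = 0; i < 3; ++i) {
    ld s = 0;
    for (int k = 0; k < 3; ++k)
      s += ((ld)q[i][k]) * q[i][k] - ((ld)a[k]) * a[k];
    rhs[i] = s;
  }
  // Gaussian elimination with partial pivoting
  int piv[3] = {0, 1, 2};
  for (int col = 0; col < 3; ++col) {
    int best = col;
    for (int r = col + 1; r < 3; ++r)
      if (fabsl(A[piv[r]][col]) > fabsl(A[piv[best]][col])) best = r;
    std::swap(piv[col], piv[best]);
    ld p = A[piv[col]][col];
    if (p == 0) p = 1e-300L;
    for (int r = col + 1; r < 3; ++r) {
      ld f = A[piv[r]][col] / p;
      for (int k = col; k < 3; ++k) A[piv[r]][k] -= f * A[piv[col]][k];
      rhs[piv[r]] -= f * rhs[piv[col]];
    }
  }
  ld x[3];
  for (int col = 2; col >= 0; --col) {
    ld s = rhs[piv[col]];
    for (int k = col + 1; k < 3; ++k) s -= A[piv[col]][k] * x[k];
    ld p = A[piv[col]][col];
    if (p == 0) p = 1e-300L;
    x[col] = s / p;
  }
  r2 = 0;
  for (int k = 0; k < 3; ++k) {
    cc[k] = x[k];
    ld dk = x[k] - a[k];
    r2 += dk * dk;
  }
}

static inline ld dist2(const ld cc[3], const double *p) {
  ld s = 0;
  for (int k = 0; k < 3; ++k) {
    ld d = cc[k] - p[k];
    s += d * d;
  }
  return s;
}

// [[Rcpp::export]]
List alpha_persistence_cpp(NumericMatrix pts, IntegerMatrix tets,
                           IntegerMatrix tris_in, double min_persistence) {
  int n = pts.nrow();
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) P[3 * i + k] = pts(i, k);
  auto PT = [&](int i) { return &P[3 * i]; };

  int nt = tets.nrow();
  // triangles: either faces of the tetrahedra, or supplied directly (planar
  // input triangulated in 2D)
  std::unordered_map<Key3, int, Key3Hash> tri_id;
  std::vector<std::array<int, 3>> tri;
  std::vector<std::array<int, 4>> tet(nt);
  static const int TF[4][3] = {{1, 2, 3}, {0, 2, 3}, {0, 1, 3}, {0, 1, 2}};
  if (nt > 0) {
    for (int t = 0; t < nt; ++t) {
      for (int k = 0; k < 4; ++k) tet[t][k] = tets(t, k) - 1;
      for (int f = 0; f < 4; ++f) {
        Key3 k3 = mk3(tet[t][TF[f][0]], tet[t][TF[f][1]], tet[t][TF[f][2]]);
        if (!tri_id.count(k3)) {
          tri_id[k3] = (int)tri.size();
          tri.push_back({k3.a, k3.b, k3.c});
        }
      }
    }
  } else {
    for (int t = 0; t < tris_in.nrow(); ++t) {
      Key3 k3 = mk3(tris_in(t, 0) - 1, tris_in(t, 1) - 1, tris_in(t, 2) - 1);
      if (!tri_id.count(k3)) {
        tri_id[k3] = (int)tri.size();
        tri.push_back({k3.a, k3.b, k3.c});
      }
    }
  }
  int ntri = (int)tri.size();

  std::unordered_map<Key2, int, Key2Hash> edge_id;
  std::vector<std::array<int, 2>> edge;
  for (const auto &T : tri) {
    const int pr[3][2] = {{0, 1}, {0, 2}, {1, 2}};
    for (auto &p2 : pr) {
      Key2 k2 = mk2(T[p2[0]], T[p2[1]]);
      if (!edge_id.count(k2)) {
        edge_id[k2] = (int)edge.size();
        edge.push_back({k2.a, k2.b});
      }
    }
  }
  int ne = (int)edge.size();

  // --- filtration values -------------------------------------------------
  const ld UNSET = -1;
  std::vector<ld> ftet(nt), ftri(ntri, UNSET), fedge(ne, UNSET);
  std::vector<std::array<ld, 3>> tri_cc(ntri);
  std::vector<ld> tri_r2(ntri);
  std::vector<std::array<ld, 3>> edge_cc(ne);
  std::vector<ld> edge_r2(ne);
  for (int i = 0; i < ntri; ++i) {
    ld cc[3], r2;
    circum_tri(PT(tri[i][0]), PT(tri[i][1]), PT(tri[i][2]), cc, r2);
    for (int k = 0; k < 3; ++k) tri_cc[i][k] = cc[k];
    tri_r2[i] = r2;
  }
  for (int i = 0; i < ne; ++i) {
    ld cc[3], r2;
    circum_edge(PT(edge[i][0]), PT(edge[i][1]), cc, r2);
    for (int k = 0; k < 3; ++k) edge_cc[i][k] = cc[k];
    edge_r2[i] = r2;
  }
  for (int t = 0; t < nt; ++t) {
    ld cc[3], r2;
    circum_tet(PT(tet[t][0]), PT(tet[t][1]), PT(tet[t][2]), PT(tet[t][3]), cc,
               r2);
    ftet[t] = r2;
  }
  // propagate tets -> triangles
  for (int t = 0; t < nt; ++t) {
    for (int f = 0; f < 4; ++f) {
      int a = tet[t][TF[f][0]], b = tet[t][TF[f][1]], c = tet[t][TF[f][2]];
      int opp = tet[t][f];
      int ti = tri_id[mk3(a, b, c)];
      if (ftri[ti] != UNSET)
        ftri[ti] = std::min(ftri[ti], ftet[t]);
      else if (dist2(tri_cc[ti].data(), PT(opp)) < tri_r2[ti])
        ftri[ti] = ftet[t];  // not Gabriel: inherits
    }
  }
  for (int i = 0; i < ntri; ++i)
    if (ftri[i] == UNSET) ftri[i] = tri_r2[i];
  // propagate triangles -> edges
  for (int i = 0; i < ntri; ++i) {
    const int pr[3][2] = {{0, 1}, {0, 2}, {1, 2}};
    const int op[3] = {2, 1, 0};
    for (int s = 0; s < 3; ++s) {
      int ei = edge_id[mk2(tri[i][pr[s][0]], tri[i][pr[s][1]])];
      int opp = tri[i][op[s]];
      if (fedge[ei] != UNSET)
        fedge[ei] = std::min(fedge[ei], ftri[i]);
      else if (dist2(edge_cc[ei].data(), PT(opp)) < edge_r2[ei])
        fedge[ei] = ftri[i];
    }
  }
  for (int i = 0; i < ne; ++i)
    if (fedge[i] == UNSET) fedge[i] = edge_r2[i];

  // --- sort simplices ----------------------------------------------------
  std::vector<int> eord(ne), tord(ntri);
  for (int i = 0; i < ne; ++i) eord[i] = i;
  for (int i = 0; i < ntri; ++i) tord[i] = i;
  std::sort(eord.begin(), eord.end(), [&](int a, int b) {
    if (fedge[a] != fedge[b]) return fedge[a] < fedge[b];
    return a < b;
  });
  std::sort(tord.begin(), tord.end(), [&](int a, int b) {
    if (ftri[a] != ftri[b]) return ftri[a] < ftri[b];
    return a < b;
  });
  std::vector<int> erank(ne);
  for (int i = 0; i < ne; ++i) erank[eord[i]] = i;

  // --- reduce the triangle boundary matrix -------------------------------
  // pairs (edge, triangle) are the degree-1 persistence pairs
  std::vector<std::vector<int>> stored(ne);  // reduced column claiming a low
  std::vector<int> low_owner(ne, -1);
  std::vector<std::pair<ld, ld>> pairs;
  std::vector<char> edge_paired(ne, 0);
  std::vector<int> col, tmp;
  for (int idx = 0; idx < ntri; ++idx) {
    int ti = tord[idx];
    col.clear();
    const int pr[3][2] = {{0, 1}, {0, 2}, {1, 2}};
    for (auto &p2 : pr)
      col.push_back(erank[edge_id[mk2(tri[ti][p2[0]], tri[ti][p2[1]])]]);
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int low = col.back();
      if (low_owner[low] < 0) {
        low_owner[low] = 1;
        stored[low] = col;
        int ei = eord[low];
        edge_paired[ei] = 1;
        ld birth = fedge[ei], death = ftri[ti];
        if (death - birth > (ld)min_persistence)
          pairs.push_back({birth, death});
        break;
      }
      // symmetric difference with the stored column
      const std::vector<int> &other = stored[low];
      tmp.clear();
      size_t i = 0, j = 0;
      while (i < col.size() || j < other.size()) {
        if (i < col.size() &&
            (j == other.size() || col[i] < other[j]))
          tmp.push_back(col[i++]);
        else if (j < other.size() &&
                 (i == col.size() || other[j] < col[i]))
          tmp.push_back(other[j++]);
        else {
          ++i;
          ++j;
        }
      }
      col.swap(tmp);
    }
  }

  // essential-class check: positive edges must all be paired.
  // union-find over the 1-skeleton (edges processed in filtration order)
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) x = parent[x] = parent[parent[x]];
    return x;
  };
  int n_negative = 0;
  for (int i = 0; i < ne; ++i) {
    int ei = eord[i];
    int ra = find(edge[ei][0]), rb = find(edge[ei][1]);
    if (ra != rb) {
      parent[ra] = rb;
      ++n_negative;
    }
  }
  int n_positive = ne - n_negative;
  int n_paired = 0;
  for (int i = 0; i < ne; ++i) n_paired += edge_paired[i];
  if (n_paired != n_positive)
    stop("essential degree-1 class detected: triangulation is not simply "
         "connected (degenerate input?)");

  NumericMatrix out((int)pairs.size(), 2);
  for (size_t i = 0; i < pairs.size(); ++i) {
    out(i, 0) = (double)pairs[i].first;
    out(i, 1) = (double)pairs[i].second;
  }
  return List::create(_["pairs"] = out, _["n_edges"] = ne,
                      _["n_triangles"] = ntri, _["n_tetrahedra"] = nt);
}
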