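// Geodesic distances on triangle meshes by first-order fast marching.
//
// The update at a vertex C from a triangle (A, B, C) with known values
// T_A, T_B unfolds a virtual point source S into the triangle's plane such
// that |S - A| = T_A and |S - B| = T_B with S on the far side of edge AB,
// and sets T_C = |S - C|.  The update is accepted only when the segment
// S -> C actually crosses the edge AB (the characteristic enters through
// the face); otherwise the scheme falls back to the one-sided (edge /
// Dijkstra) update, which keeps the solver causal on obtuse or degenerate
// configurations.  On a planar mesh the virtual source coincides with the
// true source, so planar distances are reproduced to rounding error.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

inline double dist3(const NumericMatrix& V, int i, int j) {
  double dx = V(i, 0) - V(j, 0);
  double dy = V(i, 1) - V(j, 1);
  double dz = V(i, 2) - V(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Virtual-source update for vertex C given T_A, T_B and the triangle's
// edge lengths b = |CA|, a = |CB| and the angle theta at C.  Returns the
// candidate value, or +Inf when the characteristic misses the triangle.
double triangleUpdate(double TA, double TB, double b, double a,
                      double cosTheta, double sinTheta) {
  if (sinTheta <= 1e-12) return INF;
  // local frame: A at (0, 0), B at (c, 0), C above the edge AB
  const double c2e = a * a + b * b - 2.0 * a * b * cosTheta;  // |AB|^2
  if (c2e <= 1e-24) return INF;
  const double c = std::sqrt(c2e);
  const double cx = (b * b + c2e - a * a) / (2.0 * c);
  const double cy = std::sqrt(std::max(0.0, b * b - cx * cx));
  // source S = (sx, sy), sy < 0: |S-A| = TA, |S-B| = TB
  const double sx = (TA * TA - TB * TB + c2e) / (2.0 * c);
  const double sy2 = TA * TA - sx * sx;
  if (sy2 < 0.0) return INF;  // inconsistent wavefront data
  const double sy = -std::sqrt(sy2);
  if (cy - sy <= 1e-12) return INF;
  // the segment S -> C must cross the edge AB between A and B
  const double t = sx + (0.0 - sy) * (cx - sx) / (cy - sy);
  if (t < 0.0 || t > c) return INF;
  const double dx = cx - sx, dy = cy - sy;
  const double TC = std::sqrt(dx * dx + dy * dy);
  if (TC < TA || TC < TB) return INF;  // not upwind
  return TC;
}

}  // namespace

// Fast-marching geodesic distance field from vertex `src` (0-based).
// Stops early once `dst` (0-based) is settled unless dst < 0, in which case
// the full field is computed.  Returns the vector of distances (mm).
// [[Rcpp::export(name = ".fmmGeodesic")]]
NumericVector fmmGeodesic(const NumericMatrix& V, const IntegerMatrix& F,
                          int src, int dst) {
  const int n = V.nrow(), m = F.nrow();
  if (src < 0 || src >= n) stop("source vertex out of range");
  if (dst >= n) stop("destination vertex out of range");

  // vertex -> incident faces
  std::vector<std::vector<int> > vfaces(n);
  for (int f = 0; f < m; ++f)
    for (int k = 0; k < 3; ++k) vfaces[F(f, k)].push_back(f);

  std::vector<double> T(n, INF);
  std::vector<char> fixed(n, 0);
  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > q;
  T[src] = 0.0;
  q.push(QN(0.0, src));

  while (!q.empty()) {
    const QN top = q.top();
    q.pop();
    const int u = top.second;
    if (fixed[u]) continue;
    fixed[u] = 1;
    if (u == dst) break;

    for (size_t fi = 0; fi < vfaces[u].size(); ++fi) {
      const int f = vfaces[u][fi];
      const int vs[3] = {F(f, 0), F(f, 1), F(f, 2)};
      for (int k = 0; k < 3; ++k) {
        const int c = vs[k];
        if (fixed[c]) continue;
        // third vertex of the face
        int other = -1;
        for (int j = 0; j < 3; ++j)
          if (vs[j] != c && vs[j] != u) other = vs[j];
        double cand = T[u] + dist3(V, c, u);  // edge update from u
        if (other >= 0 && fixed[other]) {
          const double b = dist3(V, c, u);      // |C-A|, A = u
          const double a = dist3(V, c, other);  // |C-B|, B = other
          double dot = 0.0;
          for (int d = 0; d < 3; ++d)
            dot += (V(u, d) - V(c, d)) * (V(other, d) - V(c, d));
          const double cosT = std::max(-1.0, std::min(1.0, dot / (a * b)));
          const double sinT = std::sqrt(std::max(0.0, 1.0 - cosT * cosT));
          const double tri = triangleUpdate(T[u], T[other], b, a, cosT, sinT);
          if (tri < cand) cand = tri;
          const double edgeOther = T[other] + a;
          if (edgeOther < cand) cand = edgeOther;
        }
        if (cand < T[c]) {
          T[c] = cand;
          q.push(QN(cand, c));
        }
      }
    }
  }

  return NumericVector(T.begin(), T.end());
}

// CRC-32 (ISO 3309 / PNG) of a raw vector; used by the 16-bit PNG writer.
// [[Rcpp::export(name = ".crc32")]]
double crc32raw(const RawVector& data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : (c >> 1);
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return static_cast<double>(crc ^ 0xFFFFFFFFu);
}
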