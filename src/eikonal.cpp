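// Multi-stencils fast marching solver for the 2-D Eikonal equation |grad T| = f
// (f = slowness, us/mm). Two stencils: axis-aligned (spacing h) and diagonal
// (spacing h*sqrt(2)); the causal minimum over stencils is kept. Second-order
// upwind differences are used where two accepted upwind neighbours exist.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Node {
  double t;
  int r, c;
};

// min-heap; ties broken on (row, col) so runs are bit-reproducible
struct NodeCmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.r != b.r) return a.r > b.r;
    return a.c > b.c;
  }
};

enum State { FAR = 0, TRIAL = 1, ACCEPTED = 2 };

struct Axis {
  bool have;    // at least a first-order upwind value
  double t1;    // first-order upwind value
  bool have2;   // a valid second-order pair
  double a2;    // second-order effective value (4 t1 - t2) / 3
};

inline int idx(int r, int c, int m) { return c * m + r; }

// examine one axis of a stencil: directions +/- (dr, dc)
Axis probe_axis(const double* T, const int* state, int m, int n,
                int r, int c, int dr, int dc, int order) {
  Axis ax; ax.have = false; ax.t1 = INF; ax.have2 = false; ax.a2 = INF;
  double t1 = INF;
  int sgn = 0;
  for (int s = -1; s <= 1; s += 2) {
    int rr = r + s * dr, cc = c + s * dc;
    if (rr < 0 || rr >= m || cc < 0 || cc >= n) continue;
    int k = idx(rr, cc, m);
    if (state[k] == ACCEPTED && T[k] < t1) { t1 = T[k]; sgn = s; }
  }
  if (!std::isfinite(t1)) return ax;
  ax.have = true; ax.t1 = t1;
  if (order >= 2) {
    int rr = r + 2 * sgn * dr, cc = c + 2 * sgn * dc;
    if (rr >= 0 && rr < m && cc >= 0 && cc < n) {
      int k = idx(rr, cc, m);
      if (state[k] == ACCEPTED && T[k] <= t1) {
        ax.a2 = (4.0 * t1 - T[k]) / 3.0;
        ax.have2 = true;
      }
    }
  }
  return ax;
}

// two-axis quadratic sum beta_i (t - a_i)^2 = rhs^2; causality is checked
// against the actual first-order neighbour times
double solve_pair(double ax_a, double ax_b, double bx_a, double bx_b,
                  double t1x, double t1y, double rhs) {
  double A = ax_b + bx_b;
  double B = ax_b * ax_a + bx_b * bx_a;
  double C = ax_b * ax_a * ax_a + bx_b * bx_a * bx_a - rhs * rhs;
  double disc = B * B - A * C;
  if (disc < 0.0) return INF;
  double t = (B + std::sqrt(disc)) / A;
  if (t < t1x || t < t1y) return INF;
  return t;
}

// causal update from one stencil. Second-order differences enter only through
// the full two-axis quadratic; one-sided (single-axis) updates stay first
// order — a lone second-order extrapolation along an axis that is nearly
// tangent to the front underestimates the arrival time.
double solve_stencil(const Axis& x, const Axis& y, double rhs) {
  if (x.have && y.have) {
    double t = solve_pair(x.have2 ? x.a2 : x.t1, x.have2 ? 2.25 : 1.0,
                          y.have2 ? y.a2 : y.t1, y.have2 ? 2.25 : 1.0,
                          x.t1, y.t1, rhs);
    if (std::isfinite(t)) return t;
    t = solve_pair(x.t1, 1.0, y.t1, 1.0, x.t1, y.t1, rhs);
    if (std::isfinite(t)) return t;
  }
  double best = INF;
  if (x.have) best = std::min(best, x.t1 + rhs);
  if (y.have) best = std::min(best, y.t1 + rhs);
  return best;
}

double update_node(const double* T, const int* state, int m, int n,
                   int r, int c, double f, double h, int order) {
  // stencil 1: grid axes
  Axis x1 = probe_axis(T, state, m, n, r, c, 0, 1, order);
  Axis y1 = probe_axis(T, state, m, n, r, c, 1, 0, order);
  double t = solve_stencil(x1, y1, h * f);
  // stencil 2: diagonals, spacing h*sqrt(2)
  Axis x2 = probe_axis(T, state, m, n, r, c, 1, 1, order);
  Axis y2 = probe_axis(T, state, m, n, r, c, -1, 1, order);
  double t2 = solve_stencil(x2, y2, h * std::sqrt(2.0) * f);
  return std::min(t, t2);
}

} // namespace

// [[Rcpp::export(name = ".fm_solve_cpp")]]
NumericMatrix fm_solve_cpp(NumericMatrix slowness, double h,
                           IntegerVector seed_r, IntegerVector seed_c,
                           NumericVector seed_t, int order) {
  const int m = slowness.nrow(), n = slowness.ncol();
  if (order != 1 && order != 2) stop("order must be 1 or 2");
  for (int k = 0; k < m * n; ++k)
    if (!(slowness[k] > 0.0)) stop("non-positive or non-finite slowness value");

  NumericMatrix T(m, n);
  std::fill(T.begin(), T.end(), INF);
  std::vector<int> state(m * n, FAR);
  std::vector<char> frozen(m * n, 0);   // seed values are exact: never updated
  std::priority_queue<Node, std::vector<Node>, NodeCmp> heap;

  for (int s = 0; s < seed_r.size(); ++s) {
    int r = seed_r[s] - 1, c = seed_c[s] - 1;
    if (r < 0 || r >= m || c < 0 || c >= n) stop("seed outside grid");
    int k = idx(r, c, m);
    if (seed_t[s] < T[k]) {
      T[k] = seed_t[s];
      state[k] = TRIAL;
      frozen[k] = 1;
      heap.push({seed_t[s], r, c});
    }
  }
  if (heap.empty()) stop("no seed nodes supplied");

  const int drs[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dcs[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  while (!heap.empty()) {
    Node nd = heap.top(); heap.pop();
    int k = idx(nd.r, nd.c, m);
    if (state[k] == ACCEPTED) continue;   // stale heap entry
    state[k] = ACCEPTED;
    for (int q = 0; q < 8; ++q) {
      int rr = nd.r + drs[q], cc = nd.c + dcs[q];
      if (rr < 0 || rr >= m || cc < 0 || cc >= n) continue;
      int kk = idx(rr, cc, m);
      if (state[kk] == ACCEPTED || frozen[kk]) continue;
      double t = update_node(&T[0], state.data(), m, n, rr, cc,
                             slowness(rr, cc), h, order);
      if (t < T[kk]) {
        T[kk] = t;
        state[kk] = TRIAL;
        heap.push({t, rr, cc});
      }
    }
  }
  return T;
}
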