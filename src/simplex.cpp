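// Dense two-phase bounded-variable primal simplex.
//
// Solves  min c'x  s.t.  A x = b,  l <= x <= u  (all bounds finite).
// Sized for FBA problems of a few hundred reactions: the basis inverse is
// kept as a dense matrix and updated by elementary row operations.
// Dantzig pricing with a Bland's-rule fallback guards against cycling.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double TOL_PIVOT = 1e-9;   // minimum acceptable pivot magnitude
static const double TOL_DJ    = 1e-9;   // reduced-cost optimality tolerance
static const double TOL_FEAS  = 1e-7;   // phase-1 feasibility tolerance
static const double BIG       = 1e30;

namespace {

struct Simplex {
  int m, n, ntot;              // rows, structural cols, cols incl. artificials
  std::vector<double> A;       // m x ntot, column-major
  std::vector<double> b;
  std::vector<double> lo, up;  // bounds for all ntot columns
  std::vector<double> cost;    // current phase costs
  std::vector<double> Binv;    // m x m, column-major
  std::vector<int> basis;      // basis[i] = column basic in row i
  std::vector<int> state;      // nonbasic at lower (0), upper (1), basic (2)
  std::vector<double> xB;      // values of basic variables by row
  std::vector<double> xN;      // current value of every column (kept in sync)

  double colA(int i, int j) const { return A[(size_t)j * m + i]; }

  // w = Binv * A_j
  void ftran(int j, std::vector<double>& w) const {
    for (int i = 0; i < m; ++i) w[i] = 0.0;
    for (int i = 0; i < m; ++i) {
      double aij = colA(i, j);
      if (aij == 0.0) continue;
      const double* bcol = &Binv[(size_t)i * m];
      for (int r = 0; r < m; ++r) w[r] += bcol[r] * aij;
    }
  }

  // y = c_B' * Binv
  void btran(std::vector<double>& y) const {
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      const double* bcol = &Binv[(size_t)i * m];
      for (int r = 0; r < m; ++r) s += cost[basis[r]] * bcol[r];
      y[i] = s;
    }
  }

  double reduced_cost(int j, const std::vector<double>& y) const {
    double d = cost[j];
    for (int i = 0; i < m; ++i) {
      double aij = colA(i, j);
      if (aij != 0.0) d -= y[i] * aij;
    }
    return d;
  }

  // One simplex phase. Returns 0 optimal, 1 unbounded, 2 iteration limit.
  int iterate(long maxit) {
    std::vector<double> y(m), w(m);
    long it = 0, bland_after = 20L * (m + ntot) + 200L;
    while (it++ < maxit) {
      bool bland = it > bland_after;
      btran(y);
      int enter = -1, dir = 0;  // dir +1: increase from lower, -1: decrease from upper
      double best = -TOL_DJ;
      for (int j = 0; j < ntot; ++j) {
        if (state[j] == 2) continue;
        if (up[j] - lo[j] < TOL_PIVOT) continue;  // fixed column cannot move
        double d = reduced_cost(j, y);
        if (state[j] == 0 && d < -TOL_DJ) {
          if (bland) { enter = j; dir = 1; break; }
          if (d < best) { best = d; enter = j; dir = 1; }
        } else if (state[j] == 1 && d > TOL_DJ) {
          if (bland) { enter = j; dir = -1; break; }
          if (-d < best) { best = -d; enter = j; dir = -1; }
        }
      }
      if (enter < 0) return 0;  // optimal

      ftran(enter, w);
      // x_enter moves by dir * t, t >= 0; basic row i moves by -dir * w[i] * t
      double tmax = up[enter] - lo[enter];
      int leave = -1, leave_to = 0;
      for (int i = 0; i < m; ++i) {
        double d = dir * w[i];
        double t;
        int to;
        if (d > TOL_PIVOT) { t = (xB[i] - lo[basis[i]]) / d; to = 0; }
        else if (d < -TOL_PIVOT) { t = (up[basis[i]] - xB[i]) / (-d); to = 1; }
        else continue;
        if (t < -1e-12) t = 0.0;
        if (t < tmax - 1e-12 || (bland && leave >= 0 && t <= tmax + 1e-12 &&
                                 basis[i] < basis[leave])) {
          if (t < tmax - 1e-12) { tmax = t; leave = i; leave_to = to; }
          else if (bland && leave >= 0) { leave = i; leave_to = to; }
        }
      }
      if (tmax >= BIG) return 1;  // unbounded ray

      if (leave < 0) {
        // bound flip: entering variable jumps to its opposite bound
        for (int i = 0; i < m; ++i) xB[i] -= dir * w[i] * tmax;
        xN[enter] = (dir > 0) ? up[enter] : lo[enter];
        state[enter] = (dir > 0) ? 1 : 0;
        continue;
      }

      // pivot: entering replaces basis[leave]
      double piv = w[leave];
      if (std::fabs(piv) < TOL_PIVOT) return 2;  // numerical breakdown
      int out = basis[leave];
      for (int i = 0; i < m; ++i) xB[i] -= dir * w[i] * tmax;
      double x_enter = xN[enter] + dir * tmax;

      // row ops on Binv: row 'leave' /= piv; others -= w[i] * row(leave)
      for (int cidx = 0; cidx < m; ++cidx) {
        double* bcol = &Binv[(size_t)cidx * m];
        double pr = bcol[leave] / piv;
        bcol[leave] = pr;
        for (int i = 0; i < m; ++i) {
          if (i == leave) continue;
          bcol[i] -= w[i] * pr;
        }
      }
      basis[leave] = enter;
      state[enter] = 2;
      xB[leave] = x_enter;
      xN[out] = (leave_to == 0) ? lo[out] : up[out];
      state[out] = leave_to;
    }
    return 2;
  }

  void recompute_xB() {
    // xB = Binv * (b - sum over nonbasic A_j x_j)
    std::vector<double> r(b);
    for (int j = 0; j < ntot; ++j) {
      if (state[j] == 2 || xN[j] == 0.0) continue;
      for (int i = 0; i < m; ++i) r[i] -= colA(i, j) * xN[j];
    }
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      const double* brow = &Binv[0];
      (void)brow;
      for (int k = 0; k < m; ++k) s += Binv[(size_t)k * m + i] * r[k];
      xB[i] = s;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".simplex_solve")]]
List simplex_solve(NumericMatrix Amat, NumericVector bvec,
                   NumericVector lb, NumericVector ub,
                   NumericVector obj, bool maximize) {
  int m = Amat.nrow(), n = Amat.ncol();
  Simplex sx;
  sx.m = m; sx.n = n; sx.ntot = n + m;
  sx.A.assign((size_t)sx.ntot * m, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) sx.A[(size_t)j * m + i] = Amat(i, j);
  sx.b.assign(bvec.begin(), bvec.end());
  sx.lo.resize(sx.ntot); sx.up.resize(sx.ntot);
  std::vector<bool> inf_lo(n, false), inf_up(n, false);
  for (int j = 0; j < n; ++j) {
    double l = lb[j], u = ub[j];
    if (!R_finite(l)) { l = -1e8; inf_lo[j] = true; }
    if (!R_finite(u)) { u = 1e8; inf_up[j] = true; }
    if (l > u) stop("lower bound exceeds upper bound for column %d", j + 1);
    sx.lo[j] = l; sx.up[j] = u;
  }
  sx.state.assign(sx.ntot, 0);
  sx.xN.assign(sx.ntot, 0.0);
  for (int j = 0; j < n; ++j) {
    // start at the bound nearest zero
    double v = (std::fabs(sx.lo[j]) <= std::fabs(sx.up[j])) ? sx.lo[j] : sx.up[j];
    sx.state[j] = (v == sx.lo[j]) ? 0 : 1;
    sx.xN[j] = v;
  }
  // residual determines artificial column signs
  std::vector<double> r(m);
  for (int i = 0; i < m; ++i) r[i] = sx.b[i];
  for (int j = 0; j < n; ++j) {
    if (sx.xN[j] == 0.0) continue;
    for (int i = 0; i < m; ++i) r[i] -= sx.colA(i, j) * sx.xN[j];
  }
  sx.basis.resize(m); sx.xB.resize(m);
  sx.Binv.assign((size_t)m * m, 0.0);
  for (int i = 0; i < m; ++i) {
    int j = n + i;
    double s = (r[i] >= 0.0) ? 1.0 : -1.0;
    sx.A[(size_t)j * m + i] = s;
    sx.lo[j] = 0.0; sx.up[j] = BIG;
    sx.basis[i] = j;
    sx.state[j] = 2;
    sx.xB[i] = std::fabs(r[i]);
    sx.Binv[(size_t)i * m + i] = s;
  }

  long maxit = 50000;
  std::string status;
  double objval = NA_REAL;

  // phase 1: drive artificials to zero (skipped when the starting point
  // already satisfies the equalities, e.g. b = 0 with 0 inside all bounds)
  double p1 = 0.0;
  for (int i = 0; i < m; ++i) if (sx.basis[i] >= n) p1 += sx.xB[i];
  int rc = 0;
  if (p1 > TOL_FEAS) {
    sx.cost.assign(sx.ntot, 0.0);
    for (int i = 0; i < m; ++i) sx.cost[n + i] = 1.0;
    rc = sx.iterate(maxit);
    p1 = 0.0;
    for (int i = 0; i < m; ++i) if (sx.basis[i] >= n) p1 += sx.xB[i];
  }
  if (rc == 2) status = "maxiter";
  else if (p1 > TOL_FEAS) status = "infeasible";
  else {
    // phase 2
    for (int j = n; j < sx.ntot; ++j) sx.up[j] = 0.0;  // pin artificials
    for (int i = 0; i < m; ++i) {
      if (sx.basis[i] >= n && sx.xB[i] < 0.0) sx.xB[i] = 0.0;
    }
    sx.cost.assign(sx.ntot, 0.0);
    for (int j = 0; j < n; ++j) sx.cost[j] = maximize ? -obj[j] : obj[j];
    rc = sx.iterate(maxit);
    if (rc == 1) status = "unbounded";
    else if (rc == 2) status = "maxiter";
    else {
      status = "optimal";
      sx.recompute_xB();  // refresh accumulated roundoff before reporting
    }
  }

  NumericVector x(n);
  if (status == "optimal") {
    for (int j = 0; j < n; ++j) x[j] = sx.xN[j];
    for (int i = 0; i < m; ++i) if (sx.basis[i] < n) x[sx.basis[i]] = sx.xB[i];
    // a solution pinned to the clamp of an originally infinite bound means
    // the optimum lies on an unbounded ray
    for (int j = 0; j < n; ++j) {
      if ((inf_up[j] && x[j] > 1e8 - 1e-3) ||
          (inf_lo[j] && x[j] < -1e8 + 1e-3)) {
        status = "unbounded";
        break;
      }
    }
  }
  if (status == "optimal") {
    double z = 0.0;
    for (int j = 0; j < n; ++j) z += obj[j] * x[j];
    objval = z;
  } else {
    std::fill(x.begin(), x.end(), NA_REAL);
  }
  return List::create(_["status"] = status, _["objective"] = objval,
                      _["x"] = x);
}
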