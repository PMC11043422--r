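// Dense two-phase primal simplex.
//
// Solves  min c'x  s.t.  A x (dir) b,  x >= 0,
// with dir coded per row as -1 (<=), 0 (=), +1 (>=).
//
// Classic tableau method with Dantzig pricing, a Bland's-rule fallback after
// a run of degenerate pivots (anti-cycling), row equilibration and objective
// scaling for numerical stability.  Sized for the dense facility-location
// models this package builds (hundreds of rows/columns), not for sparse
// large-scale LPs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double TOL_RED = 1e-9;    // reduced-cost tolerance (on scaled data)
const double TOL_PIV = 1e-8;    // minimum pivot magnitude
const double TOL_ART = 1e-7;    // phase-1 residual => infeasible
const int    BLAND_AFTER = 400; // consecutive degenerate pivots

struct Tableau {
  int m, N;                 // rows, total columns (excluding rhs)
  std::vector<double> T;    // (m + 2) x (N + 1), row-major; row m: phase-2
                            // reduced costs, row m+1: phase-1 reduced costs
  std::vector<int> basis;   // basic column of each row
  inline double& at(int i, int j) { return T[(size_t)i * (N + 1) + j]; }
};

void pivot(Tableau& tb, int r, int jc) {
  const int ncol = tb.N + 1;
  double* prow = &tb.T[(size_t)r * ncol];
  const double piv = prow[jc];
  for (int j = 0; j < ncol; ++j) prow[j] /= piv;
  prow[jc] = 1.0;
  for (int i = 0; i < tb.m + 2; ++i) {
    if (i == r) continue;
    double* row = &tb.T[(size_t)i * ncol];
    const double f = row[jc];
    if (std::fabs(f) < 1e-13) { row[jc] = 0.0; continue; }
    for (int j = 0; j < ncol; ++j) row[j] -= f * prow[j];
    row[jc] = 0.0;
  }
  tb.basis[r] = jc;
}

// One simplex phase on cost row `crow`; columns with allowed[j] == 0 may not
// enter.  If ban_from >= 0, a basic variable with column >= ban_from that
// leaves the basis is barred from re-entering (used for artificials in
// phase 1).  Returns 0 optimal, 2 unbounded, 3 iteration limit.
int run_phase(Tableau& tb, int crow, std::vector<char>& allowed,
              int ban_from, int max_iter, int& iter) {
  int degen = 0;
  const int ncol = tb.N + 1;
  while (iter < max_iter) {
    double* cr = &tb.T[(size_t)crow * ncol];
    int jc = -1;
    const bool bland = degen >= BLAND_AFTER;
    if (!bland) {
      double best = -TOL_RED;
      for (int j = 0; j < tb.N; ++j)
        if (allowed[j] && cr[j] < best) { best = cr[j]; jc = j; }
    } else {
      for (int j = 0; j < tb.N; ++j)
        if (allowed[j] && cr[j] < -TOL_RED) { jc = j; break; }
    }
    if (jc < 0) return 0;
    // Harris-style two-pass ratio test: find the tightest ratio, then pivot
    // on the largest eligible element among near-ties -- small pivots are
    // what corrupt a long-running tableau.  Negative right-hand sides from
    // round-off are clamped to zero so a ratio is never negative.
    int r = -1;
    double theta = std::numeric_limits<double>::infinity();
    for (int i = 0; i < tb.m; ++i) {
      const double a = tb.at(i, jc);
      if (a > TOL_PIV) {
        double num = tb.at(i, tb.N);
        if (num < 0) num = 0;
        const double q = (num + 1e-9) / a;
        if (q < theta) theta = q;
      }
    }
    if (!std::isfinite(theta)) return 2;
    if (!bland) {
      double abest = 0.0;
      for (int i = 0; i < tb.m; ++i) {
        const double a = tb.at(i, jc);
        if (a > TOL_PIV) {
          double num = tb.at(i, tb.N);
          if (num < 0) num = 0;
          if (num / a <= theta && a > abest) { abest = a; r = i; }
        }
      }
    } else {
      // exact Bland leaving rule: minimum ratio, ties by smallest basis label
      double ratio = std::numeric_limits<double>::infinity();
      for (int i = 0; i < tb.m; ++i) {
        const double a = tb.at(i, jc);
        if (a > TOL_PIV) {
          double num = tb.at(i, tb.N);
          if (num < 0) num = 0;
          const double q = num / a;
          if (q < ratio - 1e-12 ||
              (q < ratio + 1e-12 && (r < 0 || tb.basis[i] < tb.basis[r]))) {
            ratio = q; r = i;
          }
        }
      }
    }
    if (r < 0) return 2;
    double step = tb.at(r, tb.N) / tb.at(r, jc);
    if (step < 0) step = 0;
    // Bland's rule stays engaged for the rest of the phase once triggered
    if (step < 1e-11) ++degen; else if (degen < BLAND_AFTER) degen = 0;
    const int leaving = tb.basis[r];
    pivot(tb, r, jc);
    if (ban_from >= 0 && leaving >= ban_from) allowed[leaving] = 0;
    ++iter;
  }
  return 3;
}

} // namespace

// [[Rcpp::export(name = ".simplex_core")]]
List simplex_core(NumericVector cvec, NumericMatrix Amat, IntegerVector dir,
                  NumericVector bvec, int max_iter) {
  const int m = Amat.nrow(), n = Amat.ncol();
  std::vector<double> b(bvec.begin(), bvec.end());
  std::vector<int> d(dir.begin(), dir.end());
  std::vector<double> A((size_t)m * n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) A[(size_t)i * n + j] = Amat(i, j);

  // rhs >= 0
  for (int i = 0; i < m; ++i) {
    if (b[i] < 0) {
      b[i] = -b[i];
      d[i] = -d[i];
      for (int j = 0; j < n; ++j) A[(size_t)i * n + j] = -A[(size_t)i * n + j];
    }
  }
  // row equilibration by the geometric mean of the extreme magnitudes, so
  // rows mixing unit and big-M coefficients keep both above the pivot
  // tolerance
  for (int i = 0; i < m; ++i) {
    double mx = 0.0, mn = std::numeric_limits<double>::infinity();
    for (int j = 0; j < n; ++j) {
      const double a = std::fabs(A[(size_t)i * n + j]);
      if (a > 1e-12) { mx = std::max(mx, a); mn = std::min(mn, a); }
    }
    if (mx > 1e-12) {
      const double s = std::sqrt(mx * mn);
      for (int j = 0; j < n; ++j) A[(size_t)i * n + j] /= s;
      b[i] /= s;
    }
  }
  // objective scaling
  double cmax = 0.0;
  for (int j = 0; j < n; ++j) cmax = std::max(cmax, std::fabs(cvec[j]));
  const double cscale = (cmax > 1e-12) ? cmax : 1.0;

  int n_slk = 0, n_art = 0;
  for (int i = 0; i < m; ++i) {
    if (d[i] != 0) ++n_slk;
    if (d[i] >= 0) ++n_art;
  }
  Tableau tb;
  tb.m = m;
  tb.N = n + n_slk + n_art;
  tb.T.assign((size_t)(m + 2) * (tb.N + 1), 0.0);
  tb.basis.assign(m, -1);

  int ks = n, ka = n + n_slk;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) tb.at(i, j) = A[(size_t)i * n + j];
    tb.at(i, tb.N) = b[i];
    if (d[i] == -1) {            // <= : slack, basic
      tb.at(i, ks) = 1.0; tb.basis[i] = ks++;
    } else if (d[i] == 1) {      // >= : surplus + artificial
      tb.at(i, ks++) = -1.0;
      tb.at(i, ka) = 1.0; tb.basis[i] = ka++;
    } else {                     // =  : artificial
      tb.at(i, ka) = 1.0; tb.basis[i] = ka++;
    }
  }
  // phase-2 cost row (scaled)
  for (int j = 0; j < n; ++j) tb.at(m, j) = cvec[j] / cscale;
  // phase-1 cost row: sum of artificials, priced out over artificial rows
  for (int i = 0; i < m; ++i) {
    if (tb.basis[i] >= n + n_slk) {
      for (int j = 0; j <= tb.N; ++j) tb.at(m + 1, j) -= tb.at(i, j);
      tb.at(m + 1, tb.basis[i]) = 0.0;
    }
  }

  std::vector<char> allowed(tb.N, 1);
  int iter = 0, status = 0;

  if (n_art > 0) {
    status = run_phase(tb, m + 1, allowed, n + n_slk, max_iter, iter);
    if (status == 2) status = 3;  // phase 1 cannot be unbounded; treat as limit
    const double p1 = -tb.at(m + 1, tb.N);
    if (status == 0 && p1 > TOL_ART) {
      return List::create(_["status"] = 1, _["x"] = NumericVector(n),
                          _["obj"] = NA_REAL, _["iter"] = iter);
    }
    if (status == 0) {
      // drive artificials out of the basis (or leave redundant rows inert)
      for (int i = 0; i < m; ++i) {
        if (tb.basis[i] >= n + n_slk) {
          int jc = -1;
          for (int j = 0; j < n + n_slk; ++j)
            if (std::fabs(tb.at(i, j)) > TOL_PIV) { jc = j; break; }
          if (jc >= 0) { pivot(tb, i, jc); ++iter; }
        }
      }
    }
    for (int j = n + n_slk; j < tb.N; ++j) allowed[j] = 0;
  }
  if (status == 0) status = run_phase(tb, m, allowed, -1, max_iter, iter);

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] < n) x[tb.basis[i]] = tb.at(i, tb.N);
  const double obj = -tb.at(m, tb.N) * cscale;
  // status: 0 optimal, 2 unbounded, 3 iteration limit
  return List::create(_["status"] = status, _["x"] = x, _["obj"] = obj,
                      _["iter"] = iter);
}
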