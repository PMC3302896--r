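// Depth-first branch-and-bound for pure 0/1 linear programs with two-sided
// row bounds (maximization). Prunes on row activity intervals, propagates
// forced assignments to a fixpoint, bounds the objective by the sum of
// positive free coefficients. Deterministic: fixed variable order
// (decreasing |objective|), promising branch first, first-found optimum
// kept among exact ties.
#include <Rcpp.h>
#include <chrono>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Solver {
  int nv, m;
  std::vector<double> obj;
  // sparse rows and columns
  std::vector<std::vector<std::pair<int, double> > > rowvars; // row -> (var, coef)
  std::vector<std::vector<std::pair<int, double> > > colrows; // var -> (row, coef)
  std::vector<double> lo, hi;
  std::vector<double> actmin, actmax; // attainable activity interval
  std::vector<int> x;                 // -1 free, 0/1 fixed
  std::vector<int> order;             // branching order
  std::vector<char> capped;           // vars counting toward the cardinality cap
  int cap, ncap_active;               // cap and currently active capped vars
  double cur, possum;                 // current obj, positive free obj sum
  double best_obj;
  std::vector<int> best_x;
  bool have_best, timed_out;
  std::chrono::steady_clock::time_point deadline;
  bool use_deadline;
  long long nodes;
  static constexpr double eps = 1e-9;

  void fix(int v, int b, std::vector<int>& trail) {
    x[v] = b;
    trail.push_back(v);
    for (auto& rc : colrows[v]) {
      double a = rc.second;
      actmin[rc.first] += a * b - std::min(a, 0.0);
      actmax[rc.first] += a * b - std::max(a, 0.0);
    }
    cur += obj[v] * b;
    if (obj[v] > 0) possum -= obj[v];
    if (capped[v] && b == 1) ++ncap_active;
  }

  // upper bound: current objective plus the best still-selectable positive
  // coefficients, honouring the cardinality cap on capped variables
  double bound() {
    int room = cap - ncap_active;
    if (room <= 0) {
      double s = cur;
      for (int v = 0; v < nv; ++v)
        if (x[v] == -1 && !capped[v] && obj[v] > 0) s += obj[v];
      return s;
    }
    scratch.clear();
    double s = cur;
    for (int v = 0; v < nv; ++v) {
      if (x[v] != -1 || obj[v] <= 0) continue;
      if (capped[v]) scratch.push_back(obj[v]); else s += obj[v];
    }
    if ((int)scratch.size() > room) {
      std::nth_element(scratch.begin(), scratch.begin() + room, scratch.end(),
                       std::greater<double>());
      for (int k = 0; k < room; ++k) s += scratch[k];
    } else {
      for (double c : scratch) s += c;
    }
    return s;
  }
  std::vector<double> scratch;

  void undo(std::vector<int>& trail, size_t mark) {
    while (trail.size() > mark) {
      int v = trail.back();
      trail.pop_back();
      int b = x[v];
      x[v] = -1;
      for (auto& rc : colrows[v]) {
        double a = rc.second;
        actmin[rc.first] -= a * b - std::min(a, 0.0);
        actmax[rc.first] -= a * b - std::max(a, 0.0);
      }
      cur -= obj[v] * b;
      if (obj[v] > 0) possum += obj[v];
      if (capped[v] && b == 1) --ncap_active;
    }
  }

  bool row_feasible(int r) const {
    return actmin[r] <= hi[r] + eps && actmax[r] >= lo[r] - eps;
  }

  // propagate: returns false on conflict; fixed vars appended to trail
  bool propagate(std::vector<int>& trail) {
    bool changed = true;
    while (changed) {
      changed = false;
      for (int r = 0; r < m; ++r) {
        if (!row_feasible(r)) return false;
        for (auto& vc : rowvars[r]) {
          int u = vc.first;
          if (x[u] != -1) continue;
          double a = vc.second;
          double amin = std::min(a, 0.0), amax = std::max(a, 0.0);
          bool can1 = actmin[r] + a - amin <= hi[r] + eps &&
                      actmax[r] + a - amax >= lo[r] - eps;
          bool can0 = actmin[r] - amin <= hi[r] + eps &&
                      actmax[r] - amax >= lo[r] - eps;
          if (!can1 && !can0) return false;
          if (can1 != can0) {
            fix(u, can1 ? 1 : 0, trail);
            changed = true;
            for (auto& rc : colrows[u]) {
              if (!row_feasible(rc.first)) return false;
            }
          }
        }
      }
    }
    return true;
  }

  void search() {
    if (timed_out) return;
    if (((++nodes) & 1023) == 0 && use_deadline &&
        std::chrono::steady_clock::now() > deadline) {
      timed_out = true;
      return;
    }
    for (int r = 0; r < m; ++r) if (!row_feasible(r)) return;
    if (have_best && bound() <= best_obj + eps) return;

    std::vector<int> trail;
    if (!propagate(trail)) { undo(trail, 0); return; }
    if (have_best && bound() <= best_obj + eps) { undo(trail, 0); return; }

    int v = -1;
    for (int k = 0; k < nv; ++k) {
      if (x[order[k]] == -1) { v = order[k]; break; }
    }
    if (v == -1) {
      if (!have_best || cur > best_obj + eps) {
        best_obj = cur;
        best_x.assign(x.begin(), x.end());
        have_best = true;
      }
      undo(trail, 0);
      return;
    }
    int first = obj[v] >= 0 ? 1 : 0;
    for (int pass = 0; pass < 2 && !timed_out; ++pass) {
      int b = pass == 0 ? first : 1 - first;
      size_t mark = trail.size();
      fix(v, b, trail);
      search();
      undo(trail, mark);
    }
    undo(trail, 0);
  }
};

} // namespace

// [[Rcpp::export(name = ".bnb_solve")]]
List bnb_solve(NumericVector obj, List rows, double time_limit,
               int cap, LogicalVector cap_mask) {
  Solver s;
  s.nv = obj.size();
  s.m = rows.size();
  s.obj.assign(obj.begin(), obj.end());
  s.rowvars.resize(s.m);
  s.colrows.resize(s.nv);
  s.lo.resize(s.m);
  s.hi.resize(s.m);
  s.actmin.assign(s.m, 0.0);
  s.actmax.assign(s.m, 0.0);
  for (int r = 0; r < s.m; ++r) {
    List row = rows[r];
    IntegerVector idx = row["idx"];
    NumericVector coef = row["coef"];
    s.lo[r] = as<double>(row["lo"]);
    s.hi[r] = as<double>(row["hi"]);
    for (int k = 0; k < idx.size(); ++k) {
      int v = idx[k] - 1; // 1-based from R
      double a = coef[k];
      if (a == 0.0) continue;
      s.rowvars[r].push_back(std::make_pair(v, a));
      s.colrows[v].push_back(std::make_pair(r, a));
      s.actmin[r] += std::min(a, 0.0);
      s.actmax[r] += std::max(a, 0.0);
    }
  }
  s.x.assign(s.nv, -1);
  s.capped.assign(s.nv, 0);
  if (cap_mask.size() == s.nv) {
    for (int v = 0; v < s.nv; ++v) s.capped[v] = cap_mask[v] ? 1 : 0;
  }
  s.cap = cap >= 0 ? cap : s.nv;
  s.ncap_active = 0;
  s.order.resize(s.nv);
  for (int v = 0; v < s.nv; ++v) s.order[v] = v;
  std::stable_sort(s.order.begin(), s.order.end(), [&](int a, int b) {
    return std::fabs(s.obj[a]) > std::fabs(s.obj[b]);
  });
  s.cur = 0.0;
  s.possum = 0.0;
  for (int v = 0; v < s.nv; ++v) s.possum += std::max(0.0, s.obj[v]);
  s.best_obj = -std::numeric_limits<double>::infinity();
  s.have_best = false;
  s.timed_out = false;
  s.nodes = 0;
  s.use_deadline = std::isfinite(time_limit);
  if (s.use_deadline) {
    s.deadline = std::chrono::steady_clock::now() +
      std::chrono::milliseconds((long long)(time_limit * 1000.0));
  }
  s.search();

  std::string status;
  if (s.timed_out) status = "timeout";
  else if (!s.have_best) status = "infeasible";
  else status = "optimal";
  if (s.have_best) {
    IntegerVector xr(s.nv);
    for (int v = 0; v < s.nv; ++v) xr[v] = s.best_x[v];
    return List::create(_["status"] = status, _["x"] = xr,
                        _["objective"] = s.best_obj,
                        _["nodes"] = (double)s.nodes);
  }
  return List::create(_["status"] = status, _["x"] = R_NilValue,
                      _["objective"] = NA_REAL, _["nodes"] = (double)s.nodes);
}
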