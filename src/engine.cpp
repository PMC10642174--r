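// Core state-space search for the 4-level decisional-logic engine.
//
// Levels are 0..3. Each edge carries a perception threshold tau (1..3) and a
// positive weight w; the perceived input of a node is the signed weighted sum
// over in-edges whose source is at or above tau. A node's image moves one
// level toward the sign of that sum (ties: hold or decay). All searches here
// are exact depth-first enumerations with branch-and-bound on Manhattan
// departure, plus a node-expansion budget so callers can degrade gracefully
// on state spaces too large to enumerate.

#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

static inline int image1(int lvl, int s, int tie) {
  if (s > 0) return lvl < 3 ? lvl + 1 : 3;
  if (s < 0) return lvl > 0 ? lvl - 1 : 0;
  return tie == 0 ? lvl : (lvl > 0 ? lvl - 1 : 0);
}

// [[Rcpp::export]]
IntegerVector cpp_images(IntegerVector state,
                         IntegerVector esrc, IntegerVector etgt,
                         IntegerVector esign, IntegerVector tau,
                         IntegerVector w, int tie, IntegerVector clampv) {
  int n = state.size(), m = esrc.size();
  std::vector<int> s(n, 0);
  for (int e = 0; e < m; ++e)
    if (state[esrc[e]] >= tau[e]) s[etgt[e]] += esign[e] * w[e];
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = clampv[i] >= 0 ? clampv[i] : image1(state[i], s[i], tie);
  return out;
}

// Search over either predecessor space (mode 0: variables are the previous
// state y, the achieved state is x = step(y)) or fixed-point space (mode 1:
// variables are the state x itself, constrained to satisfy step(x) = x).
struct Search {
  int n, m, tie, mode;
  std::vector<int> src, tgt, sgn, tau, w, clampv, obs, ord, posOf;
  std::vector<std::vector<int>> inedges, checklist;
  std::vector<int> assign, ximg;

  long long budget, expanded;
  bool truncated, stopAll, early0, collecting, collectY;
  int best, collectCap;
  bool overflow;
  std::vector<std::vector<int>> optima;

  bool presenceMode, found;
  int presNode, presLevel, presTarget;

  void init(const IntegerVector& esrc, const IntegerVector& etgt,
            const IntegerVector& esign, const IntegerVector& tau_,
            const IntegerVector& w_, int tie_, const IntegerVector& clampv_,
            const IntegerVector& ord_, int mode_) {
    m = esrc.size();
    n = clampv_.size();
    tie = tie_; mode = mode_;
    src.assign(esrc.begin(), esrc.end());
    tgt.assign(etgt.begin(), etgt.end());
    sgn.assign(esign.begin(), esign.end());
    tau.assign(tau_.begin(), tau_.end());
    w.assign(w_.begin(), w_.end());
    clampv.assign(clampv_.begin(), clampv_.end());
    ord.assign(ord_.begin(), ord_.end());
    inedges.assign(n, {});
    for (int e = 0; e < m; ++e) inedges[tgt[e]].push_back(e);
    posOf.assign(n, 0);
    for (int p = 0; p < n; ++p) posOf[ord[p]] = p;
    checklist.assign(n, {});
    for (int i = 0; i < n; ++i) {
      int cp = posOf[i];
      for (int e : inedges[i]) cp = std::max(cp, posOf[src[e]]);
      checklist[cp].push_back(i);
    }
    assign.assign(n, 0);
    ximg.assign(n, 0);
  }

  void reset(const std::vector<int>& obs_, long long budget_, int bound,
             bool early0_, bool collecting_, int cap, bool collectY_) {
    obs = obs_;
    budget = budget_; expanded = 0;
    truncated = false; stopAll = false;
    early0 = early0_; collecting = collecting_;
    collectCap = cap; collectY = collectY_;
    best = bound; overflow = false;
    optima.clear();
    presenceMode = false; found = false;
    presNode = -1; presLevel = -1; presTarget = 0;
  }

  void store() {
    if (!collecting) return;
    if ((int)optima.size() >= collectCap) { overflow = true; return; }
    optima.push_back(collectY ? assign : (mode == 0 ? ximg : assign));
  }

  void leaf(int dev) {
    if (presenceMode) {
      if (dev == presTarget) { found = true; stopAll = true; }
      return;
    }
    if (dev < best) {
      best = dev;
      optima.clear(); overflow = false;
      store();
      if (early0 && dev == 0) stopAll = true;
    } else if (dev == best) {
      store();
    }
  }

  void dfs(int p, int dev) {
    if (stopAll) return;
    if (p == n) { leaf(dev); return; }
    int v = ord[p];
    int lo = 0, hi = 3;
    if (clampv[v] >= 0) lo = hi = clampv[v];
    if (mode == 1 && presNode == v) {
      if (presLevel < lo || presLevel > hi) return;
      lo = hi = presLevel;
    }
    for (int val = lo; val <= hi; ++val) {
      if (stopAll) return;
      if (++expanded > budget) { truncated = true; stopAll = true; return; }
      assign[v] = val;
      int d2 = dev;
      if (mode == 1 && obs[v] >= 0) {
        d2 += std::abs(val - obs[v]);
        if (d2 > best) continue;
      }
      bool ok = true;
      for (int i : checklist[p]) {
        if (mode == 1 && clampv[i] >= 0) continue;  // held externally
        int s = 0;
        for (int e : inedges[i])
          if (assign[src[e]] >= tau[e]) s += sgn[e] * w[e];
        if (mode == 0) {
          int xi = clampv[i] >= 0 ? clampv[i] : image1(assign[i], s, tie);
          ximg[i] = xi;
          if (presNode == i && xi != presLevel) { ok = false; break; }
          if (obs[i] >= 0) {
            d2 += std::abs(xi - obs[i]);
            if (d2 > best) { ok = false; break; }
          }
        } else {
          if (image1(assign[i], s, tie) != assign[i]) { ok = false; break; }
        }
      }
      if (ok) dfs(p + 1, d2);
    }
  }

  // existence of an optimum (departure == target) placing node at level
  bool presence(const std::vector<int>& obs_, int target, int node, int level,
                long long budget_) {
    obs = obs_;
    budget = budget_; expanded = 0;
    truncated = false; stopAll = false;
    early0 = false; collecting = false;
    best = target; overflow = false;
    optima.clear();
    presenceMode = true; found = false;
    presNode = node; presLevel = level; presTarget = target;
    dfs(0, 0);
    return found;
  }
};

static std::vector<int> as_vec(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

// Impute a full state consistent with the dynamics (mode 0: has a
// predecessor; mode 1: is a fixed point) minimizing Manhattan departure from
// the observed levels (obs, -1 = unobserved). Optionally reports, for every
// node and level, whether some departure-optimal consistent state places the
// node at that level.
// [[Rcpp::export]]
List cpp_impute(IntegerVector obs,
                IntegerVector esrc, IntegerVector etgt, IntegerVector esign,
                IntegerVector tau, IntegerVector w, int tie,
                IntegerVector clampv, IntegerVector ord, int mode,
                double budget, int collect_cap, bool want_presence,
                bool collect_y) {
  Search S;
  S.init(esrc, etgt, esign, tau, w, tie, clampv, ord, mode);
  int n = S.n;
  int maxdev = 0;
  for (int i = 0; i < n; ++i) if (obs[i] >= 0) maxdev += 3;
  S.reset(as_vec(obs), (long long)budget, maxdev, false, true, collect_cap,
          collect_y);
  S.dfs(0, 0);
  bool feasible = !S.optima.empty() || S.best <= maxdev;
  // no leaf reached at all (possible in mode 1 when no fixed point exists
  // within budget): optima empty and best still at the initial bound with no
  // stored state
  bool any = !S.optima.empty();
  int best = S.best;
  IntegerMatrix opt(any ? (int)S.optima.size() : 0, n);
  for (int k = 0; k < (int)S.optima.size(); ++k)
    for (int i = 0; i < n; ++i) opt(k, i) = S.optima[k][i];
  bool truncated = S.truncated;
  LogicalMatrix pres(0, 0);
  if (want_presence && any) {
    LogicalMatrix pm(4, n);
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < 4; ++l) {
        bool f = S.presence(as_vec(obs), best, i, l, (long long)budget);
        pm(l, i) = f;
        if (S.truncated) truncated = true;
      }
    pres = pm;
  }
  (void)feasible;
  return List::create(_["best_dev"] = any ? best : NA_INTEGER,
                      _["feasible"] = any,
                      _["optima"] = opt,
                      _["overflow"] = S.overflow,
                      _["truncated"] = truncated,
                      _["presence"] = pres);
}

// Minimum departure only (early exit at zero). Returns NA when infeasible
// (mode 1 with no fixed point reachable within budget).
// [[Rcpp::export]]
List cpp_min_dep(IntegerVector obs,
                 IntegerVector esrc, IntegerVector etgt, IntegerVector esign,
                 IntegerVector tau, IntegerVector w, int tie,
                 IntegerVector clampv, IntegerVector ord, int mode,
                 double budget) {
  Search S;
  S.init(esrc, etgt, esign, tau, w, tie, clampv, ord, mode);
  int n = S.n, maxdev = 0;
  for (int i = 0; i < n; ++i) if (obs[i] >= 0) maxdev += 3;
  S.reset(as_vec(obs), (long long)budget, maxdev, true, true, 1, false);
  S.dfs(0, 0);
  bool any = !S.optima.empty();
  return List::create(_["dev"] = any ? S.best : NA_INTEGER,
                      _["exact"] = !S.truncated);
}

// All predecessors y with step(y) == x (exact enumeration up to cap).
// [[Rcpp::export]]
List cpp_predecessors(IntegerVector x,
                      IntegerVector esrc, IntegerVector etgt,
                      IntegerVector esign, IntegerVector tau, IntegerVector w,
                      int tie, IntegerVector clampv, IntegerVector ord,
                      double budget, int cap) {
  Search S;
  S.init(esrc, etgt, esign, tau, w, tie, clampv, ord, 0);
  int n = S.n;
  S.reset(as_vec(x), (long long)budget, 0, false, true, cap, true);
  S.dfs(0, 0);
  int k = (int)S.optima.size();
  IntegerMatrix out(k, n);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < n; ++i) out(j, i) = S.optima[j][i];
  return List::create(_["preds"] = out, _["overflow"] = S.overflow,
                      _["truncated"] = S.truncated);
}

// Exhaustive sweep of the logic-program grid. Per edge, candidate
// (tau, w) pairs are the cross product of tau_dom[[e]] and w_dom[[e]].
// For each program the aggregate minimum departure over subjects is computed
// under the given consistency mode; programs with aggregate departure
// <= max_departure are counted as feasible.
// [[Rcpp::export]]
List cpp_fit_grid(IntegerMatrix obsmat,
                  IntegerVector esrc, IntegerVector etgt, IntegerVector esign,
                  int tie, IntegerVector clampv, IntegerVector ord,
                  List tau_dom, List w_dom, int mode,
                  double max_departure, bool early_stop,
                  int keep_cap, double budget, bool paired) {
  int m = esrc.size(), S_n = obsmat.nrow();
  std::vector<std::vector<std::pair<int,int>>> combos(m);
  for (int e = 0; e < m; ++e) {
    IntegerVector td = tau_dom[e], wd = w_dom[e];
    if (paired) {
      // td and wd are parallel lists of surviving (tau, w) pairs
      for (int a = 0; a < td.size(); ++a) combos[e].push_back({td[a], wd[a]});
    } else {
      for (int a = 0; a < td.size(); ++a)
        for (int b = 0; b < wd.size(); ++b)
          combos[e].push_back({td[a], wd[b]});
    }
  }
  std::vector<int> digit(m, 0);
  IntegerVector tau(m), w(m);
  Search S;
  std::vector<std::vector<int>> obsrows(S_n);
  for (int s = 0; s < S_n; ++s) {
    obsrows[s].resize(obsmat.ncol());
    for (int i = 0; i < obsmat.ncol(); ++i) obsrows[s][i] = obsmat(s, i);
  }
  int n_obs_tot = 0;
  for (int s = 0; s < S_n; ++s)
    for (size_t i = 0; i < obsrows[s].size(); ++i)
      if (obsrows[s][i] >= 0) n_obs_tot += 3;

  double bestAgg = R_PosInf;
  std::vector<std::vector<int>> bestProgs, feasProgs;
  bool bestOverflow = false, feasOverflow = false, anyTrunc = false;
  double feasCount = 0, evaluated = 0;
  double maxdep = max_departure < 0 ? R_PosInf : max_departure;

  bool done = false;
  while (!done) {
    for (int e = 0; e < m; ++e) {
      tau[e] = combos[e][digit[e]].first;
      w[e] = combos[e][digit[e]].second;
    }
    S.init(esrc, etgt, esign, tau, w, tie, clampv, ord, mode);
    double agg = 0;
    bool feas = true;
    for (int s = 0; s < S_n && feas; ++s) {
      int md = 0;
      for (size_t i = 0; i < obsrows[s].size(); ++i)
        if (obsrows[s][i] >= 0) md += 3;
      S.reset(obsrows[s], (long long)budget, md, true, true, 1, false);
      S.dfs(0, 0);
      if (S.truncated) anyTrunc = true;
      if (S.optima.empty()) { feas = false; agg = R_PosInf; }
      else agg += S.best;
    }
    evaluated += 1;
    std::vector<int> prog(2 * m);
    for (int e = 0; e < m; ++e) { prog[e] = tau[e]; prog[m + e] = w[e]; }
    if (feas && agg < bestAgg) {
      bestAgg = agg;
      bestProgs.clear(); bestOverflow = false;
      bestProgs.push_back(prog);
    } else if (feas && agg == bestAgg) {
      if ((int)bestProgs.size() < keep_cap) bestProgs.push_back(prog);
      else bestOverflow = true;
    }
    if (feas && agg <= maxdep) {
      feasCount += 1;
      if ((int)feasProgs.size() < keep_cap) feasProgs.push_back(prog);
      else feasOverflow = true;
      if (early_stop) break;
    }
    // odometer
    int e = 0;
    while (e < m) {
      if (++digit[e] < (int)combos[e].size()) break;
      digit[e] = 0; ++e;
    }
    if (e == m) done = true;
    if (m == 0) done = true;
  }
  (void)n_obs_tot;
  IntegerMatrix bp((int)bestProgs.size(), 2 * m), fp((int)feasProgs.size(), 2 * m);
  for (int k = 0; k < (int)bestProgs.size(); ++k)
    for (int j = 0; j < 2 * m; ++j) bp(k, j) = bestProgs[k][j];
  for (int k = 0; k < (int)feasProgs.size(); ++k)
    for (int j = 0; j < 2 * m; ++j) fp(k, j) = feasProgs[k][j];
  return List::create(_["best_dev"] = bestAgg,
                      _["best_programs"] = bp,
                      _["best_overflow"] = bestOverflow,
                      _["feasible_count"] = feasCount,
                      _["feasible_programs"] = fp,
                      _["feasible_overflow"] = feasOverflow,
                      _["evaluated"] = evaluated,
                      _["truncated"] = anyTrunc);
}
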