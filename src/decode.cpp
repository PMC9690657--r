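#include <Rcpp.h>
#include <vector>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// Nussinov-style maximum expected gain dynamic programming.
//
// S is an n x n matrix of per-pair gains ((gamma+1) p_ij - 1, possibly
// loss-augmented); entries set to -Inf mark pairs that may never form
// (e.g. below a candidate threshold).  A pair (i, j) additionally
// requires j - i >= min_sep.  Recursion (0-based spans):
//   M(i,j) = max( M(i+1,j), M(i,j-1), M(i+1,j-1) + S(i,j),
//                 max_{i<c<j} M(i,c) + M(c+1,j) )
// Tie-break order is fixed (unpaired-left, unpaired-right, pair,
// bifurcation with smallest split first) with strict improvement, so
// co-optimal solutions resolve deterministically toward fewer pairs and a
// pair with non-positive gain is never included.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct NussDP {
  int n;
  std::vector<double> M;   // n*n, row-major, valid for i <= j
  std::vector<int> choice; // 0 empty, 1 left, 2 right, 3 pair, 4+c split at c

  double get(int i, int j) const { return (i > j) ? 0.0 : M[(size_t)i * n + j]; }

  void run(const std::vector<double>& S, int min_sep) {
    M.assign((size_t)n * n, 0.0);
    choice.assign((size_t)n * n, 0);
    for (int len = 1; len < n; ++len) {
      for (int i = 0; i + len < n; ++i) {
        int j = i + len;
        double best = get(i + 1, j);
        int ch = 1;
        double v = get(i, j - 1);
        if (v > best) { best = v; ch = 2; }
        double s = S[(size_t)i * n + j];
        if (len >= min_sep && s > NEG_INF) {
          v = get(i + 1, j - 1) + s;
          if (v > best) { best = v; ch = 3; }
        }
        for (int c = i + 1; c < j; ++c) {
          v = get(i, c) + get(c + 1, j);
          if (v > best) { best = v; ch = 4 + c; }
        }
        M[(size_t)i * n + j] = best;
        choice[(size_t)i * n + j] = ch;
      }
    }
  }

  void traceback(std::vector<std::pair<int, int> >& out) const {
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
      int i = stack.back().first, j = stack.back().second;
      stack.pop_back();
      if (i >= j) continue;
      int ch = choice[(size_t)i * n + j];
      if (ch == 1) stack.push_back(std::make_pair(i + 1, j));
      else if (ch == 2) stack.push_back(std::make_pair(i, j - 1));
      else if (ch == 3) {
        out.push_back(std::make_pair(i, j));
        stack.push_back(std::make_pair(i + 1, j - 1));
      } else if (ch >= 4) {
        int c = ch - 4;
        stack.push_back(std::make_pair(i, c));
        stack.push_back(std::make_pair(c + 1, j));
      }
    }
  }
};

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(NumericMatrix S, int min_sep) {
  int n = S.nrow();
  if (S.ncol() != n) stop("score matrix must be square");
  if (n == 0) stop("empty score matrix");
  std::vector<double> s((size_t)n * n, NEG_INF);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = S(i, j);
      s[(size_t)i * n + j] = ISNAN(v) ? NEG_INF : v;
    }
  NussDP dp; dp.n = n;
  dp.run(s, min_sep);
  std::vector<std::pair<int, int> > pr;
  dp.traceback(pr);
  int np = (int)pr.size();
  IntegerMatrix pairs(np, 2);
  for (int a = 0; a < np; ++a) { pairs(a, 0) = pr[a].first + 1; pairs(a, 1) = pr[a].second + 1; }
  colnames(pairs) = CharacterVector::create("i", "j");
  return List::create(_["score"] = dp.get(0, n - 1), _["pairs"] = pairs);
}

// [[Rcpp::export(name = ".nussinov_table_cpp")]]
NumericMatrix nussinov_table_cpp(NumericMatrix S, int min_sep) {
  int n = S.nrow();
  std::vector<double> s((size_t)n * n, NEG_INF);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = S(i, j);
      s[(size_t)i * n + j] = ISNAN(v) ? NEG_INF : v;
    }
  NussDP dp; dp.n = n;
  dp.run(s, min_sep);
  NumericMatrix M(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) M(i, j) = dp.get(i, j);
  return M;
}

// ---------------------------------------------------------------------------
// Exact branch-and-bound solver for the hierarchical pseudoknot IP:
//   maximize sum_p sum_{i<j} s^(p)_ij y^(p)_ij
//   s.t. one partner per base across all levels, no crossing within a
//   level, and every level-p pair crossed by >= 1 selected pair at every
//   level q < p.
//
// Levels 1..m-1 are explored by depth-first include/exclude branching in
// level-major order, so when level p is being branched all lower levels
// are final and the lower-level-crossing condition is a plain feasibility
// check.  Once levels 1..m-1 are fixed, the last level is a pure
// non-crossing matching over its still-allowed candidates and is solved
// exactly by the DP above.  The upper bound at a node is the current
// score plus, for every level, the DP optimum over that level's remaining
// allowed candidates (a relaxation that ignores base sharing across
// levels and the crossing requirement for levels not yet reached).
// ---------------------------------------------------------------------------

struct Cand { int i, j; double s; };

static inline bool cross_pairs(int i, int j, int k, int l) {
  return (i < k && k < j && j < l) || (k < i && i < l && l < j);
}

struct BB {
  int n, m, min_sep;
  std::vector<std::vector<Cand> > cands;        // per level, sorted by score desc
  std::vector<char> baseUsed;                   // 1..n
  std::vector<std::vector<int> > selected;      // candidate indices per level
  double curScore;
  double bestVal;
  std::vector<std::vector<std::pair<int, int> > > bestSel; // pairs per level
  long long nodes, nodeLimit;
  bool limitHit;
  NussDP dp;
  std::vector<double> sbuf;

  bool crossesAllLower(int p, int ci, int cj) const {
    for (int q = 0; q < p; ++q) {
      bool ok = false;
      for (size_t a = 0; a < selected[q].size(); ++a) {
        const Cand& c = cands[q][selected[q][a]];
        if (cross_pairs(c.i, c.j, ci, cj)) { ok = true; break; }
      }
      if (!ok) return false;
    }
    return true;
  }

  // Relaxed version for upper bounds while level `bp` is still being
  // branched at position `bt`: a lower level q counts as supporting
  // (ci, cj) if a selected pair crosses it, or -- when q is not yet
  // final -- some still-available candidate crosses it.  Any truly
  // feasible completion satisfies this, so it is a valid relaxation.
  bool crossesAllLowerRelaxed(int p, int ci, int cj, int bp, int bt) const {
    for (int q = 0; q < p; ++q) {
      bool ok = false;
      for (size_t a = 0; a < selected[q].size() && !ok; ++a) {
        const Cand& c = cands[q][selected[q][a]];
        if (cross_pairs(c.i, c.j, ci, cj)) ok = true;
      }
      if (!ok && q >= bp) {
        size_t from = (q == bp) ? (size_t)bt : 0;
        for (size_t a = from; a < cands[q].size() && !ok; ++a) {
          const Cand& c = cands[q][a];
          if (baseUsed[c.i] || baseUsed[c.j]) continue;
          if (cross_pairs(c.i, c.j, ci, cj)) ok = true;
        }
      }
      if (!ok) return false;
    }
    return true;
  }

  bool feasibleInclude(int p, const Cand& c) const {
    if (baseUsed[c.i] || baseUsed[c.j]) return false;
    for (size_t a = 0; a < selected[p].size(); ++a) {
      const Cand& d = cands[p][selected[p][a]];
      if (cross_pairs(d.i, d.j, c.i, c.j)) return false;
    }
    return crossesAllLower(p, c.i, c.j);
  }

  // DP over remaining allowed candidates of level q (indices >= from).
  // lower_mode selects the crossing-vs-lower-levels filter: 0 none,
  // 1 exact (valid only when all levels below q are final), 2 relaxed
  // against the partially-branched level bp at position bt (upper bound).
  double levelDP(int q, int from, int lower_mode, bool tb,
                 std::vector<std::pair<int, int> >* out,
                 int bp = 0, int bt = 0) {
    std::fill(sbuf.begin(), sbuf.end(), NEG_INF);
    bool any = false;
    for (size_t a = (size_t)from; a < cands[q].size(); ++a) {
      const Cand& c = cands[q][a];
      if (baseUsed[c.i] || baseUsed[c.j]) continue;
      bool ok = true;
      for (size_t b = 0; b < selected[q].size(); ++b) {
        const Cand& d = cands[q][selected[q][b]];
        if (cross_pairs(d.i, d.j, c.i, c.j)) { ok = false; break; }
      }
      if (!ok) continue;
      if (lower_mode == 1 && !crossesAllLower(q, c.i, c.j)) continue;
      if (lower_mode == 2 && !crossesAllLowerRelaxed(q, c.i, c.j, bp, bt)) continue;
      size_t idx = (size_t)(c.i - 1) * n + (c.j - 1);
      if (c.s > sbuf[idx]) sbuf[idx] = c.s;   // duplicates: keep best score
      any = true;
    }
    if (!any) return 0.0;
    dp.run(sbuf, min_sep);
    if (tb && out) {
      dp.traceback(*out);
      for (size_t a = 0; a < out->size(); ++a) {  // back to 1-based positions
        (*out)[a].first += 1;
        (*out)[a].second += 1;
      }
    }
    return dp.get(0, n - 1);
  }

  void saveBest(const std::vector<std::pair<int, int> >& lastLevelPairs, double val) {
    bestVal = val;
    bestSel.assign(m, std::vector<std::pair<int, int> >());
    for (int q = 0; q < m - 1; ++q)
      for (size_t a = 0; a < selected[q].size(); ++a) {
        const Cand& c = cands[q][selected[q][a]];
        bestSel[q].push_back(std::make_pair(c.i, c.j));
      }
    bestSel[m - 1] = lastLevelPairs;
  }

  // Greedy primal heuristic (the IPknot refinement start): solve the
  // levels sequentially by the DP, fixing each level before the next.
  // Always feasible, and usually optimal or near-optimal, so it seeds a
  // strong incumbent for pruning.
  void heuristic() {
    std::vector<std::vector<std::pair<int, int> > > sel(m);
    double total = 0.0;
    for (int p = 0; p < m; ++p) {
      std::vector<std::pair<int, int> > pr;
      total += levelDP(p, 0, 1, true, &pr);
      sel[p] = pr;
      if (p == m - 1) break;
      // commit this level so the next one sees final lower levels
      for (size_t a = 0; a < pr.size(); ++a) {
        baseUsed[pr[a].first] = baseUsed[pr[a].second] = 1;
        for (size_t b = 0; b < cands[p].size(); ++b)
          if (cands[p][b].i == pr[a].first && cands[p][b].j == pr[a].second) {
            selected[p].push_back((int)b);
            break;
          }
      }
    }
    if (total > bestVal + 1e-12) {
      bestVal = total;
      bestSel = sel;
    }
    for (int p = 0; p < m; ++p) {
      for (size_t a = 0; a < selected[p].size(); ++a) {
        const Cand& c = cands[p][selected[p][a]];
        baseUsed[c.i] = baseUsed[c.j] = 0;
      }
      selected[p].clear();
    }
  }

  void dfs(int p, int t) {
    if (limitHit) return;
    if (++nodes > nodeLimit) { limitHit = true; return; }
    if (p == m - 1) {
      std::vector<std::pair<int, int> > pr;
      double val = curScore + levelDP(p, 0, 1, true, &pr);
      if (val > bestVal + 1e-12) saveBest(pr, val);
      return;
    }
    if (t == (int)cands[p].size()) { dfs(p + 1, 0); return; }
    // bound: relax base sharing across levels; Eq-11 for levels > p is
    // enforced against selected-or-still-available lower candidates
    double bnd = curScore;
    for (int q = p; q < m; ++q)
      bnd += levelDP(q, q == p ? t : 0, q == p ? 1 : 2, false, 0, p, t);
    if (bnd <= bestVal + 1e-12) return;
    const Cand& c = cands[p][t];
    if (feasibleInclude(p, c)) {
      baseUsed[c.i] = baseUsed[c.j] = 1;
      selected[p].push_back(t);
      curScore += c.s;
      dfs(p, t + 1);
      curScore -= c.s;
      selected[p].pop_back();
      baseUsed[c.i] = baseUsed[c.j] = 0;
    }
    dfs(p, t + 1);
  }
};

// [[Rcpp::export(name = ".ipknot_bb_cpp")]]
List ipknot_bb_cpp(int n, List cand_i, List cand_j, List cand_s,
                   int min_sep, double node_limit) {
  int m = cand_i.size();
  if (m < 1) stop("at least one level is required");
  BB bb;
  bb.n = n; bb.m = m; bb.min_sep = min_sep;
  bb.cands.resize(m);
  for (int p = 0; p < m; ++p) {
    IntegerVector ii = cand_i[p], jj = cand_j[p];
    NumericVector ss = cand_s[p];
    if (ii.size() != jj.size() || ii.size() != ss.size())
      stop("candidate vectors must have equal length");
    for (int a = 0; a < ii.size(); ++a) {
      if (ii[a] < 1 || jj[a] > n || ii[a] >= jj[a]) stop("malformed candidate pair");
      Cand c; c.i = ii[a]; c.j = jj[a]; c.s = ss[a];
      bb.cands[p].push_back(c);
    }
    // deduplicate identical (i, j) keeping the best score: fewer branch
    // decisions, same optimum
    std::stable_sort(bb.cands[p].begin(), bb.cands[p].end(),
                     [](const Cand& a, const Cand& b) {
                       if (a.i != b.i) return a.i < b.i;
                       if (a.j != b.j) return a.j < b.j;
                       return a.s > b.s;
                     });
    std::vector<Cand> uniq;
    for (size_t a = 0; a < bb.cands[p].size(); ++a)
      if (uniq.empty() || uniq.back().i != bb.cands[p][a].i ||
          uniq.back().j != bb.cands[p][a].j)
        uniq.push_back(bb.cands[p][a]);
    bb.cands[p] = uniq;
    std::stable_sort(bb.cands[p].begin(), bb.cands[p].end(),
                     [](const Cand& a, const Cand& b) { return a.s > b.s; });
  }
  // a level-p candidate that crosses no candidate at some lower level can
  // never satisfy the lower-level-crossing constraint: drop it up front
  for (int p = 1; p < m; ++p) {
    std::vector<Cand> keep;
    for (size_t a = 0; a < bb.cands[p].size(); ++a) {
      bool ok = true;
      for (int q = 0; q < p && ok; ++q) {
        bool any = false;
        for (size_t b = 0; b < bb.cands[q].size(); ++b)
          if (cross_pairs(bb.cands[q][b].i, bb.cands[q][b].j,
                          bb.cands[p][a].i, bb.cands[p][a].j)) { any = true; break; }
        ok = any;
      }
      if (ok) keep.push_back(bb.cands[p][a]);
    }
    bb.cands[p] = keep;
  }
  bb.baseUsed.assign(n + 1, 0);
  bb.selected.assign(m, std::vector<int>());
  bb.curScore = 0.0;
  bb.bestVal = 0.0;  // empty solution is always feasible
  bb.bestSel.assign(m, std::vector<std::pair<int, int> >());
  bb.nodes = 0;
  bb.nodeLimit = (long long)node_limit;
  bb.limitHit = false;
  bb.dp.n = n;
  bb.sbuf.assign((size_t)n * n, NEG_INF);
  bb.heuristic();
  bb.dfs(0, 0);

  List levels(m);
  for (int p = 0; p < m; ++p) {
    int np = (int)bb.bestSel[p].size();
    IntegerMatrix pm(np, 2);
    for (int a = 0; a < np; ++a) {
      pm(a, 0) = bb.bestSel[p][a].first;
      pm(a, 1) = bb.bestSel[p][a].second;
    }
    colnames(pm) = CharacterVector::create("i", "j");
    levels[p] = pm;
  }
  return List::create(_["objective"] = bb.bestVal, _["levels"] = levels,
                      _["nodes"] = (double)bb.nodes,
                      _["status"] = bb.limitHit ? "node_limit" : "optimal");
}
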