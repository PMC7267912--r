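// Core search engine: per-origin expand/prune traversal with memoized
// per-voxel spectral scores and a lazily-filled pairwise MI hash table.
// A pure-R reference implementation of the same rules lives in R/search.R;
// the two are cross-checked in the test suite.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double DEG_EPS = 1e-12;  // within-scatter below this is degenerate

struct Problem {
  int p, n;
  const NumericMatrix X;    // voxels x subjects, already standardized in R
  const NumericMatrix Lb, Lw;
  const IntegerMatrix binned;  // p x n, codes 1..nb[i]
  const IntegerVector nb;
  std::vector<std::vector<int>> adj;  // 0-based
  bool memoize;

  std::vector<double> bCache, wCache;
  std::vector<char> haveBW;

  std::unordered_map<uint64_t, double> miTab;
  std::unordered_set<uint64_t> miTouched;

  Problem(const NumericMatrix& X_, const NumericMatrix& Lb_,
          const NumericMatrix& Lw_, const IntegerMatrix& binned_,
          const IntegerVector& nb_, const List& adj_, bool memoize_)
      : p(X_.nrow()), n(X_.ncol()), X(X_), Lb(Lb_), Lw(Lw_),
        binned(binned_), nb(nb_), memoize(memoize_) {
    adj.resize(p);
    for (int i = 0; i < p; ++i) {
      IntegerVector a = adj_[i];
      adj[i].assign(a.begin(), a.end());
      for (int& v : adj[i]) --v;
    }
    if (memoize) {
      bCache.resize(p); wCache.resize(p);
      haveBW.assign(p, 0);
    }
  }

  double quad(int i, const NumericMatrix& L) const {
    // x_i' L x_i ; PSD in exact arithmetic, clamp numerical dust
    double s = 0.0;
    for (int a = 0; a < n; ++a) {
      const double xa = X(i, a);
      if (xa == 0.0) continue;
      double row = 0.0;
      for (int c = 0; c < n; ++c) row += L(a, c) * X(i, c);
      s += xa * row;
    }
    return s > 0.0 ? s : 0.0;
  }

  void bw(int i, double& b, double& w) {
    if (memoize) {
      if (!haveBW[i]) {
        bCache[i] = quad(i, Lb);
        wCache[i] = quad(i, Lw);
        haveBW[i] = 1;
      }
      b = bCache[i]; w = wCache[i];
    } else {
      b = quad(i, Lb); w = quad(i, Lw);
    }
  }

  double mi(int i, int j) {
    const uint64_t key = (i < j)
        ? (uint64_t)i * (uint64_t)p + (uint64_t)j
        : (uint64_t)j * (uint64_t)p + (uint64_t)i;
    if (memoize) {
      auto it = miTab.find(key);
      if (it != miTab.end()) return it->second;
    }
    miTouched.insert(key);
    const int nbi = nb[i], nbj = nb[j];
    std::vector<int> joint(nbi * nbj, 0);
    std::vector<int> mi_(nbi, 0), mj_(nbj, 0);
    for (int s = 0; s < n; ++s) {
      const int a = binned(i, s) - 1, c = binned(j, s) - 1;
      ++joint[a + nbi * c]; ++mi_[a]; ++mj_[c];
    }
    double val = 0.0;
    for (int c = 0; c < nbj; ++c)
      for (int a = 0; a < nbi; ++a) {
        const int cnt = joint[a + nbi * c];
        if (cnt == 0) continue;
        const double pj = (double)cnt / n;
        val += pj * std::log(pj * n * n / ((double)mi_[a] * (double)mj_[c]));
      }
    if (val < 0.0) val = 0.0;
    if (memoize) miTab.emplace(key, val);
    return val;
  }
};

inline double ratio(double B, double W) {
  return (W < DEG_EPS) ? R_PosInf : B / W;
}

struct GrowResult {
  std::vector<int> members;  // 0-based, sorted
  double relevance;
  int steps;
  bool capped;
};

GrowResult grow_one(Problem& pr, int origin, int max_steps) {
  std::vector<char> inMember(pr.p, 0), inRemoved(pr.p, 0), seen(pr.p, 0);
  std::vector<int> members{origin}, lastRemoved;
  inMember[origin] = 1;

  double bo, wo;
  pr.bw(origin, bo, wo);
  double B = bo, W = wo;
  int steps = 0;
  bool capped = false;

  for (;;) {
    // expansion: candidates adjacent to the whole cluster, skipping the
    // voxels removed by the immediately preceding prune (anti-loop rule)
    std::vector<int> cand;
    for (int m : members)
      for (int u : pr.adj[m])
        if (!inMember[u] && !inRemoved[u] && !seen[u]) {
          seen[u] = 1;
          cand.push_back(u);
        }
    for (int u : cand) seen[u] = 0;
    std::sort(cand.begin(), cand.end());

    const double s0 = ratio(B, W);
    std::vector<int> admitted;
    double addB = 0.0, addW = 0.0;
    for (int c : cand) {
      double bc, wc;
      pr.bw(c, bc, wc);
      if (ratio(B + bc, W + wc) > s0) {  // strict: ties reject
        admitted.push_back(c);
        addB += bc; addW += wc;
      }
    }
    ++steps;
    if (admitted.empty()) break;
    for (int a : admitted) inMember[a] = 1;
    members.insert(members.end(), admitted.begin(), admitted.end());
    std::sort(members.begin(), members.end());
    B += addB; W += addW;
    for (int r : lastRemoved) inRemoved[r] = 0;
    lastRemoved.clear();
    if (steps >= max_steps) { capped = true; break; }

    // prune: protected = origin + voxels admitted by this expansion
    std::vector<char> prot(pr.p, 0);
    prot[origin] = 1;
    for (int a : admitted) prot[a] = 1;
    for (;;) {
      if ((int)members.size() < 3) break;  // removal must leave >= 2
      std::vector<int> free;
      for (int m : members) if (!prot[m]) free.push_back(m);
      if (free.empty()) break;
      std::vector<double> J(free.size());
      for (size_t k = 0; k < free.size(); ++k) {
        double s = 0.0;
        for (int m : members) if (m != free[k]) s += pr.mi(free[k], m);
        J[k] = s / (double)(members.size() - 1);
      }
      std::vector<size_t> ord(free.size());
      for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
      std::stable_sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
        if (J[a] != J[b]) return J[a] > J[b];
        return free[a] < free[b];
      });
      const double sc = ratio(B, W);
      const double tol = 1e-12 * std::max(1.0, std::abs(sc) == R_PosInf ? 1.0 : std::abs(sc));
      bool removedOne = false;
      for (size_t k : ord) {
        const int v = free[k];
        double bv, wv;
        pr.bw(v, bv, wv);
        const double s1 = ratio(B - bv, W - wv);
        const bool ok = std::isinf(sc) ? std::isinf(s1) : (s1 >= sc - tol);
        if (ok) {
          members.erase(std::find(members.begin(), members.end(), v));
          inMember[v] = 0;
          inRemoved[v] = 1;
          lastRemoved.push_back(v);
          B -= bv; W -= wv;
          removedOne = true;
          break;
        }
      }
      if (!removedOne) break;
    }
    ++steps;
    if (steps >= max_steps) { capped = true; break; }
  }

  GrowResult res;
  res.members = members;
  res.relevance = ratio(B, W);
  res.steps = steps;
  res.capped = capped;
  return res;
}

}  // namespace

// [[Rcpp::export(name = ".ics_engine")]]
List ics_engine(NumericMatrix X, NumericMatrix Lb, NumericMatrix Lw,
                IntegerMatrix binned, IntegerVector nbins, List adj,
                IntegerVector origins, bool memoize, int max_steps,
                bool progress) {
  Problem pr(X, Lb, Lw, binned, nbins, adj, memoize);
  const int k = origins.size();
  List members(k);
  NumericVector relevance(k);
  IntegerVector steps(k);
  LogicalVector capped(k);

  for (int q = 0; q < k; ++q) {
    if (q % 64 == 0) Rcpp::checkUserInterrupt();
    GrowResult g = grow_one(pr, origins[q] - 1, max_steps);
    IntegerVector mm(g.members.size());
    for (size_t t = 0; t < g.members.size(); ++t) mm[t] = g.members[t] + 1;
    members[q] = mm;
    relevance[q] = g.relevance;
    steps[q] = g.steps;
    capped[q] = g.capped;
    if (progress && (q + 1) % 100 == 0)
      Rcout << "origin " << (q + 1) << "/" << k << "\n";
  }

  const size_t npair = pr.miTouched.size();
  IntegerMatrix pairs(npair, 2);
  size_t r = 0;
  for (uint64_t key : pr.miTouched) {
    pairs(r, 0) = (int)(key / (uint64_t)pr.p) + 1;
    pairs(r, 1) = (int)(key % (uint64_t)pr.p) + 1;
    ++r;
  }

  return List::create(
      _["members"] = members, _["relevance"] = relevance,
      _["steps"] = steps, _["capped"] = capped, _["mi_pairs"] = pairs);
}
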