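#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Interventional Shapley attribution for forests of regression trees.
//
// For one foreground record x, one background record z and one tree, the
// value function over feature coalitions S (features taken from x, the rest
// from z) is the tree prediction of the hybrid record. A leaf with value v
// is reached by the hybrid exactly when the path features it forces to the
// x-branch are all inside S (set P, |P| = k) and the ones it forces to the
// z-branch are all outside S (set N, |N| = m); features on which x and z
// agree are dummies. The Shapley value of that conjunctive game is closed
// form:
//   j in P:  phi_j += v * (k-1)! m! / (k+m)!
//   j in N:  phi_j -= v * k! (m-1)! / (k+m)!
// Averaging over background rows and trees gives the forest attribution;
// efficiency (sum_j phi_j = f(x) - mean_z f(z)) holds by construction, so
// additivity against the background-mean base value is exact.
//
// Implementation: each leaf's path is flattened once into unique per-feature
// interval constraints (lo, hi]; whether a record satisfies each constraint
// is a bitmask (paths are far shorter than 64 features). Background masks
// are hoisted out of the record loop, so the per-(record, background, leaf)
// work is a handful of bit operations, and leaves that neither record can
// reach are skipped with one test.

struct Leaf {
  std::vector<int> feat;       // unique features on the path
  std::vector<double> lo, hi;  // satisfied iff lo < value <= hi
  double value;
  uint64_t all;                // mask with one bit per path feature
};

struct Tree {
  std::vector<Leaf> leaves;
  double root_value;           // used when the tree is a single leaf
  bool is_stump;
};

static void collect_leaves(const IntegerVector& L, const IntegerVector& R,
                           const IntegerVector& V, const NumericVector& S,
                           const NumericVector& P, int node,
                           std::vector<int>& feat, std::vector<double>& lo,
                           std::vector<double>& hi, Tree& out) {
  const int f = V[node];
  if (f < 0) {
    Leaf lf;
    for (size_t d = 0; d < feat.size(); ++d) {
      lf.feat.push_back(feat[d]);
      lf.lo.push_back(lo[d]);
      lf.hi.push_back(hi[d]);
    }
    lf.value = P[node];
    if (lf.feat.size() > 60) stop("tree path exceeds 60 distinct features");
    lf.all = (lf.feat.empty()) ? 0ULL
      : ((lf.feat.size() == 64) ? ~0ULL
         : ((1ULL << lf.feat.size()) - 1ULL));
    out.leaves.push_back(lf);
    return;
  }
  const double sv = S[node];
  int d = -1;
  for (size_t i = 0; i < feat.size(); ++i) if (feat[i] == f) { d = (int)i; break; }
  if (d < 0) {
    feat.push_back(f);
    lo.push_back(-std::numeric_limits<double>::infinity());
    hi.push_back(std::numeric_limits<double>::infinity());
    d = (int)feat.size() - 1;
    const double olo = lo[d], ohi = hi[d];
    hi[d] = std::min(ohi, sv);
    collect_leaves(L, R, V, S, P, L[node], feat, lo, hi, out);
    hi[d] = ohi;
    lo[d] = std::max(olo, sv);
    collect_leaves(L, R, V, S, P, R[node], feat, lo, hi, out);
    lo[d] = olo;
    feat.pop_back(); lo.pop_back(); hi.pop_back();
  } else {
    const double olo = lo[d], ohi = hi[d];
    hi[d] = std::min(ohi, sv);
    if (lo[d] < hi[d]) collect_leaves(L, R, V, S, P, L[node], feat, lo, hi, out);
    hi[d] = ohi;
    lo[d] = std::max(olo, sv);
    if (lo[d] < hi[d]) collect_leaves(L, R, V, S, P, R[node], feat, lo, hi, out);
    lo[d] = olo;
  }
}

static std::vector<Tree> parse_forest(const List& trees) {
  std::vector<Tree> forest(trees.size());
  for (R_xlen_t t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector L = tr["left"], R = tr["right"], V = tr["var"];
    NumericVector S = tr["split"], P = tr["pred"];
    Tree& o = forest[t];
    o.is_stump = (V[0] < 0);
    o.root_value = o.is_stump ? P[0] : 0.0;
    if (!o.is_stump) {
      std::vector<int> feat;
      std::vector<double> lo, hi;
      collect_leaves(L, R, V, S, P, 0, feat, lo, hi, o);
    }
  }
  return forest;
}

static inline uint64_t sat_mask(const Leaf& lf, const double* row) {
  uint64_t m = 0;
  for (size_t d = 0; d < lf.feat.size(); ++d) {
    const double v = row[lf.feat[d]];
    if (v > lf.lo[d] && v <= lf.hi[d]) m |= (1ULL << d);
  }
  return m;
}

// [[Rcpp::export]]
NumericMatrix shap_interventional_cpp(List trees, NumericMatrix X,
                                      NumericMatrix BG) {
  const std::vector<Tree> forest = parse_forest(trees);
  const int n = X.nrow(), p = X.ncol(), B = BG.nrow();
  if (BG.ncol() != p) stop("background and records differ in width");

  // factorial weight tables: Wpos[k][m], Wneg[k][m]
  std::vector<double> fact(2 * p + 2, 1.0);
  for (size_t i = 1; i < fact.size(); ++i) fact[i] = fact[i - 1] * i;
  std::vector<std::vector<double> > Wpos(p + 1, std::vector<double>(p + 1, 0.0));
  std::vector<std::vector<double> > Wneg = Wpos;
  for (int k = 0; k <= p; ++k)
    for (int m = 0; m <= p - k; ++m) {
      if (k > 0) Wpos[k][m] = fact[k - 1] * fact[m] / fact[k + m];
      if (m > 0) Wneg[k][m] = fact[k] * fact[m - 1] / fact[k + m];
    }

  // column-major copies for row access
  std::vector<double> Xr((size_t)n * p), Zr((size_t)B * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) Xr[(size_t)i * p + j] = X(i, j);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < p; ++j) Zr[(size_t)b * p + j] = BG(b, j);

  NumericMatrix phi(n, p);
  std::vector<double> acc(p);
  const double scale = 1.0 / (double)(forest.size() * B);
  std::vector<uint64_t> zmask;   // per (leaf, background)
  std::vector<uint64_t> xmask;   // per leaf, current record

  for (size_t t = 0; t < forest.size(); ++t) {
    const Tree& tr = forest[t];
    if (tr.is_stump) continue;   // constant tree: no attribution
    const size_t L = tr.leaves.size();
    zmask.assign(L * B, 0);
    for (size_t l = 0; l < L; ++l)
      for (int b = 0; b < B; ++b)
        zmask[l * B + b] = sat_mask(tr.leaves[l], &Zr[(size_t)b * p]);
    xmask.assign(L, 0);

    for (int i = 0; i < n; ++i) {
      const double* xr = &Xr[(size_t)i * p];
      for (size_t l = 0; l < L; ++l) xmask[l] = sat_mask(tr.leaves[l], xr);
      for (size_t l = 0; l < L; ++l) {
        const Leaf& lf = tr.leaves[l];
        const uint64_t A = xmask[l];
        const uint64_t* zm = &zmask[l * B];
        for (int b = 0; b < B; ++b) {
          const uint64_t Z = zm[b];
          if ((A | Z) != lf.all) continue;       // some feature fails both ways
          const uint64_t Pm = A & ~Z, Nm = Z & ~A;
          if (!(Pm | Nm)) continue;              // x and z agree along the path
          const int k = __builtin_popcountll(Pm);
          const int m = __builtin_popcountll(Nm);
          if (Pm) {
            const double w = Wpos[k][m] * lf.value;
            uint64_t bits = Pm;
            while (bits) {
              const int d = __builtin_ctzll(bits);
              phi(i, lf.feat[d]) += w;
              bits &= bits - 1;
            }
          }
          if (Nm) {
            const double w = Wneg[k][m] * lf.value;
            uint64_t bits = Nm;
            while (bits) {
              const int d = __builtin_ctzll(bits);
              phi(i, lf.feat[d]) -= w;
              bits &= bits - 1;
            }
          }
        }
      }
      if ((i & 255) == 0) Rcpp::checkUserInterrupt();
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) phi(i, j) *= scale;
  return phi;
}

// Plain forest prediction from the flattened leaves (a record satisfies
// exactly one leaf's constraints per tree); cross-checks that the extracted
// structure reproduces the fitted ensemble.
// [[Rcpp::export]]
NumericVector forest_predict_cpp(List trees, NumericMatrix X) {
  const std::vector<Tree> forest = parse_forest(trees);
  const int n = X.nrow(), p = X.ncol();
  NumericVector out(n);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    double s = 0.0;
    for (size_t t = 0; t < forest.size(); ++t) {
      const Tree& tr = forest[t];
      if (tr.is_stump) { s += tr.root_value; continue; }
      for (size_t l = 0; l < tr.leaves.size(); ++l) {
        if (sat_mask(tr.leaves[l], row.data()) == tr.leaves[l].all) {
          s += tr.leaves[l].value;
          break;
        }
      }
    }
    out[i] = s / forest.size();
  }
  return out;
}
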