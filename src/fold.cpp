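#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Stem-loop folder: interval dynamic program over pseudoknot-free structures
// in which every base pair encloses at most one branch (no multiloops; the
// pipeline targets single-hairpin precursors).  The objective is a
// stacking-aware score: pair terms (GC > AU > GU), a bonus for each stacked
// pair, and penalties for hairpin and interior/bulge loops.  The reported
// energy proxy is -energy_per_score * score (see R/fold.R).

static const double NEG = -1e18;

struct FoldParams {
  double p_gc, p_at, p_gt, stack, hairpin, int_base, int_per_nt;
  int max_bulge;  // per-side bound on interior/bulge loop size
};

static inline double pair_score(char a, char b, const FoldParams &P) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return P.p_gc;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return P.p_at;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return P.p_gt;
  return NEG;
}

// best score of a structure on [i, j] with (i, j) paired (0-based, inclusive)
static void fill_V(const std::string &s, const FoldParams &P,
                   std::vector<std::vector<double> > &V) {
  int n = (int)s.size();
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double ps = pair_score(s[i], s[j], P);
      if (ps <= NEG / 2) { V[i][j] = NEG; continue; }
      double best = -P.hairpin;  // terminal loop (size >= 3 by span bound)
      int kmax = std::min(i + 1 + P.max_bulge, j - 5);
      for (int k = i + 1; k <= kmax; ++k) {
        int lmin = std::max(k + 4, j - 1 - P.max_bulge);
        for (int l = lmin; l <= j - 1; ++l) {
          if (V[k][l] <= NEG / 2) continue;
          double gain = (k == i + 1 && l == j - 1)
            ? P.stack
            : -(P.int_base + P.int_per_nt * ((k - i - 1) + (j - l - 1)));
          double cand = V[k][l] + gain;
          if (cand > best) best = cand;
        }
      }
      V[i][j] = ps + best;
    }
  }
}

static void trace_V(const std::string &s, const FoldParams &P,
                    const std::vector<std::vector<double> > &V,
                    int i, int j, std::vector<int> &partner) {
  for (;;) {
    partner[i] = j; partner[j] = i;
    double target = V[i][j] - pair_score(s[i], s[j], P);
    if (target == -P.hairpin) return;  // hairpin option chosen (same eval order)
    int kmax = std::min(i + 1 + P.max_bulge, j - 5);
    bool found = false;
    double best = -P.hairpin;
    int bk = -1, bl = -1;
    for (int k = i + 1; k <= kmax && !found; ++k) {
      int lmin = std::max(k + 4, j - 1 - P.max_bulge);
      for (int l = lmin; l <= j - 1; ++l) {
        if (V[k][l] <= NEG / 2) continue;
        double gain = (k == i + 1 && l == j - 1)
          ? P.stack
          : -(P.int_base + P.int_per_nt * ((k - i - 1) + (j - l - 1)));
        double cand = V[k][l] + gain;
        if (cand > best) { best = cand; bk = k; bl = l; }
      }
    }
    if (bk < 0) return;  // numerically degenerate; stop at hairpin
    i = bk; j = bl;
  }
}

// [[Rcpp::export]]
List fold_cpp(std::string seq, double p_gc, double p_at, double p_gt,
              double stack, double hairpin, double int_base,
              double int_per_nt, int max_bulge) {
  FoldParams P;
  P.p_gc = p_gc; P.p_at = p_at; P.p_gt = p_gt; P.stack = stack;
  P.hairpin = hairpin; P.int_base = int_base; P.int_per_nt = int_per_nt;
  P.max_bulge = max_bulge;
  int n = (int)seq.size();
  std::vector<int> partner(n, -1);
  double total = 0.0;
  if (n >= 5) {
    std::vector<std::vector<double> > V(n, std::vector<double>(n, NEG));
    fill_V(seq, P, V);
    // external level: bases outside stems are free; pick disjoint stems
    std::vector<double> W(n + 1, 0.0);
    for (int j = 1; j <= n; ++j) {
      W[j] = W[j - 1];
      for (int i = 1; i + 4 <= j; ++i) {
        if (V[i - 1][j - 1] <= NEG / 2) continue;
        double cand = W[i - 1] + V[i - 1][j - 1];
        if (cand > W[j]) W[j] = cand;
      }
    }
    total = W[n];
    int j = n;
    while (j > 0) {
      if (W[j] == W[j - 1]) { --j; continue; }
      int pick = -1;
      for (int i = 1; i + 4 <= j; ++i) {
        if (V[i - 1][j - 1] <= NEG / 2) continue;
        if (W[i - 1] + V[i - 1][j - 1] == W[j]) { pick = i; break; }
      }
      if (pick < 0) { --j; continue; }
      trace_V(seq, P, V, pick - 1, j - 1, partner);
      j = pick - 1;
    }
  }
  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) db[i] = '(';
    else if (partner[i] >= 0) db[i] = ')';
  }
  return List::create(_["dotbracket"] = db, _["score"] = total);
}
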