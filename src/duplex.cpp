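#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// miRNA-target duplex scoring.  The miRNA (5'->3') is aligned globally
// against the reverse complement of a transcript window, minimising a
// penalty ("expectation"): match 0, G:U wobble p_wobble, mismatch
// p_mismatch, gap p_gap, all multiplied by seed_mult at miRNA positions
// seed_lo..seed_hi.  In reverse-complement space a wobble is
// (q=G, s=A) -- miRNA G opposite target U -- or (q=T, s=C).
//
// Column states: '=' match, 'w' wobble, 'X' mismatch,
//                'd' gap in target (miRNA base bulged),
//                'b' gap in miRNA (target base bulged).

static inline char col_state(char q, char s) {
  if (q == s && q != 'N') return '=';
  if ((q == 'G' && s == 'A') || (q == 'T' && s == 'C')) return 'w';
  return 'X';
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'G': return 'C'; case 'C': return 'G';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

struct DuplexParams {
  double p_mismatch, p_wobble, p_gap, seed_mult;
  int seed_lo, seed_hi;
};

static inline double seedw(int pos, const DuplexParams &P) {
  return (pos >= P.seed_lo && pos <= P.seed_hi) ? P.seed_mult : 1.0;
}

static inline double state_pen(char st, const DuplexParams &P) {
  if (st == '=') return 0.0;
  if (st == 'w') return P.p_wobble;
  return P.p_mismatch;
}

struct AlnResult {
  double expectation;
  std::string col_states;   // one char per alignment column
  std::vector<int> col_pos; // miRNA position per column (0 for 'b' columns)
  std::string pos_states;   // one char per miRNA position ('=', 'w', 'X', 'd')
};

// global alignment of q (miRNA) against s (reverse-complemented window)
static AlnResult nw_align(const std::string &q, const std::string &s,
                          const DuplexParams &P) {
  int m = (int)q.size(), n = (int)s.size();
  std::vector<std::vector<double> > D(m + 1, std::vector<double>(n + 1, 0.0));
  for (int i = 1; i <= m; ++i) D[i][0] = D[i - 1][0] + P.p_gap * seedw(i, P);
  for (int j = 1; j <= n; ++j) D[0][j] = D[0][j - 1] + P.p_gap * seedw(1, P);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      char st = col_state(q[i - 1], s[j - 1]);
      double diag = D[i - 1][j - 1] + state_pen(st, P) * seedw(i, P);
      double up   = D[i - 1][j] + P.p_gap * seedw(i, P);
      double left = D[i][j - 1] + P.p_gap * seedw(std::min(i + 1, m), P);
      double best = diag;
      if (up < best) best = up;
      if (left < best) best = left;
      D[i][j] = best;
    }
  }
  AlnResult R;
  R.expectation = D[m][n];
  R.pos_states.assign(m, '?');
  int i = m, j = n;
  std::string cs;
  std::vector<int> cp;
  while (i > 0 || j > 0) {
    // tie-break order: pairing before gaps (fewer gaps), miRNA gap last
    if (i > 0 && j > 0) {
      char st = col_state(q[i - 1], s[j - 1]);
      if (D[i][j] == D[i - 1][j - 1] + state_pen(st, P) * seedw(i, P)) {
        cs.push_back(st); cp.push_back(i); R.pos_states[i - 1] = st;
        --i; --j; continue;
      }
    }
    if (i > 0 && D[i][j] == D[i - 1][j] + P.p_gap * seedw(i, P)) {
      cs.push_back('d'); cp.push_back(i); R.pos_states[i - 1] = 'd';
      --i; continue;
    }
    cs.push_back('b'); cp.push_back(0);
    --j;
  }
  R.col_states.assign(cs.rbegin(), cs.rend());
  R.col_pos.assign(cp.rbegin(), cp.rend());
  return R;
}

// [[Rcpp::export]]
List duplex_align_cpp(std::string q, std::string window,
                      double p_mismatch, double p_wobble, double p_gap,
                      double seed_mult, int seed_lo, int seed_hi) {
  DuplexParams P;
  P.p_mismatch = p_mismatch; P.p_wobble = p_wobble; P.p_gap = p_gap;
  P.seed_mult = seed_mult; P.seed_lo = seed_lo; P.seed_hi = seed_hi;
  AlnResult R = nw_align(q, revcomp(window), P);
  return List::create(
    _["expectation"] = R.expectation,
    _["col_states"] = R.col_states,
    _["col_pos"] = IntegerVector(R.col_pos.begin(), R.col_pos.end()),
    _["pos_states"] = R.pos_states);
}

// Scan every window of tx (one sense only) at widths m-1, m, m+1 and report
// windows whose optimal alignment penalty is <= cutoff.  Any alignment with
// two or more gaps costs >= 2 * p_gap, so these widths realise every
// alignment reportable under the default cutoff (documented in the package).
// [[Rcpp::export]]
DataFrame scan_duplex_cpp(std::string q, std::string tx,
                          double p_mismatch, double p_wobble, double p_gap,
                          double seed_mult, int seed_lo, int seed_hi,
                          double cutoff) {
  DuplexParams P;
  P.p_mismatch = p_mismatch; P.p_wobble = p_wobble; P.p_gap = p_gap;
  P.seed_mult = seed_mult; P.seed_lo = seed_lo; P.seed_hi = seed_hi;
  int m = (int)q.size(), n = (int)tx.size();
  std::vector<int> starts, widths, nmm, nwob, ngap;
  std::vector<double> exps;
  std::vector<std::string> posst, colst;
  for (int w = m - 1; w <= m + 1; ++w) {
    if (w < 1) continue;
    for (int s0 = 0; s0 + w <= n; ++s0) {
      std::string win = tx.substr(s0, w);
      AlnResult R = nw_align(q, revcomp(win), P);
      if (R.expectation <= cutoff + 1e-9) {
        int a = 0, b = 0, g = 0;
        for (size_t k = 0; k < R.col_states.size(); ++k) {
          char c = R.col_states[k];
          if (c == 'X') ++a;
          else if (c == 'w') ++b;
          else if (c == 'd' || c == 'b') ++g;
        }
        starts.push_back(s0); widths.push_back(w);
        exps.push_back(R.expectation);
        nmm.push_back(a); nwob.push_back(b); ngap.push_back(g);
        posst.push_back(R.pos_states); colst.push_back(R.col_states);
      }
    }
  }
  return DataFrame::create(
    _["start"] = IntegerVector(starts.begin(), starts.end()),
    _["width"] = IntegerVector(widths.begin(), widths.end()),
    _["expectation"] = NumericVector(exps.begin(), exps.end()),
    _["n_mismatch"] = IntegerVector(nmm.begin(), nmm.end()),
    _["n_wobble"] = IntegerVector(nwob.begin(), nwob.end()),
    _["n_gap"] = IntegerVector(ngap.begin(), ngap.end()),
    _["pos_states"] = CharacterVector(posst.begin(), posst.end()),
    _["col_states"] = CharacterVector(colst.begin(), colst.end()),
    _["stringsAsFactors"] = false);
}
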