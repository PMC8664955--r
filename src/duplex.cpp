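// Affine-gap duplex alignment of a miRNA (written 5'->3') against a target
// site (written 3'->5'). Aligning the two written strings left-to-right
// corresponds to antiparallel duplex formation, so "match" means the letters
// base-pair (Watson-Crick or G:U wobble). Global over the miRNA; leading and
// trailing unaligned target positions are free (the site window is wider
// than the binding register).
#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using Rcpp::List;
using Rcpp::Named;

namespace {
const double NEG = -std::numeric_limits<double>::infinity();
// letters: 0=A, 1=C, 2=G, 3=U
inline int pair_type(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 1; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2; // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 3; // G:U wobble
  return 0;
}
}

// [[Rcpp::export]]
Rcpp::List cpp_align_duplex(const Rcpp::IntegerVector& mi,
                            const Rcpp::IntegerVector& tg,
                            double sc_gc, double sc_au, double sc_gu,
                            double mismatch, double gap_open,
                            double gap_extend) {
  const int m = mi.size(), n = tg.size();
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };
  std::vector<double> M((m + 1) * (n + 1), NEG), P(M), Q(M);
  // traceback: predecessor state 0=M,1=P,2=Q,3=start
  std::vector<signed char> tbM(M.size(), -1), tbP(M.size(), -1), tbQ(M.size(), -1);

  auto score_of = [&](int i, int j) {
    int t = pair_type(mi[i - 1], tg[j - 1]);
    if (t == 1) return sc_gc;
    if (t == 2) return sc_au;
    if (t == 3) return sc_gu;
    return mismatch;
  };

  for (int j = 0; j <= n; ++j) { Q[idx(0, j)] = 0.0; tbQ[idx(0, j)] = 3; } // free prefix
  for (int i = 1; i <= m; ++i) {
    P[idx(i, 0)] = gap_open + i * gap_extend;
    tbP[idx(i, 0)] = (i == 1) ? 3 : 1;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M: mi[i] aligned with tg[j]; predecessor preference M > P > Q
      double s = score_of(i, j);
      double bm = M[idx(i - 1, j - 1)], bp = P[idx(i - 1, j - 1)], bq = Q[idx(i - 1, j - 1)];
      double best = bm; signed char st = 0;
      if (bp > best) { best = bp; st = 1; }
      if (bq > best) { best = bq; st = 2; }
      if (i == 1 && j >= 1 && 0.0 > best) { best = 0.0; st = 3; } // covered by Q(0,j-1)=0 but keep explicit
      M[idx(i, j)] = (best == NEG) ? NEG : best + s;
      tbM[idx(i, j)] = st;
      // P: mi[i] against a gap
      double pm = M[idx(i - 1, j)] + gap_open + gap_extend;
      double pp = P[idx(i - 1, j)] + gap_extend;
      double pq = Q[idx(i - 1, j)] + gap_open + gap_extend;
      double pb = pm; signed char pst = 0;
      if (pp > pb) { pb = pp; pst = 1; }
      if (pq > pb) { pb = pq; pst = 2; }
      P[idx(i, j)] = pb; tbP[idx(i, j)] = pst;
      // Q: tg[j] against a gap (internal; prefix row handled above)
      double qm = M[idx(i, j - 1)] + gap_open + gap_extend;
      double qq = Q[idx(i, j - 1)] + gap_extend;
      double qp = P[idx(i, j - 1)] + gap_open + gap_extend;
      double qb = qm; signed char qst = 0;
      if (qq > qb) { qb = qq; qst = 2; }
      if (qp > qb) { qb = qp; qst = 1; }
      Q[idx(i, j)] = qb; tbQ[idx(i, j)] = qst;
    }
  }

  // free trailing target suffix: best over j at i = m; prefer ending in M
  double best = NEG; int bj = -1; signed char bstate = 0;
  for (int j = 0; j <= n; ++j) {
    double vm = M[idx(m, j)], vp = P[idx(m, j)], vq = Q[idx(m, j)];
    if (vm > best) { best = vm; bj = j; bstate = 0; }
    if (vp > best) { best = vp; bj = j; bstate = 1; }
    if (vq > best) { best = vq; bj = j; bstate = 2; }
  }

  std::vector<int> pi, pj, ptype;
  int i = m, j = bj; signed char st = bstate;
  while (i > 0) {
    if (st == 0) {
      int t = pair_type(mi[i - 1], tg[j - 1]);
      if (t > 0) { pi.push_back(i); pj.push_back(j); ptype.push_back(t == 3 ? 2 : 1); }
      signed char prev = tbM[idx(i, j)];
      --i; --j; st = (prev == 3) ? 2 : prev;
    } else if (st == 1) {
      signed char prev = tbP[idx(i, j)];
      --i; st = (prev == 3) ? 2 : prev;
    } else {
      signed char prev = tbQ[idx(i, j)];
      if (i == 0) break;
      --j; st = (prev == 3) ? 2 : prev;
    }
  }
  const int np = (int)pi.size();
  Rcpp::IntegerMatrix paired(np, 3);
  for (int r = 0; r < np; ++r) { // reverse to increasing order
    paired(r, 0) = pi[np - 1 - r];
    paired(r, 1) = pj[np - 1 - r];
    paired(r, 2) = ptype[np - 1 - r];
  }
  return List::create(Named("score") = best, Named("paired") = paired);
}
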