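// Decision-point recursions for the nucleosome-occupancy HMM.
//
// Hidden states are {free, M_1..M_L (H3K4me3), N_1..N_L (H3)} with
// deterministic within-nucleosome transitions; all stochastic choices
// happen at "decision points" (positions where a free base or a completed
// nucleosome just ended).  The forward/backward quantities over decision
// points therefore fully determine the per-state quantities, and
// per-base occupancy posteriors are sliding-window sums of nucleosome
// start posteriors.  All recursions run in log space; cumulative
// log-emission sums use long-double accumulation so that differences over
// an L-window keep full double precision.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// extended-precision log-sum-exp keeps the accumulated drift of the
// recursions far below the 1e-9 posterior tolerance even at megabase T
static inline long double lse2(long double a, long double b) {
  if (a == -INFINITY) return b;
  if (b == -INFINITY) return a;
  long double m = a > b ? a : b;
  return m + logl(expl(a - m) + expl(b - m));
}

static inline long double lse3(long double a, long double b, long double c) {
  return lse2(lse2(a, b), c);
}

// Per-position log emission probabilities under one state's conditional
// tables.  `s` holds bases coded 0..3 (no N allowed); `tabs` has 6
// matrices for context orders 0..5 (element j+1: 4^j rows, 4 columns),
// entries already on the log scale.  Position t uses order min(5, t).
// [[Rcpp::export]]
NumericVector logemis_cpp(IntegerVector s, List tabs) {
  const int T = s.size();
  NumericVector out(T);
  std::vector<const double*> tp(6);
  std::vector<int> nr(6);
  for (int j = 0; j < 6; ++j) {
    NumericMatrix m = tabs[j];
    tp[j] = REAL(m);
    nr[j] = m.nrow();
  }
  int ctx = 0;                       // rolling full-order context
  const int mask5 = (1 << 10) - 1;   // 4^5 - 1
  for (int t = 0; t < T; ++t) {
    int b = s[t];
    if (b < 0 || b > 3) stop("sequence contains a non-ACGT base");
    int ord = t < 5 ? t : 5;
    int c = ctx & ((1 << (2 * ord)) - 1);
    out[t] = tp[ord][c + nr[ord] * b];
    ctx = ((ctx << 2) | b) & mask5;
  }
  return out;
}

struct CumEmis {
  std::vector<long double> bg, me3, h3;  // leading-zero cumulative sums
  const NumericVector lbg;
  CumEmis(const NumericVector& lbg_, const NumericVector& lme3,
          const NumericVector& lh3)
      : lbg(lbg_) {
    const int T = lbg_.size();
    bg.resize(T + 1); me3.resize(T + 1); h3.resize(T + 1);
    long double a = 0, b = 0, c = 0;
    bg[0] = me3[0] = h3[0] = 0.0;
    for (int t = 0; t < T; ++t) {
      a += lbg_[t]; b += lme3[t]; c += lh3[t];
      bg[t + 1] = a; me3[t + 1] = b; h3[t + 1] = c;
    }
  }
};

static std::vector<long double> forward_rec(const CumEmis& E, int T, int L,
                                       double ld, double l1md,
                                       double lrho, double l1mrho) {
  std::vector<long double> lf(T + 1);
  lf[0] = 0.0;
  for (int u = 1; u <= T; ++u) {
    long double fr = lf[u - 1] + ld + E.lbg[u - 1];
    long double me = -INFINITY, h3 = -INFINITY;
    if (u >= L) {
      long double base = lf[u - L] + l1md;
      me = base + lrho + (E.me3[u] - E.me3[u - L]);
      h3 = base + l1mrho + (E.h3[u] - E.h3[u - L]);
    }
    lf[u] = lse3(fr, me, h3);
  }
  return lf;
}

static std::vector<long double> backward_rec(const CumEmis& E, int T, int L,
                                        double ld, double l1md,
                                        double lrho, double l1mrho) {
  std::vector<long double> lb(T + 1);
  lb[T] = 0.0;
  for (int u = T - 1; u >= 0; --u) {
    long double fr = ld + E.lbg[u] + lb[u + 1];
    long double me = -INFINITY, h3 = -INFINITY;
    if (u + L <= T) {
      me = l1md + lrho + (E.me3[u + L] - E.me3[u]) + lb[u + L];
      h3 = l1md + l1mrho + (E.h3[u + L] - E.h3[u]) + lb[u + L];
    }
    lb[u] = lse3(fr, me, h3);
  }
  return lb;
}

// Log forward values over decision points; lf[u] = log P(S_1..S_u, the
// chain is at a decision point after position u).  loglik = lf[T].
// [[Rcpp::export]]
List renewal_forward_cpp(NumericVector lbg, NumericVector lme3,
                         NumericVector lh3, int L, double ld, double l1md,
                         double lrho, double l1mrho) {
  const int T = lbg.size();
  CumEmis E(lbg, lme3, lh3);
  std::vector<long double> lf = forward_rec(E, T, L, ld, l1md, lrho, l1mrho);
  return List::create(_["log_forward"] = NumericVector(lf.begin(), lf.end()),
                      _["loglik"] = (double)lf[T]);
}

// Log backward values: lb[u] = log P(S_{u+1}..S_T | decision point after
// position u).  loglik = lb[0].
// [[Rcpp::export]]
List renewal_backward_cpp(NumericVector lbg, NumericVector lme3,
                          NumericVector lh3, int L, double ld, double l1md,
                          double lrho, double l1mrho) {
  const int T = lbg.size();
  CumEmis E(lbg, lme3, lh3);
  std::vector<long double> lb = backward_rec(E, T, L, ld, l1md, lrho, l1mrho);
  return List::create(_["log_backward"] = NumericVector(lb.begin(), lb.end()),
                      _["loglik"] = (double)lb[0]);
}

// Per-base posterior occupancy probabilities.  For each legal nucleosome
// start u (1-based), the start posterior is
//   exp(lf[u-1] + log(1-d) + log(rho) + sum of state log emissions over
//       [u, u+L-1] + lb[u+L-1] - loglik),
// and the probability that base t is covered by that state is the sum of
// start posteriors over u in [t-L+1, t] (computed as a difference of
// long-double prefix sums).  The free posterior is computed directly from
// lf/lb, so conservation (me3 + h3 + free = 1) is a genuine numerical
// check, not an identity by construction.
// [[Rcpp::export]]
List renewal_posterior_cpp(NumericVector lbg, NumericVector lme3,
                           NumericVector lh3, int L, double ld, double l1md,
                           double lrho, double l1mrho) {
  const int T = lbg.size();
  CumEmis E(lbg, lme3, lh3);
  std::vector<long double> lf = forward_rec(E, T, L, ld, l1md, lrho, l1mrho);
  std::vector<long double> lb = backward_rec(E, T, L, ld, l1md, lrho, l1mrho);
  const long double loglik = lf[T];

  const int nstart = T - L + 1;  // may be <= 0: no nucleosome fits
  std::vector<long double> cs_me3(std::max(nstart, 0) + 1, 0.0),
      cs_h3(std::max(nstart, 0) + 1, 0.0);
  long double acc_m = 0, acc_h = 0;
  for (int u = 1; u <= nstart; ++u) {
    long double base = lf[u - 1] + l1md + lb[u + L - 1] - loglik;
    long double sm = lrho == R_NegInf ? -INFINITY
                : base + lrho + (E.me3[u + L - 1] - E.me3[u - 1]);
    long double sh = l1mrho == R_NegInf ? -INFINITY
                : base + l1mrho + (E.h3[u + L - 1] - E.h3[u - 1]);
    acc_m += sm == -INFINITY ? 0.0L : expl(sm);
    acc_h += sh == -INFINITY ? 0.0L : expl(sh);
    cs_me3[u] = acc_m;
    cs_h3[u] = acc_h;
  }
  NumericVector pme3(T), ph3(T), pfree(T);
  for (int t = 1; t <= T; ++t) {
    int hi = std::min(t, nstart), lo = std::max(0, t - L);
    if (hi > lo) {
      pme3[t - 1] = (double)(cs_me3[hi] - cs_me3[lo]);
      ph3[t - 1] = (double)(cs_h3[hi] - cs_h3[lo]);
    }
    pfree[t - 1] =
        (double)expl(lf[t - 1] + ld + E.lbg[t - 1] + lb[t] - loglik);
  }
  return List::create(_["p_me3"] = pme3, _["p_h3"] = ph3,
                      _["p_free"] = pfree, _["loglik"] = (double)loglik);
}

// Sample a genome and nucleosome arrangement from the generative model.
// At each decision point: free base with probability d, else a nucleosome
// (H3K4me3 with probability rho) provided L bases still fit before T
// (otherwise forced free).  Bases are emitted from the active state's
// conditional tables (probability scale; element j+1 = order j) using the
// running context.  Uses R's RNG, so results are reproducible under
// set.seed().
// [[Rcpp::export]]
List sim_genome_cpp(int T, int L, double d, double rho, List tabs_bg,
                    List tabs_me3, List tabs_h3) {
  IntegerVector s(T);
  std::vector<int> starts, types;  // 0-based start, type 1 = me3, 2 = h3
  std::vector<std::vector<const double*> > tp(3, std::vector<const double*>(6));
  std::vector<std::vector<int> > nr(3, std::vector<int>(6));
  for (int j = 0; j < 6; ++j) {
    NumericMatrix mb = tabs_bg[j], mm = tabs_me3[j], mh = tabs_h3[j];
    tp[0][j] = REAL(mb); nr[0][j] = mb.nrow();
    tp[1][j] = REAL(mm); nr[1][j] = mm.nrow();
    tp[2][j] = REAL(mh); nr[2][j] = mh.nrow();
  }
  int ctx = 0;
  const int mask5 = (1 << 10) - 1;
  int t = 0;
  while (t < T) {
    bool nuc = unif_rand() >= d;
    if (nuc && t + L > T) nuc = false;  // forced free at the right edge
    int state = 0, span = 1;
    if (nuc) {
      state = unif_rand() < rho ? 1 : 2;
      span = L;
      starts.push_back(t);
      types.push_back(state);
    }
    for (int i = 0; i < span; ++i, ++t) {
      int ord = t < 5 ? t : 5;
      int c = ctx & ((1 << (2 * ord)) - 1);
      const double* row = tp[state][ord];
      int n = nr[state][ord];
      double u = unif_rand(), cum = 0.0;
      int b = 3;
      for (int bb = 0; bb < 4; ++bb) {
        cum += row[c + n * bb];
        if (u < cum) { b = bb; break; }
      }
      s[t] = b;
      ctx = ((ctx << 2) | b) & mask5;
    }
  }
  return List::create(_["seq"] = s,
                      _["starts"] = IntegerVector(starts.begin(), starts.end()),
                      _["types"] = IntegerVector(types.begin(), types.end()));
}
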