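#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Poisson-binomial machinery for pairwise co-occurrence counts.
//
// For a pair of taxa the null co-occurrence count over M samples is a sum of
// independent Bernoulli draws with per-sample success probability
// w_m = pi_im * pi_jm.  The exact distribution P(n | M) follows the recursion
//   P(n|m) = P(n|m-1) (1 - w_m) + P(n-1|m-1) w_m,   P(0|0) = 1.
// Samples with w_m = 0 leave the distribution unchanged, so the DP runs over
// the K positive-probability samples only and the support is 0..K.

static const double TAIL_UNDERFLOW = 1e-280;
static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double log_add(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

// linear-space DP over positive weights; returns vector of length K + 1
static std::vector<double> pb_dp(const std::vector<double>& w) {
  const int K = (int)w.size();
  std::vector<double> P(K + 1, 0.0);
  P[0] = 1.0;
  int cur = 0;
  for (int m = 0; m < K; ++m) {
    const double wm = w[m], vm = 1.0 - wm;
    ++cur;
    P[cur] = P[cur - 1] * wm;
    for (int n = cur - 1; n >= 1; --n) P[n] = P[n] * vm + P[n - 1] * wm;
    P[0] *= vm;
  }
  return P;
}

// log-space DP, used only when a requested tail underflows linear doubles
static std::vector<double> pb_dp_log(const std::vector<double>& w) {
  const int K = (int)w.size();
  std::vector<double> lp(K + 1, NEG_INF);
  lp[0] = 0.0;
  int cur = 0;
  for (int m = 0; m < K; ++m) {
    const double lw = std::log(w[m]), lv = std::log1p(-w[m]);
    ++cur;
    lp[cur] = lp[cur - 1] + lw;
    for (int n = cur - 1; n >= 1; --n)
      lp[n] = log_add(lp[n] + lv, lp[n - 1] + lw);
    lp[0] += lv;
  }
  return lp;
}

static double log_sum_range(const std::vector<double>& lp, int from, int to) {
  double s = NEG_INF;
  for (int n = from; n <= to; ++n) s = log_add(s, lp[n]);
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_pb_dist(NumericVector joint_probs) {
  const int M = joint_probs.size();
  std::vector<double> w;
  w.reserve(M);
  for (int m = 0; m < M; ++m) {
    double x = joint_probs[m];
    if (ISNAN(x) || x < 0.0 || x > 1.0)
      stop("joint probability out of [0, 1] at position %d", m + 1);
    if (x > 0.0) w.push_back(x);
  }
  std::vector<double> P = pb_dp(w);
  NumericVector out(M + 1);           // zero beyond the feasible support
  for (size_t n = 0; n < P.size(); ++n) out[n] = P[n];
  return out;
}

struct TailResult {
  double log_upper;   // log P(n >= n_obs)
  double log_lower;   // log P(n <= n_obs)
  double p_at_n;      // P(n = n_obs)
  int n_max;
};

static TailResult pb_tails(const std::vector<double>& w, int n_obs) {
  const int K = (int)w.size();
  TailResult r;
  r.n_max = K;
  if (n_obs > K) {  // observation outside feasible support
    r.log_upper = NEG_INF;
    r.log_lower = 0.0;
    r.p_at_n = 0.0;
    return r;
  }
  std::vector<double> P = pb_dp(w);
  double upper = 0.0, lower = 0.0;
  for (int n = K; n >= n_obs; --n) upper += P[n];
  for (int n = 0; n <= n_obs; ++n) lower += P[n];
  if (upper > 1.0) upper = 1.0;
  if (lower > 1.0) lower = 1.0;
  r.p_at_n = P[n_obs];
  bool need_log = (upper < TAIL_UNDERFLOW) || (lower < TAIL_UNDERFLOW);
  if (!need_log) {
    r.log_upper = std::log(upper);
    r.log_lower = std::log(lower);
  } else {
    std::vector<double> lp = pb_dp_log(w);
    r.log_upper = log_sum_range(lp, n_obs, K);
    r.log_lower = log_sum_range(lp, 0, n_obs);
    if (r.log_upper > 0.0) r.log_upper = 0.0;
    if (r.log_lower > 0.0) r.log_lower = 0.0;
    r.p_at_n = std::exp(lp[n_obs]);
  }
  return r;
}

// [[Rcpp::export]]
List cpp_pb_tails(NumericVector joint_probs, int n_obs) {
  const int M = joint_probs.size();
  std::vector<double> w;
  w.reserve(M);
  for (int m = 0; m < M; ++m) {
    double x = joint_probs[m];
    if (ISNAN(x) || x < 0.0 || x > 1.0)
      stop("joint probability out of [0, 1] at position %d", m + 1);
    if (x > 0.0) w.push_back(x);
  }
  if (n_obs < 0 || n_obs > M) stop("n_obs must lie in 0..M");
  TailResult r = pb_tails(w, n_obs);
  return List::create(_["S_agg"] = -r.log_upper, _["S_seg"] = -r.log_lower,
                      _["p_at_n"] = r.p_at_n, _["n_max"] = r.n_max);
}

// All unordered row pairs of Pi / X: n_obs, tail scores, detectability limits.
// Columns: i, j, n_obs, S_agg, S_seg, p_at_n, n_max, S_agg_limit, S_seg_limit
// S_agg_limit = -log P(n = n_max) (always co-occur), S_seg_limit = -log P(0).
// [[Rcpp::export]]
NumericMatrix cpp_all_pair_scores(NumericMatrix Pi, IntegerMatrix X) {
  const int N = Pi.nrow(), M = Pi.ncol();
  if (X.nrow() != N || X.ncol() != M) stop("Pi and X dimensions disagree");
  const int n_pairs = N * (N - 1) / 2;
  NumericMatrix out(n_pairs, 9);
  std::vector<double> w;
  w.reserve(M);
  int row = 0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      w.clear();
      int n_obs = 0;
      double log_all = 0.0, log_none = 0.0;
      for (int m = 0; m < M; ++m) {
        const double wm = Pi(i, m) * Pi(j, m);
        if (wm > 0.0) {
          w.push_back(wm);
          log_all += std::log(wm);
          log_none += std::log1p(-wm);
        }
        if (X(i, m) == 1 && X(j, m) == 1) ++n_obs;
      }
      TailResult r = pb_tails(w, n_obs);
      out(row, 0) = i + 1;
      out(row, 1) = j + 1;
      out(row, 2) = n_obs;
      out(row, 3) = -r.log_upper;
      out(row, 4) = -r.log_lower;
      out(row, 5) = r.p_at_n;
      out(row, 6) = r.n_max;
      out(row, 7) = (r.n_max == 0) ? 0.0 : -log_all;
      out(row, 8) = (r.n_max == 0) ? 0.0 : -log_none;
      ++row;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
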