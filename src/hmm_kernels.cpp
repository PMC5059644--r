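#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Log-domain HMM recursions over an explicit arc-list graph.
//
// A graph has S emitting states, each tagged with a pdf index into the
// columns of `logobs` (T x P, per-frame log emission densities), `start`
// and `final` log-probability vectors of length S, and A arcs
// (from, to, logp).  All indices are 0-based on the C++ side.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logadd(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

static void run_forward(const NumericMatrix& logobs, const IntegerVector& pdf,
                        const NumericVector& start, const IntegerVector& from,
                        const IntegerVector& to, const NumericVector& alogp,
                        NumericMatrix& alpha) {
  const int T = alpha.nrow(), S = alpha.ncol(), A = from.size();
  for (int s = 0; s < S; ++s)
    alpha(0, s) = (start[s] == NEG_INF) ? NEG_INF
                                        : start[s] + logobs(0, pdf[s]);
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) alpha(t, s) = NEG_INF;
    for (int a = 0; a < A; ++a) {
      double v = alpha(t - 1, from[a]);
      if (v == NEG_INF) continue;
      alpha(t, to[a]) = logadd(alpha(t, to[a]), v + alogp[a]);
    }
    for (int s = 0; s < S; ++s)
      if (alpha(t, s) != NEG_INF) alpha(t, s) += logobs(t, pdf[s]);
  }
}

// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix logobs, IntegerVector pdf,
                          NumericVector start, NumericVector final_lp,
                          IntegerVector arc_from, IntegerVector arc_to,
                          NumericVector arc_logp) {
  const int T = logobs.nrow(), S = pdf.size();
  if (T == 0) return NEG_INF;
  NumericMatrix alpha(T, S);
  run_forward(logobs, pdf, start, arc_from, arc_to, arc_logp, alpha);
  double ll = NEG_INF;
  for (int s = 0; s < S; ++s)
    if (final_lp[s] != NEG_INF && alpha(T - 1, s) != NEG_INF)
      ll = logadd(ll, alpha(T - 1, s) + final_lp[s]);
  return ll;
}

// Forward-backward pass: returns total log-likelihood, per-frame state
// occupancies gamma (T x S), expected transition counts per arc (A), and
// the exit occupancy per state (weight of ending in s at the last frame).
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix logobs, IntegerVector pdf,
                          NumericVector start, NumericVector final_lp,
                          IntegerVector arc_from, IntegerVector arc_to,
                          NumericVector arc_logp) {
  const int T = logobs.nrow(), S = pdf.size(), A = arc_from.size();
  NumericMatrix alpha(T, S), beta(T, S);
  run_forward(logobs, pdf, start, arc_from, arc_to, arc_logp, alpha);

  double ll = NEG_INF;
  for (int s = 0; s < S; ++s)
    if (final_lp[s] != NEG_INF && alpha(T - 1, s) != NEG_INF)
      ll = logadd(ll, alpha(T - 1, s) + final_lp[s]);

  NumericMatrix gamma(T, S);
  NumericVector arc_post(A), final_post(S);
  if (ll == NEG_INF) {
    return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                        _["arc_post"] = arc_post,
                        _["final_post"] = final_post);
  }

  for (int s = 0; s < S; ++s) beta(T - 1, s) = final_lp[s];
  for (int t = T - 2; t >= 0; --t) {
    for (int s = 0; s < S; ++s) beta(t, s) = NEG_INF;
    for (int a = 0; a < A; ++a) {
      double v = beta(t + 1, arc_to[a]);
      if (v == NEG_INF) continue;
      double w = arc_logp[a] + logobs(t + 1, pdf[arc_to[a]]) + v;
      beta(t, arc_from[a]) = logadd(beta(t, arc_from[a]), w);
    }
  }

  for (int t = 0; t < T; ++t)
    for (int s = 0; s < S; ++s) {
      double g = alpha(t, s) + beta(t, s) - ll;
      gamma(t, s) = (alpha(t, s) == NEG_INF || beta(t, s) == NEG_INF)
                        ? 0.0 : std::exp(g);
    }

  for (int a = 0; a < A; ++a) {
    double acc = 0.0;
    for (int t = 0; t + 1 < T; ++t) {
      double av = alpha(t, arc_from[a]);
      double bv = beta(t + 1, arc_to[a]);
      if (av == NEG_INF || bv == NEG_INF) continue;
      acc += std::exp(av + arc_logp[a] + logobs(t + 1, pdf[arc_to[a]]) +
                      bv - ll);
    }
    arc_post[a] = acc;
  }
  for (int s = 0; s < S; ++s) {
    if (final_lp[s] == NEG_INF || alpha(T - 1, s) == NEG_INF)
      final_post[s] = 0.0;
    else
      final_post[s] = std::exp(alpha(T - 1, s) + final_lp[s] - ll);
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["arc_post"] = arc_post, _["final_post"] = final_post);
}

// Viterbi decoding with arc traceback.  Keeps only two rows of scores (the
// backtrace needs the per-frame best-arc table psi, T x S ints).  An
// optional beam prunes states whose score falls more than `beam` below the
// frame maximum; beam = Inf is exact search.  Returns the best final
// score, the state path (1-based, length T) and the arc path (1-based
// indices, length T-1); empty vectors when no complete path exists.
// [[Rcpp::export]]
List viterbi_cpp(NumericMatrix logobs, IntegerVector pdf,
                 NumericVector start, NumericVector final_lp,
                 IntegerVector arc_from, IntegerVector arc_to,
                 NumericVector arc_logp, double beam) {
  const int T = logobs.nrow(), S = pdf.size(), A = arc_from.size();
  if (T == 0)
    return List::create(_["score"] = NEG_INF, _["path"] = IntegerVector(0),
                        _["arcs"] = IntegerVector(0));
  std::vector<double> prev(S), cur(S);
  IntegerMatrix psi(T, S);  // arc index (0-based) taken into (t, s); -1 none
  for (int s = 0; s < S; ++s) {
    prev[s] = (start[s] == NEG_INF) ? NEG_INF : start[s] + logobs(0, pdf[s]);
    psi(0, s) = -1;
  }
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) { cur[s] = NEG_INF; psi(t, s) = -1; }
    for (int a = 0; a < A; ++a) {
      double v = prev[arc_from[a]];
      if (v == NEG_INF) continue;
      double cand = v + arc_logp[a];
      if (cand > cur[arc_to[a]]) {
        cur[arc_to[a]] = cand;
        psi(t, arc_to[a]) = a;
      }
    }
    double mx = NEG_INF;
    for (int s = 0; s < S; ++s) {
      if (cur[s] != NEG_INF) {
        cur[s] += logobs(t, pdf[s]);
        if (cur[s] > mx) mx = cur[s];
      }
    }
    if (R_finite(beam) && mx != NEG_INF) {
      const double cut = mx - beam;
      for (int s = 0; s < S; ++s)
        if (cur[s] < cut) cur[s] = NEG_INF;
    }
    std::swap(prev, cur);
  }
  double best = NEG_INF;
  int best_s = -1;
  for (int s = 0; s < S; ++s) {
    if (final_lp[s] == NEG_INF || prev[s] == NEG_INF) continue;
    double v = prev[s] + final_lp[s];
    if (v > best) { best = v; best_s = s; }
  }
  if (best_s < 0)
    return List::create(_["score"] = NEG_INF, _["path"] = IntegerVector(0),
                        _["arcs"] = IntegerVector(0));
  IntegerVector path(T), arcs(T > 1 ? T - 1 : 0);
  int s = best_s;
  for (int t = T - 1; t >= 0; --t) {
    path[t] = s + 1;
    int a = psi(t, s);
    if (t > 0) {
      arcs[t - 1] = a + 1;
      s = arc_from[a];
    }
  }
  return List::create(_["score"] = best, _["path"] = path, _["arcs"] = arcs);
}
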