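#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning for the symmetric k-state Mk model with discrete-gamma
// rate heterogeneity, on rooted trees with arbitrary multifurcations.
//
// The per-character generator is the k-state symmetric matrix with
// off-diagonal rate 1/(k-1), scaled so the expected number of substitutions
// per unit branch length is 1:
//   P(same, t) = 1/k + (k-1)/k * exp(-t * k/(k-1))
//   P(diff, t) = 1/k -   1/k   * exp(-t * k/(k-1))
// Tip state sets enter as partial likelihoods of 1 on every allowed state.
// Underflow is handled by per-node rescaling of partials; category
// likelihoods are combined on the log scale.
//
// `brlen[v]` is the length of the branch above node v (ignored for root).

static inline void pmat(double t, int k, double &psame, double &pdiff) {
  double e = std::exp(-t * k / (k - 1.0));
  psame = 1.0 / k + (k - 1.0) / k * e;
  pdiff = 1.0 / k - e / k;
}

// log-likelihood of one pattern (bitmask per tip) for one category rate
static double pattern_loglik_cat(const std::vector<int> &masks,
                                 int k,
                                 IntegerVector internalPost,
                                 IntegerVector childVec,
                                 IntegerVector childOff,
                                 NumericVector brlen,
                                 double rate) {
  const int nTip = masks.size();
  const int nInt = internalPost.size();
  const int nNodes = nTip + nInt;
  const int root = internalPost[nInt - 1];
  std::vector<double> part(nNodes * 16);
  double logscale = 0.0;

  for (int t = 0; t < nTip; t++)
    for (int s = 0; s < k; s++)
      part[t * 16 + s] = (masks[t] >> s) & 1 ? 1.0 : 0.0;

  for (int i = 0; i < nInt; i++) {
    const int v = internalPost[i];
    double *pv = &part[v * 16];
    for (int s = 0; s < k; s++) pv[s] = 1.0;
    for (int c = childOff[i]; c < childOff[i + 1]; c++) {
      const int w = childVec[c];
      const double *pw = &part[w * 16];
      double psame, pdiff;
      pmat(brlen[w] * rate, k, psame, pdiff);
      double sum = 0.0;
      for (int s = 0; s < k; s++) sum += pw[s];
      for (int s = 0; s < k; s++) {
        // psame*pw[s] + pdiff*(sum - pw[s])
        pv[s] *= pdiff * sum + (psame - pdiff) * pw[s];
      }
    }
    double mx = 0.0;
    for (int s = 0; s < k; s++) if (pv[s] > mx) mx = pv[s];
    if (mx <= 0.0) return R_NegInf;
    for (int s = 0; s < k; s++) pv[s] /= mx;
    logscale += std::log(mx);
  }
  double L = 0.0;
  const double *pr = &part[root * 16];
  for (int s = 0; s < k; s++) L += pr[s] / k;
  return std::log(L) + logscale;
}

static double logsumexp(const std::vector<double> &x) {
  double mx = R_NegInf;
  for (double v : x) if (v > mx) mx = v;
  if (!R_finite(mx)) return mx;
  double s = 0.0;
  for (double v : x) s += std::exp(v - mx);
  return mx + std::log(s);
}

// [[Rcpp::export]]
List mk_loglik_cpp(IntegerMatrix tipMasks,
                   IntegerVector nStates,
                   IntegerVector internalPost,
                   IntegerVector childVec,
                   IntegerVector childOff,
                   NumericVector brlen,
                   NumericVector catRates,
                   bool conditionVariable) {
  const int nTip = tipMasks.nrow();
  const int nChar = tipMasks.ncol();
  const int nCat = catRates.size();
  NumericVector ll(nChar);

  // per-character mixture log-likelihood
  for (int c = 0; c < nChar; c++) {
    const int k = nStates[c];
    std::vector<int> masks(nTip);
    for (int t = 0; t < nTip; t++) masks[t] = tipMasks(t, c);
    std::vector<double> percat(nCat);
    for (int g = 0; g < nCat; g++)
      percat[g] = pattern_loglik_cat(masks, k, internalPost, childVec,
                                     childOff, brlen, catRates[g]);
    ll[c] = logsumexp(percat) - std::log((double)nCat);
  }

  // Mkv conditioning: divide by P(variable | k) per state-count class
  NumericVector logPvar(nChar);
  if (conditionVariable) {
    std::map<int, double> cache;
    for (int c = 0; c < nChar; c++) {
      const int k = nStates[c];
      if (!cache.count(k)) {
        // P(constant) = k * P(all tips in state 0), by symmetry
        std::vector<int> masks(nTip, 1);  // all tips = state 0
        std::vector<double> percat(nCat);
        for (int g = 0; g < nCat; g++)
          percat[g] = pattern_loglik_cat(masks, k, internalPost, childVec,
                                         childOff, brlen, catRates[g]);
        double logPconst =
            std::log((double)k) + logsumexp(percat) - std::log((double)nCat);
        cache[k] = logPconst >= 0 ? R_NegInf : std::log1p(-std::exp(logPconst));
      }
      logPvar[c] = cache[k];
      ll[c] -= logPvar[c];
    }
  }

  double tot = 0.0;
  for (int c = 0; c < nChar; c++) tot += ll[c];
  return List::create(_["per_char"] = ll, _["total"] = tot,
                      _["log_p_variable"] = logPvar);
}

#include "ptree.h"

// Likelihood on a parent-vector tree with per-node branch lengths (the MCMC
// hot path; brlen[v-1] is the branch above node v, ignored for the root).
// [[Rcpp::export]]
double ptree_mk_loglik_cpp(IntegerVector parent, int nTip,
                           IntegerMatrix tipMasks, IntegerVector nStates,
                           NumericVector brlen, NumericVector catRates,
                           bool conditionVariable) {
  std::vector<int> ip, cv, co;
  ptree_csr_build(parent, nTip, ip, cv, co);
  List res = mk_loglik_cpp(tipMasks, nStates,
                           IntegerVector(ip.begin(), ip.end()),
                           IntegerVector(cv.begin(), cv.end()),
                           IntegerVector(co.begin(), co.end()),
                           brlen, catRates, conditionVariable);
  return as<double>(res["total"]);
}

// P(character is variable) for a given state count, tree and gamma rates.
// [[Rcpp::export]]
double p_variable_cpp(int k,
                      int nTip,
                      IntegerVector internalPost,
                      IntegerVector childVec,
                      IntegerVector childOff,
                      NumericVector brlen,
                      NumericVector catRates) {
  const int nCat = catRates.size();
  std::vector<int> masks(nTip, 1);
  std::vector<double> percat(nCat);
  for (int g = 0; g < nCat; g++)
    percat[g] = pattern_loglik_cat(masks, k, internalPost, childVec,
                                   childOff, brlen, catRates[g]);
  double logPconst =
      std::log((double)k) + logsumexp(percat) - std::log((double)nCat);
  double p = 1.0 - std::exp(logPconst);
  return p < 0 ? 0.0 : p;
}
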