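// Core computations for the semiparametric rate-based estimating equations:
// profile partial score, observed information, log partial likelihood,
// Breslow baseline increments and per-subject score residuals, on
// counting-process (start, stop] data with (time-dependent) strata.
//
// Risk-set convention: a row (start, stop] is at risk at event time t when
// start < t <= stop.  Ties share the risk-set denominator (Breslow).

#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".ag_score")]]
List ag_score(const arma::vec& start,
              const arma::vec& stop,
              const arma::ivec& status,
              const arma::ivec& stratum,
              const arma::mat& X,
              const arma::ivec& subject,   // 0-based subject index
              int nSubjects,
              const arma::vec& beta,
              bool doExtra) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec eta = X * beta;
  arma::vec w = arma::exp(eta);

  arma::vec score(p, arma::fill::zeros);
  arma::mat info(p, p, arma::fill::zeros);
  double loglik = 0.0;
  int nevent = 0;

  arma::mat W;                       // per-subject score residuals
  if (doExtra) W.zeros(nSubjects, p);
  std::vector<double> bl_time;       // Breslow baseline steps
  std::vector<int> bl_str;
  std::vector<double> bl_inc;

  // group rows by stratum
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return stratum[a] < stratum[b];
  });

  int gs = 0;
  while (gs < n) {
    int ge = gs;
    const int str = stratum[ord[gs]];
    while (ge < n && stratum[ord[ge]] == str) ++ge;
    const int m = ge - gs;
    std::vector<int> rows(ord.begin() + gs, ord.begin() + ge);
    gs = ge;

    // distinct event times, descending, with tied-event row lists
    std::vector<int> evRows;
    for (int r : rows) if (status[r] == 1) evRows.push_back(r);
    if (evRows.empty()) continue;    // stratum contributes nothing
    std::sort(evRows.begin(), evRows.end(), [&](int a, int b) {
      return stop[a] > stop[b];
    });

    std::vector<int> byStop(rows), byStart(rows);
    std::sort(byStop.begin(), byStop.end(), [&](int a, int b) {
      return stop[a] > stop[b];
    });
    std::sort(byStart.begin(), byStart.end(), [&](int a, int b) {
      return start[a] > start[b];
    });

    double s0 = 0.0;
    arma::vec s1(p, arma::fill::zeros);
    arma::mat s2(p, p, arma::fill::zeros);
    size_t iAdd = 0, iRem = 0;

    // per distinct event time (ascending order filled later)
    std::vector<double> ut, dmu;
    std::vector<arma::vec> xbars;

    size_t ie = 0;
    while (ie < evRows.size()) {
      const double t = stop[evRows[ie]];
      // add rows with stop >= t
      while (iAdd < byStop.size() && stop[byStop[iAdd]] >= t) {
        const int r = byStop[iAdd++];
        s0 += w[r];
        s1 += w[r] * X.row(r).t();
        if (p) s2 += w[r] * (X.row(r).t() * X.row(r));
      }
      // remove rows with start >= t (not at risk: need start < t)
      while (iRem < byStart.size() && start[byStart[iRem]] >= t) {
        const int r = byStart[iRem++];
        s0 -= w[r];
        s1 -= w[r] * X.row(r).t();
        if (p) s2 -= w[r] * (X.row(r).t() * X.row(r));
      }
      // tied events at t
      int d = 0;
      arma::vec xsum(p, arma::fill::zeros);
      double etasum = 0.0;
      while (ie < evRows.size() && stop[evRows[ie]] == t) {
        const int r = evRows[ie++];
        ++d;
        xsum += X.row(r).t();
        etasum += eta[r];
      }
      nevent += d;
      const arma::vec xbar = s1 / s0;
      score += xsum - double(d) * xbar;
      info += double(d) * (s2 / s0 - xbar * xbar.t());
      loglik += etasum - double(d) * std::log(s0);
      if (doExtra) {
        ut.push_back(t);
        dmu.push_back(double(d) / s0);
        xbars.push_back(xbar);
        // own-event part of the score residuals
        size_t je = ie - d;
        for (int k = 0; k < d; ++k) {
          const int r = evRows[je + k];
          W.row(subject[r]) += (X.row(r).t() - xbar).t();
        }
      }
    }

    if (doExtra) {
      // ascending prefix sums of dmu and xbar*dmu over distinct event times
      std::reverse(ut.begin(), ut.end());
      std::reverse(dmu.begin(), dmu.end());
      std::reverse(xbars.begin(), xbars.end());
      const int ne = ut.size();
      std::vector<double> cumL(ne + 1, 0.0);
      arma::mat cumPsi(ne + 1, p, arma::fill::zeros);
      for (int k = 0; k < ne; ++k) {
        cumL[k + 1] = cumL[k] + dmu[k];
        cumPsi.row(k + 1) = cumPsi.row(k) + dmu[k] * xbars[k].t();
        bl_time.push_back(ut[k]);
        bl_str.push_back(str);
        bl_inc.push_back(dmu[k]);
      }
      // compensator part: event times in (start, stop]
      for (int r : rows) {
        // index of first event time > start, and of last <= stop
        const int lo = std::upper_bound(ut.begin(), ut.end(), start[r]) - ut.begin();
        const int hi = std::upper_bound(ut.begin(), ut.end(), stop[r]) - ut.begin();
        if (hi <= lo) continue;
        const double dL = cumL[hi] - cumL[lo];
        const arma::rowvec dPsi = cumPsi.row(hi) - cumPsi.row(lo);
        W.row(subject[r]) -= w[r] * (X.row(r) * dL - dPsi);
      }
    }
  }

  List out = List::create(
    Named("score") = score,
    Named("info") = info,
    Named("loglik") = loglik,
    Named("nevent") = nevent);
  if (doExtra) {
    out["residuals"] = W;
    out["baselineTime"] = bl_time;
    out["baselineStratum"] = bl_str;
    out["baselineInc"] = bl_inc;
  }
  return out;
}
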