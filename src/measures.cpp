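#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Detrended fluctuation per scale on an integrated profile.
// For each window length L: split `profile` into windows advancing by
// L*(1-overlap) samples, remove each window's least-squares linear trend,
// take the SD (population) of the residual, and average across windows.
// Returns a list with the mean fluctuation and the window count per scale.
// [[Rcpp::export]]
List dfa_fluct_cpp(NumericVector profile, IntegerVector winlens, double overlap) {
  int n = profile.size();
  int ns = winlens.size();
  NumericVector fluct(ns, NA_REAL);
  IntegerVector nwin(ns, 0);
  for (int s = 0; s < ns; ++s) {
    int L = winlens[s];
    if (L < 4 || L > n) continue;
    int step = (int)std::lround(L * (1.0 - overlap));
    if (step < 1) step = 1;
    double tm = (L - 1) / 2.0;
    double stt = 0.0;
    for (int t = 0; t < L; ++t) stt += (t - tm) * (t - tm);
    double acc = 0.0;
    int nw = 0;
    for (int start = 0; start + L <= n; start += step) {
      double sy = 0.0, sty = 0.0, syy = 0.0;
      const double *p = &profile[start];
      const double c0 = p[0];  // center to avoid cancellation: profile is a cumsum
      for (int t = 0; t < L; ++t) {
        double y = p[t] - c0;
        sy += y;
        sty += (t - tm) * y;
        syy += y * y;
      }
      // residual SS of the linear fit in closed form
      double ss = syy - sy * sy / L - sty * sty / stt;
      if (ss < 0.0) ss = 0.0;
      acc += std::sqrt(ss / L);
      ++nw;
    }
    if (nw > 0) {
      fluct[s] = acc / nw;
      nwin[s] = nw;
    }
  }
  return List::create(_["fluct"] = fluct, _["nwin"] = nwin);
}

// Per-window amplitude (wAmp) and normalized detrended fluctuation (wDNF)
// for the fE/I statistic. Each window of length L (advancing by `step`
// samples): wAmp = mean envelope; the window's envelope is divided by wAmp,
// demeaned and integrated; wDNF = SD of the linearly detrended profile.
// [[Rcpp::export]]
List fei_windows_cpp(NumericVector env, int L, int step) {
  int n = env.size();
  int nw = (n >= L) ? (n - L) / step + 1 : 0;
  NumericVector wamp(nw), wdnf(nw);
  double tm = (L - 1) / 2.0;
  double stt = 0.0;
  for (int t = 0; t < L; ++t) stt += (t - tm) * (t - tm);
  std::vector<double> prof(L);
  for (int w = 0; w < nw; ++w) {
    int start = w * step;
    double sy = 0.0;
    for (int t = 0; t < L; ++t) sy += env[start + t];
    double amp = sy / L;
    wamp[w] = amp;
    if (amp <= 0.0) { wdnf[w] = NA_REAL; continue; }
    double c = 0.0;
    for (int t = 0; t < L; ++t) {
      c += env[start + t] / amp - 1.0;  // normalized envelope has mean 1
      prof[t] = c;
    }
    double pm = 0.0;
    for (int t = 0; t < L; ++t) pm += prof[t];
    pm /= L;
    double spt = 0.0;
    for (int t = 0; t < L; ++t) spt += (t - tm) * (prof[t] - pm);
    double b = spt / stt;
    double ss = 0.0;
    for (int t = 0; t < L; ++t) {
      double r = prof[t] - pm - b * (t - tm);
      ss += r * r;
    }
    wdnf[w] = std::sqrt(ss / L);
  }
  return List::create(_["wamp"] = wamp, _["wdnf"] = wdnf);
}
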