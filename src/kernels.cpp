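#include <Rcpp.h>
#include <R_ext/Random.h>
using namespace Rcpp;

// Gaussian deviates via the Marsaglia polar method on R's uniform
// stream: deterministic under set.seed and ~2x faster than inversion
// for the bulk noise draws the renderer needs.
static inline void fill_gauss(double *x, int n, double sd) {
  int i = 0;
  while (i < n) {
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s) * sd;
    x[i++] = u * f;
    if (i < n) x[i++] = v * f;
  }
}

// Render all channels of one session: white Gaussian noise (R RNG, so
// seeding behaves like any R draw), plus each neuron's template scaled
// by its per-channel amplitude at the given spike sample indices, then
// quantisation to 16-bit integer codes. Returns a time x channels
// matrix (contiguous per-channel columns); the caller transposes.
//
// spikeIdx: list of integer vectors (1-based trough sample indices)
// templates: list of numeric vectors
// ampMat: neurons x channels amplitude matrix (uV)
// [[Rcpp::export(name = ".renderChannels")]]
IntegerMatrix renderChannels(int nChannels, int nSamp, double noiseSd,
                             double gainUv, List spikeIdx, List templates,
                             NumericMatrix ampMat, double minAmpUv,
                             int preSamples) {
  int nNeurons = spikeIdx.size();
  IntegerMatrix out(nSamp, nChannels);
  std::vector<double> x(nSamp);
  RNGScope scope;

  for (int ch = 0; ch < nChannels; ch++) {
    if (noiseSd > 0) {
      fill_gauss(x.data(), nSamp, noiseSd);
    } else {
      std::fill(x.begin(), x.end(), 0.0);
    }
    for (int i = 0; i < nNeurons; i++) {
      double amp = ampMat(i, ch);
      if (amp < minAmpUv) continue;
      IntegerVector s = spikeIdx[i];
      if (s.size() == 0) continue;
      NumericVector w = templates[i];
      const double *pw = w.begin();
      int wlen = w.size();
      for (int k = 0; k < s.size(); k++) {
        int start = s[k] - 1 - preSamples; // 0-based window start
        int j0 = start < 0 ? -start : 0;
        int j1 = std::min(wlen, nSamp - start);
        for (int j = j0; j < j1; j++) x[start + j] += amp * pw[j];
      }
    }
    int *po = &out(0, ch);
    for (int t = 0; t < nSamp; t++) {
      double q = std::nearbyint(x[t] / gainUv);
      if (q > 32767.0) q = 32767.0;
      if (q < -32768.0) q = -32768.0;
      po[t] = (int)q;
    }
  }
  return out;
}

// One causal direct-form-I IIR pass, a[0] assumed 1.
// [[Rcpp::export(name = ".iirPass")]]
NumericVector iirPass(NumericVector b, NumericVector a, NumericVector x) {
  int n = x.size(), nb = b.size(), na = a.size();
  NumericVector y(n);
  const double *px = x.begin();
  double *py = y.begin();
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  int head = std::max(nb, na);
  for (int i = 0; i < std::min(head, n); i++) {
    double acc = 0.0;
    for (int j = 0; j <= std::min(i, nb - 1); j++) acc += bb[j] * px[i - j];
    for (int k = 1; k <= std::min(i, na - 1); k++) acc -= aa[k] * py[i - k];
    py[i] = acc;
  }
  for (int i = head; i < n; i++) {
    double acc = bb[0] * px[i];
    for (int j = 1; j < nb; j++) acc += bb[j] * px[i - j];
    for (int k = 1; k < na; k++) acc -= aa[k] * py[i - k];
    py[i] = acc;
  }
  return y;
}

// Threshold-crossing event scan: downward crossings of a negative
// threshold; event = minimum within the following postSamples window;
// crossings within deadTime samples of the last event are ignored;
// events whose snippet window would overrun the trace are dropped (but
// still claim dead time).
// [[Rcpp::export(name = ".detectScan")]]
IntegerVector detectScan(NumericVector x, double threshold, int preSamples,
                         int postSamples, int deadTime) {
  int n = x.size();
  const double *px = x.begin();
  std::vector<int> events;
  double lastEvent = -1e18;
  for (int i = 0; i < n; i++) {
    bool crossed = px[i] < threshold && (i == 0 || px[i - 1] >= threshold);
    if (!crossed) continue;
    if (i + 1 <= lastEvent + deadTime) continue; // 1-based comparison
    int hi = std::min(i + postSamples, n - 1);
    int trough = i;
    for (int j = i; j <= hi; j++) {
      if (px[j] < px[trough]) trough = j;
    }
    int trough1 = trough + 1; // 1-based
    lastEvent = trough1;
    if (trough1 - preSamples >= 1 && trough1 + postSamples - 1 <= n) {
      events.push_back(trough1);
    }
  }
  return wrap(events);
}

// Row-wise peak-to-trough amplitude and derivative-extrema width (in
// samples) for a snippet matrix: the QC quantities.
// [[Rcpp::export(name = ".qcStats")]]
NumericMatrix qcStats(NumericMatrix m) {
  int n = m.nrow(), w = m.ncol();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; i++) {
    double mn = m(i, 0), mx = m(i, 0);
    int amax = 0, amin = 0;
    double dmax = 0, dmin = 0;
    bool first = true;
    for (int j = 0; j < w; j++) {
      double v = m(i, j);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
      if (j > 0) {
        double d = v - m(i, j - 1);
        if (first || d > dmax) { dmax = d; amax = j; }
        if (first || d < dmin) { dmin = d; amin = j; }
        first = false;
      }
    }
    out(i, 0) = mx - mn;
    out(i, 1) = std::abs(amax - amin);
  }
  return out;
}

// One EM run for a 1-D Gaussian mixture from given initial means.
// Returns weights, means, sds, log-likelihood and a variance-floor
// flag. Component order follows the initialisation.
// [[Rcpp::export(name = ".emFit")]]
List emFit(NumericVector x, int k, NumericVector mu0, int maxIter,
           double tol, double varFloor) {
  int n = x.size();
  const double *px = x.begin();
  std::vector<double> w(k, 1.0 / k), mu(mu0.begin(), mu0.end()), var(k);
  double sx = 0, sxx = 0;
  for (int i = 0; i < n; i++) { sx += px[i]; sxx += px[i] * px[i]; }
  double v0 = sxx / n - (sx / n) * (sx / n);
  if (v0 < varFloor) v0 = varFloor;
  std::fill(var.begin(), var.end(), v0);

  std::vector<double> r(n * k), nk(k), sum1(k), sum2(k);
  const double log2pi = std::log(2.0 * M_PI);
  double ll = -1e300;
  bool floored = false;

  for (int iter = 0; iter < maxIter; iter++) {
    // E step in log space per observation
    double llNew = 0.0;
    for (int i = 0; i < n; i++) {
      double tot = 0.0;
      for (int j = 0; j < k; j++) {
        double z = px[i] - mu[j];
        double d = w[j] * std::exp(-0.5 * (z * z / var[j] +
                    std::log(var[j]) + log2pi));
        r[i * k + j] = d;
        tot += d;
      }
      if (tot < 1e-300) tot = 1e-300;
      for (int j = 0; j < k; j++) r[i * k + j] /= tot;
      llNew += std::log(tot);
    }
    // M step
    std::fill(nk.begin(), nk.end(), 0.0);
    std::fill(sum1.begin(), sum1.end(), 0.0);
    for (int i = 0; i < n; i++) {
      for (int j = 0; j < k; j++) {
        nk[j] += r[i * k + j];
        sum1[j] += r[i * k + j] * px[i];
      }
    }
    for (int j = 0; j < k; j++) {
      if (nk[j] < 1e-12) nk[j] = 1e-12;
      w[j] = nk[j] / n;
      mu[j] = sum1[j] / nk[j];
    }
    std::fill(sum2.begin(), sum2.end(), 0.0);
    for (int i = 0; i < n; i++) {
      for (int j = 0; j < k; j++) {
        double z = px[i] - mu[j];
        sum2[j] += r[i * k + j] * z * z;
      }
    }
    for (int j = 0; j < k; j++) {
      double v = sum2[j] / nk[j];
      if (v < varFloor) { v = varFloor; floored = true; }
      var[j] = v;
    }
    if (std::abs(llNew - ll) < tol && iter > 0) { ll = llNew; break; }
    ll = llNew;
  }
  NumericVector sd(k);
  for (int j = 0; j < k; j++) sd[j] = std::sqrt(var[j]);
  return List::create(_["w"] = w, _["mu"] = mu, _["sd"] = sd,
                      _["logLik"] = ll, _["floored"] = floored);
}

// Re-align each row so its minimum sits at (1-based) troughIndex,
// padding with the row's edge values.
// [[Rcpp::export(name = ".realignRows")]]
NumericMatrix realignRows(NumericMatrix m, int troughIndex) {
  int n = m.nrow(), w = m.ncol();
  NumericMatrix out(n, w);
  for (int i = 0; i < n; i++) {
    int amin = 0;
    for (int j = 1; j < w; j++) if (m(i, j) < m(i, amin)) amin = j;
    int shift = (troughIndex - 1) - amin;
    for (int j = 0; j < w; j++) {
      int src = j - shift;
      if (src < 0) src = 0;
      if (src >= w) src = w - 1;
      out(i, j) = m(i, src);
    }
  }
  return out;
}
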