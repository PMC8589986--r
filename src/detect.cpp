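// Signal-path primitives used by the click detector and the feature
// extractor: direct-form-II-transposed IIR filtering, the Teager-Kaiser
// energy chain, and run-based transient detection against a median noise
// floor.  Kept in C++ because the detector walks minutes of 500 kHz audio.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nw = std::max(nb, na) - 1;
  std::vector<double> w(nw, 0.0);
  NumericVector y(n);
  // normalize by a[0]
  std::vector<double> bb(nb), aa(na);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  for (int i = 0; i < n; ++i) {
    double yn = bb[0] * x[i] + (nw > 0 ? w[0] : 0.0);
    for (int k = 0; k < nw - 1; ++k) {
      double bk = (k + 1 < nb) ? bb[k + 1] : 0.0;
      double ak = (k + 1 < na) ? aa[k + 1] : 0.0;
      w[k] = bk * x[i] + w[k + 1] - ak * yn;
    }
    if (nw > 0) {
      double bk = (nw < nb) ? bb[nw] : 0.0;
      double ak = (nw < na) ? aa[nw] : 0.0;
      w[nw - 1] = bk * x[i] - ak * yn;
    }
    y[i] = yn;
  }
  return y;
}

// Teager-Kaiser energy psi[i] = x[i]^2 - x[i-1]*x[i+1]; ends set to 0.
// [[Rcpp::export(name = ".tk_energy_cpp")]]
NumericVector tk_energy_cpp(NumericVector x) {
  const int n = x.size();
  NumericVector psi(n);
  for (int i = 1; i < n - 1; ++i) psi[i] = x[i] * x[i] - x[i - 1] * x[i + 1];
  return psi;
}

// centred moving average with truncated edges
// [[Rcpp::export(name = ".boxcar_cpp")]]
NumericVector boxcar_cpp(NumericVector x, int width) {
  const int n = x.size();
  const int h = width / 2;
  NumericVector out(n);
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - h), hi = std::min(n - 1, i + h);
    out[i] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
  }
  return out;
}

// Detect transients in a smoothed TK-energy trace.  The noise floor is the
// median of the trace (estimated on a stride subsample for long inputs);
// runs exceeding floor * 10^(snr_db/10) yield one detection at the run's
// energy maximum, and detections closer than min_sep keep the larger peak.
// [[Rcpp::export(name = ".tk_detect_cpp")]]
List tk_detect_cpp(NumericVector energy, double snr_db, int min_sep) {
  const int n = energy.size();

  int stride = std::max(1, n / 1000000);
  std::vector<double> sub;
  sub.reserve(n / stride + 1);
  for (int i = 0; i < n; i += stride) sub.push_back(energy[i]);
  const size_t mid = sub.size() / 2;
  std::nth_element(sub.begin(), sub.begin() + mid, sub.end());
  double floor_est = sub[mid];
  if (floor_est <= 0) floor_est = 1e-300;  // silent recording: any energy fires

  const double thr = floor_est * std::pow(10.0, snr_db / 10.0);

  std::vector<int> peaks;
  std::vector<double> peak_e;
  bool in_run = false;
  int best_i = 0;
  double best_e = 0.0;
  for (int i = 0; i < n; ++i) {
    if (energy[i] > thr) {
      if (!in_run || energy[i] > best_e) {
        best_i = i;
        best_e = energy[i];
      }
      in_run = true;
    } else if (in_run) {
      in_run = false;
      if (!peaks.empty() && best_i - peaks.back() < min_sep) {
        if (best_e > peak_e.back()) {
          peaks.back() = best_i;
          peak_e.back() = best_e;
        }
      } else {
        peaks.push_back(best_i);
        peak_e.push_back(best_e);
      }
    }
  }
  if (in_run) {
    if (!peaks.empty() && best_i - peaks.back() < min_sep) {
      if (best_e > peak_e.back()) {
        peaks.back() = best_i;
        peak_e.back() = best_e;
      }
    } else {
      peaks.push_back(best_i);
      peak_e.push_back(best_e);
    }
  }

  const int k = static_cast<int>(peaks.size());
  IntegerVector idx(k);
  NumericVector snr(k);
  for (int i = 0; i < k; ++i) {
    idx[i] = peaks[i] + 1;  // 1-based for R
    snr[i] = 10.0 * std::log10(peak_e[i] / floor_est);
  }
  return List::create(_["index"] = idx, _["snr_db"] = snr,
                      _["noise_floor"] = floor_est);
}
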