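// Delay-and-sum accumulation over transmit events and an adjacent receive
// aperture, on the analytic (complex) channel data. Delay maps are per-element
// one-way times to every pixel; the two-way delay is tx leg + rx leg. Linear
// interpolation in fast time.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".das_cpp")]]
List das_cpp(NumericVector re, NumericVector im, IntegerVector dims,
             IntegerVector tx_of_event,
             NumericMatrix delays, NumericMatrix apod,
             IntegerVector ap_offsets,
             double t0, double fs, double peak_offset,
             bool incoherent) {
  const int n_time = dims[0], n_rx = dims[1], n_ev = dims[2];
  const int npix = delays.nrow();
  const int n_elem = delays.ncol();
  if (apod.nrow() != npix || apod.ncol() != n_elem)
    stop("apodization matrix shape mismatch");
  if (tx_of_event.size() != n_ev) stop("tx_of_event length mismatch");

  NumericVector acc_re(npix), acc_im(npix), env(npix);
  std::vector<double> ev_re, ev_im;
  if (incoherent) { ev_re.assign(npix, 0.0); ev_im.assign(npix, 0.0); }

  long long clipped = 0, total = 0;

  for (int ev = 0; ev < n_ev; ++ev) {
    const int a = tx_of_event[ev] - 1;            // transmit element, 0-based
    if (incoherent) {
      std::fill(ev_re.begin(), ev_re.end(), 0.0);
      std::fill(ev_im.begin(), ev_im.end(), 0.0);
    }
    for (int q = 0; q < ap_offsets.size(); ++q) {
      int k = a + ap_offsets[q];
      k %= n_elem; if (k < 0) k += n_elem;        // ring wrap
      if (k >= n_rx) continue;
      const double* tr_re = &re[0] + (size_t)n_time * (k + (size_t)n_rx * ev);
      const double* tr_im = &im[0] + (size_t)n_time * (k + (size_t)n_rx * ev);
      const double* d_a = &delays(0, a);
      const double* d_k = &delays(0, k);
      const double* w_a = &apod(0, a);
      const double* w_k = &apod(0, k);
      for (int p = 0; p < npix; ++p) {
        double w = w_a[p] * w_k[p];
        if (w <= 0.0) continue;
        double tau = d_a[p] + d_k[p] + peak_offset;
        double s = (tau - t0) * fs;
        int i0 = (int)std::floor(s);
        ++total;
        if (i0 < 0 || i0 + 1 >= n_time) { ++clipped; continue; }
        double f = s - i0;
        double vr = tr_re[i0] * (1.0 - f) + tr_re[i0 + 1] * f;
        double vi = tr_im[i0] * (1.0 - f) + tr_im[i0 + 1] * f;
        if (incoherent) { ev_re[p] += w * vr; ev_im[p] += w * vi; }
        else            { acc_re[p] += w * vr; acc_im[p] += w * vi; }
      }
    }
    if (incoherent)
      for (int p = 0; p < npix; ++p)
        env[p] += std::sqrt(ev_re[p] * ev_re[p] + ev_im[p] * ev_im[p]);
  }
  return List::create(_["re"] = acc_re, _["im"] = acc_im, _["env"] = env,
                      _["clipped"] = (double)clipped, _["total"] = (double)total);
}
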