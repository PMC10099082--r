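// Echo synthesis for one transmit event: each (scatterer, receiver) pair adds
// the pulse waveform, delayed with linear fractional-sample interpolation, to
// the receiver trace.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".synth_echoes_cpp")]]
NumericMatrix synth_echoes_cpp(int n_time, double fs, double t0,
                               NumericMatrix delay,   // n_scat x n_rx, us
                               NumericMatrix amp,     // n_scat x n_rx
                               NumericVector pulse) { // onset at sample 1
  const int n_scat = delay.nrow(), n_rx = delay.ncol();
  const int lp = pulse.size();
  NumericMatrix tr(n_time, n_rx);
  for (int k = 0; k < n_rx; ++k) {
    double* col = &tr(0, k);
    for (int q = 0; q < n_scat; ++q) {
      double a = amp(q, k);
      if (a == 0.0 || !std::isfinite(delay(q, k))) continue;
      double s0 = (delay(q, k) - t0) * fs;   // fractional onset sample
      int i0 = (int)std::floor(s0);
      double f = s0 - i0;
      for (int l = 0; l < lp; ++l) {
        int i = i0 + l;
        if (i >= 0 && i < n_time)     col[i]     += a * pulse[l] * (1.0 - f);
        if (i + 1 >= 0 && i + 1 < n_time) col[i + 1] += a * pulse[l] * f;
      }
    }
  }
  return tr;
}
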