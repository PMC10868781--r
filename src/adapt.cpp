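#include <Rcpp.h>
using namespace Rcpp;

// Synaptic depression + gain control recursion, one column per channel.
// s: frames x channels (nonnegative). w_sd weights the current and past
// inputs (n = 0..len-1); w_gc weights strictly past outputs (n = 1..len).
// D(t,c) = V * (1 + sum_n s(t-n,c) w_sd[n])
// G(t,c) = 1 / (1 + sum_n r(t-n,c) w_gc[n-1])
// r(t,c) = max(s(t,c) - D(t,c), 0) * G(t,c)
// [[Rcpp::export]]
NumericMatrix adapt_core(NumericMatrix s, double V,
                         NumericVector w_sd, NumericVector w_gc) {
  const int T = s.nrow(), C = s.ncol();
  const int nsd = w_sd.size(), ngc = w_gc.size();
  NumericMatrix r(T, C);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < T; ++t) {
      double dep = 0.0;
      for (int n = 0; n < nsd; ++n) {
        int tt = t - n;
        if (tt < 0) break;
        dep += s(tt, c) * w_sd[n];
      }
      double D = V * (1.0 + dep);
      double g = 0.0;
      for (int n = 1; n <= ngc; ++n) {
        int tt = t - n;
        if (tt < 0) break;
        g += r(tt, c) * w_gc[n - 1];
      }
      double G = 1.0 / (1.0 + g);
      double x = s(t, c) - D;
      r(t, c) = (x > 0.0 ? x : 0.0) * G;
    }
  }
  return r;
}
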