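#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Event loop for the centroid jump process.  Uses R's RNG stream with a
// fixed, documented draw order per event: (1) event-type uniform,
// (2) FA-selection uniform, then for an attach event (3) outreach length
// and (4) outreach angle.  Degenerate laws still consume their draw so the
// stream does not depend on the law type.  This order is mirrored exactly
// by the pure-R step_event(), so a C++ run and a step-by-step R run from
// the same RNG state coincide bitwise.
// [[Rcpp::export]]
List sim_core(int n, double r, int events, int burn_in,
              IntegerVector psi_init, NumericMatrix v_init,
              NumericVector c_init, NumericVector weights,
              double len_lo, double len_hi, double ang_lo, double ang_hi) {
  std::vector<int> psi(psi_init.begin(), psi_init.end());
  std::vector<double> vx(n), vy(n), w(weights.begin(), weights.end());
  for (int i = 0; i < n; ++i) { vx[i] = v_init(i, 0); vy[i] = v_init(i, 1); }
  double cx = c_init[0], cy = c_init[1];
  int k = 0;
  for (int i = 0; i < n; ++i) k += psi[i];

  IntegerVector ev_kind(events), ev_fa(events), ev_att(events);
  NumericVector ev_cx(events), ev_cy(events);
  NumericVector x0(2);
  x0[0] = cx; x0[1] = cy;
  const double d2r = M_PI / 180.0;

  long total = (long)burn_in + (long)events;
  for (long t = 0; t < total; ++t) {
    if (t == burn_in) { x0[0] = cx; x0[1] = cy; }
    double p = 1.0 / (k + (n - k) * r);
    double pa = (n - k) * r * p;
    double u = unif_rand();
    int fa = -1, kind;
    if (u < pa) {                        // attach
      int m = n - k;
      int idx = (int)(unif_rand() * m);
      if (idx >= m) idx = m - 1;
      for (int i = 0, cnt = 0; i < n; ++i)
        if (!psi[i] && cnt++ == idx) { fa = i; break; }
      double L  = len_lo + (len_hi - len_lo) * unif_rand();
      double th = (ang_lo + (ang_hi - ang_lo) * unif_rand()) * d2r;
      vx[fa] = cx + L * std::cos(th);
      vy[fa] = cy + L * std::sin(th);
      psi[fa] = 1; ++k; kind = 1;
    } else {                             // detach
      int m = k;
      int idx = (int)(unif_rand() * m);
      if (idx >= m) idx = m - 1;
      for (int i = 0, cnt = 0; i < n; ++i)
        if (psi[i] && cnt++ == idx) { fa = i; break; }
      psi[fa] = 0; --k; kind = 0;
    }
    if (k > 0) {                         // weighted mean of attached sites
      // long double accumulation to match R's colSums()/sum() bitwise
      long double sw = 0, sx = 0, sy = 0;
      for (int i = 0; i < n; ++i)
        if (psi[i]) { sw += w[i]; sx += w[i] * vx[i]; sy += w[i] * vy[i]; }
      cx = (double)sx / (double)sw; cy = (double)sy / (double)sw;
    }                                    // k == 0: centroid does not move
    if (t >= burn_in) {
      long j = t - burn_in;
      ev_kind[j] = kind; ev_fa[j] = fa + 1; ev_att[j] = k;
      ev_cx[j] = cx; ev_cy[j] = cy;
    }
  }

  NumericMatrix v_out(n, 2);
  IntegerVector psi_out(n);
  for (int i = 0; i < n; ++i) {
    v_out(i, 0) = vx[i]; v_out(i, 1) = vy[i]; psi_out[i] = psi[i];
  }
  return List::create(_["kind"] = ev_kind, _["fa"] = ev_fa,
                      _["attached"] = ev_att, _["cx"] = ev_cx,
                      _["cy"] = ev_cy, _["x0"] = x0,
                      _["psi"] = psi_out, _["v"] = v_out,
                      _["centroid"] = NumericVector::create(cx, cy));
}
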