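// Felsenstein pruning for a 20-state reversible amino-acid model.
// Transition matrices come from the cached spectral decomposition
// P(t) = V diag(exp(lambda t)) Vinv; per-node scaling guards against
// underflow. States are 1..20, 0 = fully ambiguous (X or gap).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
double prune_lnl_cpp(IntegerMatrix edge, NumericVector el, int ntip,
                     int nnode, IntegerMatrix states, NumericVector weights,
                     NumericMatrix V, NumericMatrix Vinv, NumericVector eval,
                     NumericVector freqs, double rate) {
  const int nE = edge.nrow();
  const int npat = states.ncol();
  const int nn = ntip + nnode;

  // flat partial-likelihood buffer for internal nodes only, plus log-scales
  std::vector<double> buf((size_t)(nnode) * npat * 20);
  std::vector<double> logs((size_t)(nnode) * npat, 0.0);
  std::vector<char> has(nn + 1, 0);
  const double *Vp = REAL(V), *Vip = REAL(Vinv), *ev = REAL(eval);
  const int *st = INTEGER(states);

  double P[400];   // P[i + 20*j] = P(i -> j)
  double ex[20], tmp[20];

  for (int e = 0; e < nE; ++e) {
    const int par = edge(e, 0);
    const int ch = edge(e, 1);
    const double t = el[e] * rate;
    for (int k = 0; k < 20; ++k) ex[k] = std::exp(ev[k] * t);
    for (int j = 0; j < 20; ++j) {
      for (int i = 0; i < 20; ++i) {
        double s = 0.0;
        // V is column-major 20x20: V(i,k) = Vp[i + 20k]
        for (int k = 0; k < 20; ++k) s += Vp[i + 20 * k] * ex[k] * Vip[k + 20 * j];
        P[i + 20 * j] = s > 0.0 ? s : 0.0;
      }
    }

    double *A = &buf[(size_t)(par - ntip - 1) * npat * 20];
    double *Al = &logs[(size_t)(par - ntip - 1) * npat];
    const bool first = !has[par];

    if (ch <= ntip) {
      for (int p = 0; p < npat; ++p) {
        const int s = st[(size_t)p * ntip + (ch - 1)];
        double *a = A + (size_t)p * 20;
        if (s > 0) {
          const double *Pcol = &P[20 * (s - 1)];  // P(i -> s) over i
          if (first) for (int i = 0; i < 20; ++i) a[i] = Pcol[i];
          else       for (int i = 0; i < 20; ++i) a[i] *= Pcol[i];
        } else if (first) {
          for (int i = 0; i < 20; ++i) a[i] = 1.0;
        }
      }
      if (first) for (int p = 0; p < npat; ++p) Al[p] = 0.0;
    } else {
      double *D = &buf[(size_t)(ch - ntip - 1) * npat * 20];
      double *Dl = &logs[(size_t)(ch - ntip - 1) * npat];
      for (int p = 0; p < npat; ++p) {
        double *d = D + (size_t)p * 20;
        double m = 0.0;
        for (int j = 0; j < 20; ++j) if (d[j] > m) m = d[j];
        if (m <= 0.0) m = 1e-300;
        const double inv = 1.0 / m;
        const double lg = Dl[p] + std::log(m);
        // tmp_i = sum_j d_j P(i -> j), scaled
        for (int i = 0; i < 20; ++i) {
          double s = 0.0;
          const double *Pi = &P[i];  // stride 20 over j
          for (int j = 0; j < 20; ++j) s += d[j] * Pi[20 * j];
          tmp[i] = s * inv;
        }
        double *a = A + (size_t)p * 20;
        if (first) {
          for (int i = 0; i < 20; ++i) a[i] = tmp[i];
          Al[p] = lg;
        } else {
          for (int i = 0; i < 20; ++i) a[i] *= tmp[i];
          Al[p] += lg;
        }
      }
    }
    has[par] = 1;
  }

  const int root = edge(nE - 1, 0);
  const double *R = &buf[(size_t)(root - ntip - 1) * npat * 20];
  const double *Rl = &logs[(size_t)(root - ntip - 1) * npat];
  const double *fr = REAL(freqs), *w = REAL(weights);
  double lnl = 0.0;
  for (int p = 0; p < npat; ++p) {
    double s = 0.0;
    const double *row = R + (size_t)p * 20;
    for (int i = 0; i < 20; ++i) s += row[i] * fr[i];
    lnl += w[p] * (std::log(s) + Rl[p]);
  }
  return lnl;
}
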