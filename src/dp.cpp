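#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Statistical weights are accumulated in linear space; values above this cap
// are saturated (deterministically) and flagged, with the derivative rows of
// capped entries zeroed.
static const double WEIGHT_CAP = 1e250;

// Effective-concentration tables for spacer distances d = 0..dmax:
//   cb[d] = cAB + S * NB(d; r, p),  cAB fixed to 1,
// with the negative binomial generalised to non-integer r via log-gamma,
// plus partial derivatives w.r.t. the unconstrained parameters
// rho (r = e^rho), pi (p = logistic(pi)) and log S.
struct SpacerTables {
  std::vector<double> cb, d_rho, d_pi, d_logS;
};

static SpacerTables spacer_tables(int dmax, double rho, double pi_,
                                  double log_s) {
  double r = std::exp(rho);
  double p = 1.0 / (1.0 + std::exp(-pi_));
  double S = std::exp(log_s); // log_s = -Inf encodes S = 0
  SpacerTables t;
  int n = dmax + 1;
  t.cb.assign(n, 1.0);
  t.d_rho.assign(n, 0.0);
  t.d_pi.assign(n, 0.0);
  t.d_logS.assign(n, 0.0);
  if (S == 0.0) return t;
  double lgr = R::lgammafn(r), dgr = R::digamma(r);
  double logp = std::log(p), log1mp = std::log1p(-p);
  for (int d = 0; d < n; ++d) {
    double nb = std::exp(R::lgammafn(d + r) - lgr - R::lgammafn(d + 1.0) +
                         r * logp + d * log1mp);
    double snb = S * nb;
    t.cb[d] = 1.0 + snb;
    // d/d rho = S * dNB/dr * r ; d/d pi = S * dNB/dp * p(1-p)
    t.d_rho[d] = snb * r * (R::digamma(d + r) - dgr + logp);
    t.d_pi[d] = snb * (r * (1.0 - p) - d * p);
    t.d_logS[d] = snb;
  }
  return t;
}

struct DpOut {
  double Z;
  std::vector<double> ZA, ZB, grad;
  bool overflow;
};

// One-sequence DP over all binding configurations.
//
// ZA(i): configurations on x[0..i] with domain A bound at i-k+1..i.
// ZB(i): configurations on x[0..i] with nothing bound at i, or domain B
//        bound with right edge <= i.
// Boundary: ZA(i) = 0, ZB(i) = 1 for i < k-1 (incl. negative i).
//
//   ZA(i) = (ZB(i-k) + sum_{j<=i-k} ZA(j)) * cAB * e^{-EA(win_i)}
//   ZB(i) = ZB(i-1)
//         + sum_{j<=i-k} ZA(j) * cB(i-k-j) * e^{-EB(win_i)}   (paired B)
//         + ZB(i-k) * cAB * e^{-EB(win_i)}                    (free B)
//   Z = ZB(L-1) + sum_i ZA(i)
//
// win[] holds the 0-based lexicographic k-mer index of the window starting
// at each position, or -1 for windows containing ambiguous bases (weight 0).
//
// When `gradient` is set, derivative recursions are propagated alongside for
// the parameter vector [EA(0..M-1), EB(0..M-1), rho, pi, logS], P = 2M + 3.
static void dp_one(const int *win, int L, int k, const double *eA,
                   const double *eB, int M, const SpacerTables &sp,
                   bool gradient, DpOut &out) {
  int P = 2 * M + 3;
  out.overflow = false;
  out.ZA.assign(std::max(L, 0), 0.0);
  out.ZB.assign(std::max(L, 0), 1.0);
  out.grad.assign(gradient ? P : 0, 0.0);
  out.Z = 1.0;
  if (L < k) return;

  std::vector<double> SA(L, 0.0); // prefix sums of ZA
  std::vector<double> dZA, dZB, dSA;
  if (gradient) {
    dZA.assign((size_t)L * P, 0.0);
    dZB.assign((size_t)L * P, 0.0);
    dSA.assign((size_t)L * P, 0.0);
  }
  std::vector<double> dconv(gradient ? P : 0);

  for (int i = k - 1; i < L; ++i) {
    int idx = win[i - k + 1];
    double wA = idx >= 0 ? std::exp(-eA[idx]) : 0.0;
    double wB = idx >= 0 ? std::exp(-eB[idx]) : 0.0;
    double ZBm = (i - k < 0) ? 1.0 : out.ZB[i - k];
    double SAm = (i - k < 0) ? 0.0 : SA[i - k];
    double za = (ZBm + SAm) * wA;

    double conv = 0.0, conv_rho = 0.0, conv_pi = 0.0, conv_logS = 0.0;
    if (gradient) std::fill(dconv.begin(), dconv.end(), 0.0);
    for (int j = k - 1; j <= i - k; ++j) {
      double zaj = out.ZA[j];
      int d = i - k - j;
      double cbd = sp.cb[d];
      if (zaj != 0.0) {
        conv += zaj * cbd;
        conv_rho += zaj * sp.d_rho[d];
        conv_pi += zaj * sp.d_pi[d];
        conv_logS += zaj * sp.d_logS[d];
      }
      if (gradient) {
        const double *dzaj = &dZA[(size_t)j * P];
        double *dc = dconv.data();
        for (int t = 0; t < P; ++t) dc[t] += dzaj[t] * cbd;
      }
    }
    double ZBp = (i - 1 < 0) ? 1.0 : out.ZB[i - 1];
    double zb = ZBp + (conv + ZBm) * wB;

    bool capA = false, capB = false;
    if (za > WEIGHT_CAP) { za = WEIGHT_CAP; capA = true; out.overflow = true; }
    if (zb > WEIGHT_CAP) { zb = WEIGHT_CAP; capB = true; out.overflow = true; }
    out.ZA[i] = za;
    out.ZB[i] = zb;
    SA[i] = ((i > 0) ? SA[i - 1] : 0.0) + za;
    if (SA[i] > WEIGHT_CAP) { SA[i] = WEIGHT_CAP; out.overflow = true; }

    if (gradient) {
      double *dzai = &dZA[(size_t)i * P];
      const double *dzbm = (i - k >= 0) ? &dZB[(size_t)(i - k) * P] : NULL;
      const double *dsam = (i - k >= 0) ? &dSA[(size_t)(i - k) * P] : NULL;
      if (!capA && wA != 0.0) {
        for (int t = 0; t < P; ++t)
          dzai[t] = ((dzbm ? dzbm[t] : 0.0) + (dsam ? dsam[t] : 0.0)) * wA;
        dzai[idx] -= za; // d(e^{-EA})/dEA = -e^{-EA}
      }
      double *dzbi = &dZB[(size_t)i * P];
      const double *dzbp = (i - 1 >= 0) ? &dZB[(size_t)(i - 1) * P] : NULL;
      if (!capB) {
        for (int t = 0; t < P; ++t)
          dzbi[t] =
              (dzbp ? dzbp[t] : 0.0) + (dconv[t] + (dzbm ? dzbm[t] : 0.0)) * wB;
        if (wB != 0.0) {
          dzbi[M + idx] -= (conv + ZBm) * wB;
          dzbi[2 * M] += conv_rho * wB;
          dzbi[2 * M + 1] += conv_pi * wB;
          dzbi[2 * M + 2] += conv_logS * wB;
        }
      }
      double *dsai = &dSA[(size_t)i * P];
      const double *dsap = (i - 1 >= 0) ? &dSA[(size_t)(i - 1) * P] : NULL;
      for (int t = 0; t < P; ++t) dsai[t] = (dsap ? dsap[t] : 0.0) + dzai[t];
    }
  }
  out.Z = out.ZB[L - 1] + SA[L - 1];
  if (gradient) {
    const double *dzb = &dZB[(size_t)(L - 1) * P];
    const double *dsa = &dSA[(size_t)(L - 1) * P];
    for (int t = 0; t < P; ++t) out.grad[t] = dzb[t] + dsa[t];
  }
}

// [[Rcpp::export]]
List cpp_dp_single(IntegerVector windows, int L, int k, NumericVector eA,
                   NumericVector eB, double rho, double pi_, double log_s,
                   bool gradient) {
  int M = eA.size();
  SpacerTables sp = spacer_tables(std::max(L - 2 * k, 0), rho, pi_, log_s);
  DpOut out;
  dp_one(windows.begin(), L, k, eA.begin(), eB.begin(), M, sp, gradient, out);
  return List::create(_["Z"] = out.Z, _["ZA"] = wrap(out.ZA),
                      _["ZB"] = wrap(out.ZB), _["grad"] = wrap(out.grad),
                      _["overflow"] = out.overflow);
}

// Batched version: returns partition sums (and optionally the P x n matrix
// of dZ/dtheta) for a list of pre-encoded sequences.
// [[Rcpp::export]]
List cpp_dp_batch(List windows_list, IntegerVector lengths, int k,
                  NumericVector eA, NumericVector eB, double rho, double pi_,
                  double log_s, bool gradient) {
  int n = windows_list.size();
  int M = eA.size();
  int P = 2 * M + 3;
  int Lmax = 0;
  for (int s = 0; s < n; ++s) Lmax = std::max(Lmax, lengths[s]);
  SpacerTables sp = spacer_tables(std::max(Lmax - 2 * k, 0), rho, pi_, log_s);

  NumericVector Z(n);
  LogicalVector overflow(n);
  NumericMatrix grad(gradient ? P : 0, gradient ? n : 0);
  DpOut out;
  for (int s = 0; s < n; ++s) {
    IntegerVector win = windows_list[s];
    dp_one(win.begin(), lengths[s], k, eA.begin(), eB.begin(), M, sp, gradient,
           out);
    Z[s] = out.Z;
    overflow[s] = out.overflow;
    if (gradient)
      std::copy(out.grad.begin(), out.grad.end(), grad.column(s).begin());
  }
  return List::create(_["Z"] = Z, _["grad"] = grad, _["overflow"] = overflow);
}
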