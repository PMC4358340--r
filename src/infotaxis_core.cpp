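#include <Rcpp.h>
using namespace Rcpp;

// Entropy identities used throughout: for weights w = P * lik with
// q = sum(w), the normalized entropy is S = log(q) - (1/q) sum(w log w),
// and sum(w log w) expands to sum(P lik (log P + log lik)). With the
// per-offset kernels logLik available in closed form (-R for the no-hit
// branch, log(1 - e^{-R}) for the hit branch) and log P carried alongside
// P, no per-candidate logarithms are needed.

// Expected entropy change for each candidate move.
//
// P, logP: current grid posterior and its elementwise log (-Inf at zeros)
// rateK, expK, log1mK: shifted kernels R, exp(-R), log(1 - exp(-R))
// cand: k x 2 matrix of 1-based candidate cells
// pA: probability the source is in the area; S: current posterior entropy
// rho1_printed: use (1 - pA) instead of pA in the hit-probability weight
//
// Outcomes per candidate r_j: source found there (prob P(r_j), entropy
// falls to 0); no hit; >= 1 hit (binary coding). Both Bayes branches
// include the visited-cell zeroing at r_j.
// [[Rcpp::export]]
NumericVector delta_s_candidates_cpp(NumericMatrix P, NumericMatrix logP,
                                     NumericMatrix rateK, NumericMatrix expK,
                                     NumericMatrix log1mK, IntegerMatrix cand,
                                     double pA, double S, bool rho1_printed) {
  const int nx = P.nrow(), ny = P.ncol();
  const int k = cand.nrow();
  NumericVector out(k);
  for (int c = 0; c < k; ++c) {
    const int cx = cand(c, 0), cy = cand(c, 1);           // 1-based
    const int roff = nx - cx, coff = ny - cy;             // kernel offsets
    double s0 = 0.0, sl0 = 0.0, s1 = 0.0, sl1 = 0.0, h = 0.0;
    const double pfound = P(cx - 1, cy - 1);
    for (int j = 0; j < ny; ++j) {
      const int kc = coff + j;
      for (int i = 0; i < nx; ++i) {
        const double p = P(i, j);
        if (p <= 0.0) continue;
        const int kr = roff + i;
        const double r = rateK(kr, kc);
        h += p * r;
        if (i == cx - 1 && j == cy - 1) continue;         // visited-cell zeroing
        const double lp = logP(i, j);
        const double e = expK(kr, kc);
        const double w0 = p * e;
        s0 += w0;
        sl0 += w0 * (lp - r);
        const double w1 = p - w0;                          // p * (1 - e)
        if (w1 > 0.0) { s1 += w1; sl1 += w1 * (lp + log1mK(kr, kc)); }
      }
    }
    const double S0 = (s0 > 0.0) ? std::log(s0) - sl0 / s0 : S;
    const double S1 = (s1 > 0.0) ? std::log(s1) - sl1 / s1 : S;
    const double pw = rho1_printed ? (1.0 - pA) : pA;
    const double rho1 = pw * (-std::expm1(-h));
    const double rho0 = 1.0 - rho1;
    out[c] = pfound * (-S) +
      (1.0 - pfound) * (rho0 * (S0 - S) + rho1 * (S1 - S));
  }
  return out;
}

// Realized observation step at cell (ix, iy): visit (zero the cell), apply
// the no-hit likelihood, renormalize. Returns the new posterior and its
// log, the evidence q = P(no find & no hit | A), the posterior entropy,
// and the expected-hit count h at the cell.
// [[Rcpp::export]]
List posterior_step_cpp(NumericMatrix P, NumericMatrix logP,
                        NumericMatrix rateK, NumericMatrix expK,
                        int ix, int iy) {
  const int nx = P.nrow(), ny = P.ncol();
  const int roff = nx - ix, coff = ny - iy;
  NumericMatrix W(nx, ny), logW(nx, ny);
  double q = 0.0, h = 0.0;
  for (int j = 0; j < ny; ++j) {
    const int kc = coff + j;
    for (int i = 0; i < nx; ++i) {
      const double p = P(i, j);
      if (p <= 0.0) { W(i, j) = 0.0; logW(i, j) = R_NegInf; continue; }
      const int kr = roff + i;
      const double r = rateK(kr, kc);
      h += p * r;
      if (i == ix - 1 && j == iy - 1) {
        W(i, j) = 0.0; logW(i, j) = R_NegInf; continue;
      }
      W(i, j) = p * expK(kr, kc);
      logW(i, j) = logP(i, j) - r;
      q += W(i, j);
    }
  }
  if (q <= 0.0)
    stop("posterior_step: posterior weights underflowed to zero");
  const double lq = std::log(q);
  double sl = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (W(i, j) <= 0.0) continue;
      W(i, j) /= q;
      logW(i, j) -= lq;
      sl += W(i, j) * logW(i, j);
    }
  return List::create(_["posterior"] = W, _["log_posterior"] = logW,
                      _["q"] = q, _["entropy"] = -sl, _["h"] = h);
}
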