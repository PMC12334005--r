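// Blocked Gibbs sampler for Gaussian APC models under a hard sum-to-zero
// parameterization. Each effect block of length M is carried by its first
// M - 1 free coordinates; the last level is minus their sum. Given the
// scale parameters the joint conditional of (intercept, all free effects)
// is multivariate normal; given the effects each scale has a (truncated)
// inverse-gamma conditional, because the scale hyperpriors are flat.
// Model codes: 0 = random effects, 1 = ridge, 2 = random walk.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Draw sigma^2 from InvGamma(shape, rate) truncated to sigma >= lb,
// via the inverse CDF of the gamma-distributed precision.
static double rinvgamma_trunc(double shape, double rate, double lb) {
  const double gmax = 1.0 / (lb * lb); // precision upper bound
  const double scale = 1.0 / rate;
  double pmax = R::pgamma(gmax, shape, scale, 1, 0);
  double g;
  if (!std::isfinite(pmax) || pmax <= 1e-300) {
    g = gmax; // posterior mass essentially entirely below the bound
  } else {
    double u = unif_rand() * pmax;
    g = R::qgamma(u, shape, scale, 1, 0);
    if (!std::isfinite(g) || g <= 0.0 || g > gmax) g = gmax;
  }
  double s2 = 1.0 / g;
  if (s2 > 1e8) s2 = 1e8;
  return s2;
}

// log of the scale-integrated block prior: integral over sigma >= L of
// sigma^(-expnt) * exp(-S / (2 sigma^2)) d sigma, in closed form via the
// lower incomplete gamma function. Used by the collapsed shift move.
static double marg_log(double S, double expnt, double L) {
  const double a = (expnt - 1.0) / 2.0;
  const double T = S / (2.0 * L * L);
  return -M_LN2 + a * (M_LN2 - std::log(S)) + R::lgammafn(a) +
         R::pgamma(T, a, 1.0, 1, 1);
}

static arma::vec expand_block(const arma::vec& a) {
  arma::vec b(a.n_elem + 1);
  b.head(a.n_elem) = a;
  b(a.n_elem) = -arma::accu(a);
  return b;
}

static double sum_sq(const arma::vec& x) { return arma::dot(x, x); }

static double sum_diff_sq(const arma::vec& x) {
  double s = 0.0;
  for (arma::uword m = 1; m < x.n_elem; ++m) {
    double d = x(m) - x(m - 1);
    s += d * d;
  }
  return s;
}

// [[Rcpp::export(name = ".gibbs_chain")]]
arma::mat gibbs_chain(const arma::mat& XtX, const arma::vec& Xty, double yty,
                      int N, int I, int J, int K, int model,
                      const arma::mat& RA, const arma::mat& RP,
                      const arma::mat& RC,
                      int iter, int warmup, int thin,
                      const arma::vec& theta0, double sigma0,
                      const arma::vec& scales0,
                      double sigma_lb, const arma::vec& block_lb) {
  const int pA = I - 1, pP = J - 1, pC = K - 1;
  const int p = 1 + pA + pP + pC;
  const arma::span sA(1, pA), sP(1 + pA, pA + pP), sC(1 + pA + pP, p - 1);

  arma::vec theta = theta0;
  double sig2 = sigma0 * sigma0;
  // block variances; for ridge all three alias lam^2
  double s2A = scales0(0) * scales0(0);
  double s2P = (model == 1) ? s2A : scales0(1) * scales0(1);
  double s2C = (model == 1) ? s2A : scales0(2) * scales0(2);

  const int nsave = (iter - warmup + thin - 1) / thin;
  const int nscale = (model == 1) ? 1 : 3;
  arma::mat out(nsave, 1 + I + J + K + 1 + nscale + 1);

  arma::mat Q(p, p), U;
  arma::vec z(p), bA, bP, bC;
  int row = 0;

  for (int it = 0; it < iter; ++it) {
    // --- effects | scales: joint Gaussian draw ---
    Q = XtX / sig2;
    Q(arma::span(1, pA), arma::span(1, pA)) += RA / s2A;
    Q(arma::span(1 + pA, pA + pP), arma::span(1 + pA, pA + pP)) += RP / s2P;
    Q(arma::span(1 + pA + pP, p - 1), arma::span(1 + pA + pP, p - 1)) += RC / s2C;
    if (!arma::chol(U, Q))
      stop("Cholesky factorization failed; posterior precision not PD");
    arma::vec mu = arma::solve(arma::trimatu(U),
                   arma::solve(arma::trimatl(U.t()), Xty / sig2));
    for (int d = 0; d < p; ++d) z(d) = norm_rand();
    theta = mu + arma::solve(arma::trimatu(U), z);

    bA = expand_block(theta(sA));
    bP = expand_block(theta(sP));
    bC = expand_block(theta(sC));

    // --- collapsed shift move along the likelihood-flat direction ---
    // The identification shift (bA + ds*vA, bP - ds*vP, bC + ds*vC) leaves
    // every fitted mean unchanged, so the posterior along it is shaped by
    // the prior alone and can be multimodal. A Metropolis move with the
    // scales integrated out in closed form lets chains cross between
    // modes; the scales are then redrawn from their exact conditional.
    {
      arma::vec vA(I), vP(J), vC(K);
      for (int m = 0; m < I; ++m) vA(m) = m + 1 - (I + 1) / 2.0;
      for (int m = 0; m < J; ++m) vP(m) = m + 1 - (J + 1) / 2.0;
      for (int m = 0; m < K; ++m) vC(m) = m + 1 - (K + 1) / 2.0;
      auto marg_total = [&](const arma::vec& a, const arma::vec& p,
                            const arma::vec& c) -> double {
        if (model == 1) {
          double S = sum_sq(a) + sum_sq(p) + sum_sq(c);
          return marg_log(std::max(S, 1e-12), I + J + K, block_lb(0));
        } else if (model == 0) {
          return marg_log(std::max(sum_sq(a), 1e-12), I, block_lb(0)) +
                 marg_log(std::max(sum_sq(p), 1e-12), J, block_lb(1)) +
                 marg_log(std::max(sum_sq(c), 1e-12), K, block_lb(2));
        }
        return marg_log(std::max(sum_diff_sq(a), 1e-12), I - 1, block_lb(0)) +
               marg_log(std::max(sum_diff_sq(p), 1e-12), J - 1, block_lb(1)) +
               marg_log(std::max(sum_diff_sq(c), 1e-12), K - 1, block_lb(2));
      };
      const double steps[3] = {0.02, 0.06, 0.15};
      double cur = marg_total(bA, bP, bC);
      for (int mv = 0; mv < 3; ++mv) {
        double ds = steps[mv] * norm_rand();
        arma::vec nA = bA + ds * vA, nP = bP - ds * vP, nC = bC + ds * vC;
        double prop = marg_total(nA, nP, nC);
        if (std::log(unif_rand()) < prop - cur) {
          bA = nA; bP = nP; bC = nC; cur = prop;
          theta(sA) += ds * vA.head(pA);
          theta(sP) -= ds * vP.head(pP);
          theta(sC) += ds * vC.head(pC);
        }
      }
    }

    // --- sigma | effects ---
    double sse = yty - 2.0 * arma::dot(theta, Xty) +
                 arma::as_scalar(theta.t() * XtX * theta);
    if (sse < 1e-12) sse = 1e-12;
    sig2 = rinvgamma_trunc((N - 1) / 2.0, sse / 2.0, sigma_lb);

    // --- block scales | effects ---
    double SA, SP, SC;
    if (model == 2) {
      SA = sum_diff_sq(bA); SP = sum_diff_sq(bP); SC = sum_diff_sq(bC);
    } else {
      SA = sum_sq(bA); SP = sum_sq(bP); SC = sum_sq(bC);
    }
    if (SA < 1e-12) SA = 1e-12;
    if (SP < 1e-12) SP = 1e-12;
    if (SC < 1e-12) SC = 1e-12;

    if (model == 1) { // ridge: one shared scale over all levels
      double S = SA + SP + SC;
      s2A = rinvgamma_trunc((I + J + K - 1) / 2.0, S / 2.0, block_lb(0));
      s2P = s2A; s2C = s2A;
    } else if (model == 0) { // random effects
      s2A = rinvgamma_trunc((I - 1) / 2.0, SA / 2.0, block_lb(0));
      s2P = rinvgamma_trunc((J - 1) / 2.0, SP / 2.0, block_lb(1));
      s2C = rinvgamma_trunc((K - 1) / 2.0, SC / 2.0, block_lb(2));
    } else { // random walk: M - 1 difference terms per block
      s2A = rinvgamma_trunc((I - 2) / 2.0, SA / 2.0, block_lb(0));
      s2P = rinvgamma_trunc((J - 2) / 2.0, SP / 2.0, block_lb(1));
      s2C = rinvgamma_trunc((K - 2) / 2.0, SC / 2.0, block_lb(2));
    }

    // --- record ---
    if (it >= warmup && (it - warmup) % thin == 0) {
      double loglik = -N * 0.5 * std::log(sig2) - sse / (2.0 * sig2);
      double lprior;
      if (model == 0) {
        lprior = -(I * 0.5 * std::log(s2A) + J * 0.5 * std::log(s2P) +
                   K * 0.5 * std::log(s2C)) -
                 0.5 * (SA / s2A + SP / s2P + SC / s2C);
      } else if (model == 1) {
        lprior = -(I + J + K) * 0.5 * std::log(s2A) -
                 (SA + SP + SC) / (2.0 * s2A);
      } else {
        lprior = -((I - 1) * 0.5 * std::log(s2A) +
                   (J - 1) * 0.5 * std::log(s2P) +
                   (K - 1) * 0.5 * std::log(s2C)) -
                 0.5 * (SA / s2A + SP / s2P + SC / s2C);
      }
      int c = 0;
      out(row, c++) = theta(0);
      for (int m = 0; m < I; ++m) out(row, c++) = bA(m);
      for (int m = 0; m < J; ++m) out(row, c++) = bP(m);
      for (int m = 0; m < K; ++m) out(row, c++) = bC(m);
      out(row, c++) = std::sqrt(sig2);
      out(row, c++) = std::sqrt(s2A);
      if (nscale == 3) {
        out(row, c++) = std::sqrt(s2P);
        out(row, c++) = std::sqrt(s2C);
      }
      out(row, c++) = loglik + lprior;
      ++row;
    }
  }
  return out;
}
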