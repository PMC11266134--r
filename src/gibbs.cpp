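#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs samplers for the Bayesian alphabet models.
// Model codes: 1 = BayesA (scaled-t), 2 = BayesB (point mass + t),
// 3 = BayesC (point mass + Gaussian), 4 = BayesL (Laplace / Bayesian lasso).
//
// Scaled-inverse-chi-square convention: s2 ~ InvScChi2(df, S) has density
// proportional to s2^-(df/2 + 1) exp(-S / (2 s2)), mode S/(df + 2),
// mean S/(df - 2); a draw is S / rchisq(df).

static double rinvgauss(double mu, double lambda) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export]]
List gibbs_sampler(NumericMatrix Z, NumericVector y, int model,
                   double nu, double Sbeta0, bool updateSbeta,
                   double SbShape, double SbRate,
                   double pi0, double piA, double piB, bool updatePi,
                   double lambda2_0, double l2Shape, double l2Rate,
                   double dfE, double Se,
                   double varEFixed, double varBFixed,
                   int nIter, int burnIn, int thin, bool keepTrace) {
  const int n = Z.nrow(), p = Z.ncol();
  if (burnIn >= nIter) stop("burnIn must be smaller than nIter");

  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    xtx[j] = s;
  }

  double mu = mean(y);
  std::vector<double> beta(p, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  double varE = (varEFixed > 0.0) ? varEFixed : Se / (dfE + 2.0);
  double Sbeta = Sbeta0;
  double varB = (varBFixed > 0.0) ? varBFixed : Sbeta / (nu - 2.0);
  double pi = pi0;
  double lambda2 = lambda2_0;
  std::vector<double> s2(p, Sbeta / (nu - 2.0));   // per-marker variances (A/B)
  std::vector<double> tau2(p, 2.0 / lambda2);      // Laplace mixture scales
  std::vector<int> incl(p, 1);
  if (varBFixed > 0.0) std::fill(s2.begin(), s2.end(), varBFixed);

  const int nSaved = (nIter - burnIn) / thin;
  std::vector<double> betaMean(p, 0.0);
  double muMean = 0.0, varEMean = 0.0, varBMean = 0.0, piMean = 0.0;
  NumericVector varETrace(nSaved);
  NumericMatrix betaTrace = keepTrace ? NumericMatrix(nSaved, p)
                                      : NumericMatrix(0, 0);
  int saved = 0;

  for (int it = 1; it <= nIter; ++it) {
    // intercept
    double em = 0.0;
    for (int i = 0; i < n; ++i) em += e[i];
    double muNew = (em / n + mu) + norm_rand() * std::sqrt(varE / n);
    double dmu = mu - muNew;
    for (int i = 0; i < n; ++i) e[i] += dmu;
    mu = muNew;

    int m1 = 0;
    double sumB2Incl = 0.0;
    for (int j = 0; j < p; ++j) {
      double c = xtx[j];
      double bOld = beta[j];
      if (c <= 0.0) { beta[j] = 0.0; incl[j] = 0; continue; }
      double rhs = bOld * c;
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];

      double priorVar;
      switch (model) {
        case 1: case 2: priorVar = s2[j]; break;
        case 3: priorVar = varB; break;
        default: priorVar = varE * tau2[j]; break;
      }

      bool in = true;
      if ((model == 2 || model == 3) && pi < 1.0) {
        double v0 = c * varE;
        double v1 = c * c * priorVar + c * varE;
        double llr = 0.5 * (std::log(v0) - std::log(v1)) +
                     0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
        double logodds = std::log(pi / (1.0 - pi)) + llr;
        double p1 = 1.0 / (1.0 + std::exp(-logodds));
        in = unif_rand() < p1;
      }

      double bNew = 0.0;
      if (in) {
        double denom = c + varE / priorVar;
        double m = rhs / denom;
        bNew = m + norm_rand() * std::sqrt(varE / denom);
      }
      if (bNew != bOld) {
        double d = bOld - bNew;
        for (int i = 0; i < n; ++i) e[i] += Z(i, j) * d;
      }
      beta[j] = bNew;
      incl[j] = in ? 1 : 0;
      if (in) { ++m1; sumB2Incl += bNew * bNew; }

      if (varBFixed <= 0.0) {
        if (model == 1) {
          s2[j] = (Sbeta + bNew * bNew) / R::rchisq(nu + 1.0);
        } else if (model == 2) {
          s2[j] = in ? (Sbeta + bNew * bNew) / R::rchisq(nu + 1.0)
                     : Sbeta / R::rchisq(nu);
        } else if (model == 4) {
          double b2 = bNew * bNew;
          if (b2 < 1e-12) b2 = 1e-12;
          double it2 = rinvgauss(std::sqrt(lambda2 * varE / b2), lambda2);
          tau2[j] = 1.0 / it2;
        }
      }
    }

    if ((model == 2 || model == 3) && updatePi)
      pi = R::rbeta(piA + m1, piB + (p - m1));
    if (model == 3 && varBFixed <= 0.0)
      varB = (Sbeta + sumB2Incl) / R::rchisq(nu + m1);
    if ((model == 1 || model == 2) && updateSbeta && varBFixed <= 0.0) {
      double sInv = 0.0;
      for (int j = 0; j < p; ++j) sInv += 1.0 / s2[j];
      Sbeta = R::rgamma(SbShape + 0.5 * p * nu, 1.0 / (SbRate + 0.5 * sInv));
    }
    if (model == 4) {
      double sTau = 0.0;
      for (int j = 0; j < p; ++j) sTau += tau2[j];
      lambda2 = R::rgamma(l2Shape + p, 1.0 / (l2Rate + 0.5 * sTau));
    }

    if (varEFixed <= 0.0) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      double extra = 0.0, dfExtra = 0.0;
      if (model == 4) {
        for (int j = 0; j < p; ++j) extra += beta[j] * beta[j] / tau2[j];
        dfExtra = p;
      }
      varE = (sse + extra + Se) / R::rchisq(n + dfE + dfExtra);
    }
    if (!R_finite(varE) || varE <= 0.0)
      stop("non-finite residual variance draw at iteration %d", it);

    if (it > burnIn && (it - burnIn) % thin == 0) {
      for (int j = 0; j < p; ++j) betaMean[j] += beta[j];
      muMean += mu;
      varEMean += varE;
      piMean += pi;
      double vb;
      if (model == 3) vb = varB;
      else if (model == 4) vb = varE * 2.0 / lambda2;
      else { vb = 0.0; for (int j = 0; j < p; ++j) vb += s2[j]; vb /= p; }
      varBMean += vb;
      varETrace[saved] = varE;
      if (keepTrace)
        for (int j = 0; j < p; ++j) betaTrace(saved, j) = beta[j];
      ++saved;
    }
  }

  NumericVector bOut(p);
  for (int j = 0; j < p; ++j) bOut[j] = betaMean[j] / saved;
  List out = List::create(
    _["beta"] = bOut, _["mu"] = muMean / saved,
    _["varE"] = varEMean / saved, _["varB"] = varBMean / saved,
    _["piMean"] = piMean / saved, _["nSaved"] = saved,
    _["varETrace"] = varETrace);
  if (keepTrace) out["betaTrace"] = betaTrace;
  return out;
}
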