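#include <Rcpp.h>
using namespace Rcpp;

// log Binomial(k | n, 1 - exp(-lam * v)); R::dbinom handles the p = 0 edge
static inline double chan_ll(double k, double n, double lam, double v) {
  double p = -std::expm1(-lam * v);
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return R::dbinom(k, n, p, 1);
}

// expected reference-channel share theta given genotype and fetal fraction,
// with a multiplicative reference-allele bias factor
static inline double theta_of(int hom_ref, double f, double bias) {
  double th0 = hom_ref ? 0.5 + f / 2.0 : 0.5;
  if (bias == 1.0) return th0;
  return bias * th0 / (bias * th0 + (1.0 - th0));
}

// variant-assay pair log-likelihood (channels 1-2): allelic balance or
// copy-number mode (channel 1 = target, channel 2 = reference locus, with
// conc = reference-locus concentration)
static inline double ll_var(const NumericVector& k, const NumericVector& n,
                            double v, int cnv_mode, double bias,
                            int hom_ref, double f, double cvar) {
  if (cnv_mode) {
    double r = hom_ref ? 0.5 + f / 2.0 : 0.5;
    return chan_ll(k[0], n[0], cvar * r, v) + chan_ll(k[1], n[1], cvar, v);
  }
  double th = theta_of(hom_ref, f, bias);
  return chan_ll(k[0], n[0], cvar * th, v) +
         chan_ll(k[1], n[1], cvar * (1.0 - th), v);
}

// fetal-fraction assay pair (channels 3 = paternal, 4 = maternal)
static inline double ll_ff(const NumericVector& k, const NumericVector& n,
                           double v, double f, double cff) {
  return chan_ll(k[2], n[2], cff * f / 2.0, v) +
         chan_ll(k[3], n[3], cff * (1.0 - f / 2.0), v);
}

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// One Metropolis-within-Gibbs chain for the joint posterior over
// (genotype, fetal fraction f, assay concentrations cvar, cff).
// Continuous parameters move by Gaussian random walks on logit(f/f_max) and
// log-concentrations (step sizes adapted toward 0.4 acceptance during the
// adaptation phase only); the binary genotype is redrawn from its exact full
// conditional every sweep. Uses R's RNG: seed with set.seed() before calling.
//
// k, n: counts for channels (ref/target, var/ref-locus, paternal, maternal).
// Returns a draws matrix (sampling_iters x 4: f, conc_var, conc_ff, genotype)
// plus acceptance rates over the post-adaptation phase.
// [[Rcpp::export]]
List fc_mcmc_chain(NumericVector k, NumericVector n, double v, int cnv_mode,
                   double bias, double f_max, double cvar_max, double cff_max,
                   double prior_hom, int adapt_iters, int burn_in,
                   int sampling_iters, double f0, double cvar0, double cff0) {
  RNGScope scope;
  const double log_prior_odds = std::log(prior_hom / (1.0 - prior_hom));
  const bool f_free = f_max > 0.0;

  // initial state, jittered so chains start dispersed
  double u1 = 0.0, f = 0.0;
  if (f_free) {
    double s0 = std::min(std::max(f0 / f_max, 0.02), 0.98);
    u1 = std::log(s0 / (1.0 - s0)) + 0.5 * norm_rand();
    f = f_max * sigmoid(u1);
  }
  double u2 = std::log(cvar0) + 0.1 * norm_rand();
  double u3 = std::log(cff0) + 0.1 * norm_rand();
  double cvar = std::exp(u2), cff = std::exp(u3);
  if (cvar >= cvar_max) { cvar = 0.9 * cvar_max; u2 = std::log(cvar); }
  if (cff >= cff_max)   { cff = 0.9 * cff_max;  u3 = std::log(cff); }
  int g = unif_rand() < prior_hom ? 1 : 0;

  double lv = ll_var(k, n, v, cnv_mode, bias, g, f, cvar);
  double lf = ll_ff(k, n, v, f, cff);

  double step1 = 0.5, step2 = 0.1, step3 = 0.1;
  long acc1 = 0, acc2 = 0, acc3 = 0, n_post = 0;

  const int total = adapt_iters + burn_in + sampling_iters;
  NumericMatrix draws(sampling_iters, 4);

  for (int t = 0; t < total; ++t) {
    const bool adapting = t < adapt_iters;

    // Gibbs update of the latent genotype from its full conditional
    double l1 = ll_var(k, n, v, cnv_mode, bias, 1, f, cvar);
    double l0 = ll_var(k, n, v, cnv_mode, bias, 0, f, cvar);
    double p1 = 1.0 / (1.0 + std::exp(-(log_prior_odds + l1 - l0)));
    g = unif_rand() < p1 ? 1 : 0;
    lv = g ? l1 : l0;

    // f: random walk on logit(f / f_max); uniform prior on f gives a
    // Jacobian term log(s) + log(1 - s)
    if (f_free) {
      double u1p = u1 + step1 * norm_rand();
      double sp = sigmoid(u1p), fp = f_max * sp;
      double lvp = ll_var(k, n, v, cnv_mode, bias, g, fp, cvar);
      double lfp = ll_ff(k, n, v, fp, cff);
      double s = sigmoid(u1);
      double d = (lvp + lfp + std::log(sp) + std::log1p(-sp)) -
                 (lv + lf + std::log(s) + std::log1p(-s));
      bool ok = std::log(unif_rand()) < d;
      if (ok) { u1 = u1p; f = fp; lv = lvp; lf = lfp; }
      if (adapting) step1 *= std::exp(((ok ? 1.0 : 0.0) - 0.4) / std::sqrt(t + 1.0));
      else acc1 += ok;
    }

    // variant-assay concentration: random walk on log scale; uniform prior
    // on [0, cvar_max] gives Jacobian log(cvar) and a hard upper bound
    {
      double u2p = u2 + step2 * norm_rand();
      double cp = std::exp(u2p);
      bool ok = false;
      if (cp < cvar_max) {
        double lvp = ll_var(k, n, v, cnv_mode, bias, g, f, cp);
        double d = (lvp + u2p) - (lv + u2);
        ok = std::log(unif_rand()) < d;
        if (ok) { u2 = u2p; cvar = cp; lv = lvp; }
      }
      if (adapting) step2 *= std::exp(((ok ? 1.0 : 0.0) - 0.4) / std::sqrt(t + 1.0));
      else acc2 += ok;
    }

    // fetal-fraction-assay concentration
    {
      double u3p = u3 + step3 * norm_rand();
      double cp = std::exp(u3p);
      bool ok = false;
      if (cp < cff_max) {
        double lfp = ll_ff(k, n, v, f, cp);
        double d = (lfp + u3p) - (lf + u3);
        ok = std::log(unif_rand()) < d;
        if (ok) { u3 = u3p; cff = cp; lf = lfp; }
      }
      if (adapting) step3 *= std::exp(((ok ? 1.0 : 0.0) - 0.4) / std::sqrt(t + 1.0));
      else acc3 += ok;
    }

    if (!adapting) ++n_post;
    int s_idx = t - adapt_iters - burn_in;
    if (s_idx >= 0) {
      draws(s_idx, 0) = f;
      draws(s_idx, 1) = cvar;
      draws(s_idx, 2) = cff;
      draws(s_idx, 3) = g;
    }
  }

  double denom = n_post > 0 ? (double)n_post : 1.0;
  return List::create(
    _["draws"] = draws,
    _["accept"] = NumericVector::create(
      _["f"] = acc1 / denom, _["conc_var"] = acc2 / denom,
      _["conc_ff"] = acc3 / denom),
    _["steps"] = NumericVector::create(step1, step2, step3));
}
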