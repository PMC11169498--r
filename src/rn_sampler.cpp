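// Single-chain Metropolis-within-Gibbs sampler for the hierarchical
// multi-species Royle-Nichols model with data augmentation.
//
// Model (species i, site j):
//   Z[i,j] ~ Poisson(lambda[i,j]) truncated to 0..z_max
//   log(lambda) = a0 + Xa %*% a[1:5]
//   logit(r)    = b0 + Xd %*% b[1:3]
//   Y[i,j] | w[i]=1 ~ Binomial(V[j], 1 - (1-r)^Z)
//   w[i] ~ Bernoulli(omega); a,b ~ Normal(mu, sd) per coefficient;
//   mu ~ Normal(0, mu_sd), sd ~ Uniform(0, sd_max), omega ~ Uniform(0,1).
//
// Updates: (1) w for augmented species from its Z-marginalized conditional,
// with an immediate Z redraw (partially collapsed Gibbs), then conjugate
// omega; (2) coefficients by per-coordinate adaptive random-walk Metropolis
// for included species, exact community-prior draws for excluded ones;
// (3) Z by exact enumeration of the full conditional; (4) conjugate normal
// Gibbs for community means, slice sampling for community sds (with
// non-centered interweaving moves to traverse the funnel).
// Proposal adaptation runs in batches during burn-in only, so the
// post-burn-in kernel satisfies detailed balance. All randomness comes from
// the R RNG, making runs reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const int NA_COEF = 6; // abundance coefficients a0..a5
static const int ND_COEF = 4; // detection coefficients b0..b3

// log(1 - r) for logit-scale eta, stable for |eta| large: -log(1 + exp(eta))
static inline double log_one_minus_r(double eta) {
  if (eta > 0) return -(eta + log1p(std::exp(-eta)));
  return -log1p(std::exp(eta));
}

static inline double ipow_small(double x, int n) {
  double out = 1.0;
  for (int k = 0; k < n; ++k) out *= x;
  return out;
}

// log of the truncation normalizer P(Pois(lambda) <= z_max). Z is modelled
// on 0..z_max, so the abundance-coefficient likelihood is the truncated
// Poisson; for lambda well below z_max the correction is < 1e-11 and
// skipped.
static inline double log_trunc_norm(double lambda, int z_max) {
  if (lambda <= 0.35 * z_max) return 0.0;
  return R::ppois((double)z_max, lambda, 1, 1);
}

struct ZDrawResult { int z; double tail_mass; };

// Univariate slice sampler on (lo, hi) with stepping-out and shrinkage
// (Neal 2003): exact and tuning-free, which matters near the sd -> 0
// funnel neck of the hierarchical variance parameters.
template <typename F>
static double slice_draw(double cur, double lo, double hi, double width,
                         F logf) {
  double y = logf(cur) - exp_rand();
  double L = cur - width * unif_rand();
  double R = L + width;
  if (L < lo) L = lo;
  if (R > hi) R = hi;
  int cap = 30;
  while (L > lo && logf(L) > y && cap-- > 0) L -= width;
  if (L < lo) L = lo;
  cap = 30;
  while (R < hi && logf(R) > y && cap-- > 0) R += width;
  if (R > hi) R = hi;
  for (int tries = 0; tries < 100; ++tries) {
    double x = L + unif_rand() * (R - L);
    if (logf(x) > y) return x;
    if (x < cur) L = x; else R = x;
  }
  return cur; // degenerate shrinkage: keep current value
}

// Centered update of a community sd given the M species coefficients:
// target log f(sd) = sum_i log N(c_i; mu, sd) under the Uniform(0, sd_max)
// prior.
static double slice_sd(double sd, double mu, const double *c, int stride,
                       int M, double sd_max) {
  return slice_draw(sd, 0.0, sd_max, 0.25, [&](double s) {
    if (s <= 0.0 || s >= sd_max) return R_NegInf;
    double ll = 0.0;
    for (int i = 0; i < M; ++i) ll += R::dnorm(c[i * stride], mu, s, 1);
    return ll;
  });
}

// Draw Z from the enumerated full conditional
//   p(z) propto Poisson(z; lambda) * p^Y * (1-p)^(V-Y),  p = 1 - (1-r)^z,
// over z = 0..z_max. `lq` is log(1-r). Falls back to log-space weights if
// the multiplicative path underflows.
static ZDrawResult draw_z_conditional(double lambda, double lq, int Y, int V,
                                      int z_max, std::vector<double> &buf) {
  double q = std::exp(lq);
  double pw = std::exp(-lambda); // Poisson weight at z = 0 (unnormalized)
  double g = ipow_small(q, V - Y);
  double h = 1.0, qz = 1.0, tot = 0.0;
  int z_top = z_max;
  if (pw > 0.0) {
    for (int z = 0; z <= z_max; ++z) {
      if (z > 0) { pw *= lambda / z; qz *= q; h *= g; }
      double p = 1.0 - qz;
      double term = pw * h;
      if (Y > 0) term *= ipow_small(p, Y);
      buf[z] = term;
      tot += term;
      if (z > lambda && term < tot * 1e-14) { z_top = z; break; }
    }
  }
  if (!(tot > 0.0)) { // log-space fallback (very large lambda or tiny r)
    double lpois = -lambda, mx = R_NegInf;
    z_top = z_max;
    for (int z = 0; z <= z_max; ++z) {
      if (z > 0) lpois += std::log(lambda) - std::log((double)z);
      double lp1m = z * lq;                 // log (1-p)
      double p = -std::expm1(lp1m);         // 1 - (1-r)^z
      double lw = lpois + (V - Y) * lp1m;
      if (Y > 0) lw += (p > 0.0 ? Y * std::log(p) : R_NegInf);
      buf[z] = lw;
      if (lw > mx) mx = lw;
    }
    tot = 0.0;
    for (int z = 0; z <= z_max; ++z) {
      buf[z] = std::isfinite(buf[z]) ? std::exp(buf[z] - mx) : 0.0;
      tot += buf[z];
    }
  }
  double u = unif_rand() * tot, cum = 0.0;
  int draw = z_top;
  for (int z = 0; z <= z_top; ++z) {
    cum += buf[z];
    if (u <= cum) { draw = z; break; }
  }
  ZDrawResult res;
  res.z = draw;
  res.tail_mass = (z_top == z_max && tot > 0.0) ? buf[z_max] / tot : 0.0;
  return res;
}

// log P(Y = 0 over V visits | lambda, r, z truncated to 0..z_max)
static double log_all_zero_prob(double lambda, double lq, int V, int z_max) {
  double s = std::exp(lq * V); // (1-r)^V
  double pw = std::exp(-lambda);
  double tot = 0.0, norm = 0.0, sz = 1.0;
  if (pw > 0.0) {
    for (int z = 0; z <= z_max; ++z) {
      if (z > 0) { pw *= lambda / z; sz *= s; }
      tot += pw * sz;
      norm += pw;
    }
    return std::log(tot) - std::log(norm);
  }
  // log-space fallback
  double lpois = -lambda, mx = R_NegInf, mxn = R_NegInf;
  std::vector<double> lw(z_max + 1), ln(z_max + 1);
  for (int z = 0; z <= z_max; ++z) {
    if (z > 0) lpois += std::log(lambda) - std::log((double)z);
    lw[z] = lpois + z * V * lq;
    ln[z] = lpois;
    if (lw[z] > mx) mx = lw[z];
    if (ln[z] > mxn) mxn = ln[z];
  }
  double t = 0.0, n = 0.0;
  for (int z = 0; z <= z_max; ++z) { t += std::exp(lw[z] - mx); n += std::exp(ln[z] - mxn); }
  return (mx + std::log(t)) - (mxn + std::log(n));
}

// Binomial log-likelihood of one species' history given Z (binomial
// coefficient dropped; constant in the parameters being updated).
static double det_loglik_row(const IntegerMatrix &Y, const IntegerVector &V,
                             const std::vector<double> &eta_d, int i, int J,
                             const int *Zrow) {
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    int y = Y(i, j), v = V[j], z = Zrow[j];
    double lq = log_one_minus_r(eta_d[j]);
    double lp1m = z * lq;
    if (y > 0) {
      double p = -std::expm1(lp1m);
      if (p <= 0.0) return R_NegInf;
      ll += y * std::log(p);
    }
    ll += (v - y) * lp1m;
  }
  return ll;
}

// [[Rcpp::export(name = ".rn_chain")]]
List rn_chain_cpp(IntegerMatrix Y, IntegerVector V,
                  NumericMatrix Xa, NumericMatrix Xd,
                  LogicalVector augmented, List init,
                  double mu_sd, double sd_max, int z_max,
                  int n_iter, int burn_in, int thin,
                  int adapt_interval, double target_accept) {
  const int M = Y.nrow(), J = Y.ncol();
  if (Xa.nrow() != J || Xd.nrow() != J) stop("design matrix rows != sites");
  const int Ka = Xa.ncol(), Kd = Xd.ncol(); // slope counts (5 and 3)
  if (Ka != NA_COEF - 1 || Kd != ND_COEF - 1) stop("unexpected design matrix widths");

  NumericMatrix a = clone(as<NumericMatrix>(init["a"]));
  NumericMatrix b = clone(as<NumericMatrix>(init["b"]));
  NumericVector mu_a = clone(as<NumericVector>(init["mu_a"]));
  NumericVector sd_a = clone(as<NumericVector>(init["sd_a"]));
  NumericVector mu_b = clone(as<NumericVector>(init["mu_b"]));
  NumericVector sd_b = clone(as<NumericVector>(init["sd_b"]));
  double omega = as<double>(init["omega"]);
  IntegerMatrix Z = clone(as<IntegerMatrix>(init["Z"]));
  IntegerVector w = clone(as<IntegerVector>(init["w"]));

  // cached linear predictors per species x site
  std::vector<double> eta_a(M * J), eta_d(M * J), lam(M * J);
  auto refresh_eta_a = [&](int i) {
    for (int j = 0; j < J; ++j) {
      double e = a(i, 0);
      for (int k = 0; k < Ka; ++k) e += a(i, k + 1) * Xa(j, k);
      if (e > 30.0) e = 30.0;
      if (e < -30.0) e = -30.0;
      eta_a[i * J + j] = e;
      lam[i * J + j] = std::exp(e);
    }
  };
  auto refresh_eta_d = [&](int i) {
    for (int j = 0; j < J; ++j) {
      double e = b(i, 0);
      for (int k = 0; k < Kd; ++k) e += b(i, k + 1) * Xd(j, k);
      eta_d[i * J + j] = e;
    }
  };
  for (int i = 0; i < M; ++i) { refresh_eta_a(i); refresh_eta_d(i); }

  // adaptive proposal log-scales and batch acceptance counters
  NumericMatrix ls_a(M, NA_COEF), ls_b(M, ND_COEF);
  std::fill(ls_a.begin(), ls_a.end(), std::log(0.3));
  std::fill(ls_b.begin(), ls_b.end(), std::log(0.3));
  NumericVector ls_tra(NA_COEF, std::log(0.3)), ls_trb(ND_COEF, std::log(0.3));
  IntegerVector acc_tra(NA_COEF), acc_trb(ND_COEF);
  IntegerVector try_tra(NA_COEF), try_trb(ND_COEF);
  IntegerMatrix acc_a(M, NA_COEF), acc_b(M, ND_COEF);
  IntegerMatrix try_a(M, NA_COEF), try_b(M, ND_COEF);
  long long acc_total = 0, try_total = 0;

  const int n_ret = (n_iter - burn_in) / thin;
  const int n_hyper = 2 * NA_COEF + 2 * ND_COEF + 1; // mus, sds, omega
  const int P = n_hyper + M * (NA_COEF + ND_COEF) + M; // + coefs + w
  NumericMatrix draws(n_ret, P);
  IntegerVector Zdraws(n_ret * M * J);
  double max_tail = 0.0;

  std::vector<double> buf(z_max + 1);
  std::vector<double> eta_tmp(J);
  std::vector<int> zrow(J);
  int batch = 0, kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- (1) inclusion indicators + omega ------------------------------
    int w_sum = 0;
    for (int i = 0; i < M; ++i) {
      if (augmented[i]) {
        double logL = 0.0;
        for (int j = 0; j < J; ++j) {
          logL += log_all_zero_prob(lam[i * J + j],
                                    log_one_minus_r(eta_d[i * J + j]),
                                    V[j], z_max);
        }
        // q = omega L / (omega L + 1 - omega), stable on the logit scale
        double logit_q = std::log(omega) - std::log1p(-omega) + logL;
        double q = 1.0 / (1.0 + std::exp(-logit_q));
        w[i] = (unif_rand() < q) ? 1 : 0;
        for (int j = 0; j < J; ++j) {
          double lq = log_one_minus_r(eta_d[i * J + j]);
          ZDrawResult res = w[i] == 1
            ? draw_z_conditional(lam[i * J + j], lq, 0, V[j], z_max, buf)
            : draw_z_conditional(lam[i * J + j], 0.0, 0, 0, z_max, buf);
          Z(i, j) = res.z;
          // tail mass is only a truncation-adequacy signal for
          // data-informed conditionals, not prior draws
          if (w[i] == 1 && res.tail_mass > max_tail) max_tail = res.tail_mass;
        }
      }
      w_sum += w[i];
    }
    omega = R::rbeta(1.0 + w_sum, 1.0 + (M - w_sum));

    // --- (2) species coefficients --------------------------------------
    for (int i = 0; i < M; ++i) {
      if (w[i] == 0) { // excluded: exact draws from community prior
        for (int k = 0; k < NA_COEF; ++k) a(i, k) = R::rnorm(mu_a[k], sd_a[k]);
        for (int k = 0; k < ND_COEF; ++k) b(i, k) = R::rnorm(mu_b[k], sd_b[k]);
        refresh_eta_a(i); refresh_eta_d(i);
        for (int j = 0; j < J; ++j) {
          ZDrawResult res = draw_z_conditional(lam[i * J + j], 0.0, 0, 0,
                                               z_max, buf);
          Z(i, j) = res.z;
        }
        continue;
      }
      // abundance coefficients: Poisson(Z | lambda) x Normal prior
      for (int k = 0; k < NA_COEF; ++k) {
        double eps = R::rnorm(0.0, std::exp(ls_a(i, k)));
        double delta = R::dnorm(a(i, k) + eps, mu_a[k], sd_a[k], 1) -
                       R::dnorm(a(i, k), mu_a[k], sd_a[k], 1);
        for (int j = 0; j < J; ++j) {
          double x = (k == 0) ? 1.0 : Xa(j, k - 1);
          double e_new = eta_a[i * J + j] + eps * x;
          if (e_new > 30.0) e_new = 30.0;
          if (e_new < -30.0) e_new = -30.0;
          double lam_new = std::exp(e_new);
          delta += Z(i, j) * (e_new - eta_a[i * J + j]) -
                   (lam_new - lam[i * J + j]) +
                   log_trunc_norm(lam[i * J + j], z_max) -
                   log_trunc_norm(lam_new, z_max);
          eta_tmp[j] = e_new;
        }
        ++try_a(i, k); ++try_total;
        if (std::isfinite(delta) && std::log(unif_rand()) < delta) {
          a(i, k) += eps;
          for (int j = 0; j < J; ++j) {
            eta_a[i * J + j] = eta_tmp[j];
            lam[i * J + j] = std::exp(eta_tmp[j]);
          }
          ++acc_a(i, k); ++acc_total;
        }
      }
      // detection coefficients: Binomial(Y | V, 1-(1-r)^Z) x Normal prior
      for (int j = 0; j < J; ++j) zrow[j] = Z(i, j);
      std::vector<double> eta_cur(eta_d.begin() + i * J,
                                  eta_d.begin() + (i + 1) * J);
      double ll_cur = det_loglik_row(Y, V, eta_cur, i, J, zrow.data());
      // two sweeps: detection coefficients are the slowest species-level
      // block (weakly identified for rare and augmented species)
      for (int rep2 = 0; rep2 < 2; ++rep2)
      for (int k = 0; k < ND_COEF; ++k) {
        double eps = R::rnorm(0.0, std::exp(ls_b(i, k)));
        for (int j = 0; j < J; ++j) {
          double x = (k == 0) ? 1.0 : Xd(j, k - 1);
          eta_tmp[j] = eta_cur[j] + eps * x;
        }
        double ll_new = det_loglik_row(Y, V, eta_tmp, i, J, zrow.data());
        double delta = ll_new - ll_cur +
          R::dnorm(b(i, k) + eps, mu_b[k], sd_b[k], 1) -
          R::dnorm(b(i, k), mu_b[k], sd_b[k], 1);
        ++try_b(i, k); ++try_total;
        if (std::isfinite(delta) && std::log(unif_rand()) < delta) {
          b(i, k) += eps;
          for (int j = 0; j < J; ++j) eta_cur[j] = eta_tmp[j];
          ll_cur = ll_new;
          ++acc_b(i, k); ++acc_total;
        }
      }
      for (int j = 0; j < J; ++j) eta_d[i * J + j] = eta_cur[j];
    }

    // --- (3) latent abundance for included species ---------------------
    for (int i = 0; i < M; ++i) {
      if (w[i] == 0) continue; // refreshed in step 2
      for (int j = 0; j < J; ++j) {
        double lq = log_one_minus_r(eta_d[i * J + j]);
        ZDrawResult res = draw_z_conditional(lam[i * J + j], lq, Y(i, j),
                                             V[j], z_max, buf);
        Z(i, j) = res.z;
        if (res.tail_mass > max_tail) max_tail = res.tail_mass;
      }
    }

    // --- (4) community hyperparameters ---------------------------------
    for (int k = 0; k < NA_COEF; ++k) {
      double sum = 0.0;
      for (int i = 0; i < M; ++i) sum += a(i, k);
      double prec = M / (sd_a[k] * sd_a[k]) + 1.0 / (mu_sd * mu_sd);
      mu_a[k] = R::rnorm((sum / (sd_a[k] * sd_a[k])) / prec,
                         std::sqrt(1.0 / prec));
      sd_a[k] = slice_sd(sd_a[k], mu_a[k], &a(0, k), 1, M, sd_max);
    }
    for (int k = 0; k < ND_COEF; ++k) {
      double sum = 0.0;
      for (int i = 0; i < M; ++i) sum += b(i, k);
      double prec = M / (sd_b[k] * sd_b[k]) + 1.0 / (mu_sd * mu_sd);
      mu_b[k] = R::rnorm((sum / (sd_b[k] * sd_b[k])) / prec,
                         std::sqrt(1.0 / prec));
      sd_b[k] = slice_sd(sd_b[k], mu_b[k], &b(0, k), 1, M, sd_max);
    }

    // --- (5) non-centered slice update of each community sd -------------
    // Interweaving move: with standardized deviations eta_i = (c_i - mu)/sd
    // held fixed, the sd is slice-sampled from its non-centered conditional
    // (the data likelihood with every species coefficient rescaled jointly;
    // the eta_i keep their N(0,1) prior, the sd its uniform prior). This
    // traverses the sd -> 0 funnel that freezes a purely centered sampler
    // when a community sd is weakly identified.
    for (int k = 0; k < NA_COEF; ++k) {
      double sd0 = sd_a[k];
      std::vector<double> eta_i(M);
      for (int i = 0; i < M; ++i) eta_i[i] = (a(i, k) - mu_a[k]) / sd0;
      auto logf = [&](double s) {
        if (s <= 0.0 || s >= sd_max) return R_NegInf;
        double ll = 0.0;
        for (int i = 0; i < M; ++i) {
          double shift = eta_i[i] * (s - sd0);
          for (int j = 0; j < J; ++j) {
            double x = (k == 0) ? 1.0 : Xa(j, k - 1);
            double e = eta_a[i * J + j] + shift * x;
            if (e > 30.0) e = 30.0;
            if (e < -30.0) e = -30.0;
            double lam_e = std::exp(e);
            ll += Z(i, j) * e - lam_e - log_trunc_norm(lam_e, z_max);
          }
        }
        return ll;
      };
      double s_new = slice_draw(sd0, 0.0, sd_max, 0.25, logf);
      if (s_new != sd0) {
        sd_a[k] = s_new;
        for (int i = 0; i < M; ++i) a(i, k) += eta_i[i] * (s_new - sd0);
        for (int i = 0; i < M; ++i) refresh_eta_a(i);
      }
    }
    for (int k = 0; k < ND_COEF; ++k) {
      double sd0 = sd_b[k];
      std::vector<double> eta_i(M);
      for (int i = 0; i < M; ++i) eta_i[i] = (b(i, k) - mu_b[k]) / sd0;
      auto logf = [&](double s) {
        if (s <= 0.0 || s >= sd_max) return R_NegInf;
        double ll = 0.0;
        for (int i = 0; i < M; ++i) {
          if (w[i] == 0) continue; // excluded species carry no data term
          double shift = eta_i[i] * (s - sd0);
          for (int j = 0; j < J; ++j) {
            double x = (k == 0) ? 1.0 : Xd(j, k - 1);
            eta_tmp[j] = eta_d[i * J + j] + shift * x;
          }
          for (int j = 0; j < J; ++j) zrow[j] = Z(i, j);
          double li = det_loglik_row(Y, V, eta_tmp, i, J, zrow.data());
          if (!std::isfinite(li)) return R_NegInf;
          ll += li;
        }
        return ll;
      };
      double s_new = slice_draw(sd0, 0.0, sd_max, 0.25, logf);
      if (s_new != sd0) {
        sd_b[k] = s_new;
        for (int i = 0; i < M; ++i) b(i, k) += eta_i[i] * (s_new - sd0);
        for (int i = 0; i < M; ++i) refresh_eta_d(i);
      }
    }
    for (int sweep = 0; sweep < 2; ++sweep) {
    // Interweaving translation move: shift mu_k and every species
    // coefficient k by the same delta (deviations fixed). Moves the
    // community mean through the data likelihood directly, the direction
    // the centered Gibbs step traverses slowly when abundance covariates
    // are confounded (fire status vs burned-area proportion).
    for (int k = 0; k < NA_COEF; ++k) {
      double delta = R::rnorm(0.0, std::exp(ls_tra[k]));
      ++try_tra[k]; ++try_total;
      double lr = R::dnorm(mu_a[k] + delta, 0.0, mu_sd, 1) -
                  R::dnorm(mu_a[k], 0.0, mu_sd, 1);
      for (int i = 0; i < M; ++i) {
        for (int j = 0; j < J; ++j) {
          double x = (k == 0) ? 1.0 : Xa(j, k - 1);
          double e_new = eta_a[i * J + j] + delta * x;
          if (e_new > 30.0) e_new = 30.0;
          if (e_new < -30.0) e_new = -30.0;
          double lam_new = std::exp(e_new);
          lr += Z(i, j) * (e_new - eta_a[i * J + j]) -
                (lam_new - lam[i * J + j]) +
                log_trunc_norm(lam[i * J + j], z_max) -
                log_trunc_norm(lam_new, z_max);
        }
      }
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        mu_a[k] += delta;
        for (int i = 0; i < M; ++i) a(i, k) += delta;
        for (int i = 0; i < M; ++i) refresh_eta_a(i);
        ++acc_tra[k]; ++acc_total;
      }
    }
    for (int k = 0; k < ND_COEF; ++k) {
      double delta = R::rnorm(0.0, std::exp(ls_trb[k]));
      ++try_trb[k]; ++try_total;
      double lr = R::dnorm(mu_b[k] + delta, 0.0, mu_sd, 1) -
                  R::dnorm(mu_b[k], 0.0, mu_sd, 1);
      bool ok = true;
      for (int i = 0; i < M && ok; ++i) {
        if (w[i] == 0) continue;
        for (int j = 0; j < J; ++j) {
          double x = (k == 0) ? 1.0 : Xd(j, k - 1);
          eta_tmp[j] = eta_d[i * J + j] + delta * x;
        }
        for (int j = 0; j < J; ++j) zrow[j] = Z(i, j);
        std::vector<double> eta_old(eta_d.begin() + i * J,
                                    eta_d.begin() + (i + 1) * J);
        lr += det_loglik_row(Y, V, eta_tmp, i, J, zrow.data()) -
              det_loglik_row(Y, V, eta_old, i, J, zrow.data());
        if (!std::isfinite(lr)) ok = false;
      }
      if (ok && std::isfinite(lr) && std::log(unif_rand()) < lr) {
        mu_b[k] += delta;
        for (int i = 0; i < M; ++i) b(i, k) += delta;
        for (int i = 0; i < M; ++i) refresh_eta_d(i);
        ++acc_trb[k]; ++acc_total;
      }
    }
    } // translation sweeps

    // --- adaptation (burn-in only) --------------------------------------
    if (iter <= burn_in && iter % adapt_interval == 0) {
      ++batch;
      double step = std::min(0.05, 1.0 / std::sqrt((double)batch));
      auto adapt = [&](double &ls, int &acc, int &tries) {
        if (tries > 0) {
          ls += ((double)acc / tries > target_accept ? step : -step);
          if (ls < -8.0) ls = -8.0;
          if (ls > 4.0) ls = 4.0;
        }
        acc = 0; tries = 0;
      };
      for (int i = 0; i < M; ++i) {
        for (int k = 0; k < NA_COEF; ++k) adapt(ls_a(i, k), acc_a(i, k), try_a(i, k));
        for (int k = 0; k < ND_COEF; ++k) adapt(ls_b(i, k), acc_b(i, k), try_b(i, k));
      }
      for (int k = 0; k < NA_COEF; ++k) adapt(ls_tra[k], acc_tra[k], try_tra[k]);
      for (int k = 0; k < ND_COEF; ++k) adapt(ls_trb[k], acc_trb[k], try_trb[k]);
    }

    // --- retention ------------------------------------------------------
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      int col = 0;
      for (int k = 0; k < NA_COEF; ++k) draws(kept, col++) = mu_a[k];
      for (int k = 0; k < NA_COEF; ++k) draws(kept, col++) = sd_a[k];
      for (int k = 0; k < ND_COEF; ++k) draws(kept, col++) = mu_b[k];
      for (int k = 0; k < ND_COEF; ++k) draws(kept, col++) = sd_b[k];
      draws(kept, col++) = omega;
      for (int k = 0; k < NA_COEF; ++k)
        for (int i = 0; i < M; ++i) draws(kept, col++) = a(i, k);
      for (int k = 0; k < ND_COEF; ++k)
        for (int i = 0; i < M; ++i) draws(kept, col++) = b(i, k);
      for (int i = 0; i < M; ++i) draws(kept, col++) = (double)w[i];
      for (int i = 0; i < M; ++i)
        for (int j = 0; j < J; ++j)
          Zdraws[kept + n_ret * (i + M * j)] = Z(i, j);
      ++kept;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["Z"] = Zdraws,
    _["n_ret"] = n_ret,
    _["accept_rate"] = (try_total > 0) ? (double)acc_total / try_total : NA_REAL,
    _["max_zmax_tail"] = max_tail);
}

// [[Rcpp::export(name = ".rn_z_draws")]]
IntegerVector rn_z_draws_cpp(double lambda, double r, int Y, int V,
                             int z_max, int n) {
  // repeated draws from the enumerated Z full conditional (for sampler
  // vs pmf chi-square checks)
  std::vector<double> buf(z_max + 1);
  double lq = log1p(-r);
  IntegerVector out(n);
  for (int t = 0; t < n; ++t) {
    out[t] = draw_z_conditional(lambda, lq, Y, V, z_max, buf).z;
  }
  return out;
}
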