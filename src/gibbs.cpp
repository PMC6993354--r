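// Single-site Gibbs sampler for the hierarchical repeatability model:
//   y = X b + herd + CowA + CowPE + e,   CowA_l = sum_m g_lm a_m
// Flat priors on fixed effects b; N(0, s2) priors on herd, PE and SNP
// effects; variances get flat priors on (0, bound] realised as truncated
// scaled-inverse-chi-square conditional draws. All random numbers come from
// R's RNG, so set.seed() upstream makes chains bit-reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double draw_var(double ss, double df, double bound) {
  // flat prior on sigma^2  =>  sigma^2 | data  ~  ss / chisq(df), truncated
  for (int t = 0; t < 100; ++t) {
    double v = ss / R::rchisq(df);
    if (v <= bound) return v;
  }
  return bound;
}

// [[Rcpp::export(name = ".gibbs_repeatability")]]
List gibbs_repeatability(const arma::vec& y,
                         const arma::mat& X,
                         const arma::ivec& herd,   // 0-based per record
                         const arma::ivec& cow,    // 0-based per record
                         const arma::mat& Gc,      // cows x SNPs, centred
                         int n_iter, int burn_in, int thin,
                         double bound,
                         NumericVector init_b,
                         NumericVector init_var,   // s2H, s2PE, s2E, s2a
                         bool update_vars,
                         bool store_effects) {
  const int n = y.n_elem, q = X.n_cols;
  const int n_cows = Gc.n_rows, p = Gc.n_cols;
  const int n_herds = herd.max() + 1;

  arma::vec b(q), h(n_herds, arma::fill::zeros),
    pe(n_cows, arma::fill::zeros), a(p, arma::fill::zeros),
    u(n_cows, arma::fill::zeros);
  for (int j = 0; j < q; ++j) b[j] = init_b[j];
  double s2H = init_var[0], s2PE = init_var[1], s2E = init_var[2],
    s2a = init_var[3];

  // sufficient statistics that never change. Fixed effects are drawn as a
  // block from N((X'X)^-1 X'(e + Xb), s2E (X'X)^-1): the Wilmink term is
  // nearly collinear with intercept + DIM, and single-site updates would
  // random-walk along that ridge for thousands of iterations.
  arma::mat XtX = X.t() * X;
  XtX.diag() += 1e-10 * arma::trace(XtX) / q;  // guard exact collinearity
  arma::mat Rchol = arma::chol(XtX);           // upper triangular
  arma::vec n_herd(n_herds, arma::fill::zeros), n_cow(n_cows, arma::fill::zeros);
  for (int i = 0; i < n; ++i) { n_herd[herd[i]] += 1.0; n_cow[cow[i]] += 1.0; }
  arma::vec cgg(p);  // sum_l n_l g_lm^2
  for (int m = 0; m < p; ++m) {
    double s = 0.0;
    for (int l = 0; l < n_cows; ++l) s += n_cow[l] * Gc(l, m) * Gc(l, m);
    cgg[m] = s;
  }

  arma::vec e = y - X * b;  // residual at current state (random effects 0)

  const int n_save = (n_iter - burn_in) / thin;
  arma::mat sv_b(n_save, q), sv_a(n_save, p), sv_u(n_save, n_cows);
  arma::mat sv_h, sv_pe;
  if (store_effects) { sv_h.set_size(n_save, n_herds); sv_pe.set_size(n_save, n_cows); }
  arma::mat sv_var(n_save, 4);
  int at_bound = 0, var_draws = 0, save_i = 0;

  arma::vec s_cow(n_cows);  // per-cow residual sums, rebuilt each SNP sweep

  for (int it = 1; it <= n_iter; ++it) {
    // --- fixed effects (flat prior, joint conjugate block draw) ---
    {
      arma::vec rhs = X.t() * e + XtX * b;
      arma::vec mu_b = arma::solve(arma::trimatl(Rchol.t()),
                                   rhs, arma::solve_opts::fast);
      mu_b = arma::solve(arma::trimatu(Rchol), mu_b, arma::solve_opts::fast);
      arma::vec z(q);
      for (int j = 0; j < q; ++j) z[j] = R::norm_rand();
      arma::vec bn = mu_b + std::sqrt(s2E) *
        arma::solve(arma::trimatu(Rchol), z, arma::solve_opts::fast);
      e -= X * (bn - b);
      b = bn;
    }
    // --- herd effects ---
    // records of different herds are disjoint, so all herds can be updated
    // from one pass of per-herd residual sums
    {
      double lam = (s2H > 0.0) ? s2E / s2H : 1e12;
      arma::vec s(n_herds, arma::fill::zeros);
      for (int i = 0; i < n; ++i) s[herd[i]] += e[i];
      for (int k = 0; k < n_herds; ++k) {
        double C = n_herd[k] + lam;
        double rhs = s[k] + n_herd[k] * h[k];
        h[k] = rhs / C + std::sqrt(s2E / C) * R::norm_rand();
      }
      e = y - X * b;
      for (int i = 0; i < n; ++i) e[i] -= h[herd[i]] + pe[cow[i]] + u[cow[i]];
    }
    // --- permanent environment effects (cows disjoint, same scheme) ---
    {
      double lam = (s2PE > 0.0) ? s2E / s2PE : 1e12;
      arma::vec s(n_cows, arma::fill::zeros);
      for (int i = 0; i < n; ++i) s[cow[i]] += e[i];
      for (int l = 0; l < n_cows; ++l) {
        double C = n_cow[l] + lam;
        double rhs = s[l] + n_cow[l] * pe[l];
        pe[l] = rhs / C + std::sqrt(s2E / C) * R::norm_rand();
      }
      e = y - X * b;
      for (int i = 0; i < n; ++i) e[i] -= h[herd[i]] + pe[cow[i]] + u[cow[i]];
    }
    // --- SNP effects (cow-level sufficient statistics) ---
    {
      double lam = (s2a > 0.0) ? s2E / s2a : 1e12;
      s_cow.zeros();
      for (int i = 0; i < n; ++i) s_cow[cow[i]] += e[i];
      for (int m = 0; m < p; ++m) {
        if (cgg[m] <= 0.0) { a[m] = 0.0; continue; }
        const double* g = Gc.colptr(m);
        double rhs = 0.0;
        for (int l = 0; l < n_cows; ++l) rhs += g[l] * s_cow[l];
        rhs += a[m] * cgg[m];
        double C = cgg[m] + lam;
        double an = rhs / C + std::sqrt(s2E / C) * R::norm_rand();
        double d = an - a[m];
        if (d != 0.0) {
          for (int l = 0; l < n_cows; ++l) {
            u[l] += g[l] * d;
            s_cow[l] -= n_cow[l] * g[l] * d;
          }
        }
        a[m] = an;
      }
      // rebuild record residuals exactly (also kills float drift)
      e = y - X * b;
      for (int i = 0; i < n; ++i) e[i] -= h[herd[i]] + pe[cow[i]] + u[cow[i]];
    }
    // --- variance components ---
    if (update_vars) {
      double ssE = arma::dot(e, e);
      s2E = draw_var(ssE, std::max((double)n - 2.0, 1.0), bound);
      double ssH = arma::dot(h, h);
      s2H = draw_var(ssH, std::max((double)n_herds - 2.0, 1.0), bound);
      double ssPE = arma::dot(pe, pe);
      s2PE = draw_var(ssPE, std::max((double)n_cows - 2.0, 1.0), bound);
      double ssA = arma::dot(a, a);
      s2a = draw_var(ssA, std::max((double)p - 2.0, 1.0), bound);
      var_draws += 4;
      at_bound += (s2E >= bound) + (s2H >= bound) + (s2PE >= bound) + (s2a >= bound);
    }
    // --- save ---
    if (it > burn_in && (it - burn_in) % thin == 0 && save_i < n_save) {
      for (int j = 0; j < q; ++j) sv_b(save_i, j) = b[j];
      for (int m = 0; m < p; ++m) sv_a(save_i, m) = a[m];
      for (int l = 0; l < n_cows; ++l) sv_u(save_i, l) = u[l];
      if (store_effects) {
        for (int k = 0; k < n_herds; ++k) sv_h(save_i, k) = h[k];
        for (int l = 0; l < n_cows; ++l) sv_pe(save_i, l) = pe[l];
      }
      sv_var(save_i, 0) = s2H; sv_var(save_i, 1) = s2PE;
      sv_var(save_i, 2) = s2E; sv_var(save_i, 3) = s2a;
      ++save_i;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["fixed"] = sv_b, _["snp"] = sv_a, _["cow_a"] = sv_u,
    _["var"] = sv_var,
    _["bound_frac"] = var_draws > 0 ? (double)at_bound / var_draws : 0.0);
  if (store_effects) { out["herd"] = sv_h; out["pe"] = sv_pe; }
  return out;
}
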