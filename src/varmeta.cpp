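// Hierarchical random-variance model: joint log density on the unconstrained
// scale, analytic gradient, and a no-U-turn sampler (slice variant, dual
// averaging, windowed diagonal mass-matrix adaptation).
//
// Unconstrained parameter layout (D = 2 + 2P + n_multi + n_multi_batches):
//   [0]            mu            population location
//   [1]            eta = ln(sigma)
//   [2 .. 2+P)     mu_i          product means
//   [2+P .. 2+2P)  u_i           non-centered product log-SDs:
//                                ln(sigma_i) = mu + sigma * u_i, u_i ~ N(0,1)
//   then           q_i = logit(p_i)       one per multi-cycle product
//   then           z_ij                   one per multi-cycle batch
// with tau_i = sigma_i*sqrt(p_i), nu_i = sigma_i*sqrt(1-p_i),
// mu_ij = mu_i + tau_i*z_ij (non-centered batch means).
//
// Likelihood terms use per-batch sufficient statistics (n, sum, sum of
// squares), so a gradient evaluation is O(P + total batches).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

struct Model {
  int P = 0, D = 0;
  std::vector<int> mode;           // 0 single-cycle, 1 multi-cycle
  std::vector<double> scn, scs, scss; // single-cycle sufficient stats per product
  std::vector<int> bptr;           // P+1 offsets into batch arrays (multi only)
  std::vector<double> bn, bs, bss; // per-batch sufficient stats
  std::vector<int> qidx, zidx0;    // layout indices (-1 for single-cycle)
  double s_mu = 1, s_sig = 1, s_pm = 5;
};

static Model build_model(const List& md, const List& prior) {
  Model M;
  IntegerVector mode = md["modes"];
  M.P = mode.size();
  M.mode.assign(mode.begin(), mode.end());
  NumericVector scn = md["sc_n"], scs = md["sc_sum"], scss = md["sc_ss"];
  M.scn.assign(scn.begin(), scn.end());
  M.scs.assign(scs.begin(), scs.end());
  M.scss.assign(scss.begin(), scss.end());
  IntegerVector bptr = md["bptr"];
  M.bptr.assign(bptr.begin(), bptr.end());
  NumericVector bn = md["b_n"], bs = md["b_sum"], bss = md["b_ss"];
  M.bn.assign(bn.begin(), bn.end());
  M.bs.assign(bs.begin(), bs.end());
  M.bss.assign(bss.begin(), bss.end());
  M.s_mu = as<double>(prior["mu_prior_sd"]);
  M.s_sig = as<double>(prior["sigma_prior_sd"]);
  M.s_pm = as<double>(prior["product_mean_prior_sd"]);
  int pos = 2 + 2 * M.P;
  M.qidx.assign(M.P, -1);
  M.zidx0.assign(M.P, -1);
  for (int i = 0; i < M.P; ++i)
    if (M.mode[i] == 1) M.qidx[i] = pos++;
  for (int i = 0; i < M.P; ++i)
    if (M.mode[i] == 1) {
      M.zidx0[i] = pos;
      pos += M.bptr[i + 1] - M.bptr[i];
    }
  M.D = pos;
  return M;
}

// joint log density and gradient; returns -inf (grad unspecified) when the
// evaluation is not finite
static double logpost_grad(const Model& M, const double* th, double* g) {
  const int P = M.P;
  for (int d = 0; d < M.D; ++d) g[d] = 0.0;
  const double mu = th[0], eta = th[1];
  const double sigma = std::exp(eta), sig2 = sigma * sigma;

  double lp = -0.5 * mu * mu / (M.s_mu * M.s_mu) - 0.5 * LOG2PI - std::log(M.s_mu);
  g[0] += -mu / (M.s_mu * M.s_mu);

  // half-normal prior on sigma, sampled as eta (Jacobian + eta)
  lp += std::log(2.0) - 0.5 * LOG2PI - std::log(M.s_sig)
      - 0.5 * sig2 / (M.s_sig * M.s_sig) + eta;
  g[1] += 1.0 - sig2 / (M.s_sig * M.s_sig);

  for (int i = 0; i < P; ++i) {
    const int imu = 2 + i, iu = 2 + P + i;
    const double mui = th[imu], u = th[iu];
    const double lam = mu + sigma * u; // ln(sigma_i), non-centered
    const double sig_i = std::exp(lam), sig_i2 = sig_i * sig_i;
    double dlam = 0.0; // accumulated d lp / d lam from likelihood terms

    lp += -0.5 * mui * mui / (M.s_pm * M.s_pm) - 0.5 * LOG2PI - std::log(M.s_pm);
    g[imu] += -mui / (M.s_pm * M.s_pm);

    // standard-normal prior on the non-centered deviate
    lp += -0.5 * LOG2PI - 0.5 * u * u;
    g[iu] += -u;

    if (M.mode[i] == 0) {
      const double n = M.scn[i], S = M.scs[i], SS = M.scss[i];
      const double ss = SS - 2.0 * mui * S + n * mui * mui;
      lp += -0.5 * n * LOG2PI - n * lam - 0.5 * ss / sig_i2;
      g[imu] += (S - n * mui) / sig_i2;
      dlam += -n + ss / sig_i2;
    } else {
      const int iq = M.qidx[i];
      const double q = th[iq];
      const double p = 1.0 / (1.0 + std::exp(-q));
      const double tau = sig_i * std::sqrt(p), nu = sig_i * std::sqrt(1.0 - p);
      // uniform prior on p via logit Jacobian
      lp += std::log(p) + std::log(1.0 - p);
      g[iq] += 1.0 - 2.0 * p;
      double dtau = 0.0, dnu = 0.0;
      const double nu2 = nu * nu;
      for (int b = M.bptr[i]; b < M.bptr[i + 1]; ++b) {
        const int iz = M.zidx0[i] + (b - M.bptr[i]);
        const double z = th[iz];
        lp += -0.5 * LOG2PI - 0.5 * z * z;
        g[iz] += -z;
        const double m = mui + tau * z;
        const double n = M.bn[b], S = M.bs[b], SS = M.bss[b];
        const double ss = SS - 2.0 * m * S + n * m * m;
        lp += -0.5 * n * LOG2PI - n * std::log(nu) - 0.5 * ss / nu2;
        const double dm = (S - n * m) / nu2;
        g[imu] += dm;
        g[iz] += dm * tau;
        dtau += dm * z;
        dnu += -n / nu + ss / (nu2 * nu);
      }
      dlam += dtau * tau + dnu * nu;
      g[iq] += dtau * tau * (1.0 - p) * 0.5 - dnu * nu * p * 0.5;
    }
    // chain rule through lam = mu + sigma * u
    g[0] += dlam;
    g[1] += dlam * sigma * u;
    g[iu] += dlam * sigma;
  }
  if (!std::isfinite(lp)) return -INFINITY;
  return lp;
}

// [[Rcpp::export]]
List vm_lp_grad(NumericVector theta, List model_data, List prior) {
  Model M = build_model(model_data, prior);
  if ((int)theta.size() != M.D) stop("theta has wrong length (expected %d)", M.D);
  NumericVector g(M.D);
  double lp = logpost_grad(M, theta.begin(), g.begin());
  return List::create(_["lp"] = lp, _["grad"] = g, _["dim"] = M.D);
}

// ---------------------------------------------------------------------------
// NUTS

struct State {
  std::vector<double> th, r, g;
  State(int D) : th(D), r(D), g(D) {}
};

struct Sampler {
  const Model* M;
  std::vector<double> em; // diagonal inverse mass (posterior variance est.)
  double eps = 0.05, delta = 0.95;
  int max_depth = 15;
  // per-iteration scratch
  double H0 = 0, logu = 0, alpha_sum = 0;
  int n_alpha = 0;
  bool divergent = false;

  double kinetic(const std::vector<double>& r) const {
    double k = 0;
    for (size_t d = 0; d < r.size(); ++d) k += r[d] * r[d] * em[d];
    return 0.5 * k;
  }

  void leapfrog(State& s, double dir) {
    const int D = M->D;
    const double e = dir * eps;
    for (int d = 0; d < D; ++d) s.r[d] += 0.5 * e * s.g[d];
    for (int d = 0; d < D; ++d) s.th[d] += e * em[d] * s.r[d];
    double lp = logpost_grad(*M, s.th.data(), s.g.data());
    s_lp = lp;
    for (int d = 0; d < D; ++d) s.r[d] += 0.5 * e * s.g[d];
  }
  double s_lp = 0;

  bool no_uturn(const State& sm, const State& sp) const {
    double dm = 0, dp = 0;
    for (int d = 0; d < M->D; ++d) {
      const double dth = sp.th[d] - sm.th[d];
      dm += dth * em[d] * sm.r[d];
      dp += dth * em[d] * sp.r[d];
    }
    return dm >= 0 && dp >= 0;
  }

  struct Tree {
    State sm, sp, sel;
    double n = 0;
    bool s = true;
    Tree(int D) : sm(D), sp(D), sel(D) {}
  };

  // preallocated scratch trees: two per recursion level, so subtree
  // construction never allocates
  std::vector<Tree> pool;
  void init_pool() {
    pool.assign(2 * (max_depth + 1), Tree(M->D));
  }

  // build a subtree of depth j starting from `from` in direction `dir`,
  // writing the result into `out`
  void build(const State& from, double dir, int j, Tree& out) {
    if (j == 0) {
      out.sel = from;
      leapfrog(out.sel, dir);
      double H = std::isfinite(s_lp) ? s_lp - kinetic(out.sel.r) : -INFINITY;
      out.n = (logu <= H) ? 1.0 : 0.0;
      out.s = (logu < H + 1000.0);
      if (!out.s) divergent = true;
      double a = std::exp(std::min(0.0, H - H0));
      if (!std::isfinite(a)) a = 0.0;
      alpha_sum += a;
      n_alpha += 1;
      out.sm = out.sel;
      out.sp = out.sel;
      return;
    }
    Tree& t1 = pool[2 * j];
    Tree& t2 = pool[2 * j + 1];
    build(from, dir, j - 1, t1);
    if (!t1.s) {
      out = t1;
      return;
    }
    build(dir > 0 ? t1.sp : t1.sm, dir, j - 1, t2);
    if (dir > 0) {
      out.sm = t1.sm;
      out.sp = t2.sp;
    } else {
      out.sm = t2.sm;
      out.sp = t1.sp;
    }
    out.n = t1.n + t2.n;
    out.sel = t1.sel;
    if (out.n > 0 && unif_rand() * out.n < t2.n) out.sel = t2.sel;
    out.s = t1.s && t2.s && no_uturn(out.sm, out.sp);
  }
};

// welford accumulator for the diagonal metric
struct Welford {
  int n = 0;
  std::vector<double> m, s;
  void init(int D) {
    n = 0;
    m.assign(D, 0.0);
    s.assign(D, 0.0);
  }
  void add(const std::vector<double>& x) {
    ++n;
    for (size_t d = 0; d < x.size(); ++d) {
      double dl = x[d] - m[d];
      m[d] += dl / n;
      s[d] += dl * (x[d] - m[d]);
    }
  }
};

// [[Rcpp::export]]
List vm_nuts(List model_data, List prior, NumericMatrix theta0, int n_iter,
             int n_warmup, int thin, double target_accept, double init_step,
             int max_depth) {
  Model M = build_model(model_data, prior);
  const int D = M.D, n_chains = theta0.ncol();
  if (theta0.nrow() != D) stop("theta0 has wrong dimension (expected %d rows)", D);
  if (n_warmup >= n_iter) stop("n_warmup must be < n_iter");
  const int n_keep = (n_iter - n_warmup) / thin;

  NumericVector draws((R_xlen_t)n_keep * n_chains * D);
  draws.attr("dim") = IntegerVector::create(n_keep, n_chains, D);
  IntegerVector divergences(n_chains), depth_hits(n_chains);
  NumericVector step_sizes(n_chains), accept_stats(n_chains);

  // adaptation schedule (Stan-style windows)
  const int init_buffer = std::min(75, std::max(1, n_warmup / 4));
  const int term_buffer = std::min(50, std::max(1, n_warmup / 10));
  const bool adapt_metric = n_warmup >= 150;

  for (int c = 0; c < n_chains; ++c) {
    Sampler S;
    S.M = &M;
    S.em.assign(D, 1.0);
    S.eps = init_step;
    S.delta = target_accept;
    S.max_depth = max_depth;
    S.init_pool();

    State cur(D);
    for (int d = 0; d < D; ++d) cur.th[d] = theta0(d, c);
    double lp = logpost_grad(M, cur.th.data(), cur.g.data());
    if (!std::isfinite(lp)) stop("non-finite log density at initial values");

    // dual averaging state
    double mu_da = std::log(10.0 * S.eps), log_eps_bar = std::log(S.eps);
    double Hbar = 0.0;
    int t_da = 0;
    const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
    auto reset_da = [&]() {
      mu_da = std::log(10.0 * S.eps);
      log_eps_bar = std::log(S.eps);
      Hbar = 0.0;
      t_da = 0;
    };

    Welford wf;
    wf.init(D);
    int window_end = adapt_metric ? init_buffer + 25 : n_warmup;
    int window_size = 25;

    double acc_sum = 0;
    int acc_n = 0, keep_i = 0, pw = 0;
    Sampler::Tree t(D), sub(D);

    for (int it = 0; it < n_iter; ++it) {
      // momentum refresh
      for (int d = 0; d < D; ++d) cur.r[d] = norm_rand() / std::sqrt(S.em[d]);
      lp = logpost_grad(M, cur.th.data(), cur.g.data());
      S.H0 = lp - S.kinetic(cur.r);
      S.logu = S.H0 - exp_rand();
      S.alpha_sum = 0;
      S.n_alpha = 0;
      S.divergent = false;

      t.sm = cur;
      t.sp = cur;
      t.sel = cur;
      t.n = 1;
      t.s = true;
      int depth = 0;
      while (t.s && depth < S.max_depth) {
        const double dir = (unif_rand() < 0.5) ? -1.0 : 1.0;
        S.build(dir > 0 ? t.sp : t.sm, dir, depth, sub);
        if (sub.s && sub.n > 0 && unif_rand() * t.n < sub.n) t.sel = sub.sel;
        t.n += sub.n;
        if (!sub.s) break;
        if (dir > 0) t.sp = sub.sp; else t.sm = sub.sm;
        t.s = S.no_uturn(t.sm, t.sp);
        ++depth;
      }
      cur = t.sel;

      const bool warm = it < n_warmup;
      const double alpha = (S.n_alpha > 0) ? S.alpha_sum / S.n_alpha : 0.0;
      if (!warm) {
        acc_sum += alpha;
        ++acc_n;
        if (S.divergent) ++divergences[c];
        if (depth >= S.max_depth) ++depth_hits[c];
        ++pw;
        if (pw % thin == 0 && keep_i < n_keep) {
          for (int d = 0; d < D; ++d)
            draws[(R_xlen_t)keep_i + (R_xlen_t)n_keep * (c + (R_xlen_t)n_chains * d)] = cur.th[d];
          ++keep_i;
        }
      } else {
        // step-size adaptation (dual averaging, Hoffman & Gelman 2014)
        ++t_da;
        Hbar += (1.0 / (t_da + t0)) * ((S.delta - alpha) - Hbar);
        double log_eps = mu_da - std::sqrt((double)t_da) / gamma * Hbar;
        double w = std::pow((double)t_da, -kappa);
        log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
        S.eps = std::exp(log_eps);
        if (!std::isfinite(S.eps) || S.eps <= 0) S.eps = init_step;

        if (adapt_metric && it >= init_buffer && it < n_warmup - term_buffer) {
          wf.add(cur.th);
          if (it + 1 == window_end) {
            if (wf.n >= 10) {
              for (int d = 0; d < D; ++d) {
                double v = wf.s[d] / (wf.n - 1);
                S.em[d] = (wf.n / (wf.n + 5.0)) * v + 1e-3 * (5.0 / (wf.n + 5.0));
              }
            }
            wf.init(D);
            S.eps = std::exp(log_eps_bar);
            reset_da();
            window_size *= 2;
            window_end += window_size;
            if (window_end + 2 * window_size > n_warmup - term_buffer)
              window_end = n_warmup - term_buffer;
          }
        }
        if (it + 1 == n_warmup) S.eps = std::exp(log_eps_bar);
      }
    }
    step_sizes[c] = S.eps;
    accept_stats[c] = acc_n > 0 ? acc_sum / acc_n : NA_REAL;
  }

  return List::create(
    _["draws"] = draws, _["divergences"] = divergences,
    _["treedepth_hits"] = depth_hits, _["step_sizes"] = step_sizes,
    _["accept_stats"] = accept_stats, _["dim"] = D
  );
}
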