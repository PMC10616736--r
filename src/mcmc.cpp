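#include <Rcpp.h>
using namespace Rcpp;

// Latent-state augmented Metropolis-within-Gibbs sampler for the
// three-state occupancy model.  Site-years are site-major: rows
// i*n_years + j of `counts` belong to site i (0-based).  Because
// occasions are exchangeable given the latent state, each site-year
// enters the complete-data likelihood only through its counts of
// active occasions with observed state 0/1/2.

// log(plogis(x)), stable over the double range
static inline double log_plogis(double x) {
  return (x < 0.0) ? x - log1p(exp(x)) : -log1p(exp(-x));
}
static inline double plogis_(double x) { return 1.0 / (1.0 + exp(-x)); }

// parameter vector layout
enum {
  OCC_A = 0, OCC_BH, OCC_BE,
  REP_A, REP_BH, REP_BE,
  DET_A22, DET_A23, DET_A33,
  DET_B22, DET_B23, DET_B33,
  SD_OCC, SD_REP, NFIX
};

struct Model {
  int S, J, nsy;
  IntegerMatrix counts;           // nsy x 3: active occasions with y = 0/1/2
  NumericVector x5, x1, eco;      // per site (standardized / indicator)
  double fixed_sd, sd_upper;
  NumericVector par;              // NFIX + 2S (random effects at the tail)
  IntegerVector z;                // nsy
  std::vector<double> lp_psi, lp_r, lp22, lp23, lp33; // per-site predictors

  double occ_re(int i) const { return par[NFIX + i]; }
  double rep_re(int i) const { return par[NFIX + S + i]; }

  void refresh_site(int i) {
    lp_psi[i] = par[OCC_A] + occ_re(i) + par[OCC_BH] * x5[i] + par[OCC_BE] * eco[i];
    lp_r[i]   = par[REP_A] + rep_re(i) + par[REP_BH] * x5[i] + par[REP_BE] * eco[i];
    lp22[i] = par[DET_A22] + par[DET_B22] * x1[i];
    lp23[i] = par[DET_A23] + par[DET_B23] * x1[i];
    lp33[i] = par[DET_A33] + par[DET_B33] * x1[i];
  }
  void refresh_all() { for (int i = 0; i < S; ++i) refresh_site(i); }

  // multinomial detection constraint p23 + p33 <= 1 at every site
  bool constraint_ok() const {
    for (int i = 0; i < S; ++i)
      if (plogis_(lp23[i]) + plogis_(lp33[i]) > 1.0) return false;
    return true;
  }

  // occupancy-level term of one site-year given z
  double occ_term(int i, int zz) const {
    return (zz == 0) ? log_plogis(-lp_psi[i]) : log_plogis(lp_psi[i]);
  }
  // reproduction-level term
  double rep_term(int i, int zz) const {
    if (zz == 0) return 0.0;
    return (zz == 1) ? log_plogis(-lp_r[i]) : log_plogis(lp_r[i]);
  }
  // detection term; assumes z is compatible with the counts
  double det_term(int i, int sy, int zz) const {
    int n0 = counts(sy, 0), n1 = counts(sy, 1), n2 = counts(sy, 2);
    if (zz == 0) return 0.0;
    if (zz == 1)
      return n1 * log_plogis(lp22[i]) + n0 * log_plogis(-lp22[i]);
    double p23 = plogis_(lp23[i]), p33 = plogis_(lp33[i]);
    double rest = 1.0 - p23 - p33;
    if (rest <= 0.0) return R_NegInf;
    return n2 * log_plogis(lp33[i]) + n1 * log_plogis(lp23[i]) + n0 * log(rest);
  }

  double occ_ll() const {
    double s = 0.0;
    for (int sy = 0; sy < nsy; ++sy) s += occ_term(sy / J, z[sy]);
    return s;
  }
  double rep_ll() const {
    double s = 0.0;
    for (int sy = 0; sy < nsy; ++sy) s += rep_term(sy / J, z[sy]);
    return s;
  }
  double det_ll() const {
    double s = 0.0;
    for (int sy = 0; sy < nsy; ++sy) s += det_term(sy / J, sy, z[sy]);
    return s;
  }
  double log_prior_fixed(int k, double v) const {
    return -0.5 * v * v / (fixed_sd * fixed_sd);
  }
  double complete_data_log_post() const {
    double sd_o = par[SD_OCC], sd_r = par[SD_REP];
    if (sd_o <= 0 || sd_o >= sd_upper || sd_r <= 0 || sd_r >= sd_upper)
      return R_NegInf;
    double lp = occ_ll() + rep_ll() + det_ll();
    for (int k = 0; k < SD_OCC; ++k) lp += log_prior_fixed(k, par[k]);
    for (int i = 0; i < S; ++i) {
      lp += -0.5 * occ_re(i) * occ_re(i) / (sd_o * sd_o) - log(sd_o);
      lp += -0.5 * rep_re(i) * rep_re(i) / (sd_r * sd_r) - log(sd_r);
    }
    return lp;
  }
};

// Gibbs draw of every latent state from its exact full conditional
static void update_latent(Model &m) {
  for (int sy = 0; sy < m.nsy; ++sy) {
    int i = sy / m.J;
    int n1 = m.counts(sy, 1), n2 = m.counts(sy, 2);
    double lw0 = (n1 == 0 && n2 == 0) ? m.occ_term(i, 0) : R_NegInf;
    double lw1 = (n2 == 0)
      ? m.occ_term(i, 1) + m.rep_term(i, 1) + m.det_term(i, sy, 1)
      : R_NegInf;
    double lw2 = m.occ_term(i, 2) + m.rep_term(i, 2) + m.det_term(i, sy, 2);
    double mx = std::max(lw0, std::max(lw1, lw2));
    double w0 = exp(lw0 - mx), w1 = exp(lw1 - mx), w2 = exp(lw2 - mx);
    double u = unif_rand() * (w0 + w1 + w2);
    m.z[sy] = (u < w0) ? 0 : ((u < w0 + w1) ? 1 : 2);
  }
}

// one random-walk Metropolis update of fixed-effect / detection scalar k
static bool update_fixed_scalar(Model &m, int k, double scale) {
  double old = m.par[k];
  double prop = old + scale * norm_rand();
  bool occ_blk = (k <= OCC_BE);
  bool rep_blk = (k >= REP_A && k <= REP_BE);
  double cur_ll = occ_blk ? m.occ_ll() : (rep_blk ? m.rep_ll() : m.det_ll());
  std::vector<double> save_psi = m.lp_psi, save_r = m.lp_r,
    save22 = m.lp22, save23 = m.lp23, save33 = m.lp33;
  m.par[k] = prop;
  m.refresh_all();
  double delta;
  if (!occ_blk && !rep_blk && !m.constraint_ok()) {
    delta = R_NegInf;
  } else {
    double new_ll = occ_blk ? m.occ_ll() : (rep_blk ? m.rep_ll() : m.det_ll());
    delta = new_ll - cur_ll +
      m.log_prior_fixed(k, prop) - m.log_prior_fixed(k, old);
  }
  if (R_FINITE(delta) ? (log(unif_rand()) < delta) : (delta > 0)) return true;
  m.par[k] = old;
  m.lp_psi = save_psi; m.lp_r = save_r;
  m.lp22 = save22; m.lp23 = save23; m.lp33 = save33;
  return false;
}

// random-walk update of one site's random effect (occ: which = 0, rep: 1)
static bool update_re(Model &m, int i, int which, double scale) {
  int idx = NFIX + which * m.S + i;
  double sd = m.par[which == 0 ? SD_OCC : SD_REP];
  double old = m.par[idx];
  double prop = old + scale * norm_rand();
  double cur = 0.0, prp = 0.0;
  double save_lp = (which == 0) ? m.lp_psi[i] : m.lp_r[i];
  for (int j = 0; j < m.J; ++j) {
    int sy = i * m.J + j;
    cur += (which == 0) ? m.occ_term(i, m.z[sy]) : m.rep_term(i, m.z[sy]);
  }
  m.par[idx] = prop;
  m.refresh_site(i);
  for (int j = 0; j < m.J; ++j) {
    int sy = i * m.J + j;
    prp += (which == 0) ? m.occ_term(i, m.z[sy]) : m.rep_term(i, m.z[sy]);
  }
  double delta = prp - cur - 0.5 * (prop * prop - old * old) / (sd * sd);
  if (log(unif_rand()) < delta) return true;
  m.par[idx] = old;
  if (which == 0) m.lp_psi[i] = save_lp; else m.lp_r[i] = save_lp;
  return false;
}

// Metropolis on log(sd) of a random-effect distribution, Uniform(0, upper)
// prior on the sd itself (log-scale proposal carries a +log(sd) Jacobian)
static bool update_sd(Model &m, int which, double scale) {
  int idx = (which == 0) ? SD_OCC : SD_REP;
  double old = m.par[idx];
  double prop = old * exp(scale * norm_rand());
  if (prop >= m.sd_upper || prop <= 0.0) return false;
  double ss = 0.0;
  for (int i = 0; i < m.S; ++i) {
    double a = m.par[NFIX + which * m.S + i];
    ss += a * a;
  }
  double lt_old = -m.S * log(old) - 0.5 * ss / (old * old) + log(old);
  double lt_new = -m.S * log(prop) - 0.5 * ss / (prop * prop) + log(prop);
  if (log(unif_rand()) < lt_new - lt_old) {
    m.par[idx] = prop;
    return true;
  }
  return false;
}

// [[Rcpp::export]]
List mcmc_chain_cpp(IntegerMatrix counts, int n_sites, int n_years,
                    NumericVector x5, NumericVector x1, NumericVector eco,
                    double fixed_sd, double sd_upper,
                    NumericVector init, IntegerVector z_init,
                    LogicalVector upd_fixed, bool upd_sd_occ, bool upd_sd_rep,
                    bool upd_occ_re, bool upd_rep_re, bool update_z,
                    NumericVector scales_init,
                    int n_iter, int burn_in, int thin,
                    bool adapt, bool save_latent) {
  RNGScope scope;
  Model m;
  m.S = n_sites; m.J = n_years; m.nsy = counts.nrow();
  m.counts = counts; m.x5 = x5; m.x1 = x1; m.eco = eco;
  m.fixed_sd = fixed_sd; m.sd_upper = sd_upper;
  m.par = clone(init);
  m.z = clone(z_init);
  m.lp_psi.resize(m.S); m.lp_r.resize(m.S);
  m.lp22.resize(m.S); m.lp23.resize(m.S); m.lp33.resize(m.S);
  m.refresh_all();

  int n_par = NFIX + 2 * m.S;
  // scalar update slots: 12 fixed, 2 sds, S occ REs, S rep REs
  NumericVector scales = clone(scales_init);
  std::vector<long> acc(n_par, 0), tries(n_par, 0);
  std::vector<long> acc_batch(n_par, 0), tries_batch(n_par, 0);
  const int adapt_every = 50;
  const double target = 0.35;

  int n_kept = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_kept, n_par);
  IntegerMatrix latent(save_latent ? n_kept : 0, save_latent ? m.nsy : 0);
  int kept = 0;

  for (int t = 1; t <= n_iter; ++t) {
    if (update_z) update_latent(m);
    #define TRACK(slot, a) do {                                   \
      ++tries_batch[slot]; if (a) ++acc_batch[slot];              \
      if (t > burn_in) { ++tries[slot]; if (a) ++acc[slot]; }     \
    } while (0)
    for (int k = 0; k < 12; ++k) {
      if (!upd_fixed[k]) continue;
      bool a = update_fixed_scalar(m, k, scales[k]);
      TRACK(k, a);
    }
    if (upd_occ_re)
      for (int i = 0; i < m.S; ++i) {
        int slot = NFIX + i;
        bool a = update_re(m, i, 0, scales[slot]);
        TRACK(slot, a);
      }
    if (upd_rep_re)
      for (int i = 0; i < m.S; ++i) {
        int slot = NFIX + m.S + i;
        bool a = update_re(m, i, 1, scales[slot]);
        TRACK(slot, a);
      }
    if (upd_sd_occ) {
      bool a = update_sd(m, 0, scales[SD_OCC]);
      TRACK(SD_OCC, a);
    }
    if (upd_sd_rep) {
      bool a = update_sd(m, 1, scales[SD_REP]);
      TRACK(SD_REP, a);
    }
    #undef TRACK

    if (adapt && t <= burn_in && t % adapt_every == 0) {
      for (int k = 0; k < n_par; ++k) {
        if (tries_batch[k] == 0) continue;
        double rate = double(acc_batch[k]) / double(tries_batch[k]);
        scales[k] *= exp(rate - target);
        if (scales[k] < 1e-3) scales[k] = 1e-3;
        if (scales[k] > 50.0) scales[k] = 50.0;
        acc_batch[k] = tries_batch[k] = 0;
      }
    }

    if (t > burn_in && (t - burn_in) % thin == 0 && kept < n_kept) {
      for (int k = 0; k < n_par; ++k) draws(kept, k) = m.par[k];
      if (save_latent)
        for (int sy = 0; sy < m.nsy; ++sy) latent(kept, sy) = m.z[sy];
      ++kept;
    }
  }

  NumericVector acc_rate(n_par, NA_REAL);   // post-burn-in acceptance rates
  for (int k = 0; k < n_par; ++k)
    if (tries[k] > 0) acc_rate[k] = double(acc[k]) / double(tries[k]);

  return List::create(_["draws"] = draws,
                      _["latent"] = save_latent ? (SEXP)latent : R_NilValue,
                      _["accept"] = acc_rate,
                      _["scales"] = scales,
                      _["final_z"] = m.z,
                      _["final_par"] = m.par);
}

// Complete-data log posterior at given parameters and latent states
// (used by run_mcmc to validate initial states).
// [[Rcpp::export]]
double complete_log_post_cpp(IntegerMatrix counts, int n_sites, int n_years,
                             NumericVector x5, NumericVector x1,
                             NumericVector eco,
                             double fixed_sd, double sd_upper,
                             NumericVector par, IntegerVector z) {
  Model m;
  m.S = n_sites; m.J = n_years; m.nsy = counts.nrow();
  m.counts = counts; m.x5 = x5; m.x1 = x1; m.eco = eco;
  m.fixed_sd = fixed_sd; m.sd_upper = sd_upper;
  m.par = par; m.z = z;
  m.lp_psi.resize(m.S); m.lp_r.resize(m.S);
  m.lp22.resize(m.S); m.lp23.resize(m.S); m.lp33.resize(m.S);
  m.refresh_all();
  if (!m.constraint_ok()) return R_NegInf;
  return m.complete_data_log_post();
}
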