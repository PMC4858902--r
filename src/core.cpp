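#include <Rcpp.h>
#include <unordered_map>
#include <array>
#include <cmath>
using namespace Rcpp;

// Bit layout conventions (shared with the R side, see R/genome.R):
//   host row:     4 proteins (R, C, E_S, E_N) x 3 sequences (S_N, S_I, S_O) x L bits
//   parasite row: 1 protein x 3 sequences (S_N, S_I, S_O) x L bits
// Protein indices: R=0, C=1, ES=2, EN=3.  Sequence indices: N=0, I=1, O=2.
// Column offset of sequence s of protein p: (p*3 + s) * L.

// Evolvable host edge order used throughout (into <- from):
//   1 ES<-R, 2 EN<-R, 3 ES<-C, 4 EN<-C, 5 ES<-EN, 6 EN<-ES

static inline int seq_off(int protein, int seq, int L) {
  return (protein * 3 + seq) * L;
}

static inline int hamming_cols(const IntegerMatrix& m, int row,
                               int off_a, const IntegerMatrix& m2, int row2,
                               int off_b, int L) {
  int h = 0;
  for (int k = 0; k < L; ++k)
    h += (m(row, off_a + k) != m2(row2, off_b + k));
  return h;
}

// Specific-interaction rule: coefficient 1 when the sequence match
// 1 - H/L is at least 60 %, else 0.  Integer form: 5*(L - H) >= 3*L.
static inline double specific_coef(int H, int L) {
  return (5 * (L - H) >= 3 * L) ? 1.0 : 0.0;
}

// One evaluation of the network vector field.  y = (y_R, y_ES, y_EN);
// y_C == 1 always, y_P == 1 while a parasite is present.  Each incoming
// edge contributes mu*y_j*(1-y_i) when activating and mu*y_j*y_i when
// inhibiting, so the unit interval is forward-invariant.
static inline void deriv(const double* y, const double* mu, double muRP,
                         bool parasite, double phi, double* dy) {
  auto term = [](double m, double yj, double yi) {
    return m > 0 ? m * yj * (1.0 - yi) : m * yj * yi;
  };
  dy[0] = -phi * y[0] + (parasite ? term(muRP, 1.0, y[0]) : 0.0);
  dy[1] = -phi * y[1] + term(mu[0], y[0], y[1]) + term(mu[2], 1.0, y[1]) +
          term(mu[4], y[2], y[1]);
  dy[2] = -phi * y[2] + term(mu[1], y[0], y[2]) + term(mu[3], 1.0, y[2]) +
          term(mu[5], y[1], y[2]);
}

struct EqResult {
  double y[3];
  double residual;
  long steps;
  bool converged;
};

// Fixed-step RK4 forward integration from `init` until the vector field
// residual max|dy/dt| drops below tol or t exceeds t_max.
static EqResult solve_eq(const double* mu, double muRP, bool parasite,
                         const double* init, double phi, double h,
                         double tol, double t_max) {
  EqResult res;
  double y[3] = {init[0], init[1], init[2]};
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  long max_steps = (long)std::ceil(t_max / h);
  long steps = 0;
  double resid = R_PosInf;
  while (steps < max_steps) {
    deriv(y, mu, muRP, parasite, phi, k1);
    resid = std::max(std::fabs(k1[0]), std::max(std::fabs(k1[1]), std::fabs(k1[2])));
    if (resid < tol) break;
    for (int i = 0; i < 3; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
    deriv(tmp, mu, muRP, parasite, phi, k2);
    for (int i = 0; i < 3; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
    deriv(tmp, mu, muRP, parasite, phi, k3);
    for (int i = 0; i < 3; ++i) tmp[i] = y[i] + h * k3[i];
    deriv(tmp, mu, muRP, parasite, phi, k4);
    for (int i = 0; i < 3; ++i)
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    ++steps;
  }
  for (int i = 0; i < 3; ++i) {
    // the field points into [0,1]; tolerate only numerical fuzz outside
    if (y[i] < 0 && y[i] > -1e-9) y[i] = 0;
    if (y[i] > 1 && y[i] < 1 + 1e-9) y[i] = 1;
    res.y[i] = y[i];
  }
  res.residual = resid;
  res.steps = steps;
  res.converged = (resid < tol);
  return res;
}

// [[Rcpp::export]]
List cpp_solve_equilibrium(NumericVector mu, double mu_rp, bool parasite,
                           NumericVector init, double phi, double h,
                           double tol, double t_max) {
  if (mu.size() != 6) stop("mu must have length 6");
  if (init.size() != 3) stop("init must have length 3");
  EqResult r = solve_eq(REAL(mu), mu_rp, parasite, REAL(init), phi, h, tol, t_max);
  return List::create(
    _["y"] = NumericVector::create(_["y_R"] = r.y[0], _["y_ES"] = r.y[1],
                                   _["y_EN"] = r.y[2]),
    _["residual"] = r.residual, _["steps"] = (double)r.steps,
    _["converged"] = r.converged);
}

// [[Rcpp::export]]
NumericVector cpp_derivative(NumericVector y, NumericVector mu, double mu_rp,
                             bool parasite, double phi) {
  if (mu.size() != 6 || y.size() != 3) stop("bad dimensions");
  double dy[3];
  deriv(REAL(y), REAL(mu), mu_rp, parasite, phi, dy);
  return NumericVector::create(_["y_R"] = dy[0], _["y_ES"] = dy[1],
                               _["y_EN"] = dy[2]);
}

// Mean pairwise Hamming distance over all unordered pairs of rows,
// restricted to columns [col0, col0+ncols).  Uses the per-site allele
// frequency identity: sum_sites n1*(n0)/(N choose 2).
static double mean_pairwise_distance(const IntegerMatrix& m, int col0,
                                     int ncols) {
  int N = m.nrow();
  if (N < 2) return 0.0;
  double acc = 0.0;
  for (int c = col0; c < col0 + ncols; ++c) {
    double n1 = 0;
    for (int i = 0; i < N; ++i) n1 += m(i, c);
    acc += n1 * (N - n1);
  }
  return acc / (0.5 * N * (N - 1.0));
}

// [[Rcpp::export]]
double cpp_mean_pairwise_distance(IntegerMatrix m, int col0, int ncols) {
  return mean_pairwise_distance(m, col0 - 1, ncols);
}

static void consensus_row(const IntegerMatrix& m, IntegerMatrix& out,
                          int out_row) {
  int N = m.nrow(), B = m.ncol();
  for (int c = 0; c < B; ++c) {
    int n1 = 0;
    for (int i = 0; i < N; ++i) n1 += m(i, c);
    out(out_row, c) = (2 * n1 > N) ? 1 : 0; // ties resolve to 0
  }
}

// Fitness-weighted lottery: index of the parent drawn proportional to w
// (cumulative weights cw, total tot).  Falls back to uniform when the
// population has no positive fitness.
static inline int draw_index(const std::vector<double>& cw, double tot, int N) {
  if (tot <= 0) return (int)(unif_rand() * N) % N;
  double u = unif_rand() * tot;
  int lo = 0, hi = N - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cw[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// [[Rcpp::export]]
List cpp_run_simulation(IntegerMatrix hosts0, IntegerMatrix parasites0, int L,
                        bool receptor_specific, double p_encounter,
                        double kappa, double delta, double nu, double phi,
                        double mutation_rate, int generations,
                        int consensus_every, double h, double tol,
                        double t_max) {
  int Nh = hosts0.nrow(), Np = parasites0.nrow();
  int hb = 12 * L, pb = 3 * L;
  if (hosts0.ncol() != hb) stop("host matrix must have 12*L columns");
  if (parasites0.ncol() != pb) stop("parasite matrix must have 3*L columns");
  IntegerMatrix hosts = clone(hosts0), parasites = clone(parasites0);
  IntegerMatrix hosts_next(Nh, hb), parasites_next(Np, pb);

  // equilibrium caches keyed on the (L+1)-ary code of the six edge
  // Hamming distances; induced cache additionally keyed on mu_RP class
  std::unordered_map<uint64_t, std::array<double, 3>> cache0, cacheI;
  const uint64_t base = (uint64_t)(L + 1);

  const int NCOL = 18;
  NumericMatrix summary(generations + 1, NCOL);
  CharacterVector colnames_ = CharacterVector::create(
      "generation", "n_challenged", "y0_ES", "y0_EN", "induced_ES",
      "induced_EN", "yR_challenged", "parasite_diversity", "mu_ES_R",
      "mu_EN_R", "mu_ES_C", "mu_EN_C", "mu_ES_EN", "mu_EN_ES", "W_host",
      "W_parasite", "solver_failures", "uniform_fallbacks");

  int n_snap = 0;
  for (int g = 0; g <= generations; ++g)
    if (g % consensus_every == 0 || g == generations) ++n_snap;
  IntegerMatrix host_cons(n_snap, hb), para_cons(n_snap, pb);
  IntegerVector snap_gen(n_snap);
  int snap = 0;

  // pair (input domain of into-protein, output domain of from-protein)
  // for the six evolvable edges, in the fixed order documented above
  const int edge_in[6] = {2, 3, 2, 3, 2, 3};   // ES, EN, ES, EN, ES, EN
  const int edge_out[6] = {0, 0, 1, 1, 3, 2};  // R, R, C, C, EN, ES

  std::vector<int> H6(Nh * 6);
  std::vector<uint64_t> hkey(Nh);
  std::vector<double> Wh(Nh), Wp(Np), wsum(Np);
  std::vector<int> pcnt(Np);
  std::vector<double> cwh(Nh), cwp(Np);
  long solver_fail_total = 0;

  for (int g = 0; g <= generations; ++g) {
    long solver_fail = 0, fallback = 0;
    // --- constitutive equilibria and edge coefficients ---
    double mu_sum[6] = {0, 0, 0, 0, 0, 0};
    double y0ES_sum = 0, y0EN_sum = 0;
    for (int i = 0; i < Nh; ++i) {
      uint64_t key = 0;
      for (int e = 0; e < 6; ++e) {
        int Hd = hamming_cols(hosts, i, seq_off(edge_in[e], 1, L), hosts, i,
                              seq_off(edge_out[e], 2, L), L);
        H6[i * 6 + e] = Hd;
        mu_sum[e] += 1.0 - 2.0 * Hd / (double)L;
        key = key * base + (uint64_t)Hd;
      }
      hkey[i] = key;
      auto it = cache0.find(key);
      if (it == cache0.end()) {
        double mu[6];
        for (int e = 0; e < 6; ++e)
          mu[e] = 1.0 - 2.0 * H6[i * 6 + e] / (double)L;
        double init[3] = {0, 0, 0};
        EqResult r = solve_eq(mu, 0.0, false, init, phi, h, tol, t_max);
        if (!r.converged) ++solver_fail;
        it = cache0.emplace(key, std::array<double, 3>{r.y[0], r.y[1], r.y[2]})
                 .first;
      }
      y0ES_sum += it->second[1];
      y0EN_sum += it->second[2];
    }

    // --- encounters, fitness ---
    std::fill(wsum.begin(), wsum.end(), 0.0);
    std::fill(pcnt.begin(), pcnt.end(), 0);
    int n_chal = 0;
    double indES_sum = 0, indEN_sum = 0, yR_sum = 0, Wh_sum = 0;
    for (int i = 0; i < Nh; ++i) {
      const std::array<double, 3>& y0 = cache0[hkey[i]];
      double C0 = kappa * (y0[1] + y0[2]);
      double s0 = std::max(0.0, 1.0 - C0);
      bool challenged = (p_encounter > 0) && (unif_rand() < p_encounter);
      if (!challenged) {
        Wh[i] = s0;
        Wh_sum += s0;
        continue;
      }
      ++n_chal;
      int j = (int)(unif_rand() * Np);
      if (j == Np) j = Np - 1;
      // receptor-parasite coefficient
      double muRP;
      if (receptor_specific) {
        int Hd = hamming_cols(hosts, i, seq_off(0, 1, L), parasites, j,
                              2 * L, L); // S_I^R vs S_O^P
        muRP = specific_coef(Hd, L);
      } else {
        muRP = 0.2;
      }
      // induced equilibrium (identical to constitutive when mu_RP == 0)
      std::array<double, 3> ystar;
      if (muRP == 0.0) {
        ystar = y0;
      } else {
        uint64_t ikey = hkey[i] * 2 + (muRP == 1.0 ? 1 : 0);
        auto it = cacheI.find(ikey);
        if (it == cacheI.end()) {
          double mu[6];
          for (int e = 0; e < 6; ++e)
            mu[e] = 1.0 - 2.0 * H6[i * 6 + e] / (double)L;
          double init[3] = {y0[0], y0[1], y0[2]};
          EqResult r = solve_eq(mu, muRP, true, init, phi, h, tol, t_max);
          if (!r.converged) ++solver_fail;
          it = cacheI
                   .emplace(ikey,
                            std::array<double, 3>{r.y[0], r.y[1], r.y[2]})
                   .first;
        }
        ystar = it->second;
      }
      // effector-parasite efficacies
      int Hd_eff = hamming_cols(parasites, j, L, hosts, i, seq_off(2, 2, L),
                                L); // S_I^P vs S_O^ES
      double xiS = specific_coef(Hd_eff, L), xiN = 0.2;
      double E0 = xiS * y0[1] + xiN * y0[2];
      double Es = xiS * ystar[1] + xiN * ystar[2];
      double Cs = kappa * (ystar[1] + ystar[2]);
      double f0 = std::max(0.0, (1.0 - C0) * (1.0 - nu * std::exp(-E0)));
      double fs = std::max(0.0, (1.0 - Cs) * (1.0 - nu * std::exp(-Es)));
      double sstar = std::pow(f0, delta) * std::pow(fs, 1.0 - delta);
      Wh[i] = s0 * sstar;
      Wh_sum += Wh[i];
      wsum[j] += std::exp(-(delta * E0 + (1.0 - delta) * Es));
      pcnt[j] += 1;
      indES_sum += ystar[1] - y0[1];
      indEN_sum += ystar[2] - y0[2];
      yR_sum += ystar[0];
    }
    // parasite fitness: mean over realized encounters; parasites with no
    // encounter get the mean fitness of encountered ones (neutral)
    double wp_enc_sum = 0;
    int n_enc = 0;
    for (int j = 0; j < Np; ++j)
      if (pcnt[j] > 0) {
        Wp[j] = wsum[j] / pcnt[j];
        wp_enc_sum += Wp[j];
        ++n_enc;
      }
    double wp_neutral = (n_enc > 0) ? wp_enc_sum / n_enc : 1.0;
    double Wp_sum = 0;
    for (int j = 0; j < Np; ++j) {
      if (pcnt[j] == 0) Wp[j] = wp_neutral;
      Wp_sum += Wp[j];
    }

    // --- record summary ---
    summary(g, 0) = g;
    summary(g, 1) = n_chal;
    summary(g, 2) = y0ES_sum / Nh;
    summary(g, 3) = y0EN_sum / Nh;
    summary(g, 4) = n_chal ? indES_sum / n_chal : NA_REAL;
    summary(g, 5) = n_chal ? indEN_sum / n_chal : NA_REAL;
    summary(g, 6) = n_chal ? yR_sum / n_chal : NA_REAL;
    summary(g, 7) = mean_pairwise_distance(parasites, L, 2 * L);
    for (int e = 0; e < 6; ++e) summary(g, 8 + e) = mu_sum[e] / Nh;
    summary(g, 14) = Wh_sum / Nh;
    summary(g, 15) = Wp_sum / Np;
    summary(g, 16) = solver_fail;
    solver_fail_total += solver_fail;

    if (g % consensus_every == 0 || g == generations) {
      consensus_row(hosts, host_cons, snap);
      consensus_row(parasites, para_cons, snap);
      snap_gen[snap] = g;
      ++snap;
    }
    if (g == generations) {
      summary(g, 17) = 0;
      break;
    }

    // --- reproduction ---
    double tot = 0;
    for (int i = 0; i < Nh; ++i) {
      tot += Wh[i];
      cwh[i] = tot;
    }
    if (tot <= 0) ++fallback;
    for (int i = 0; i < Nh; ++i) {
      int pa = draw_index(cwh, tot, Nh);
      int pbx = draw_index(cwh, tot, Nh);
      for (int p = 0; p < 4; ++p) {
        int src = (unif_rand() < 0.5) ? pa : pbx;
        int off = p * 3 * L;
        for (int c = 0; c < 3 * L; ++c)
          hosts_next(i, off + c) = hosts(src, off + c);
      }
      if (unif_rand() < mutation_rate) {
        int pos = (int)(unif_rand() * hb);
        if (pos == hb) pos = hb - 1;
        hosts_next(i, pos) = 1 - hosts_next(i, pos);
      }
    }
    tot = 0;
    for (int j = 0; j < Np; ++j) {
      tot += Wp[j];
      cwp[j] = tot;
    }
    if (tot <= 0) ++fallback;
    for (int j = 0; j < Np; ++j) {
      int src = draw_index(cwp, tot, Np);
      for (int c = 0; c < pb; ++c) parasites_next(j, c) = parasites(src, c);
      if (unif_rand() < mutation_rate) {
        int pos = (int)(unif_rand() * pb);
        if (pos == pb) pos = pb - 1;
        parasites_next(j, pos) = 1 - parasites_next(j, pos);
      }
    }
    summary(g, 17) = fallback;
    std::swap(hosts, hosts_next);
    std::swap(parasites, parasites_next);
  }

  colnames(summary) = colnames_;
  return List::create(
      _["summary"] = summary, _["hosts"] = hosts, _["parasites"] = parasites,
      _["host_consensus"] = host_cons, _["parasite_consensus"] = para_cons,
      _["consensus_generations"] = snap_gen,
      _["solver_failures"] = (double)solver_fail_total);
}
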