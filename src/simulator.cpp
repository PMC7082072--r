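// Hybrid multiscale simulator kernels: deterministic T3 diffusion field,
// stochastic cell/microenvironment T3 exchange, and exact Gillespie (direct
// method) sampling of the per-cell fate/expression reaction network.
//
// Randomness uses counter-based per-cell streams derived from
// (seed, cell_id, macro-step) with splitmix64, so results are reproducible
// and independent of evaluation order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Stream {
  uint64_t s;
  explicit Stream(uint64_t seed) : s(seed) {
    // warm up
    splitmix64_next(s);
    splitmix64_next(s);
  }
  // uniform in (0, 1)
  double u01() {
    return ((splitmix64_next(s) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double exp1() { return -std::log(u01()); }
  double normal() {
    double u1 = u01(), u2 = u01();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  int poisson(double lambda) {
    if (lambda <= 0) return 0;
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do {
        ++k;
        p *= u01();
      } while (p > L);
      return k - 1;
    }
    // normal approximation for large means (initialization only)
    int k = (int)std::lround(lambda + std::sqrt(lambda) * normal());
    return k < 0 ? 0 : k;
  }
  int binom(int n, double p) {
    if (p <= 0) return 0;
    if (p >= 1) return n;
    int k = 0;
    for (int i = 0; i < n; ++i)
      if (u01() < p) ++k;
    return k;
  }
};

static inline uint64_t derive_seed(uint64_t seed, uint64_t cell, uint64_t step) {
  uint64_t x = seed ^ (0xA24BAED4963EE407ULL * (cell + 1));
  splitmix64_next(x);
  x ^= 0x9FB21C651E98DF25ULL * (step + 2);
  splitmix64_next(x);
  return x;
}

struct CmConfig {
  double k_on, k_off;
  int thrb2_total;
  double k_fateS_max, K_fate, h_fate, k_fateC;
  double beta_S_high, beta_M, K_M, h_M;
  double beta_S_cec, K_Srep, h_Srep;
  double phi;
  double k_exchange_in, k_exchange_out;
};

static CmConfig read_config(const List &config) {
  CmConfig c;
  c.k_on = as<double>(config["k_on"]);
  c.k_off = as<double>(config["k_off"]);
  c.thrb2_total = as<int>(config["thrb2_total"]);
  c.k_fateS_max = as<double>(config["k_fateS_max"]);
  c.K_fate = as<double>(config["K_fate"]);
  c.h_fate = as<double>(config["h_fate"]);
  c.k_fateC = as<double>(config["k_fateC"]);
  c.beta_S_high = as<double>(config["beta_S_high"]);
  c.beta_M = as<double>(config["beta_M"]);
  c.K_M = as<double>(config["K_M"]);
  c.h_M = as<double>(config["h_M"]);
  c.beta_S_cec = as<double>(config["beta_S_cec"]);
  c.K_Srep = as<double>(config["K_Srep"]);
  c.h_Srep = as<double>(config["h_Srep"]);
  c.phi = as<double>(config["phi"]);
  c.k_exchange_in = as<double>(config["k_exchange_in"]);
  c.k_exchange_out = as<double>(config["k_exchange_out"]);
  return c;
}

// repressing Hill K^h / (K^h + x^h); equals 1 at x = 0
static inline double hill_rep(double x, double K, double h) {
  if (x <= 0) return 1.0;
  double r = std::pow(x / K, h);
  return 1.0 / (1.0 + r);
}

// activating Hill x^h / (K^h + x^h); equals 0 at x = 0
static inline double hill_act(double x, double K, double h) {
  if (x <= 0) return 0.0;
  double r = std::pow(x / K, h);
  return r / (1.0 + r);
}

// state layout: fate (0=U, 1=S, 2=C), t3_free, thrb2_inactive, thrb2_active,
// s_opsin, m_opsin
enum { ST_FATE = 0, ST_T3, ST_RI, ST_RA, ST_S, ST_M, ST_LEN };

static void propensities(const double *st, const CmConfig &c, double cap_s,
                         double cap_m, double *a) {
  double fate = st[ST_FATE];
  a[0] = c.k_on * st[ST_T3] * st[ST_RI];
  a[1] = c.k_off * st[ST_RA];
  a[2] = (fate == 0) ? c.k_fateS_max * hill_rep(st[ST_RA], c.K_fate, c.h_fate) : 0.0;
  a[3] = (fate == 0) ? c.k_fateC : 0.0;
  a[4] = (fate == 1) ? c.beta_S_high * cap_s : 0.0;
  a[5] = (fate == 2) ? c.beta_M * cap_m * hill_act(st[ST_RA], c.K_M, c.h_M) : 0.0;
  a[6] = (fate == 2)
             ? c.beta_S_cec * cap_s * (st[ST_RI] / c.thrb2_total) *
                   hill_rep(st[ST_RA], c.K_Srep, c.h_Srep)
             : 0.0;
  a[7] = c.phi * st[ST_S];
  a[8] = c.phi * st[ST_M];
}

// [[Rcpp::export]]
NumericVector cpp_propensities(NumericVector state, double c_local, List config,
                               double cap_s = 1.0, double cap_m = 1.0) {
  (void)c_local; // exchange with the microenvironment is a separate operator
  CmConfig c = read_config(config);
  double a[9];
  propensities(REAL(state), c, cap_s, cap_m, a);
  NumericVector out(9);
  for (int i = 0; i < 9; ++i) out[i] = a[i];
  return out;
}

static void ssa_advance(double *st, const CmConfig &c, double cap_s,
                        double cap_m, double duration, Stream &rng) {
  double t = 0.0, a[9];
  int rtot = c.thrb2_total;
  for (;;) {
    propensities(st, c, cap_s, cap_m, a);
    double a0 = 0.0;
    for (int i = 0; i < 9; ++i) a0 += a[i];
    if (a0 <= 0.0) return;
    t += rng.exp1() / a0;
    if (t > duration) return;
    double r = rng.u01() * a0, cum = 0.0;
    int mu = 8;
    for (int i = 0; i < 9; ++i) {
      cum += a[i];
      if (r <= cum) {
        mu = i;
        break;
      }
    }
    switch (mu) {
    case 0: st[ST_T3] -= 1; st[ST_RI] -= 1; st[ST_RA] += 1; break;
    case 1: st[ST_RA] -= 1; st[ST_RI] += 1; st[ST_T3] += 1; break;
    case 2: st[ST_FATE] = 1; break;
    case 3: st[ST_FATE] = 2; break;
    case 4: st[ST_S] += 1; break;
    case 5: st[ST_M] += 1; break;
    case 6: st[ST_S] += 1; break;
    case 7: st[ST_S] -= 1; break;
    case 8: st[ST_M] -= 1; break;
    }
    if ((int)(st[ST_RI] + st[ST_RA]) != rtot)
      stop("receptor conservation violated in SSA");
  }
}

// [[Rcpp::export]]
NumericVector cpp_gillespie(NumericVector state, double c_local, double duration,
                            List config, double seed, double cap_s = 1.0,
                            double cap_m = 1.0) {
  (void)c_local;
  CmConfig c = read_config(config);
  NumericVector out = clone(state);
  Stream rng(derive_seed((uint64_t)seed, 0, 0));
  ssa_advance(REAL(out), c, cap_s, cap_m, duration, rng);
  return out;
}

// Stochastic uptake/release between one cell and its local voxel over dt.
// Uptake (rate k_in * c_local) is capped so the voxel's molecule content
// (available) cannot go negative; release has rate k_out * T3_free.
// Returns the net number of molecules taken up (uptake - release).
static int exchange_one(double *t3_free, double c_local, double available,
                        const CmConfig &c, double dt, Stream &rng) {
  double t = 0.0;
  int net = 0;
  for (;;) {
    double a_in = (net < available) ? c.k_exchange_in * c_local : 0.0;
    double a_out = c.k_exchange_out * (*t3_free);
    double a0 = a_in + a_out;
    if (a0 <= 0.0) return net;
    t += rng.exp1() / a0;
    if (t > dt) return net;
    if (rng.u01() * a0 <= a_in) {
      *t3_free += 1;
      net += 1;
    } else {
      *t3_free -= 1;
      net -= 1;
    }
  }
}

// [[Rcpp::export]]
List cpp_exchange(double t3_free, double c_local, double available, List config,
                  double dt, double seed) {
  CmConfig c = read_config(config);
  Stream rng(derive_seed((uint64_t)seed, 1, 1));
  double t3 = t3_free;
  int net = exchange_one(&t3, c_local, available, c, dt, rng);
  return List::create(_["t3_free"] = t3, _["net_uptake"] = net);
}

// Advance all cells over one macro step: per cell, exchange with the frozen
// local concentration, then exact SSA over the reaction network. Returns the
// updated state matrix and the net molecule uptake per cell (to be debited
// from the field by the caller).
// [[Rcpp::export]]
List cpp_advance_cells(NumericMatrix state, NumericVector c_local,
                       NumericVector available, NumericMatrix caps, double dt,
                       List config, double seed, int step) {
  CmConfig c = read_config(config);
  int n = state.nrow();
  if (state.ncol() != ST_LEN) stop("state matrix must have 6 columns");
  NumericMatrix out = clone(state);
  IntegerVector net(n);
  double st[ST_LEN];
  for (int i = 0; i < n; ++i) {
    Stream rng(derive_seed((uint64_t)seed, (uint64_t)i + 1, (uint64_t)step));
    for (int j = 0; j < ST_LEN; ++j) st[j] = out(i, j);
    net[i] = exchange_one(&st[ST_T3], c_local[i], available[i], c, dt, rng);
    ssa_advance(st, c, caps(i, 0), caps(i, 1), dt, rng);
    for (int j = 0; j < ST_LEN; ++j) out(i, j) = st[j];
  }
  return List::create(_["state"] = out, _["net_uptake"] = net);
}

// Initialize cells at hormonal equilibrium with the local T3 concentration:
// free T3 ~ Poisson(k_in c / k_out), active receptors ~ Binomial with the
// binding equilibrium occupancy given the drawn T3; fates U, opsins 0.
// Capacity factors are lognormal with the requested CV (independent for S
// and M), representing extrinsic cell-to-cell expression variability.
// [[Rcpp::export]]
List cpp_init_cells(NumericVector c_local, List config, double seed,
                    double capacity_cv) {
  CmConfig c = read_config(config);
  int n = c_local.size();
  NumericMatrix state(n, ST_LEN);
  NumericMatrix caps(n, 2);
  double sdlog = capacity_cv > 0 ? std::sqrt(std::log(1.0 + capacity_cv * capacity_cv)) : 0.0;
  for (int i = 0; i < n; ++i) {
    Stream rng(derive_seed((uint64_t)seed, (uint64_t)i + 1, 0));
    double mean_t3 =
        c.k_exchange_out > 0 ? c.k_exchange_in * c_local[i] / c.k_exchange_out : 0.0;
    int t3 = rng.poisson(mean_t3);
    double occ = (c.k_on * t3) / (c.k_on * t3 + c.k_off);
    if (c.k_off <= 0 && c.k_on * t3 > 0) occ = 1.0;
    if (c.k_on <= 0) occ = 0.0;
    int ra = rng.binom(c.thrb2_total, occ);
    state(i, ST_FATE) = 0;
    state(i, ST_T3) = t3;
    state(i, ST_RI) = c.thrb2_total - ra;
    state(i, ST_RA) = ra;
    state(i, ST_S) = 0;
    state(i, ST_M) = 0;
    if (sdlog > 0) {
      caps(i, 0) = std::exp(-0.5 * sdlog * sdlog + sdlog * rng.normal());
      caps(i, 1) = std::exp(-0.5 * sdlog * sdlog + sdlog * rng.normal());
    } else {
      caps(i, 0) = 1.0;
      caps(i, 1) = 1.0;
    }
  }
  return List::create(_["state"] = state, _["caps"] = caps);
}

// One forward-Euler step of the 2D diffusion equation on a node grid
// (rows = D-V axis). boundary = 0: Dirichlet dorsal/ventral rows pinned to
// c_dorsal/c_ventral, zero-flux sides. boundary = 1: zero-flux everywhere
// (mass conserving).
// [[Rcpp::export]]
NumericMatrix cpp_step_field(NumericMatrix field, double D, double dt, double h,
                             double c_dorsal, double c_ventral, int boundary) {
  int ny = field.nrow(), nx = field.ncol();
  if (dt > h * h / (4.0 * D) + 1e-12)
    stop("dt violates the explicit-scheme stability bound h^2/(4D)");
  NumericMatrix out(ny, nx);
  double r = D * dt / (h * h);
  for (int i = 0; i < ny; ++i) {
    for (int j = 0; j < nx; ++j) {
      // zero-flux ghosts copy the boundary node itself, which keeps the
      // scheme conservative under all-reflecting boundaries
      double u = field(i, j);
      double up = (i > 0) ? field(i - 1, j) : u;
      double dn = (i < ny - 1) ? field(i + 1, j) : u;
      double lf = (j > 0) ? field(i, j - 1) : u;
      double rt = (j < nx - 1) ? field(i, j + 1) : u;
      out(i, j) = u + r * (up + dn + lf + rt - 4.0 * u);
    }
  }
  if (boundary == 0) {
    for (int j = 0; j < nx; ++j) {
      out(0, j) = c_dorsal;
      out(ny - 1, j) = c_ventral;
    }
  }
  return out;
}
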