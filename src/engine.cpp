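// Time-stepped integrator for the two-population conductance-based network.
//
// Design notes:
//  - Gating variables use the exponential-Euler update with rates frozen at
//    the step's starting voltage; the voltage uses exponential Euler on the
//    conductance-linear form of the membrane equation.
//  - Voltage-dependent gating functions are tabulated on a 0.025 mV grid
//    with linear interpolation (rebuilt per call for the configured dt).
//  - A self-contained xoshiro256++ stream drives the Ornstein-Uhlenbeck
//    noises so that trials are reproducible from a single integer seed and
//    independent of R's global RNG state.
//  - Spikes are threshold crossings of -20 mV (upward) with a 2 ms lockout
//    on detection; spike times are linearly interpolated within the step
//    and synaptic jumps are applied on the following step.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// ---- RNG: splitmix64 seeding + xoshiro256++, polar normals ----
// Ziggurat tables for standard normals (Marsaglia & Tsang 2000)
struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1); kn[1] = 0;
    wn[0] = q / m1; wn[127] = dn / m1;
    fn[0] = 1.0; fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1); tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};
static const ZigTables zig;

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double normal() {
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)next();
      int i = hz & 127;
      if ((uint32_t)std::abs(hz) < zig.kn[i]) return hz * zig.wn[i];
      // slow path: tail or wedge rejection
      const double r = 3.442619855899;
      double x = hz * zig.wn[i];
      if (i == 0) {
        double y;
        do { x = -std::log(unif()) / r; y = -std::log(unif()); }
        while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      if (zig.fn[i] + unif() * (zig.fn[i - 1] - zig.fn[i]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// ---- Gating kinetics: 1 = shifted-HH cortical (default), 2 = Wang-Buzsaki ----
inline double lin_exp(double x, double s) {  // x / (1 - exp(-x/s))
  if (std::fabs(x) < 1e-7) return s;
  return x / (1.0 - std::exp(-x / s));
}
inline double alpha_m(double V, int kin) {
  return kin == 1 ? 0.1 * lin_exp(V + 30.0, 10.0)
                  : 0.1 * lin_exp(V + 35.0, 10.0);
}
inline double beta_m(double V, int kin) {
  return kin == 1 ? 4.0 * std::exp(-(V + 55.0) / 18.0)
                  : 4.0 * std::exp(-(V + 60.0) / 18.0);
}
inline double alpha_h(double V, int kin) {
  return kin == 1 ? 0.07 * std::exp(-(V + 44.0) / 20.0)
                  : 5.0 * 0.07 * std::exp(-(V + 58.0) / 20.0);
}
inline double beta_h(double V, int kin) {
  return kin == 1 ? 1.0 / (std::exp(-0.1 * (V + 14.0)) + 1.0)
                  : 5.0 / (std::exp(-0.1 * (V + 28.0)) + 1.0);
}
inline double alpha_n(double V, int kin) {
  return kin == 1 ? 0.01 * lin_exp(V + 34.0, 10.0)
                  : 5.0 * 0.01 * lin_exp(V + 34.0, 10.0);
}
inline double beta_n(double V, int kin) {
  return kin == 1 ? 0.125 * std::exp(-(V + 44.0) / 80.0)
                  : 5.0 * 0.125 * std::exp(-(V + 44.0) / 80.0);
}
inline double z_inf_f(double V) { return 1.0 / (1.0 + std::exp(-0.7 * (V + 30.0))); }

// Tabulated gating functions for one dt.
struct GateTables {
  double Vmin, inv_step;
  int npt;
  std::vector<double> minf, hinf, eh, ninf, en, zinf;
  GateTables(double dt, int kin) : Vmin(-120.0), inv_step(40.0) {  // 0.025 mV grid
    const double Vmax = 60.0, step = 1.0 / inv_step;
    npt = (int)((Vmax - Vmin) * inv_step) + 1;
    minf.resize(npt); hinf.resize(npt); eh.resize(npt);
    ninf.resize(npt); en.resize(npt); zinf.resize(npt);
    for (int k = 0; k < npt; ++k) {
      double V = Vmin + k * step;
      double am = alpha_m(V, kin), bm = beta_m(V, kin);
      double ah = alpha_h(V, kin), bh = beta_h(V, kin);
      double an = alpha_n(V, kin), bn = beta_n(V, kin);
      minf[k] = am / (am + bm);
      hinf[k] = ah / (ah + bh);
      eh[k] = std::exp(-dt * (ah + bh));
      ninf[k] = an / (an + bn);
      en[k] = std::exp(-dt * (an + bn));
      zinf[k] = z_inf_f(V);
    }
  }
  inline void lookup(double V, double &mi, double &hi, double &ehv,
                     double &ni, double &env, double &zi) const {
    double x = (V - Vmin) * inv_step;
    if (x < 0.0) x = 0.0;
    if (x > npt - 1.001) x = npt - 1.001;
    int k = (int)x;
    double f = x - k;
    mi = minf[k] + f * (minf[k + 1] - minf[k]);
    hi = hinf[k] + f * (hinf[k + 1] - hinf[k]);
    ehv = eh[k] + f * (eh[k + 1] - eh[k]);
    ni = ninf[k] + f * (ninf[k + 1] - ninf[k]);
    env = en[k] + f * (en[k + 1] - en[k]);
    zi = zinf[k] + f * (zinf[k + 1] - zinf[k]);
  }
};

struct PopPar {
  double C_m, g_L, V_L, g_Na, V_Na, g_K, V_K, g_adapt, tau_adapt;
  void from(const NumericVector &v) {
    C_m = v[0]; g_L = v[1]; V_L = v[2]; g_Na = v[3]; V_Na = v[4];
    g_K = v[5]; V_K = v[6]; g_adapt = v[7]; tau_adapt = v[8];
  }
};

}  // namespace

// [[Rcpp::export]]
List simulate_network_cpp(int n_E, int n_I,
                          IntegerVector src_ptr, IntegerVector tgt_idx,
                          NumericMatrix jump,  // jump(post_pop, pre_pop), mS/cm2
                          double tau_syn, double rho,
                          double V_rev_E, double V_rev_I,
                          NumericVector par_E, NumericVector par_I,
                          NumericVector gb_mean, NumericVector gb_amp,
                          NumericVector gff_bar, NumericVector R_tot,
                          double eta_sigma, NumericVector I_ext,
                          double dt, double t_total, double t_record,
                          NumericVector V0, double seed, bool noise_on,
                          int kinetics = 1) {
  const int N = n_E + n_I;
  if (N < 1) stop("need at least one neuron");
  PopPar par[2];
  par[0].from(par_E); par[1].from(par_I);
  GateTables tab(dt, kinetics);

  const double d_syn = std::exp(-dt / tau_syn);
  const double ou_decay = std::exp(-dt / tau_syn);
  const double ou_sd = eta_sigma * std::sqrt(1.0 - ou_decay * ou_decay);
  const double e_z[2] = {std::exp(-dt / par[0].tau_adapt),
                         std::exp(-dt / par[1].tau_adapt)};
  const double V_thresh = -20.0, t_lockout = 2.0;

  auto get = [](const NumericVector &v, int i) {
    return v.size() == 1 ? v[0] : v[i];
  };

  std::vector<double> V(N), h(N), n(N), z(N), gE(N, 0.0), gI(N, 0.0),
      gff(N, 0.0), eta_ff(N, 0.0), eta_b(N, 0.0), last_spike(N, -1e9);
  Xoshiro rng((uint64_t)seed);

  for (int i = 0; i < N; ++i) {
    int p = (i < n_E) ? 0 : 1;
    V[i] = get(V0, i);
    double mi, hi, ehv, ni, env, zi;
    tab.lookup(V[i], mi, hi, ehv, ni, env, zi);
    h[i] = hi; n[i] = ni; z[i] = zi;
    double R = get(R_tot, i);
    gff[i] = gff_bar[p] * R;
    if (noise_on) {
      eta_ff[i] = eta_sigma * rng.normal();
      eta_b[i] = eta_sigma * rng.normal();
    }
  }

  const long nsteps = (long)std::llround(t_total / dt);
  std::vector<int> spikes_prev, spikes_now;
  spikes_prev.reserve(256); spikes_now.reserve(256);
  std::vector<double> rec_t; std::vector<int> rec_id;
  rec_t.reserve(4096); rec_id.reserve(4096);

  const bool has_edges = tgt_idx.size() > 0;
  const int *tgt = has_edges ? &tgt_idx[0] : nullptr;
  const int *ptr = &src_ptr[0];
  const double jmp[2][2] = {{jump(0, 0), jump(0, 1)},
                            {jump(1, 0), jump(1, 1)}};

  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    // synaptic decay
    for (int i = 0; i < N; ++i) { gE[i] *= d_syn; gI[i] *= d_syn; }
    // propagate last step's spikes
    for (size_t si = 0; si < spikes_prev.size(); ++si) {
      int j = spikes_prev[si];
      int pre = (j < n_E) ? 0 : 1;
      for (int k = ptr[j]; k < ptr[j + 1]; ++k) {
        int i = tgt[k];
        int post = (i < n_E) ? 0 : 1;
        if (pre == 0) gE[i] += jmp[post][0]; else gI[i] += jmp[post][1];
      }
    }
    spikes_now.clear();

    for (int i = 0; i < N; ++i) {
      const int p = (i < n_E) ? 0 : 1;
      const PopPar &pp = par[p];
      double Vi = V[i];

      // stochastic inputs
      double gb = gb_mean[p], gf = gff[i];
      if (noise_on) {
        eta_b[i] = eta_b[i] * ou_decay + ou_sd * rng.normal();
        eta_ff[i] = eta_ff[i] * ou_decay + ou_sd * rng.normal();
        gb += gb_amp[p] * eta_b[i];
        if (gb < 0.0) gb = 0.0;
        double R = get(R_tot, i);
        double drive = R + std::sqrt(R) * eta_ff[i];
        if (drive < 0.0) drive = 0.0;
        gf = gf * d_syn + (1.0 - d_syn) * gff_bar[p] * drive;
        gff[i] = gf;
      }

      // gating update (rates at start-of-step voltage)
      double mi, hi, ehv, ni, env, zi;
      tab.lookup(Vi, mi, hi, ehv, ni, env, zi);
      h[i] = hi + (h[i] - hi) * ehv;
      n[i] = ni + (n[i] - ni) * env;
      z[i] = zi + (z[i] - zi) * e_z[p];

      // conductance-linear membrane update
      double m3 = mi * mi * mi;
      double gNa = pp.g_Na * m3 * h[i];
      double n2 = n[i] * n[i];
      double gK = pp.g_K * n2 * n2 + pp.g_adapt * z[i];
      double gexc = gE[i] + gf + gb;          // excitatory reversal V_rev_E
      double Gtot = pp.g_L + gNa + gK + rho * (gexc + gI[i]);
      double S = pp.g_L * pp.V_L + gNa * pp.V_Na + gK * pp.V_K
          + gexc * (rho * V_rev_E - (1.0 - rho) * (pp.V_L - V_rev_E))
          + gI[i] * (rho * V_rev_I - (1.0 - rho) * (pp.V_L - V_rev_I))
          + get(I_ext, i);
      double Vinf = S / Gtot;
      double Vnew = Vinf + (Vi - Vinf) * std::exp(-Gtot * dt / pp.C_m);
      if (!std::isfinite(Vnew))
        stop("numerical blow-up: non-finite V for neuron %d at t = %.2f ms",
             i + 1, t);
      V[i] = Vnew;

      // spike detection
      if (Vi < V_thresh && Vnew >= V_thresh &&
          t - last_spike[i] >= t_lockout) {
        double ts = t + dt * (V_thresh - Vi) / (Vnew - Vi);
        last_spike[i] = ts;
        spikes_now.push_back(i);
        if (ts >= t_record) { rec_t.push_back(ts - t_record); rec_id.push_back(i); }
      }
    }
    spikes_prev.swap(spikes_now);
  }

  return List::create(_["spike_t"] = wrap(rec_t),
                      _["spike_id"] = wrap(rec_id),
                      _["V_end"] = wrap(V));
}
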