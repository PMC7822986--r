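// Dual-site exponential integrate-and-fire spiral-ganglion fibre simulator.
//
// Each fibre has a peripheral process and a central axon, modelled as
// separate exponential integrate-and-fire point processes with
// sub-threshold (a, tau_w) and spike-triggered (b) adaptation:
//
//   C dV/dt = -g (V - v_rest) + g dT exp((V - v_T - W) / dT) + I(t)
//   tau_w dW/dt = a (V - v_rest) - W,  W += b on spike
//
// Peripheral input is -sens_p * s(t), central +sens_c * s(t), where s(t)
// is the signed stimulus current (anodic positive), so cathodic phases
// depolarise the peripheral site and anodic phases the central axon.
// Site spike trains are merged under a shared refractory period
// (first-spike-wins); a peripheral spike additionally resets the central
// site after a propagation delay (antidromic collision).
//
// Integration: forward Euler at dt (default 1 us) inside the pulse
// footprint and a post-pulse tail while the exponential term is live;
// analytic exponential relaxation over the remaining inter-pulse gap.
// Times are microseconds throughout.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// -- deterministic RNG (splitmix64 + Box-Muller), platform independent --
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// derive an independent stream for (fibre, level, trial) from one master seed
inline uint64_t stream_seed(uint64_t master, uint64_t fibre, uint64_t level,
                            uint64_t trial) {
  uint64_t s = mix64(master + 0x9E3779B97F4A7C15ULL);
  s = mix64(s ^ (fibre + 0xBF58476D1CE4E5B9ULL));
  s = mix64(s ^ (level + 0x94D049BB133111EBULL));
  s = mix64(s ^ (trial + 0xD6E8FEB86659FD93ULL));
  return s;
}

struct Site {
  double C, g, vrest, vT, dT, vreset, tref, a, b, tauw, sens, rho;
  bool enabled;
};

Site site_from_list(const List& l) {
  Site s;
  s.C = as<double>(l["capacitance"]);
  s.g = as<double>(l["conductance"]);
  s.vrest = as<double>(l["v_rest"]);
  s.vT = as<double>(l["v_threshold"]);
  s.dT = as<double>(l["delta_t"]);
  s.vreset = as<double>(l["v_reset"]);
  s.tref = as<double>(l["t_refractory_us"]);
  s.a = as<double>(l["adapt_a"]);
  s.b = as<double>(l["adapt_b"]);
  s.tauw = as<double>(l["tau_adapt_us"]);
  s.sens = as<double>(l["sensitivity"]);
  s.rho = as<double>(l["polarity_gain"]);
  s.enabled = as<bool>(l["enabled"]);
  return s;
}

struct SiteState {
  double V, W;
  double vTeff;  // per-pulse noisy threshold
};

// One fibre, one full train. Returns spike times (us) and site ids
// (0 peripheral, 1 central); or just the count if `times` is null.
int run_fibre(const std::vector<double>& ph_on, const std::vector<double>& ph_dur,
              const std::vector<double>& ph_amp,  // unit template, signed
              double period, int n_pulses, double level_uA,
              const Site& P, const Site& Cx, double prop_delay,
              double noise_rs, double dt, Rng& rng,
              std::vector<double>* times, std::vector<int>* sites) {
  const int nph = static_cast<int>(ph_on.size());
  double footprint = 0.0;
  for (int i = 0; i < nph; ++i)
    footprint = std::max(footprint, ph_on[i] + ph_dur[i]);

  SiteState sp = {P.vrest, 0.0, P.vT};
  SiteState sc = {Cx.vrest, 0.0, Cx.vT};
  double ref_until = -1e18;        // shared fibre refractory
  double central_reset_at = 1e18;  // pending antidromic reset
  int n_spikes = 0;

  const double tail_max = 600.0;  // us past the last phase
  const Site* S[2] = {&P, &Cx};
  SiteState* st[2] = {&sp, &sc};
  const double sgn[2] = {-1.0, +1.0};

  for (int p = 0; p < n_pulses; ++p) {
    const double t0 = p * period;
    if (noise_rs > 0.0) {
      sp.vTeff = P.vT * (1.0 + noise_rs * rng.norm());
      sc.vTeff = Cx.vT * (1.0 + noise_rs * rng.norm());
    } else {
      sp.vTeff = P.vT;
      sc.vTeff = Cx.vT;
    }

    // segment boundaries within this pulse: phases + inter-phase gaps + tail
    double t = t0;
    int seg_phase = 0;  // next template phase index
    const double t_end_max = t0 + std::min(period, footprint + tail_max);

    while (t < t_end_max - 1e-9) {
      double seg_end, amp;
      if (seg_phase < nph && t < t0 + ph_on[seg_phase] - 1e-9) {
        seg_end = t0 + ph_on[seg_phase];
        amp = 0.0;
      } else if (seg_phase < nph) {
        seg_end = t0 + ph_on[seg_phase] + ph_dur[seg_phase];
        amp = ph_amp[seg_phase] * level_uA;
        if (seg_end <= t + 1e-9) { ++seg_phase; continue; }
      } else {
        // tail: integrate only while the exponential term is live
        bool live = false;
        for (int k = 0; k < 2; ++k) {
          if (!S[k]->enabled) continue;
          double arg = (st[k]->V - st[k]->vTeff - st[k]->W) / S[k]->dT;
          if (arg > -2.0) { live = true; break; }
        }
        if (!live) break;
        seg_end = std::min(t + 25.0, t_end_max);
        amp = 0.0;
      }
      seg_end = std::min(seg_end, t_end_max);

      while (t < seg_end - 1e-9) {
        const double h = std::min(dt, seg_end - t);
        if (t >= central_reset_at) {
          sc.V = Cx.vreset;
          central_reset_at = 1e18;
        }
        const bool refract = (t < ref_until);
        for (int k = 0; k < 2; ++k) {
          const Site& s = *S[k];
          SiteState& x = *st[k];
          if (!s.enabled) continue;
          if (refract) {
            x.V = s.vreset;
            x.W += h * (s.a * (x.V - s.vrest) - x.W) / s.tauw;
            continue;
          }
          // partial polarity selectivity: the non-preferred polarity is
          // attenuated by rho rather than acting at full strength
          double I = s.sens * sgn[k] * amp;
          if (I < 0) I *= s.rho;
          double arg = (x.V - x.vTeff - x.W) / s.dT;
          double expterm = (arg > -6.0)
                               ? s.g * s.dT * std::exp(std::min(arg, 16.0))
                               : 0.0;
          const double dV = (-s.g * (x.V - s.vrest) + expterm + I) / s.C;
          const double dW = (s.a * (x.V - s.vrest) - x.W) / s.tauw;
          x.V += h * dV;
          x.W += h * dW;
          if (x.V >= x.vTeff + 10.0 * s.dT) {  // spike
            if (!std::isfinite(x.V) || !std::isfinite(x.W))
              stop("non-finite membrane state during integration");
            x.V = s.vreset;
            x.W += s.b;
            ref_until = t + h + s.tref;
            ++n_spikes;
            if (times) {
              times->push_back(t + h);
              sites->push_back(k);
            }
            if (k == 0) {  // peripheral spike: antidromic reset of central
              central_reset_at = t + h + prop_delay;
            } else {
              sp.V = P.vreset;  // orthodromic collision clears peripheral
            }
          }
        }
        t += h;
      }
      if (seg_phase < nph && t >= t0 + ph_on[seg_phase] + ph_dur[seg_phase] - 1e-9)
        ++seg_phase;
    }

    // analytic relaxation over the remaining silent gap (exp term and the
    // a-coupling are negligible there; V decays to rest, W to zero)
    const double t_next = (p + 1 < n_pulses) ? (p + 1) * period : t;
    if (t_next > t) {
      const double gap = t_next - t;
      if (t < ref_until) {
        const double clamp = std::min(ref_until, t_next) - t;
        sp.V = P.vreset;
        sc.V = Cx.vreset;
        sp.W *= std::exp(-clamp / P.tauw);
        sc.W *= std::exp(-clamp / Cx.tauw);
        const double rest = gap - clamp;
        if (rest > 0) {
          sp.V = P.vrest + (sp.V - P.vrest) * std::exp(-rest * P.g / P.C);
          sc.V = Cx.vrest + (sc.V - Cx.vrest) * std::exp(-rest * Cx.g / Cx.C);
          sp.W *= std::exp(-rest / P.tauw);
          sc.W *= std::exp(-rest / Cx.tauw);
        }
      } else {
        sp.V = P.vrest + (sp.V - P.vrest) * std::exp(-gap * P.g / P.C);
        sc.V = Cx.vrest + (sc.V - Cx.vrest) * std::exp(-gap * Cx.g / Cx.C);
        sp.W *= std::exp(-gap / P.tauw);
        sc.W *= std::exp(-gap / Cx.tauw);
      }
      if (central_reset_at < t_next) {
        // reset landed inside the silent gap: V is already near rest, but
        // honour the collision for delays longer than the gap decay
        sc.V = Cx.vreset;
        central_reset_at = 1e18;
      }
    }
  }
  return n_spikes;
}

}  // namespace

// [[Rcpp::export(name = ".sim_fibre_cpp")]]
List sim_fibre_cpp(NumericVector ph_onset_us, NumericVector ph_dur_us,
                   NumericVector ph_amp_unit, double period_us, int n_pulses,
                   double level_uA, List site_peripheral, List site_central,
                   double prop_delay_us, double noise_rs, double dt_us,
                   double seed) {
  Site P = site_from_list(site_peripheral);
  Site C = site_from_list(site_central);
  std::vector<double> on(ph_onset_us.begin(), ph_onset_us.end());
  std::vector<double> du(ph_dur_us.begin(), ph_dur_us.end());
  std::vector<double> am(ph_amp_unit.begin(), ph_amp_unit.end());
  Rng rng(stream_seed(static_cast<uint64_t>(seed), 0, 0, 0));
  std::vector<double> times;
  std::vector<int> sites;
  run_fibre(on, du, am, period_us, n_pulses, level_uA, P, C, prop_delay_us,
            noise_rs, dt_us, rng, &times, &sites);
  return List::create(_["time_us"] = wrap(times), _["site"] = wrap(sites));
}

// Population spike counts: shared site parameters, per-fibre sensitivity
// scale (10^(-offset_db/20)). Returns an n_levels x n_fibres count matrix.
// [[Rcpp::export(name = ".sim_population_cpp")]]
IntegerMatrix sim_population_cpp(NumericVector ph_onset_us,
                                 NumericVector ph_dur_us,
                                 NumericVector ph_amp_unit, double period_us,
                                 int n_pulses, NumericVector levels_uA,
                                 List site_peripheral, List site_central,
                                 NumericVector sens_scale, double prop_delay_us,
                                 double noise_rs, double dt_us, double seed,
                                 double trial) {
  Site P0 = site_from_list(site_peripheral);
  Site C0 = site_from_list(site_central);
  std::vector<double> on(ph_onset_us.begin(), ph_onset_us.end());
  std::vector<double> du(ph_dur_us.begin(), ph_dur_us.end());
  std::vector<double> am(ph_amp_unit.begin(), ph_amp_unit.end());
  const int n_fib = sens_scale.size();
  const int n_lev = levels_uA.size();
  IntegerMatrix counts(n_lev, n_fib);
  const uint64_t master = static_cast<uint64_t>(seed);
  const uint64_t tr = static_cast<uint64_t>(trial);
  for (int f = 0; f < n_fib; ++f) {
    Site P = P0, C = C0;
    P.sens *= sens_scale[f];
    C.sens *= sens_scale[f];
    for (int l = 0; l < n_lev; ++l) {
      Rng rng(stream_seed(master, f + 1, l + 1, tr));
      counts(l, f) = run_fibre(on, du, am, period_us, n_pulses, levels_uA[l],
                               P, C, prop_delay_us, noise_rs, dt_us, rng,
                               nullptr, nullptr);
    }
    if (f % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}
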