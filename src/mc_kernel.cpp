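// Monte Carlo photon transport in a homogeneous semi-infinite turbid medium,
// scored at two displaced collection fibers (MCML-style hop/drop/spin with
// weight-based absorption, Henyey-Greenstein scattering and Russian roulette).
//
// Detection uses the exact azimuthal-arc estimator: conditioned on its launch
// point, a photon's trajectory distribution is rotationally symmetric about
// the vertical axis through that point, so the indicator "exit point inside
// the detector face" can be replaced by its conditional expectation -- the
// fraction of the circle of radius d (exit distance from the launch point)
// covered by the detector disk.  Exact in expectation, large variance
// reduction for small fibers.  The numerical-aperture cut on the exit polar
// angle is rotation-invariant and stays a hard cut.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

// xoshiro256++ seeded through splitmix64: fast, portable, bit-reproducible
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
};

inline double hg_cos(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// fraction of the circle of radius d centred at distance D from a disk of
// radius r that lies inside that disk
inline double arc_fraction(double d, double D, double r) {
  if (d <= 0.0) return (D <= r) ? 1.0 : 0.0;
  if (d >= D + r) return 0.0;
  if (D > r && d <= D - r) return 0.0;
  if (D <= r && d <= r - D) return 1.0;
  double c = (D * D + d * d - r * r) / (2.0 * D * d);
  if (c >= 1.0) return 0.0;
  if (c <= -1.0) return 1.0;
  return std::acos(c) / M_PI;
}

// unpolarised Fresnel reflectance, light incident from medium of relative
// index n_rel = n_in / n_out onto the interface, incidence cosine ci
inline double fresnel_R(double ci, double n_rel) {
  if (n_rel == 1.0) return 0.0;
  const double si2 = 1.0 - ci * ci;
  const double st2 = n_rel * n_rel * si2;
  if (st2 >= 1.0) return 1.0;  // total internal reflection
  const double ct = std::sqrt(1.0 - st2);
  const double rs = (n_rel * ci - ct) / (n_rel * ci + ct);
  const double rp = (n_rel * ct - ci) / (n_rel * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// Batch Beer-Lambert reweighting of a path database: for each mu_a, the
// reflectance sum(w * exp(-mu_a * L)) / N per detector, with the variance
// computed over per-primary aggregates (entries arrive grouped by primary).
// [[Rcpp::export(name = ".rescale_batch")]]
List rescale_batch_cpp(IntegerVector det, IntegerVector primary,
                       NumericVector len, NumericVector wgt,
                       double n_photons, int nd, NumericVector mu_a) {
  const R_xlen_t m = det.size();
  const int na = mu_a.size();
  NumericMatrix R(na, nd), SE(na, nd);
  std::vector<double> sum_w(nd), sum_w2(nd), cur(nd);
  for (int a = 0; a < na; ++a) {
    std::fill(sum_w.begin(), sum_w.end(), 0.0);
    std::fill(sum_w2.begin(), sum_w2.end(), 0.0);
    std::fill(cur.begin(), cur.end(), 0.0);
    int cur_prim = m > 0 ? primary[0] : -1;
    const double mua = mu_a[a];
    for (R_xlen_t i = 0; i <= m; ++i) {
      if (i == m || primary[i] != cur_prim) {
        for (int j = 0; j < nd; ++j) {
          sum_w[j] += cur[j];
          sum_w2[j] += cur[j] * cur[j];
          cur[j] = 0.0;
        }
        if (i == m) break;
        cur_prim = primary[i];
      }
      cur[det[i] - 1] += wgt[i] * std::exp(-mua * len[i]);
    }
    for (int j = 0; j < nd; ++j) {
      R(a, j) = sum_w[j] / n_photons;
      double var = (sum_w2[j] - sum_w[j] * sum_w[j] / n_photons) /
        std::max(1.0, n_photons - 1.0);
      SE(a, j) = std::sqrt(std::max(0.0, var / n_photons));
    }
  }
  return List::create(_["reflectance"] = R, _["se"] = SE);
}

// Deterministic transform of uniforms to Henyey-Greenstein deflection cosines
// [[Rcpp::export(name = ".hg_cosine")]]
NumericVector hg_cosine_cpp(double g, NumericVector u) {
  const R_xlen_t n = u.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = hg_cos(g, u[i]);
  return out;
}

namespace {

inline double hg_pdf(double g, double c) {
  // phase function per steradian
  if (g == 0.0) return 1.0 / (4.0 * M_PI);
  const double den = 1.0 + g * g - 2.0 * g * c;
  return (1.0 - g * g) / (4.0 * M_PI * den * std::sqrt(den));
}

struct PhotonState {
  double x, y, z, ux, uy, uz, L, zmax;
  unsigned mask;  // bit k set: photon is above splitting plane k (split once)
};

}  // namespace

// Core kernel.  Lengths in mm.  'cos_cone' is the cosine of the acceptance /
// launch half-angle evaluated in tissue; 'n_rel' = n_tissue / n_ambient
// (1 = index matched, Fresnel boundary otherwise).
//
// For zero-absorption (white) runs, geometric splitting with a weight window
// is applied at the planes 'z_split' (depths, mm, with integer factors
// 'split_factor'): a photon crossing plane k toward the surface is split
// into f_k copies of 1/f_k the weight; a split copy diving back through the
// plane plays Russian roulette with survival 1/f_k.  Exact in expectation;
// copies of the same primary photon are aggregated per primary for the
// variance estimate.  'split_net' books the realised (zero-mean) roulette
// imbalance so the weight budget closes exactly.
// [[Rcpp::export(name = ".mc_kernel")]]
List mc_kernel_cpp(double mu_a, double mu_s, double g,
                   double src_radius, double det_radius,
                   NumericVector sds, double cos_cone,
                   int n_photons, double seed,
                   double w_thresh, double p_survive,
                   bool record_paths,
                   double r_max, double z_max, double n_rel,
                   IntegerVector split_factor, NumericVector z_split) {
  const int nd = sds.size();
  std::vector<double> det_w(nd, 0.0), det_w2(nd, 0.0);
  std::vector<int> det_n(nd, 0);
  double absorbed = 0.0, escaped = 0.0, killed = 0.0, split_net = 0.0;

  std::vector<int> p_det, p_primary;
  std::vector<double> p_len, p_depth, p_w;

  Xoshiro rng(static_cast<uint64_t>(seed));
  const double mu_t = mu_a + mu_s;
  const double albedo = (mu_t > 0.0) ? mu_s / mu_t : 0.0;
  const double r_max2 = r_max * r_max;
  const long max_steps = 5000000L;
  // splitting planes sorted by depth, active for white runs only
  std::vector<double> pz; std::vector<int> pf;
  for (int k = 0; k < split_factor.size() && k < (int)z_split.size(); ++k)
    if (split_factor[k] > 1 && mu_a == 0.0) {
      pz.push_back(z_split[k]); pf.push_back(split_factor[k]);
    }
  const int np = (int)pz.size();
  const bool split_on = np > 0;
  // Cone-restricted next-event estimation for white runs: at every
  // scattering vertex, sample one direction uniformly in the upward NA
  // cone and score w * p_HG(Theta) * dOmega * exp(-mu_t * dist) * arc --
  // an unbiased one-sample estimate of the detection probability of the
  // next flight.  Analog surface exits then no longer score (they would
  // double count) and only book escaped weight.
  const bool nee = (mu_a == 0.0) && mu_s > 0.0;
  const double omega_cone = 2.0 * M_PI * (1.0 - cos_cone);
  const double v_min = 1e-6;  // roulette floor for micro-contributions

  std::vector<PhotonState> stack;
  std::vector<double> prim_w(nd);

  for (int ip = 0; ip < n_photons; ++ip) {
    // launch: uniform over source-fiber face, uniform over the solid-angle cone
    double rr = src_radius * std::sqrt(rng.unif());
    double ph = 2.0 * M_PI * rng.unif();
    const double x0 = rr * std::cos(ph), y0 = rr * std::sin(ph);
    double ct = 1.0 - rng.unif() * (1.0 - cos_cone);
    double st = std::sqrt(1.0 - ct * ct);
    ph = 2.0 * M_PI * rng.unif();

    if (mu_t <= 0.0) { killed += 1.0; continue; }  // transparent medium

    stack.clear();
    stack.push_back(PhotonState{x0, y0, 0.0, st * std::cos(ph),
                                st * std::sin(ph), ct, 0.0, 0.0, 0});
    std::fill(prim_w.begin(), prim_w.end(), 0.0);

    while (!stack.empty()) {
      PhotonState ps = stack.back();
      stack.pop_back();
      double x = ps.x, y = ps.y, z = ps.z;
      double ux = ps.ux, uy = ps.uy, uz = ps.uz;
      double L = ps.L, zmax = ps.zmax;
      unsigned mask = ps.mask;
      double w = 1.0;
      for (int k = 0; k < np; ++k)
        if (mask & (1u << k)) w /= pf[k];
      long steps = 0;
      bool alive = true;

      while (alive) {
        if (++steps > max_steps) { killed += w; break; }
        double s = -std::log(1.0 - rng.unif()) / mu_t;
        double znew = z + uz * s;
        // splitting-plane bookkeeping: handle the nearest crossed plane first
        if (split_on) {
          if (uz < 0.0) {
            int kc = -1;
            for (int k = np - 1; k >= 0; --k)
              if (pz[k] < z && pz[k] > znew) { kc = k; break; }
            if (kc >= 0 && !(mask & (1u << kc))) {
              // crossing upward: truncate at the plane and split
              double sc = (pz[kc] - z) / uz;
              x += ux * sc; y += uy * sc; z = pz[kc]; L += sc;
              mask |= (1u << kc);
              w /= pf[kc];
              for (int c = 1; c < pf[kc]; ++c)
                stack.push_back(PhotonState{x, y, z, ux, uy, uz, L, zmax,
                                            mask});
              continue;  // re-draw the remaining flight (memoryless)
            }
          } else if (uz > 0.0) {
            int kc = -1;
            for (int k = 0; k < np; ++k)
              if (pz[k] > z && pz[k] < znew && (mask & (1u << k))) {
                kc = k; break;
              }
            if (kc >= 0) {
              // split copy diving back down: roulette at the plane
              double sc = (pz[kc] - z) / uz;
              x += ux * sc; y += uy * sc; z = pz[kc]; L += sc;
              if (zmax < z) zmax = z;
              mask &= ~(1u << kc);
              if (rng.unif() * pf[kc] < 1.0) {
                split_net -= w * (pf[kc] - 1);  // weight restored
                w *= pf[kc];
              } else {
                split_net += w;
                alive = false;
                break;
              }
              continue;
            }
          }
        }
        if (znew < 0.0) {
          double s1 = -z / uz;
          x += ux * s1; y += uy * s1; z = 0.0; L += s1;
          double ci = -uz;
          double Rf = fresnel_R(ci, n_rel);
          if (Rf > 0.0 && rng.unif() < Rf) {
            uz = -uz;
            continue;
          }
          double rem = w;
          if (!nee && ci >= cos_cone) {
            for (int j = 0; j < nd; ++j) {
              double D = std::hypot(sds[j] - x0, y0);
              double d = std::hypot(x - x0, y - y0);
              double af = arc_fraction(d, D, det_radius);
              if (af > 0.0) {
                double v = w * af;
                prim_w[j] += v; det_n[j] += 1;
                rem -= v;
                if (record_paths) {
                  p_det.push_back(j + 1);
                  p_primary.push_back(ip + 1);
                  p_len.push_back(L);
                  p_depth.push_back(zmax);
                  p_w.push_back(v);
                }
              }
            }
          }
          escaped += rem;
          alive = false;
          break;
        }
        x += ux * s; y += uy * s; z = znew; L += s;
        if (z > zmax) zmax = z;
        if (x * x + y * y > r_max2 || z > z_max) { killed += w; break; }
        if (mu_a > 0.0) {
          absorbed += w * (1.0 - albedo);
          w *= albedo;
        }
        if (mu_s <= 0.0) { absorbed += w; break; }  // pure absorber: no spin
        if (w < w_thresh) {
          if (rng.unif() < p_survive) {
            w /= p_survive;
          } else {
            absorbed += w;
            break;
          }
        }
        if (nee && z > 0.0) {
          // next-event flight toward the surface within the NA cone
          double ctn = 1.0 - rng.unif() * (1.0 - cos_cone);
          double stn = std::sqrt(std::max(0.0, 1.0 - ctn * ctn));
          double phn = 2.0 * M_PI * rng.unif();
          double ox = stn * std::cos(phn), oy = stn * std::sin(phn);
          double ozz = -ctn;
          double dist = z / ctn;
          double cosT = ux * ox + uy * oy + uz * ozz;
          double base = w * hg_pdf(g, cosT) * omega_cone *
            std::exp(-mu_t * dist) * (1.0 - fresnel_R(ctn, n_rel));
          if (base > 0.0) {
            double xe = x + ox * dist, ye = y + oy * dist;
            double d = std::hypot(xe - x0, ye - y0);
            for (int j = 0; j < nd; ++j) {
              double D = std::hypot(sds[j] - x0, y0);
              double af = arc_fraction(d, D, det_radius);
              if (af <= 0.0) continue;
              double v = base * af;
              if (v < v_min) {  // unbiased roulette on micro-contributions
                if (rng.unif() * v_min < v) v = v_min; else continue;
              }
              prim_w[j] += v; det_n[j] += 1;
              if (record_paths) {
                p_det.push_back(j + 1);
                p_primary.push_back(ip + 1);
                p_len.push_back(L + dist);
                p_depth.push_back(zmax);
                p_w.push_back(v);
              }
            }
          }
        }
        double cs = hg_cos(g, rng.unif());
        double sn = std::sqrt(std::max(0.0, 1.0 - cs * cs));
        double psi = 2.0 * M_PI * rng.unif();
        double cp = std::cos(psi), sp = std::sin(psi);
        if (std::fabs(uz) > 0.99999) {
          ux = sn * cp; uy = sn * sp; uz = (uz >= 0.0 ? cs : -cs);
        } else {
          double den = std::sqrt(1.0 - uz * uz);
          double nux = sn * (ux * uz * cp - uy * sp) / den + ux * cs;
          double nuy = sn * (uy * uz * cp + ux * sp) / den + uy * cs;
          double nuz = -sn * cp * den + uz * cs;
          double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
          ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
        }
      }
    }
    for (int j = 0; j < nd; ++j) {
      det_w[j] += prim_w[j];
      det_w2[j] += prim_w[j] * prim_w[j];
    }
  }

  NumericVector refl(nd), se(nd);
  IntegerVector nn(nd);
  const double N = static_cast<double>(n_photons);
  for (int j = 0; j < nd; ++j) {
    refl[j] = det_w[j] / N;
    double var = (det_w2[j] - det_w[j] * det_w[j] / N) / std::max(1.0, N - 1.0);
    se[j] = std::sqrt(std::max(0.0, var / N));
    nn[j] = det_n[j];
  }

  List out = List::create(
      _["reflectance"] = refl, _["se"] = se, _["n_detected"] = nn,
      _["absorbed"] = absorbed, _["escaped"] = escaped, _["killed"] = killed,
      _["split_net"] = split_net, _["n_photons"] = n_photons);
  if (record_paths) {
    out["path_detector"] = wrap(p_det);
    out["path_primary"] = wrap(p_primary);
    out["path_length"] = wrap(p_len);
    out["path_max_depth"] = wrap(p_depth);
    out["path_weight"] = wrap(p_w);
  }
  return out;
}
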