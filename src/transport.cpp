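// Voxel Monte Carlo photon transport: Woodcock (delta) tracking with
// per-macro-cell majorants, free-electron Klein-Nishina Compton sampling,
// Thomson coherent scattering, local energy deposition (kerma approximation,
// electron transport suppressed) and a track-length air-kerma estimator on a
// coarse co-registered grid.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double u() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
};

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct EnergyTables {
  // uniform grid e0 + i*de, i in [0, nE)
  double e0, de;
  int nE, nmat;
  const double *mu;      // nE x nmat linear attenuation, 1/m
  const double *fph;     // cumulative photoelectric fraction
  const double *fpi;     // cumulative photo+incoherent fraction
  const double *muen_air; // cm^2/g on the same grid

  inline void bracket(double E, int &i, double &w) const {
    double t = (E - e0) / de;
    if (t < 0) t = 0;
    if (t > nE - 1.000001) t = nE - 1.000001;
    i = (int)t;
    w = t - i;
  }
  inline double mu_at(int i, double w, int m) const {
    return mu[i + m * nE] * (1 - w) + mu[i + 1 + m * nE] * w;
  }
  inline double fph_at(int i, double w, int m) const {
    return fph[i + m * nE] * (1 - w) + fph[i + 1 + m * nE] * w;
  }
  inline double fpi_at(int i, double w, int m) const {
    return fpi[i + m * nE] * (1 - w) + fpi[i + 1 + m * nE] * w;
  }
  inline double muen_at(int i, double w) const {
    return muen_air[i] * (1 - w) + muen_air[i + 1] * w;
  }
};

struct Grid {
  int nx, ny, nz;
  double ox, oy, oz, s;
  inline bool inside(const double *p) const {
    return p[0] >= ox && p[1] >= oy && p[2] >= oz &&
           p[0] < ox + nx * s && p[1] < oy + ny * s && p[2] < oz + nz * s;
  }
  inline long vox(const double *p) const {
    int i = (int)std::floor((p[0] - ox) / s);
    int j = (int)std::floor((p[1] - oy) / s);
    int k = (int)std::floor((p[2] - oz) / s);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return -1;
    return i + (long)nx * (j + (long)ny * k);
  }
};

// distance to the exit of the axis-aligned box [lo, hi) along dir
inline double box_exit(const double *p, const double *d,
                       const double *lo, const double *hi) {
  double t = 1e300;
  for (int a = 0; a < 3; ++a) {
    if (d[a] > 1e-14) {
      double ta = (hi[a] - p[a]) / d[a];
      if (ta < t) t = ta;
    } else if (d[a] < -1e-14) {
      double ta = (lo[a] - p[a]) / d[a];
      if (ta < t) t = ta;
    }
  }
  return t;
}

// clip a ray to the entry of box [lo, hi]; returns entry distance or -1
inline double box_entry(const double *p, const double *d,
                        const double *lo, const double *hi) {
  double t0 = 0.0, t1 = 1e300;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-14) {
      if (p[a] < lo[a] || p[a] >= hi[a]) return -1.0;
    } else {
      double ta = (lo[a] - p[a]) / d[a];
      double tb = (hi[a] - p[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return (t0 <= t1) ? t0 : -1.0;
}

inline void rotate_dir(double *d, double mu, double phi) {
  double s = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  double cp = std::cos(phi), sp = std::sin(phi);
  double rho = std::sqrt(d[0] * d[0] + d[1] * d[1]);
  double nd[3];
  if (rho > 1e-12) {
    nd[0] = mu * d[0] + s * (cp * d[0] * d[2] - sp * d[1]) / rho;
    nd[1] = mu * d[1] + s * (cp * d[1] * d[2] + sp * d[0]) / rho;
    nd[2] = mu * d[2] - s * cp * rho;
  } else {
    nd[0] = s * cp;
    nd[1] = s * sp;
    nd[2] = (d[2] >= 0 ? mu : -mu);
  }
  double n = std::sqrt(nd[0] * nd[0] + nd[1] * nd[1] + nd[2] * nd[2]);
  for (int a = 0; a < 3; ++a) d[a] = nd[a] / n;
}

// Kahn's composition-rejection sampling of the Klein-Nishina angular
// distribution; returns cos(theta), sets x = E/E'
inline double kn_sample(double k, Rng &rng, double &x) {
  double g = 1.0 + 2.0 * k;
  for (;;) {
    double r1 = rng.u(), r2 = rng.u(), r3 = rng.u();
    if (r1 <= g / (g + 8.0)) {
      x = 1.0 + 2.0 * k * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) {
        return 1.0 - (x - 1.0) / k;
      }
    } else {
      x = g / (1.0 + 2.0 * k * r2);
      double mu = 1.0 - (x - 1.0) / k;
      if (r3 <= 0.5 * (mu * mu + 1.0 / x)) return mu;
    }
  }
}

inline double thomson_sample(Rng &rng) {
  for (;;) {
    double mu = 2.0 * rng.u() - 1.0;
    if (rng.u() <= 0.5 * (1.0 + mu * mu)) return mu;
  }
}

// track-length scoring of one segment into the coarse air grid:
// each traversed voxel receives chord * val (val = w * E * muen/rho * 100)
inline void score_air(const Grid &g, std::vector<double> &tally,
                      const double *p0, const double *d, double L, double val) {
  double lo[3] = {g.ox, g.oy, g.oz};
  double hi[3] = {g.ox + g.nx * g.s, g.oy + g.ny * g.s, g.oz + g.nz * g.s};
  double t0 = 0.0, t1 = L;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-14) {
      if (p0[a] < lo[a] || p0[a] >= hi[a]) return;
    } else {
      double ta = (lo[a] - p0[a]) / d[a];
      double tb = (hi[a] - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t0 >= t1) return;
  double p[3] = {p0[0] + (t0 + 1e-10) * d[0], p0[1] + (t0 + 1e-10) * d[1],
                 p0[2] + (t0 + 1e-10) * d[2]};
  int i = (int)std::floor((p[0] - g.ox) / g.s);
  int j = (int)std::floor((p[1] - g.oy) / g.s);
  int k = (int)std::floor((p[2] - g.oz) / g.s);
  i = std::min(std::max(i, 0), g.nx - 1);
  j = std::min(std::max(j, 0), g.ny - 1);
  k = std::min(std::max(k, 0), g.nz - 1);
  int si = d[0] > 0 ? 1 : -1, sj = d[1] > 0 ? 1 : -1, sk = d[2] > 0 ? 1 : -1;
  double tmx = (std::fabs(d[0]) > 1e-14)
                   ? ((g.ox + (i + (si > 0 ? 1 : 0)) * g.s) - p0[0]) / d[0]
                   : 1e300;
  double tmy = (std::fabs(d[1]) > 1e-14)
                   ? ((g.oy + (j + (sj > 0 ? 1 : 0)) * g.s) - p0[1]) / d[1]
                   : 1e300;
  double tmz = (std::fabs(d[2]) > 1e-14)
                   ? ((g.oz + (k + (sk > 0 ? 1 : 0)) * g.s) - p0[2]) / d[2]
                   : 1e300;
  double tdx = std::fabs(d[0]) > 1e-14 ? g.s / std::fabs(d[0]) : 1e300;
  double tdy = std::fabs(d[1]) > 1e-14 ? g.s / std::fabs(d[1]) : 1e300;
  double tdz = std::fabs(d[2]) > 1e-14 ? g.s / std::fabs(d[2]) : 1e300;
  double t = t0;
  while (t < t1) {
    double tn = std::min(std::min(tmx, tmy), std::min(tmz, t1));
    long id = i + (long)g.nx * (j + (long)g.ny * k);
    tally[id] += (tn - t) * val;
    t = tn;
    if (t >= t1) break;
    if (tmx <= tmy && tmx <= tmz) {
      i += si; tmx += tdx;
      if (i < 0 || i >= g.nx) break;
    } else if (tmy <= tmz) {
      j += sj; tmy += tdy;
      if (j < 0 || j >= g.ny) break;
    } else {
      k += sk; tmz += tdz;
      if (k < 0 || k >= g.nz) break;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List mc_run_cpp(IntegerVector dims, NumericVector origin, double spacing,
                IntegerVector matidx, int nmat,
                NumericMatrix mu_lin, NumericMatrix cum_photo,
                NumericMatrix cum_pi, NumericVector muen_air,
                double e0, double de,
                List source, NumericVector spec_edges, NumericVector spec_cdf,
                double n_hist, int n_batch, double seed, double cutoff,
                IntegerVector roi_id, int n_roi,
                IntegerVector air_dims, NumericVector air_origin,
                double air_spacing, int macro,
                bool record_escapes, int escape_cap,
                bool record_first_coll, int first_cap,
                int path_log_max) {
  Grid fine{dims[0], dims[1], dims[2], origin[0], origin[1], origin[2], spacing};
  Grid air{air_dims[0], air_dims[1], air_dims[2],
           air_origin[0], air_origin[1], air_origin[2], air_spacing};
  long nvox = (long)fine.nx * fine.ny * fine.nz;
  long navox = (long)air.nx * air.ny * air.nz;

  EnergyTables tab{e0, de, (int)mu_lin.nrow(), nmat,
                   REAL(mu_lin), REAL(cum_photo), REAL(cum_pi), REAL(muen_air)};

  // macro-cell material masks (nmat <= 32)
  int mx = (fine.nx + macro - 1) / macro;
  int my = (fine.ny + macro - 1) / macro;
  int mz = (fine.nz + macro - 1) / macro;
  std::vector<uint32_t> mask((long)mx * my * mz, 0u);
  {
    const int *mi = INTEGER(matidx);
    for (int k = 0; k < fine.nz; ++k)
      for (int j = 0; j < fine.ny; ++j) {
        long base = (long)fine.nx * (j + (long)fine.ny * k);
        long mbase = (long)mx * ((j / macro) + (long)my * (k / macro));
        for (int i = 0; i < fine.nx; ++i)
          mask[mbase + i / macro] |= 1u << (mi[base + i] - 1);
      }
  }

  // source description
  int stype = as<int>(source["type"]); // 0 cone, 1 isotropic, 2 pencil, 3 parallel
  NumericVector spos = source["pos"], saxis = source["axis"];
  NumericVector su = source["u"], sv = source["v"];
  double shx = as<double>(source["half_x"]), shy = as<double>(source["half_y"]);
  double ssid = as<double>(source["sid"]);

  std::vector<double> fine_sum(nvox, 0), fine_sumsq(nvox, 0), fine_batch(nvox, 0);
  std::vector<double> air_sum(navox, 0), air_sumsq(navox, 0), air_batch(navox, 0);
  NumericMatrix roi_batch(n_roi > 0 ? n_roi : 1, n_batch);
  NumericMatrix ledger(n_batch, 7); // emitted, deposited, escaped, corruptE, nCorrupt, nVirtual, nReal
  std::vector<double> escapes;  // x y z dx dy dz E ncoll
  std::vector<double> firstcol;
  List paths;
  std::vector<double> cur_path;
  int paths_done = 0;

  const int *mi = INTEGER(matidx);
  const int *roi = INTEGER(roi_id);
  double wlo[3] = {fine.ox, fine.oy, fine.oz};
  double whi[3] = {fine.ox + fine.nx * spacing, fine.oy + fine.ny * spacing,
                   fine.oz + fine.nz * spacing};
  std::vector<double> mu_at(nmat);

  long n_total = (long)n_hist;
  long per = n_total / n_batch, rem = n_total % n_batch;
  int nbins = spec_cdf.size();

  for (int b = 0; b < n_batch; ++b) {
    Rng rng(splitmix64(((uint64_t)seed << 20) + 0x5eedULL + (uint64_t)b));
    std::fill(fine_batch.begin(), fine_batch.end(), 0.0);
    std::fill(air_batch.begin(), air_batch.end(), 0.0);
    double emitted = 0, deposited = 0, escaped = 0, corruptE = 0;
    double nvirt = 0, nreal = 0;
    long ncorr = 0;
    long nb = per + (b < rem ? 1 : 0);

    for (long h = 0; h < nb; ++h) {
      // --- source sampling
      double r = rng.u();
      int bin = 0;
      {
        int lo = 0, hi = nbins - 1;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (spec_cdf[mid] < r) lo = mid + 1; else hi = mid;
        }
        bin = lo;
      }
      double E = spec_edges[bin] +
                 rng.u() * (spec_edges[bin + 1] - spec_edges[bin]);
      double p[3] = {spos[0], spos[1], spos[2]};
      double d[3];
      if (stype == 1) {
        double mu = 2 * rng.u() - 1, phi = 2 * M_PI * rng.u();
        double s = std::sqrt(1 - mu * mu);
        d[0] = s * std::cos(phi); d[1] = s * std::sin(phi); d[2] = mu;
      } else if (stype == 2) {
        d[0] = saxis[0]; d[1] = saxis[1]; d[2] = saxis[2];
      } else if (stype == 3) {
        double a = shx * (2 * rng.u() - 1), c = shy * (2 * rng.u() - 1);
        for (int q = 0; q < 3; ++q) p[q] += a * su[q] + c * sv[q];
        d[0] = saxis[0]; d[1] = saxis[1]; d[2] = saxis[2];
      } else {
        double a = shx * (2 * rng.u() - 1), c = shy * (2 * rng.u() - 1);
        double t[3];
        double n2 = 0;
        for (int q = 0; q < 3; ++q) {
          t[q] = ssid * saxis[q] + a * su[q] + c * sv[q];
          n2 += t[q] * t[q];
        }
        n2 = std::sqrt(n2);
        for (int q = 0; q < 3; ++q) d[q] = t[q] / n2;
      }
      double w = 1.0;
      emitted += E * w;

      bool logging = path_log_max > 0 && paths_done < path_log_max;
      if (logging) {
        cur_path.clear();
        cur_path.push_back(p[0]); cur_path.push_back(p[1]);
        cur_path.push_back(p[2]); cur_path.push_back(E);
      }

      if (!fine.inside(p)) {
        double te = box_entry(p, d, wlo, whi);
        if (te < 0) { escaped += E * w; continue; }
        for (int q = 0; q < 3; ++q) p[q] += (te + 1e-9) * d[q];
        if (!fine.inside(p)) { escaped += E * w; continue; }
      }

      bool alive = true;
      int ncoll = 0;
      double Ecache = -1;
      int ei = 0; double ew = 0;
      long guard = 0;
      while (alive) {
        if (E != Ecache) {
          tab.bracket(E, ei, ew);
          for (int m = 0; m < nmat; ++m) mu_at[m] = tab.mu_at(ei, ew, m);
          Ecache = E;
        }
        // --- Woodcock flight across macro cells
        bool collided = false;
        long cvox = -1;
        while (true) {
          if (++guard > 2000000L || !std::isfinite(p[0] + p[1] + p[2])) {
            ncorr++; corruptE += E * w; alive = false; break;
          }
          int ci = (int)((p[0] - fine.ox) / spacing) / macro;
          int cj = (int)((p[1] - fine.oy) / spacing) / macro;
          int ck = (int)((p[2] - fine.oz) / spacing) / macro;
          uint32_t msk = mask[ci + (long)mx * (cj + (long)my * ck)];
          double maj = 0;
          for (int m = 0; m < nmat; ++m)
            if (msk & (1u << m))
              if (mu_at[m] > maj) maj = mu_at[m];
          double clo[3] = {fine.ox + ci * macro * spacing,
                           fine.oy + cj * macro * spacing,
                           fine.oz + ck * macro * spacing};
          double chi[3] = {std::min(clo[0] + macro * spacing, whi[0]),
                           std::min(clo[1] + macro * spacing, whi[1]),
                           std::min(clo[2] + macro * spacing, whi[2])};
          double texit = box_exit(p, d, clo, chi);
          double t = (maj > 1e-300) ? -std::log(1.0 - rng.u()) / maj : 1e300;
          double step = std::min(t, texit + 1e-9);
          score_air(air, air_batch, p, d, step,
                    w * E * tab.muen_at(ei, ew) * 100.0);
          for (int q = 0; q < 3; ++q) p[q] += step * d[q];
          if (!fine.inside(p)) { escaped += E * w; alive = false; break; }
          if (t <= texit) {
            long v = fine.vox(p);
            if (v < 0) { escaped += E * w; alive = false; break; }
            int m = mi[v] - 1;
            if (rng.u() * maj < mu_at[m]) {
              collided = true; cvox = v; break;
            }
            nvirt += 1;
          }
        }
        if (!alive || !collided) break;
        nreal += 1;

        // --- interaction
        int m = mi[cvox] - 1;
        double fr = rng.u();
        double fph = tab.fph_at(ei, ew, m), fpi = tab.fpi_at(ei, ew, m);
        if (logging) {
          cur_path.push_back(p[0]); cur_path.push_back(p[1]);
          cur_path.push_back(p[2]); cur_path.push_back(E);
        }
        if (record_first_coll && ncoll == 0 &&
            (long)firstcol.size() < first_cap) {
          double dx = p[0] - spos[0], dy = p[1] - spos[1], dz = p[2] - spos[2];
          firstcol.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
        }
        if (fr < fph) {
          fine_batch[cvox] += E * w; deposited += E * w;
          if (roi[cvox] > 0) roi_batch(roi[cvox] - 1, b) += E * w;
          alive = false;
        } else if (fr < fpi) {
          double x;
          double mu = kn_sample(E / 510.99895, rng, x);
          double Ep = E / x;
          double dep = (E - Ep) * w;
          fine_batch[cvox] += dep; deposited += dep;
          if (roi[cvox] > 0) roi_batch(roi[cvox] - 1, b) += dep;
          rotate_dir(d, mu, 2 * M_PI * rng.u());
          if (Ep < cutoff) {
            fine_batch[cvox] += Ep * w; deposited += Ep * w;
            if (roi[cvox] > 0) roi_batch(roi[cvox] - 1, b) += Ep * w;
            alive = false;
          } else {
            E = Ep;
          }
        } else {
          rotate_dir(d, thomson_sample(rng), 2 * M_PI * rng.u());
        }
        if (++ncoll > 10000) {
          ncorr++; corruptE += E * w; alive = false;
        }
      }
      if (!alive && record_escapes && (long)escapes.size() / 8 < escape_cap) {
        // record only true escapes (photon left the world with energy)
      }
      if (record_escapes && !fine.inside(p) &&
          (long)escapes.size() / 8 < escape_cap) {
        escapes.push_back(p[0]); escapes.push_back(p[1]); escapes.push_back(p[2]);
        escapes.push_back(d[0]); escapes.push_back(d[1]); escapes.push_back(d[2]);
        escapes.push_back(E); escapes.push_back((double)ncoll);
      }
      if (logging) {
        cur_path.push_back(p[0]); cur_path.push_back(p[1]);
        cur_path.push_back(p[2]); cur_path.push_back(E);
        NumericMatrix pm(4, cur_path.size() / 4);
        std::copy(cur_path.begin(), cur_path.end(), pm.begin());
        paths.push_back(Rcpp::transpose(pm));
        paths_done++;
      }
    }
    for (long v = 0; v < nvox; ++v) {
      fine_sum[v] += fine_batch[v];
      fine_sumsq[v] += fine_batch[v] * fine_batch[v];
    }
    for (long v = 0; v < navox; ++v) {
      air_sum[v] += air_batch[v];
      air_sumsq[v] += air_batch[v] * air_batch[v];
    }
    ledger(b, 0) = emitted; ledger(b, 1) = deposited; ledger(b, 2) = escaped;
    ledger(b, 3) = corruptE; ledger(b, 4) = (double)ncorr;
    ledger(b, 5) = nvirt; ledger(b, 6) = nreal;
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix esc((int)(escapes.size() / 8), 8);
  for (int i = 0; i < esc.nrow(); ++i)
    for (int j = 0; j < 8; ++j) esc(i, j) = escapes[i * 8 + j];

  return List::create(
      _["fine_sum"] = NumericVector(fine_sum.begin(), fine_sum.end()),
      _["fine_sumsq"] = NumericVector(fine_sumsq.begin(), fine_sumsq.end()),
      _["air_sum"] = NumericVector(air_sum.begin(), air_sum.end()),
      _["air_sumsq"] = NumericVector(air_sumsq.begin(), air_sumsq.end()),
      _["roi_batch"] = roi_batch, _["ledger"] = ledger,
      _["escapes"] = esc,
      _["first_coll"] = NumericVector(firstcol.begin(), firstcol.end()),
      _["paths"] = paths);
}

// [[Rcpp::export]]
NumericMatrix kn_sample_cpp(double energy_keV, int n, double seed) {
  Rng rng(splitmix64((uint64_t)seed));
  NumericMatrix out(n, 2);
  double k = energy_keV / 510.99895;
  for (int i = 0; i < n; ++i) {
    double x;
    out(i, 0) = kn_sample(k, rng, x);
    out(i, 1) = energy_keV / x;
  }
  colnames(out) = CharacterVector::create("cos_theta", "energy_out_keV");
  return out;
}

// [[Rcpp::export]]
NumericVector thomson_sample_cpp(int n, double seed) {
  Rng rng(splitmix64((uint64_t)seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = thomson_sample(rng);
  return out;
}

// chord lengths of a segment through a regular grid (for the track-length
// estimator tests): returns (voxel linear index 1-based, chord length)
// [[Rcpp::export]]
NumericMatrix segment_chords_cpp(NumericVector p0, NumericVector p1,
                                 IntegerVector dims, NumericVector origin,
                                 double spacing) {
  Grid g{dims[0], dims[1], dims[2], origin[0], origin[1], origin[2], spacing};
  double d[3], L = 0;
  for (int a = 0; a < 3; ++a) { d[a] = p1[a] - p0[a]; L += d[a] * d[a]; }
  L = std::sqrt(L);
  if (L <= 0) return NumericMatrix(0, 2);
  for (int a = 0; a < 3; ++a) d[a] /= L;
  long nv = (long)g.nx * g.ny * g.nz;
  std::vector<double> tal(nv, 0.0);
  double p[3] = {p0[0], p0[1], p0[2]};
  score_air(g, tal, p, d, L, 1.0);
  std::vector<std::pair<long, double>> hits;
  for (long v = 0; v < nv; ++v)
    if (tal[v] > 0) hits.push_back({v + 1, tal[v]});
  NumericMatrix out(hits.size(), 2);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = (double)hits[i].first;
    out(i, 1) = hits[i].second;
  }
  colnames(out) = CharacterVector::create("voxel", "chord_m");
  return out;
}
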