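// Simplified analog photon Monte Carlo with kerma-approximation track-length
// tallies in spherical cells. Geometry: an axis-aligned box of a single
// material surrounded by vacuum; the source sits at the origin. Histories use
// counter-based per-history RNG substreams so results are reproducible and
// independent of batching.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct XRng {
  uint64_t s0, s1;
  void seed(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0x9E3779B97F4A7C15ULL * (stream + 0x632BE59BD9B4E019ULL));
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if (!(s0 | s1)) s1 = 0xDEADBEEFULL;
  }
  inline uint64_t next() {
    uint64_t a = s0, b = s1, r = a + b;
    b ^= a;
    s0 = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s1 = (b << 36) | (b >> 28);
    return r;
  }
  inline double u() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// log-log interpolation on an ascending grid (exact at nodes)
struct LogTable {
  std::vector<double> le, ly;
  void init(const NumericVector &e, const NumericVector &y, bool logy = true) {
    le.resize(e.size());
    ly.resize(e.size());
    for (int i = 0; i < e.size(); ++i) {
      le[i] = std::log(e[i]);
      ly[i] = logy ? std::log(y[i]) : y[i];
    }
  }
  inline double at(double energy, bool expy = true) const {
    double x = std::log(energy);
    size_t n = le.size();
    if (x <= le[0]) return expy ? std::exp(ly[0]) : ly[0];
    if (x >= le[n - 1]) return expy ? std::exp(ly[n - 1]) : ly[n - 1];
    size_t hi = std::upper_bound(le.begin(), le.end(), x) - le.begin();
    size_t lo = hi - 1;
    double w = (x - le[lo]) / (le[hi] - le[lo]);
    double v = ly[lo] + w * (ly[hi] - ly[lo]);
    return expy ? std::exp(v) : v;
  }
};

struct Mat {
  LogTable mu;    // linear attenuation, 1/cm (0 => vacuum world)
  LogTable muen;  // mass energy-absorption, cm^2/g
  LogTable fpe, fco;  // interaction fractions, linear in log E
  bool vacuum;
};

static double kn_total(double k) {
  // total free-electron Compton cross section (units of 2*pi*re^2)
  double t = std::log(1.0 + 2.0 * k);
  return (1.0 + k) / (k * k) * (2.0 * (1.0 + k) / (1.0 + 2.0 * k) - t / k) +
         t / (2.0 * k) - (1.0 + 3.0 * k) / ((1.0 + 2.0 * k) * (1.0 + 2.0 * k));
}

// Kahn's rejection sampling of the Klein-Nishina distribution.
// Returns R = E/E' and sets cost to the scattering angle cosine.
static inline double kahn_sample(double k, XRng &rng, double &cost) {
  double R;
  for (;;) {
    double r1 = rng.u(), r2 = rng.u(), r3 = rng.u();
    if (r1 <= (1.0 + 2.0 * k) / (9.0 + 2.0 * k)) {
      R = 1.0 + 2.0 * k * r2;
      if (r3 <= 4.0 * (1.0 / R - 1.0 / (R * R))) break;
    } else {
      R = (1.0 + 2.0 * k) / (1.0 + 2.0 * k * r2);
      double c = 1.0 - (R - 1.0) / k;
      if (r3 <= 0.5 * (c * c + 1.0 / R)) break;
    }
  }
  cost = 1.0 - (R - 1.0) / k;
  return R;
}

static inline void rotate_dir(double *d, double cost, double phi, XRng &rng) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double dx = d[0], dy = d[1], dz = d[2];
  double a = std::sqrt(std::max(0.0, 1.0 - dz * dz));
  if (a > 1e-10) {
    d[0] = cost * dx + sint * (dx * dz * cphi - dy * sphi) / a;
    d[1] = cost * dy + sint * (dy * dz * cphi + dx * sphi) / a;
    d[2] = cost * dz - sint * a * cphi;
  } else {
    double sgn = dz >= 0 ? 1.0 : -1.0;
    d[0] = sint * cphi;
    d[1] = sint * sphi;
    d[2] = sgn * cost;
  }
  double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= n; d[1] /= n; d[2] /= n;
  (void)rng;
}

static inline void iso_dir(XRng &rng, double *d) {
  double mu = 2.0 * rng.u() - 1.0;
  double phi = 2.0 * M_PI * rng.u();
  double s = std::sqrt(1.0 - mu * mu);
  d[0] = s * std::cos(phi);
  d[1] = s * std::sin(phi);
  d[2] = mu;
}

struct Source {
  double line_half;            // >0: uniform line along z
  std::vector<double> pellets; // else: active pellet z centers
  std::vector<double> spec_e, spec_cum;
  inline void emit(XRng &rng, double *p, double *d, double &E) const {
    p[0] = p[1] = 0.0;
    if (line_half > 0.0) {
      p[2] = (2.0 * rng.u() - 1.0) * line_half;
    } else if (!pellets.empty()) {
      p[2] = pellets[(size_t)(rng.u() * pellets.size()) % pellets.size()];
    } else {
      p[2] = 0.0;
    }
    iso_dir(rng, d);
    double u = rng.u();
    size_t i = 0;
    while (i + 1 < spec_cum.size() && u >= spec_cum[i]) ++i;
    E = spec_e[i];
  }
};

struct Cells {
  std::vector<double> cx, cy, cz, r2, rad;
  size_t n() const { return cx.size(); }
};

// score the chords of segment [p, p + len*d] through every cell
static inline void score_segment(const Cells &cells, const double *p,
                                 const double *d, double len, double w,
                                 double *acc, std::vector<double> &hits) {
  for (size_t i = 0; i < cells.n(); ++i) {
    double wx = cells.cx[i] - p[0], wy = cells.cy[i] - p[1],
           wz = cells.cz[i] - p[2];
    double tca = wx * d[0] + wy * d[1] + wz * d[2];
    double R = cells.rad[i];
    if (tca + R < 0.0 || tca - R > len) continue;
    double dd = wx * wx + wy * wy + wz * wz - tca * tca;
    double h2 = cells.r2[i] - dd;
    if (h2 <= 0.0) continue;
    double h = std::sqrt(h2);
    double t0 = tca - h, t1 = tca + h;
    if (t0 < 0.0) t0 = 0.0;
    if (t1 > len) t1 = len;
    if (t1 > t0) {
      acc[i] += w * (t1 - t0);
      hits[i] += 1.0;
    }
  }
}

static inline double dist_to_exit(const double *p, const double *d,
                                  const double *lo, const double *hi) {
  double t = 1e30;
  for (int a = 0; a < 3; ++a) {
    if (d[a] > 1e-12) {
      double s = (hi[a] - p[a]) / d[a];
      if (s < t) t = s;
    } else if (d[a] < -1e-12) {
      double s = (lo[a] - p[a]) / d[a];
      if (s < t) t = s;
    }
  }
  return t < 0.0 ? 0.0 : t;
}

static Mat make_mat(const List &material) {
  Mat m;
  NumericVector e = material["energy_MeV"];
  NumericVector mu = material["mu_lin"];
  NumericVector muen = material["muen_rho"];
  NumericVector fpe = material["f_pe"];
  NumericVector fco = material["f_compton"];
  m.vacuum = true;
  for (int i = 0; i < mu.size(); ++i)
    if (mu[i] > 0) m.vacuum = false;
  if (!m.vacuum) m.mu.init(e, mu);
  m.muen.init(e, muen);
  m.fpe.init(e, fpe, false);
  m.fco.init(e, fco, false);
  return m;
}

static Source make_source(const List &src) {
  Source s;
  s.line_half = as<double>(src["line_half"]);
  NumericVector pz = src["pellet_z"];
  for (int i = 0; i < pz.size(); ++i) s.pellets.push_back(pz[i]);
  NumericVector se = src["spec_e"], sp = src["spec_p"];
  double cum = 0.0;
  for (int i = 0; i < se.size(); ++i) {
    s.spec_e.push_back(se[i]);
    cum += sp[i];
    s.spec_cum.push_back(cum);
  }
  if (!s.spec_cum.empty()) s.spec_cum.back() = 1.0;
  return s;
}

// [[Rcpp::export]]
List cpp_transport(NumericMatrix cellMat, NumericVector cubeLo,
                   NumericVector cubeHi, List material, List src,
                   double nhist, double seed, double cutoff, bool rayleigh,
                   int nbatch) {
  Mat mat = make_mat(material);
  Source source = make_source(src);
  Cells cells;
  for (int i = 0; i < cellMat.nrow(); ++i) {
    cells.cx.push_back(cellMat(i, 0));
    cells.cy.push_back(cellMat(i, 1));
    cells.cz.push_back(cellMat(i, 2));
    cells.rad.push_back(cellMat(i, 3));
    cells.r2.push_back(cellMat(i, 3) * cellMat(i, 3));
  }
  double lo[3] = {cubeLo[0], cubeLo[1], cubeLo[2]};
  double hi[3] = {cubeHi[0], cubeHi[1], cubeHi[2]};
  size_t nc = cells.n();
  int64_t N = (int64_t)nhist;
  std::vector<double> batch((size_t)nbatch * nc, 0.0);
  std::vector<double> hits(nc, 0.0);
  XRng rng;
  const double ESCAPE_LEN = 1e4;

  for (int64_t h = 0; h < N; ++h) {
    if ((h & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    rng.seed((uint64_t)seed, (uint64_t)h);
    double p[3], d[3], E;
    source.emit(rng, p, d, E);
    int b = (int)((h * (int64_t)nbatch) / N);
    double *acc = &batch[(size_t)b * nc];
    for (int step = 0; step < 10000; ++step) {
      double w = E * mat.muen.at(E);
      if (mat.vacuum) {
        // vacuum world: one straight flight through everything
        score_segment(cells, p, d, ESCAPE_LEN, w, acc, hits);
        break;
      }
      double mu = mat.mu.at(E);
      double s = -std::log(1.0 - rng.u()) / mu;
      double tb = dist_to_exit(p, d, lo, hi);
      if (s >= tb) {
        // escapes through the face into vacuum: straight flight to infinity
        score_segment(cells, p, d, ESCAPE_LEN, w, acc, hits);
        break;
      }
      score_segment(cells, p, d, s, w, acc, hits);
      p[0] += d[0] * s; p[1] += d[1] * s; p[2] += d[2] * s;
      // choose channel; boundary deviates take the upper channel
      double fpe = mat.fpe.at(E, false), fco = mat.fco.at(E, false);
      double u = rng.u();
      if (u < fpe) break;  // photoelectric: local absorption (kerma scope)
      if (u < fpe + fco) { // Compton
        double k = E / 0.5109989;
        double cost;
        double R = kahn_sample(k, rng, cost);
        E /= R;
        rotate_dir(d, cost, 2.0 * M_PI * rng.u(), rng);
        if (E < cutoff) break;
      } else {             // Rayleigh
        if (!rayleigh) continue; // treated as no-op when disabled
        double cost;
        do { cost = 2.0 * rng.u() - 1.0; } while (rng.u() > 0.5 * (1.0 + cost * cost));
        rotate_dir(d, cost, 2.0 * M_PI * rng.u(), rng);
      }
      if (!std::isfinite(p[0] + p[1] + p[2] + E))
        stop("non-finite photon state at history %ld", (long)h);
    }
  }
  // fold batches -> mean and relative standard error per cell
  NumericVector total(nc), relErr(nc), hitCount(nc);
  for (size_t i = 0; i < nc; ++i) {
    double sum = 0.0;
    for (int b = 0; b < nbatch; ++b) sum += batch[(size_t)b * nc + i];
    total[i] = sum;
    double mean = sum / nbatch;
    double var = 0.0;
    for (int b = 0; b < nbatch; ++b) {
      double dlt = batch[(size_t)b * nc + i] - mean;
      var += dlt * dlt;
    }
    var /= (nbatch - 1.0);
    relErr[i] = (sum > 0.0) ? std::sqrt(var / nbatch) * nbatch / sum : NA_REAL;
    hitCount[i] = hits[i];
  }
  return List::create(_["score"] = total, _["rel_err"] = relErr,
                      _["hits"] = hitCount);
}

// [[Rcpp::export]]
NumericMatrix cpp_compton_sample(double energy, int n, double seed) {
  NumericMatrix out(n, 2);
  double k = energy / 0.5109989;
  XRng rng;
  for (int i = 0; i < n; ++i) {
    rng.seed((uint64_t)seed, (uint64_t)i);
    double cost;
    double R = kahn_sample(k, rng, cost);
    out(i, 0) = energy / R;
    out(i, 1) = cost;
  }
  colnames(out) = CharacterVector::create("energy_MeV", "cos_theta");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_emit(List src, int n, double seed) {
  Source source = make_source(src);
  NumericMatrix out(n, 7);
  XRng rng;
  for (int i = 0; i < n; ++i) {
    rng.seed((uint64_t)seed, (uint64_t)i);
    double p[3], d[3], E;
    source.emit(rng, p, d, E);
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
    out(i, 3) = d[0]; out(i, 4) = d[1]; out(i, 5) = d[2];
    out(i, 6) = E;
  }
  colnames(out) = CharacterVector::create("x", "y", "z", "ux", "uy", "uz",
                                          "energy_MeV");
  return out;
}
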