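// Euler-Maruyama cores for the toroidal-trap Brownian dynamics.
//
// All integration happens in the dimensionless variables of the model:
// length in units of sqrt(kBT/kappa_r), time in units of zeta0/kappa_r.
// The Jeffreys fluid enters through the Markovian embedding with auxiliary
// variables Q and the two Wiener increments per axis, one of which (dW1)
// is shared between the position equation and its paired Q equation.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// splitmix64: tiny, statistically solid, and fully portable across
// compilers (unlike std::normal_distribution, whose stream is
// implementation-defined). One independent stream per particle.
struct Rng {
  uint64_t s;
  double cached;
  bool has_cached;
  explicit Rng(uint64_t seed) : s(seed), cached(0.0), has_cached(false) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1]: never 0, so log() below is safe
  double unif() {
    return ((next_u64() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  // Box-Muller, cached pair
  double normal() {
    if (has_cached) { has_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    cached = r * std::sin(th);
    has_cached = true;
    return r * std::cos(th);
  }
};

uint64_t particle_seed(uint64_t master, int particle) {
  // decorrelate particle streams from the master seed
  uint64_t z = master + 0x9e3779b97f4a7c15ULL * (uint64_t)(particle + 1);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

const double kAxisGuard = 1e-12;  // dimensionless z-axis exclusion radius

}  // namespace

// Newtonian halo: dx = -(1 - R/rho) x dt + sqrt(2) dW, etc.
// [[Rcpp::export]]
List sim_halo_newtonian_cpp(double R_hat, double kz_over_kr,
                            NumericMatrix init_pos, double dt,
                            int n_burn, int n_steps, int stride,
                            double seed) {
  const int P = init_pos.nrow();
  const int n_save = n_steps / stride + 1;
  NumericMatrix X(n_save, P), Y(n_save, P), Z(n_save, P);
  const double sq = std::sqrt(2.0 * dt);
  const uint64_t master = (uint64_t)seed;

  for (int p = 0; p < P; ++p) {
    Rng rng(particle_seed(master, p));
    double x = init_pos(p, 0), y = init_pos(p, 1), z = init_pos(p, 2);
    for (int step = -n_burn; step <= n_steps; ++step) {
      if (step >= 0 && step % stride == 0) {
        int k = step / stride;
        X(k, p) = x; Y(k, p) = y; Z(k, p) = z;
      }
      if (step == n_steps) break;
      double rho = std::sqrt(x * x + y * y);
      if (rho < kAxisGuard)
        stop("particle %d reached the z-axis at step %d: the toroidal force "
             "direction is undefined there (check R_hat and dt_hat)", p + 1, step);
      double fr = 1.0 - R_hat / rho;
      x += -fr * x * dt + sq * rng.normal();
      y += -fr * y * dt + sq * rng.normal();
      z += -kz_over_kr * z * dt + sq * rng.normal();
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["z"] = Z);
}

// Jeffreys halo via Markovian embedding; q = kappa_star/kappa_r, De > 0.
// Noise amplitudes sqrt(2/(De+1)), sqrt(2 De/(De+1)) on positions and
// sqrt(2 (De+1)/De) on Q, with dW1 shared between the pair.
// [[Rcpp::export]]
List sim_halo_jeffreys_cpp(double R_hat, double kz_over_kr, double q,
                           double De, NumericMatrix init_pos,
                           NumericMatrix init_q, double dt,
                           int n_burn, int n_steps, int stride,
                           double seed, bool save_q) {
  const int P = init_pos.nrow();
  const int n_save = n_steps / stride + 1;
  NumericMatrix X(n_save, P), Y(n_save, P), Z(n_save, P);
  NumericMatrix QX, QY, QZ;
  if (save_q) {
    QX = NumericMatrix(n_save, P);
    QY = NumericMatrix(n_save, P);
    QZ = NumericMatrix(n_save, P);
  }
  const double s0 = std::sqrt(2.0 * dt / (De + 1.0));
  const double s1 = std::sqrt(2.0 * dt * De / (De + 1.0));
  const double sQ = std::sqrt(2.0 * dt * (De + 1.0) / De);
  const double qq = q * (De + 1.0) / De;  // Q relaxation coefficient
  const uint64_t master = (uint64_t)seed;

  for (int p = 0; p < P; ++p) {
    Rng rng(particle_seed(master, p));
    double x = init_pos(p, 0), y = init_pos(p, 1), z = init_pos(p, 2);
    double qx = init_q(p, 0), qy = init_q(p, 1), qz = init_q(p, 2);
    for (int step = -n_burn; step <= n_steps; ++step) {
      if (step >= 0 && step % stride == 0) {
        int k = step / stride;
        X(k, p) = x; Y(k, p) = y; Z(k, p) = z;
        if (save_q) { QX(k, p) = qx; QY(k, p) = qy; QZ(k, p) = qz; }
      }
      if (step == n_steps) break;
      double rho = std::sqrt(x * x + y * y);
      if (rho < kAxisGuard)
        stop("particle %d reached the z-axis at step %d: the toroidal force "
             "direction is undefined there (check R_hat and dt_hat)", p + 1, step);
      double fr = 1.0 - R_hat / rho;
      double fx = fr * x, fy = fr * y, fz = kz_over_kr * z;
      double w0x = rng.normal(), w1x = rng.normal();
      double w0y = rng.normal(), w1y = rng.normal();
      double w0z = rng.normal(), w1z = rng.normal();
      double nx = x + (-(fx + q * qx)) * dt + s0 * w0x + s1 * w1x;
      double ny = y + (-(fy + q * qy)) * dt + s0 * w0y + s1 * w1y;
      double nz = z + (-(fz + q * qz)) * dt + s0 * w0z + s1 * w1z;
      double nqx = qx + (-(fx + qq * qx)) * dt + sQ * w1x;
      double nqy = qy + (-(fy + qq * qy)) * dt + sQ * w1y;
      double nqz = qz + (-(fz + qq * qz)) * dt + sQ * w1z;
      x = nx; y = ny; z = nz; qx = nqx; qy = nqy; qz = nqz;
    }
  }
  List out = List::create(_["x"] = X, _["y"] = Y, _["z"] = Z);
  if (save_q) {
    out["qx"] = QX; out["qy"] = QY; out["qz"] = QZ;
  }
  return out;
}

// 1D Ornstein-Uhlenbeck reference channel (same stepping and RNG machinery
// as the halo cores): dx = -k x dt + sqrt(2) dW.
// [[Rcpp::export]]
NumericMatrix sim_ou_1d_cpp(double k_hat, NumericVector init_x, double dt,
                            int n_burn, int n_steps, int stride, double seed) {
  const int P = init_x.size();
  const int n_save = n_steps / stride + 1;
  NumericMatrix X(n_save, P);
  const double sq = std::sqrt(2.0 * dt);
  const uint64_t master = (uint64_t)seed;
  for (int p = 0; p < P; ++p) {
    Rng rng(particle_seed(master, p));
    double x = init_x[p];
    for (int step = -n_burn; step <= n_steps; ++step) {
      if (step >= 0 && step % stride == 0) X(step / stride, p) = x;
      if (step == n_steps) break;
      x += -k_hat * x * dt + sq * rng.normal();
    }
  }
  return X;
}

// Batched pair-averaged statistics on a (time x particle) matrix:
// per-particle means of (x_{t+l} - x_t)^2 (squared displacements) or
// x_t * x_{t+l} (lagged products), each lag optionally on a decimated
// series (multi-tau estimator; lags[i] must be a multiple of decim[i]).
// [[Rcpp::export]]
List pair_stats_cpp(NumericMatrix M, IntegerVector lags, IntegerVector decim,
                    bool products) {
  const int n = M.nrow(), P = M.ncol(), L = lags.size();
  NumericMatrix pp(L, P);
  NumericVector npairs(L);
  for (int i = 0; i < L; ++i) {
    const int d = decim[i];
    if (lags[i] % d != 0)
      stop("lag %d is not a multiple of its decimation factor %d", lags[i], d);
    const int l = lags[i] / d;
    const int m = (n - 1) / d + 1;
    if (l >= m) stop("lag %d beyond series length", lags[i]);
    const int cnt = (l == 0) ? m : m - l;
    npairs[i] = (double)cnt * P;
    for (int p = 0; p < P; ++p) {
      const double* col = &M(0, p);
      double acc = 0.0;
      if (l == 0) {
        for (int j = 0; j < m; ++j) {
          double a = col[(R_xlen_t)j * d];
          acc += products ? a * a : 0.0;
        }
      } else {
        for (int j = 0; j < cnt; ++j) {
          double a = col[(R_xlen_t)j * d];
          double b = col[(R_xlen_t)(j + l) * d];
          acc += products ? a * b : (b - a) * (b - a);
        }
      }
      pp(i, p) = acc / cnt;
    }
  }
  return List::create(_["pp"] = pp, _["n_pairs"] = npairs);
}
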