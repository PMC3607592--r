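#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Analytic potential: per-dimension harmonic term plus a sum of negative
// Gaussian wells. U(x) = sum_j 0.5*hk_j*(x_j-hx0_j)^2
//                        - sum_i A_i * exp(-sum_j (x_j-c_ij)^2/(2 s_ij^2))
struct Potential {
  int d;
  std::vector<double> hk, hx0;
  int m;
  std::vector<double> centers;  // m*d, row-major (well-major)
  std::vector<double> depths;   // m
  std::vector<double> sigmas;   // m*d
  double wall_k;
  std::vector<double> wall_lo, wall_hi;

  explicit Potential(const List& spec) {
    d = as<int>(spec["d"]);
    hk = as<std::vector<double>>(spec["hk"]);
    hx0 = as<std::vector<double>>(spec["hx0"]);
    wall_k = as<double>(spec["wall_k"]);
    wall_lo = as<std::vector<double>>(spec["wall_lo"]);
    wall_hi = as<std::vector<double>>(spec["wall_hi"]);
    NumericMatrix c = spec["centers"], s = spec["sigmas"];
    depths = as<std::vector<double>>(spec["depths"]);
    m = depths.size();
    centers.resize(m * d);
    sigmas.resize(m * d);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < d; ++j) {
        centers[i * d + j] = c(i, j);
        sigmas[i * d + j] = s(i, j);
      }
  }

  double value(const double* x) const {
    double u = 0.0;
    for (int j = 0; j < d; ++j) {
      double dx = x[j] - hx0[j];
      u += 0.5 * hk[j] * dx * dx;
    }
    for (int i = 0; i < m; ++i) {
      double e = 0.0;
      for (int j = 0; j < d; ++j) {
        double dx = x[j] - centers[i * d + j];
        double s = sigmas[i * d + j];
        e += dx * dx / (2.0 * s * s);
      }
      u -= depths[i] * std::exp(-e);
    }
    if (wall_k > 0.0)
      for (int j = 0; j < d; ++j) {
        if (x[j] < wall_lo[j]) {
          double dx = x[j] - wall_lo[j];
          u += 0.5 * wall_k * dx * dx;
        } else if (x[j] > wall_hi[j]) {
          double dx = x[j] - wall_hi[j];
          u += 0.5 * wall_k * dx * dx;
        }
      }
    return u;
  }

  void gradient(const double* x, double* g) const {
    for (int j = 0; j < d; ++j) g[j] = hk[j] * (x[j] - hx0[j]);
    for (int i = 0; i < m; ++i) {
      double e = 0.0;
      for (int j = 0; j < d; ++j) {
        double dx = x[j] - centers[i * d + j];
        double s = sigmas[i * d + j];
        e += dx * dx / (2.0 * s * s);
      }
      double w = depths[i] * std::exp(-e);
      for (int j = 0; j < d; ++j) {
        double dx = x[j] - centers[i * d + j];
        double s = sigmas[i * d + j];
        g[j] += w * dx / (s * s);
      }
    }
    if (wall_k > 0.0)
      for (int j = 0; j < d; ++j) {
        if (x[j] < wall_lo[j]) g[j] += wall_k * (x[j] - wall_lo[j]);
        else if (x[j] > wall_hi[j]) g[j] += wall_k * (x[j] - wall_hi[j]);
      }
  }
};

// [[Rcpp::export]]
NumericVector cpp_potential_value(List spec, NumericMatrix x) {
  Potential pot(spec);
  int n = x.nrow();
  NumericVector out(n);
  std::vector<double> xi(pot.d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < pot.d; ++j) xi[j] = x(i, j);
    out[i] = pot.value(xi.data());
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_potential_gradient(List spec, NumericMatrix x) {
  Potential pot(spec);
  int n = x.nrow();
  NumericMatrix out(n, pot.d);
  std::vector<double> xi(pot.d), g(pot.d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < pot.d; ++j) xi[j] = x(i, j);
    pot.gradient(xi.data(), g.data());
    for (int j = 0; j < pot.d; ++j) out(i, j) = g[j];
  }
  return out;
}

// Overdamped (Brownian) integrator:
//   x <- x - (D/kT) * grad(U + V_bias) * dt + sqrt(2 D dt) * xi
// with an optional static harmonic umbrella bias. Uses R's RNG so runs
// are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_langevin(List spec, NumericVector x0, double dt, int n_steps,
                  double kT, double D, int save_stride,
                  NumericVector bias_center, double bias_k,
                  double guard) {
  Potential pot(spec);
  int d = pot.d;
  int n_save = n_steps / save_stride;
  NumericMatrix out(n_save, d);
  std::vector<double> x(x0.begin(), x0.end()), g(d);
  double pref = D / kT * dt;
  double noise = std::sqrt(2.0 * D * dt);
  bool has_bias = bias_center.size() == d && bias_k > 0.0;
  int isave = 0;
  for (int step = 1; step <= n_steps; ++step) {
    pot.gradient(x.data(), g.data());
    if (has_bias)
      for (int j = 0; j < d; ++j) g[j] += bias_k * (x[j] - bias_center[j]);
    for (int j = 0; j < d; ++j) {
      x[j] += -pref * g[j] + noise * norm_rand();
      if (!std::isfinite(x[j]) || std::fabs(x[j]) > guard)
        return List::create(_["ok"] = false, _["step"] = step);
    }
    if (step % save_stride == 0) {
      for (int j = 0; j < d; ++j) out(isave, j) = x[j];
      ++isave;
    }
  }
  return List::create(_["ok"] = true, _["positions"] = out);
}

// Bias grid: multilinear accumulation of hill values and analytic
// gradients on a regular grid, so the per-step force lookup is O(2^d)
// instead of O(n_hills).
struct BiasGrid {
  int d;
  std::vector<double> lo, hi, dx;
  std::vector<int> n, strides;
  long total;
  std::vector<double> V;
  std::vector<std::vector<double>> G;

  BiasGrid(NumericVector lo_, NumericVector hi_, IntegerVector n_) {
    d = lo_.size();
    lo.assign(lo_.begin(), lo_.end());
    hi.assign(hi_.begin(), hi_.end());
    n.assign(n_.begin(), n_.end());
    dx.resize(d);
    strides.resize(d);
    total = 1;
    for (int j = 0; j < d; ++j) {
      dx[j] = (hi[j] - lo[j]) / (n[j] - 1);
      strides[j] = total;
      total *= n[j];
    }
    V.assign(total, 0.0);
    G.assign(d, std::vector<double>(total, 0.0));
  }

  void add_hill(const double* c, const double* sig, double h) {
    // update grid nodes within 5 sigma per dimension (hill truncation)
    std::vector<int> i0(d), i1(d), idx(d);
    for (int j = 0; j < d; ++j) {
      int a = (int)std::floor((c[j] - 5.0 * sig[j] - lo[j]) / dx[j]);
      int b = (int)std::ceil((c[j] + 5.0 * sig[j] - lo[j]) / dx[j]);
      i0[j] = std::max(a, 0);
      i1[j] = std::min(b, n[j] - 1);
      if (i0[j] > i1[j]) return;
      idx[j] = i0[j];
    }
    while (true) {
      long flat = 0;
      double e = 0.0;
      for (int j = 0; j < d; ++j) {
        flat += (long)idx[j] * strides[j];
        double dxy = lo[j] + idx[j] * dx[j] - c[j];
        e += dxy * dxy / (2.0 * sig[j] * sig[j]);
      }
      if (e < 12.5) {  // 5 sigma in total exponent
        double w = h * std::exp(-e);
        V[flat] += w;
        for (int j = 0; j < d; ++j) {
          double dxy = lo[j] + idx[j] * dx[j] - c[j];
          G[j][flat] += -w * dxy / (sig[j] * sig[j]);
        }
      }
      int j = 0;
      while (j < d && ++idx[j] > i1[j]) { idx[j] = i0[j]; ++j; }
      if (j == d) break;
    }
  }

  void force_interp(const double* x, double* g) const {
    // multilinear interpolation of the gradient grids; flat (zero
    // gradient) outside the grid
    std::vector<int> base(d);
    std::vector<double> frac(d);
    for (int j = 0; j < d; ++j) {
      double t = (x[j] - lo[j]) / dx[j];
      if (t <= 0.0) { base[j] = 0; frac[j] = 0.0; }
      else if (t >= n[j] - 1) { base[j] = n[j] - 2; frac[j] = 1.0; }
      else { base[j] = (int)t; frac[j] = t - base[j]; }
    }
    for (int j = 0; j < d; ++j) g[j] = 0.0;
    int corners = 1 << d;
    for (int cbit = 0; cbit < corners; ++cbit) {
      double w = 1.0;
      long flat = 0;
      for (int j = 0; j < d; ++j) {
        int b = (cbit >> j) & 1;
        w *= b ? frac[j] : 1.0 - frac[j];
        flat += (long)(base[j] + b) * strides[j];
      }
      if (w == 0.0) continue;
      for (int j = 0; j < d; ++j) g[j] += w * G[j][flat];
    }
  }
};

// Metadynamics: Langevin dynamics under U + V(s,t), depositing a
// Gaussian hill at the current position every `stride` steps of the
// active phase with that phase's height. Identity CV map (the sampled
// coordinates are the CVs). Optional pre-existing hills seed the bias
// (static hill-ledger bias when all phase durations are zero).
// [[Rcpp::export]]
List cpp_metadynamics(List spec, NumericVector x0, double dt, int n_steps,
                      double kT, double D, int save_stride,
                      NumericVector sigma, NumericVector phase_heights,
                      IntegerVector phase_strides,
                      IntegerVector phase_steps, NumericVector grid_lo,
                      NumericVector grid_hi, IntegerVector grid_n,
                      NumericMatrix init_hills, double guard) {
  Potential pot(spec);
  int d = pot.d;
  BiasGrid grid(grid_lo, grid_hi, grid_n);

  for (int i = 0; i < init_hills.nrow(); ++i) {
    std::vector<double> c(d), s(d);
    for (int j = 0; j < d; ++j) {
      c[j] = init_hills(i, 1 + j);
      s[j] = init_hills(i, 1 + d + j);
    }
    grid.add_hill(c.data(), s.data(), init_hills(i, 1 + 2 * d));
  }

  int n_phases = phase_heights.size();
  long max_hills = 0;
  for (int p = 0; p < n_phases; ++p)
    max_hills += phase_steps[p] / phase_strides[p];
  NumericMatrix hills(max_hills, 2 + 2 * d);  // time, centers, sigmas, h

  int n_save = n_steps / save_stride;
  NumericMatrix out(n_save, d);
  std::vector<double> x(x0.begin(), x0.end()), g(d), gb(d);
  double pref = D / kT * dt;
  double noise = std::sqrt(2.0 * D * dt);

  int phase = 0, step_in_phase = 0, isave = 0;
  long n_hills = 0;
  while (phase < n_phases && phase_steps[phase] == 0) ++phase;

  for (int step = 1; step <= n_steps; ++step) {
    pot.gradient(x.data(), g.data());
    grid.force_interp(x.data(), gb.data());
    for (int j = 0; j < d; ++j) {
      x[j] += -pref * (g[j] + gb[j]) + noise * norm_rand();
      if (!std::isfinite(x[j]) || std::fabs(x[j]) > guard)
        return List::create(_["ok"] = false, _["step"] = step);
    }
    if (phase < n_phases) {
      ++step_in_phase;
      if (step_in_phase % phase_strides[phase] == 0) {
        grid.add_hill(x.data(), sigma.begin(), phase_heights[phase]);
        hills(n_hills, 0) = step * dt;
        for (int j = 0; j < d; ++j) {
          hills(n_hills, 1 + j) = x[j];
          hills(n_hills, 1 + d + j) = sigma[j];
        }
        hills(n_hills, 1 + 2 * d) = phase_heights[phase];
        ++n_hills;
      }
      if (step_in_phase >= phase_steps[phase]) {
        step_in_phase = 0;
        ++phase;
        while (phase < n_phases && phase_steps[phase] == 0) ++phase;
      }
    }
    if (step % save_stride == 0) {
      for (int j = 0; j < d; ++j) out(isave, j) = x[j];
      ++isave;
    }
  }
  return List::create(_["ok"] = true, _["positions"] = out,
                      _["hills"] = hills, _["n_hills"] = (double)n_hills);
}

// Direct evaluation of a hill ledger on a set of points at time t:
// V(s,t) = sum_{hills with t_dep <= t} h * exp(-sum_d (s_d-c_d)^2/(2 s_d^2)),
// hills truncated beyond 5 sigma per dimension.
// [[Rcpp::export]]
NumericVector cpp_bias_at(NumericMatrix hills, int d, NumericMatrix pts,
                          double t) {
  int np = pts.nrow();
  NumericVector out(np);
  for (int i = 0; i < hills.nrow(); ++i) {
    if (hills(i, 0) > t) continue;
    double h = hills(i, 1 + 2 * d);
    for (int p = 0; p < np; ++p) {
      double e = 0.0;
      bool trunc = false;
      for (int j = 0; j < d; ++j) {
        double dx = pts(p, j) - hills(i, 1 + j);
        double s = hills(i, 1 + d + j);
        if (std::fabs(dx) > 5.0 * s) { trunc = true; break; }
        e += dx * dx / (2.0 * s * s);
      }
      if (!trunc) out[p] += h * std::exp(-e);
    }
  }
  return out;
}

// Snapshot -V on a set of grid points at several checkpoint times
// (used for ripple-damped, time-averaged FES estimates). Checkpoints
// must be sorted ascending; hills must be in deposition order.
// [[Rcpp::export]]
NumericMatrix cpp_bias_snapshots(NumericMatrix hills, int d,
                                 NumericMatrix pts,
                                 NumericVector checkpoints) {
  int np = pts.nrow(), nc = checkpoints.size();
  NumericMatrix out(np, nc);
  std::vector<double> v(np, 0.0);
  int ih = 0, nh = hills.nrow();
  for (int c = 0; c < nc; ++c) {
    while (ih < nh && hills(ih, 0) <= checkpoints[c]) {
      double h = hills(ih, 1 + 2 * d);
      for (int p = 0; p < np; ++p) {
        double e = 0.0;
        bool trunc = false;
        for (int j = 0; j < d; ++j) {
          double dx = pts(p, j) - hills(ih, 1 + j);
          double s = hills(ih, 1 + d + j);
          if (std::fabs(dx) > 5.0 * s) { trunc = true; break; }
          e += dx * dx / (2.0 * s * s);
        }
        if (!trunc) v[p] += h * std::exp(-e);
      }
      ++ih;
    }
    for (int p = 0; p < np; ++p) out(p, c) = v[p];
  }
  return out;
}
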