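// Overdamped Langevin dynamics on toy potentials with optional OPES biasing.
// The CV map may include a small feed-forward network (the Deep-LDA CV);
// its forward/gradient here mirrors the R implementation exactly and is
// cross-checked in the test suite.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static const double SQRT2PI = 2.5066282746310002;

// ---------------------------------------------------------------- network --
struct Net {
  std::vector<std::vector<double>> W;  // row-major, rows = out
  std::vector<int> nrow, ncol;
  std::vector<std::vector<double>> b;
  std::vector<double> w, center, scale;
  double a = 1.0, b2 = 0.0;
  int act = 1;
  bool active = false;

  void load(const List& net) {
    List Wl = net["W"], bl = net["b"];
    for (int l = 0; l < Wl.size(); ++l) {
      NumericMatrix Wm = Wl[l];
      nrow.push_back(Wm.nrow());
      ncol.push_back(Wm.ncol());
      std::vector<double> wv(Wm.nrow() * Wm.ncol());
      for (int i = 0; i < Wm.nrow(); ++i)
        for (int j = 0; j < Wm.ncol(); ++j)
          wv[i * Wm.ncol() + j] = Wm(i, j);
      W.push_back(wv);
      b.push_back(as<std::vector<double>>(bl[l]));
    }
    w = as<std::vector<double>>(net["w"]);
    center = as<std::vector<double>>(net["center"]);
    scale = as<std::vector<double>>(net["scale"]);
    a = as<double>(net["a"]);
    b2 = as<double>(net["b2"]);
    act = as<int>(net["act"]);
    active = true;
  }

  inline double actf(double z) const {
    if (act == 0) return z;
    if (act == 1) return z > 0 ? z : 0.0;
    if (act == 3) return z > 0 ? z : std::expm1(z);
    return std::tanh(z);
  }
  inline double actg(double z) const {
    if (act == 0) return 1.0;
    if (act == 1) return z > 0 ? 1.0 : 0.0;
    if (act == 3) return z > 0 ? 1.0 : std::exp(z);
    double t = std::tanh(z);
    return 1.0 - t * t;
  }

  // s_w and (optionally) its gradient wrt the raw input x
  double sw(const double* x, double* grad_out) const {
    size_t L = W.size();
    std::vector<std::vector<double>> as_(L + 1), zs(L);
    as_[0].resize(center.size());
    for (size_t j = 0; j < center.size(); ++j)
      as_[0][j] = (x[j] - center[j]) / scale[j];
    for (size_t l = 0; l < L; ++l) {
      int nr = nrow[l], nc = ncol[l];
      zs[l].resize(nr);
      as_[l + 1].resize(nr);
      for (int i = 0; i < nr; ++i) {
        double z = b[l][i];
        for (int j = 0; j < nc; ++j) z += W[l][i * nc + j] * as_[l][j];
        zs[l][i] = z;
        as_[l + 1][i] = actf(z);
      }
    }
    double s = 0.0;
    for (size_t i = 0; i < w.size(); ++i) s += w[i] * as_[L][i];
    double sp = a * s + b2;
    double swv = sp + sp * sp * sp;
    if (grad_out) {
      std::vector<double> delta(w.size());
      for (size_t i = 0; i < w.size(); ++i) delta[i] = w[i] * actg(zs[L - 1][i]);
      for (size_t l = L; l-- > 1;) {
        int nr = nrow[l], nc = ncol[l];
        std::vector<double> nd(nc, 0.0);
        for (int j = 0; j < nc; ++j) {
          double v = 0.0;
          for (int i = 0; i < nr; ++i) v += delta[i] * W[l][i * nc + j];
          nd[j] = v * actg(zs[l - 1][j]);
        }
        delta.swap(nd);
      }
      double chain = a * (1.0 + 3.0 * sp * sp);
      int nr0 = nrow[0], nc0 = ncol[0];
      for (int j = 0; j < nc0; ++j) {
        double v = 0.0;
        for (int i = 0; i < nr0; ++i) v += delta[i] * W[0][i * nc0 + j];
        grad_out[j] = chain * v / scale[j];
      }
    }
    return swv;
  }
};

// --------------------------------------------------------------- potential --
struct Potential {
  int type;  // 0 toy landscape (z,q), 1 harmonic
  std::vector<double> p;
  int dim;

  double grad(const double* x, double* g) const {
    if (type == 0) {
      double eps = p[0], kap = p[1], qB = p[2], qU = p[3], al = p[4];
      double z = x[0], q = x[1];
      double th = std::tanh(al * z);
      double qb = qB + (qU - qB) * (1.0 + th) / 2.0;
      double dqb = (qU - qB) / 2.0 * al * (1.0 - th * th);
      double dz2 = z * z - 1.0;
      g[0] = 4.0 * eps * z * dz2 - kap * (q - qb) * dqb;
      g[1] = kap * (q - qb);
      return eps * dz2 * dz2 + 0.5 * kap * (q - qb) * (q - qb);
    }
    double u = 0.0;
    for (int i = 0; i < dim; ++i) {
      double d = x[i] - p[dim + i];
      g[i] = p[i] * d;
      u += 0.5 * p[i] * d * d;
    }
    return u;
  }
};

// -------------------------------------------------------------------- OPES --
struct Opes {
  int d = 1;
  std::vector<double> c, s, h;  // centers, sigmas (K*d), heights (K)
  std::vector<double> Sc;       // unnormalized prob estimate at each center
  double sum_w = 0.0, sum_w2 = 0.0, Z = 1.0;
  int n_dep = 0;
  double gamma = 10.0, dE = 6.0, kBT = 0.596, thresh = 1.0;
  std::vector<double> sigma0;
  bool adaptive = false, active = false, do_shrink = true;

  inline double pref() const { return (1.0 - 1.0 / gamma) * kBT; }
  inline double epsreg() const { return std::exp(-dE / pref()); }

  size_t K() const { return h.size(); }

  // weighted KDE estimate and its gradient at point sv
  double prob(const double* sv, double* dp) const {
    double p = 0.0;
    if (dp) for (int j = 0; j < d; ++j) dp[j] = 0.0;
    for (size_t k = 0; k < K(); ++k) {
      double e = 0.0, norm = h[k];
      for (int j = 0; j < d; ++j) {
        double sg = s[k * d + j];
        double zz = (sv[j] - c[k * d + j]) / sg;
        e += zz * zz;
        norm /= (sg * SQRT2PI);
      }
      if (e > 120.0) continue;  // beyond ~11 bandwidths: < 1e-26 relative
      double g = norm * std::exp(-0.5 * e);
      p += g;
      if (dp)
        for (int j = 0; j < d; ++j) {
          double sg = s[k * d + j];
          dp[j] += g * (-(sv[j] - c[k * d + j]) / (sg * sg));
        }
    }
    p /= sum_w;
    if (dp) for (int j = 0; j < d; ++j) dp[j] /= sum_w;
    return p;
  }

  double bias(const double* sv, double* dV) const {
    if (K() == 0) {
      if (dV) for (int j = 0; j < d; ++j) dV[j] = 0.0;
      return 0.0;
    }
    std::vector<double> dp(dV ? d : 0);
    double p = prob(sv, dV ? dp.data() : nullptr);
    double eps = epsreg();
    double arg = p / Z + eps;
    double V = pref() * std::log(arg);
    if (dV)
      for (int j = 0; j < d; ++j) dV[j] = pref() * (dp[j] / Z) / arg;
    return V;
  }

  // unnormalized contribution of kernel j at a point
  inline double kern_val(size_t j, const double* sv) const {
    double e = 0.0, norm = h[j];
    for (int jj = 0; jj < d; ++jj) {
      double sg = s[j * d + jj];
      double zz = (sv[jj] - c[j * d + jj]) / sg;
      e += zz * zz;
      norm /= (sg * SQRT2PI);
    }
    if (e > 120.0) return 0.0;
    return norm * std::exp(-0.5 * e);
  }

  // Z = mean over kernel centers of the prob estimate; Sc is maintained
  // incrementally (exactly) as kernels are inserted or merged
  void refresh_Z() {
    if (K() == 0) { Z = 1.0; return; }
    double acc = 0.0;
    for (size_t k = 0; k < K(); ++k) acc += Sc[k];
    Z = acc / (double)K() / sum_w;
  }

  void deposit(const double* sv) {
    double V = bias(sv, nullptr);
    double w = std::exp(V / kBT);
    sum_w += w;
    sum_w2 += w * w;
    n_dep += 1;
    double n_eff = sum_w * sum_w / sum_w2;
    std::vector<double> sig(d);
    double shrink = do_shrink
        ? std::pow(n_eff * (d + 2.0) / 4.0, -1.0 / (d + 4.0))
        : 1.0;
    for (int j = 0; j < d; ++j) sig[j] = sigma0[j] * shrink;
    // nearest kernel in bandwidth-scaled distance
    int kmin = -1;
    double dmin = 1e300;
    for (size_t k = 0; k < K(); ++k) {
      double e = 0.0;
      for (int j = 0; j < d; ++j) {
        double zz = (sv[j] - c[k * d + j]) / s[k * d + j];
        e += zz * zz;
      }
      if (e < dmin) { dmin = e; kmin = (int)k; }
    }
    if (kmin >= 0 && std::sqrt(dmin) < thresh) {
      // remove the old kernel's contribution from every stored center value
      for (size_t k = 0; k < K(); ++k) Sc[k] -= kern_val(kmin, &c[k * d]);
      double h1 = h[kmin], hs = h1 + w;
      for (int j = 0; j < d; ++j) {
        double c1 = c[kmin * d + j], s1 = s[kmin * d + j];
        double cm = (h1 * c1 + w * sv[j]) / hs;
        double s2 = (h1 * (s1 * s1 + c1 * c1) + w * (sig[j] * sig[j] + sv[j] * sv[j])) / hs
                    - cm * cm;
        c[kmin * d + j] = cm;
        s[kmin * d + j] = std::sqrt(std::max(s2, 1e-300));
      }
      h[kmin] = hs;
      // add the merged kernel back, then refresh its own center value fully
      for (size_t k = 0; k < K(); ++k)
        if ((int)k != kmin) Sc[k] += kern_val(kmin, &c[k * d]);
      double acc = 0.0;
      for (size_t j = 0; j < K(); ++j) acc += kern_val(j, &c[kmin * d]);
      Sc[kmin] = acc;
    } else {
      for (int j = 0; j < d; ++j) { c.push_back(sv[j]); s.push_back(sig[j]); }
      h.push_back(w);
      size_t knew = K() - 1;
      for (size_t k = 0; k < knew; ++k) Sc[k] += kern_val(knew, &c[k * d]);
      double acc = 0.0;
      for (size_t j = 0; j < K(); ++j) acc += kern_val(j, &c[knew * d]);
      Sc.push_back(acc);
    }
    refresh_Z();
  }
};

// ---------------------------------------------------------------- CV maps --
struct CvMap {
  int mode = 1;  // 1: x[0]; 2: identity; 3: (net s_w, x[0])
  int dim = 1, ncv = 1;
  const Net* net = nullptr;

  // fill cv values; grads (ncv x dim, row-major) optional
  void eval(const double* x, double* sv, double* grads) const {
    if (mode == 1) {
      sv[0] = x[0];
      if (grads) {
        for (int j = 0; j < dim; ++j) grads[j] = 0.0;
        grads[0] = 1.0;
      }
    } else if (mode == 2) {
      for (int i = 0; i < dim; ++i) sv[i] = x[i];
      if (grads) {
        for (int i = 0; i < ncv * dim; ++i) grads[i] = 0.0;
        for (int i = 0; i < dim; ++i) grads[i * dim + i] = 1.0;
      }
    } else {
      sv[0] = net->sw(x, grads ? grads : nullptr);
      sv[1] = x[0];
      if (grads) {
        for (int j = 0; j < dim; ++j) grads[dim + j] = 0.0;
        grads[dim + 0] = 1.0;
      }
    }
  }
};

// -------------------------------------------------------------- main loop --
// [[Rcpp::export]]
List cpp_langevin_run(int pot_type, NumericVector pot_params,
                      NumericVector start, double kBT, double friction,
                      double dt, int n_steps, int seed, int log_stride,
                      int cv_mode, Nullable<List> net, int bias_mode,
                      NumericMatrix kernels, NumericVector bias_params,
                      NumericVector opes_params, NumericVector wall,
                      double bound) {
  Potential pot{pot_type, as<std::vector<double>>(pot_params),
                (int)start.size()};
  int dim = start.size();

  Net network;
  if (net.isNotNull()) network.load(net.get());

  CvMap cvm;
  cvm.mode = cv_mode;
  cvm.dim = dim;
  cvm.ncv = (cv_mode == 2) ? dim : (cv_mode == 3 ? 2 : 1);
  cvm.net = &network;

  Opes opes;
  bool biased = bias_mode > 0;
  if (bias_mode == 1) {  // static kernel list
    opes.active = true;
    opes.d = cvm.ncv;
    opes.kBT = kBT;
    opes.gamma = bias_params[0];
    opes.dE = bias_params[1];
    opes.Z = bias_params[2];
    opes.sum_w = bias_params[3];
    int K = kernels.nrow();
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < opes.d; ++j) {
        opes.c.push_back(kernels(k, j));
        opes.s.push_back(kernels(k, opes.d + j));
      }
      opes.h.push_back(kernels(k, 2 * opes.d));
    }
  } else if (bias_mode == 2) {  // adaptive OPES
    opes.active = true;
    opes.adaptive = true;
    opes.d = cvm.ncv;
    opes.kBT = kBT;
    opes.gamma = opes_params[0];
    opes.dE = opes_params[1];
    opes.thresh = opes_params[3];
    opes.do_shrink = opes_params[4] > 0.5;
    for (int j = 0; j < opes.d; ++j) opes.sigma0.push_back(opes_params[5 + j]);
  }
  int stride = bias_mode == 2 ? (int)opes_params[2] : 0;

  double z_wall = wall[0], k_wall = wall[1];

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> x(start.begin(), start.end());
  std::vector<double> g(dim), sv(cvm.ncv), dV(cvm.ncv),
      cvg(cvm.ncv * dim);

  double mob = dt / friction;
  double noise = std::sqrt(2.0 * kBT * dt / friction);

  int n_log = n_steps / log_stride;
  int log_cols = 1 + dim + (biased ? cvm.ncv + 1 : 0);
  NumericMatrix log(n_log, log_cols);
  int row = 0;

  for (int step = 0; step < n_steps; ++step) {
    pot.grad(x.data(), g.data());
    if (biased && opes.K() > 0) {
      cvm.eval(x.data(), sv.data(), cvg.data());
      opes.bias(sv.data(), dV.data());
      for (int i = 0; i < cvm.ncv; ++i)
        for (int j = 0; j < dim; ++j) g[j] += dV[i] * cvg[i * dim + j];
    }
    if (std::isfinite(z_wall)) {
      double az = std::fabs(x[0]);
      if (az > z_wall) g[0] += k_wall * (az - z_wall) * (x[0] > 0 ? 1.0 : -1.0);
    }
    for (int j = 0; j < dim; ++j) {
      x[j] += -mob * g[j] + noise * gauss(rng);
      if (std::fabs(x[j]) > bound)
        stop("trajectory diverged at step %d (|coordinate %d| = %g > %g); "
             "reduce dt or check the bias",
             step + 1, j + 1, std::fabs(x[j]), bound);
    }
    bool do_log = ((step + 1) % log_stride) == 0;
    bool do_dep = opes.adaptive && ((step + 1) % stride) == 0;
    if (do_log || do_dep) {
      double V = 0.0;
      if (biased) {
        cvm.eval(x.data(), sv.data(), nullptr);
        V = opes.bias(sv.data(), nullptr);
      }
      if (do_log) {
        log(row, 0) = (step + 1) * dt;
        for (int j = 0; j < dim; ++j) log(row, 1 + j) = x[j];
        if (biased) {
          for (int i = 0; i < cvm.ncv; ++i) log(row, 1 + dim + i) = sv[i];
          log(row, 1 + dim + cvm.ncv) = V;
        }
        ++row;
      }
      if (do_dep) {
        for (int i = 0; i < cvm.ncv; ++i)
          if (!std::isfinite(sv[i]))
            stop("non-finite CV value at step %d", step + 1);
        opes.deposit(sv.data());
      }
    }
  }

  NumericMatrix kout(opes.K(), biased ? 2 * opes.d + 1 : 1);
  if (biased)
    for (size_t k = 0; k < opes.K(); ++k) {
      for (int j = 0; j < opes.d; ++j) {
        kout(k, j) = opes.c[k * opes.d + j];
        kout(k, opes.d + j) = opes.s[k * opes.d + j];
      }
      kout(k, 2 * opes.d) = opes.h[k];
    }

  return List::create(_["log"] = log,
                      _["final_state"] = NumericVector(x.begin(), x.end()),
                      _["kernels"] = kout, _["sum_w"] = opes.sum_w,
                      _["sum_w2"] = opes.sum_w2,
                      _["n_deposit"] = opes.n_dep, _["Z"] = opes.Z);
}

// Evaluate the OPES bias from an explicit kernel list (cross-check surface).
// [[Rcpp::export]]
NumericVector cpp_opes_eval(NumericMatrix kernels, int d, double gamma,
                            double dE, double kBT, double Z, double sum_w,
                            NumericMatrix points) {
  Opes opes;
  opes.d = d;
  opes.kBT = kBT;
  opes.gamma = gamma;
  opes.dE = dE;
  opes.Z = Z;
  opes.sum_w = sum_w;
  for (int k = 0; k < kernels.nrow(); ++k) {
    for (int j = 0; j < d; ++j) {
      opes.c.push_back(kernels(k, j));
      opes.s.push_back(kernels(k, d + j));
    }
    opes.h.push_back(kernels(k, 2 * d));
  }
  NumericVector out(points.nrow());
  std::vector<double> sv(d);
  for (int i = 0; i < points.nrow(); ++i) {
    for (int j = 0; j < d; ++j) sv[j] = points(i, j);
    out[i] = opes.bias(sv.data(), nullptr);
  }
  return out;
}

// Bias energy and gradient from an explicit kernel list (gradient
// cross-check surface).
// [[Rcpp::export]]
List cpp_opes_eval_grad(NumericMatrix kernels, int d, double gamma,
                        double dE, double kBT, double Z, double sum_w,
                        NumericMatrix points) {
  Opes opes;
  opes.d = d;
  opes.kBT = kBT;
  opes.gamma = gamma;
  opes.dE = dE;
  opes.Z = Z;
  opes.sum_w = sum_w;
  for (int k = 0; k < kernels.nrow(); ++k) {
    for (int j = 0; j < d; ++j) {
      opes.c.push_back(kernels(k, j));
      opes.s.push_back(kernels(k, d + j));
    }
    opes.h.push_back(kernels(k, 2 * d));
  }
  NumericVector out(points.nrow());
  NumericMatrix gr(points.nrow(), d);
  std::vector<double> sv(d), dV(d);
  for (int i = 0; i < points.nrow(); ++i) {
    for (int j = 0; j < d; ++j) sv[j] = points(i, j);
    out[i] = opes.bias(sv.data(), dV.data());
    for (int j = 0; j < d; ++j) gr(i, j) = dV[j];
  }
  return List::create(_["V"] = out, _["grad"] = gr);
}

// Feed a fixed sequence of CV points through the adaptive update logic
// (deterministic cross-check against the R implementation).
// [[Rcpp::export]]
List cpp_opes_deposit_seq(NumericMatrix points, NumericVector sigma0,
                          double gamma, double dE, double kBT,
                          double thresh, bool shrink) {
  int d = points.ncol();
  Opes opes;
  opes.do_shrink = shrink;
  opes.adaptive = true;
  opes.active = true;
  opes.d = d;
  opes.kBT = kBT;
  opes.gamma = gamma;
  opes.dE = dE;
  opes.thresh = thresh;
  opes.sigma0 = as<std::vector<double>>(sigma0);
  std::vector<double> sv(d);
  for (int i = 0; i < points.nrow(); ++i) {
    for (int j = 0; j < d; ++j) sv[j] = points(i, j);
    opes.deposit(sv.data());
  }
  NumericMatrix kout(opes.K(), 2 * d + 1);
  for (size_t k = 0; k < opes.K(); ++k) {
    for (int j = 0; j < d; ++j) {
      kout(k, j) = opes.c[k * d + j];
      kout(k, d + j) = opes.s[k * d + j];
    }
    kout(k, 2 * d) = opes.h[k];
  }
  return List::create(_["kernels"] = kout, _["Z"] = opes.Z,
                      _["sum_w"] = opes.sum_w, _["sum_w2"] = opes.sum_w2,
                      _["n_deposit"] = opes.n_dep);
}

// Deep-LDA CV values on state rows (mirrors the R forward pass).
// [[Rcpp::export]]
NumericVector cpp_net_sw(List net, NumericMatrix X) {
  Net network;
  network.load(net);
  NumericVector out(X.nrow());
  std::vector<double> x(X.ncol());
  for (int i = 0; i < X.nrow(); ++i) {
    for (int j = 0; j < X.ncol(); ++j) x[j] = X(i, j);
    out[i] = network.sw(x.data(), nullptr);
  }
  return out;
}

// Deep-LDA CV values and gradients (cross-check for the R backprop).
// [[Rcpp::export]]
List cpp_net_sw_grad(List net, NumericMatrix X) {
  Net network;
  network.load(net);
  NumericVector out(X.nrow());
  NumericMatrix gr(X.nrow(), X.ncol());
  std::vector<double> x(X.ncol()), g(X.ncol());
  for (int i = 0; i < X.nrow(); ++i) {
    for (int j = 0; j < X.ncol(); ++j) x[j] = X(i, j);
    out[i] = network.sw(x.data(), g.data());
    for (int j = 0; j < X.ncol(); ++j) gr(i, j) = g[j];
  }
  return List::create(_["sw"] = out, _["grad"] = gr);
}
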