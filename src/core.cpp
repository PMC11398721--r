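#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of the adaptive-coupling Kuramoto model with an
// optional per-node excitability resource.
//
//   dtheta_i/dt  = omega_i + lambda_i * r_i * sum_j W_ij sin(theta_j - theta_i)
//   dlambda_i/dt = alpha * (lambda_o - lambda_i) - beta * r_i      (resource mode)
//   r_i          = | sum_j W_ij e^{i theta_j} | / s_i,   s_i = sum_j W_ij
//
// W_ij is the weight of the directed edge j -> i.  In fixed-resource
// mode lambda_i is pinned at fixed_lambda and the resource equation is
// dropped.  The coupling sum is evaluated in O(E) per step from the
// per-node complex field (C_i, S_i):
//   sum_j W_ij sin(theta_j - theta_i) = cos(theta_i) S_i - sin(theta_i) C_i.
//
// Recording happens every `stride` steps on the post-update state; the
// initial state is recorded as sample 0.

static void field(const std::vector<double>& cs, const std::vector<double>& sn,
                  const IntegerVector& src, const IntegerVector& tgt,
                  const NumericVector& w,
                  std::vector<double>& C, std::vector<double>& S) {
  std::fill(C.begin(), C.end(), 0.0);
  std::fill(S.begin(), S.end(), 0.0);
  const int ne = src.size();
  for (int e = 0; e < ne; ++e) {
    const int s = src[e], t = tgt[e];
    C[t] += w[e] * cs[s];
    S[t] += w[e] * sn[s];
  }
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(IntegerVector src, IntegerVector tgt, NumericVector w,
              NumericVector instrength, int n,
              NumericVector theta0, NumericVector omega0, NumericVector lam0,
              double alpha, double beta, double lambda_o,
              bool fixed_mode, double fixed_lambda,
              double dt, int n_steps, int stride, bool per_node) {
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> lam(lam0.begin(), lam0.end());
  std::vector<double> cs(n), sn(n), C(n), S(n), r(n), dth(n);

  const int n_rec = n_steps / stride + 1;
  NumericVector t_rec(n_rec), R_rec(n_rec), L_rec(n_rec);
  NumericMatrix theta_rec, r_rec, lam_rec;
  if (per_node) {
    theta_rec = NumericMatrix(n_rec, n);
    r_rec     = NumericMatrix(n_rec, n);
    lam_rec   = NumericMatrix(n_rec, n);
  }

  int k = 0;
  // record a sample from the current (post-update) state
  auto record = [&](double time) {
    double Cr = 0, Sr = 0, Lm = 0;
    for (int i = 0; i < n; ++i) { cs[i] = cos(th[i]); sn[i] = sin(th[i]); }
    field(cs, sn, src, tgt, w, C, S);
    for (int i = 0; i < n; ++i) {
      Cr += cs[i]; Sr += sn[i];
      double li = fixed_mode ? fixed_lambda : lam[i];
      Lm += li;
      if (per_node) {
        double ri = instrength[i] > 0.0
          ? std::sqrt(C[i] * C[i] + S[i] * S[i]) / instrength[i] : 0.0;
        theta_rec(k, i) = th[i];
        r_rec(k, i) = std::min(ri, 1.0);
        lam_rec(k, i) = li;
      }
    }
    t_rec[k] = time;
    R_rec[k] = std::sqrt(Cr * Cr + Sr * Sr) / n;
    L_rec[k] = Lm / n;
    ++k;
  };

  record(0.0);

  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i) { cs[i] = cos(th[i]); sn[i] = sin(th[i]); }
    field(cs, sn, src, tgt, w, C, S);
    for (int i = 0; i < n; ++i) {
      r[i] = instrength[i] > 0.0
        ? std::sqrt(C[i] * C[i] + S[i] * S[i]) / instrength[i] : 0.0;
      if (r[i] > 1.0) r[i] = 1.0;  // guard against rounding overshoot
      const double li = fixed_mode ? fixed_lambda : lam[i];
      dth[i] = omega0[i] + li * r[i] * (cs[i] * S[i] - sn[i] * C[i]);
    }
    for (int i = 0; i < n; ++i) {
      th[i] = std::fmod(th[i] + dt * dth[i], 2.0 * M_PI);
      if (th[i] < 0) th[i] += 2.0 * M_PI;
      if (!fixed_mode)
        lam[i] += dt * (alpha * (lambda_o - lam[i]) - beta * r[i]);
      if (!std::isfinite(th[i]))
        stop("non-finite phase at step %d (node %d)", step + 1, i + 1);
    }
    if ((step + 1) % stride == 0) record((step + 1) * dt);
  }

  List out = List::create(
    _["t"] = t_rec, _["R"] = R_rec, _["mean_lambda"] = L_rec,
    _["theta_end"] = NumericVector(th.begin(), th.end()),
    _["lambda_end"] = NumericVector(lam.begin(), lam.end()));
  if (per_node) {
    out["theta"] = theta_rec;
    out["r"] = r_rec;
    out["lambda"] = lam_rec;
  }
  return out;
}

// Stationary tail means of R for a sequence of fixed-resource dwells
// (adiabatic sweep): the state is carried over between consecutive
// Lambda values.  Returns the mean of R over the last `tail_frac`
// fraction of each dwell plus the final state.
// [[Rcpp::export(name = ".adiabatic_core")]]
List adiabatic_core(IntegerVector src, IntegerVector tgt, NumericVector w,
                    NumericVector instrength, int n,
                    NumericVector theta0, NumericVector omega0,
                    NumericVector lambda_grid,
                    double dt, int dwell_steps, double tail_frac) {
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> cs(n), sn(n), C(n), S(n);
  const int ng = lambda_grid.size();
  NumericVector R_stat(ng);
  const int tail_start = dwell_steps - (int)std::floor(dwell_steps * tail_frac);

  for (int g = 0; g < ng; ++g) {
    const double Lam = lambda_grid[g];
    double acc = 0; int cnt = 0;
    for (int step = 0; step < dwell_steps; ++step) {
      for (int i = 0; i < n; ++i) { cs[i] = cos(th[i]); sn[i] = sin(th[i]); }
      field(cs, sn, src, tgt, w, C, S);
      for (int i = 0; i < n; ++i) {
        double r = instrength[i] > 0.0
          ? std::sqrt(C[i] * C[i] + S[i] * S[i]) / instrength[i] : 0.0;
        if (r > 1.0) r = 1.0;
        const double dth = omega0[i] + Lam * r * (cs[i] * S[i] - sn[i] * C[i]);
        th[i] = std::fmod(th[i] + dt * dth, 2.0 * M_PI);
        if (th[i] < 0) th[i] += 2.0 * M_PI;
      }
      if (step >= tail_start) {
        double Cr = 0, Sr = 0;
        for (int i = 0; i < n; ++i) { Cr += cos(th[i]); Sr += sin(th[i]); }
        acc += std::sqrt(Cr * Cr + Sr * Sr) / n;
        ++cnt;
      }
    }
    R_stat[g] = acc / cnt;
  }
  return List::create(_["R_stat"] = R_stat,
                      _["theta_end"] = NumericVector(th.begin(), th.end()));
}
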