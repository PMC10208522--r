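// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Forward-Euler motion on the linear track: v = target_speed(x) * factor,
// teleport to x = 0 on reaching the end. Stops after n_laps laps.
// [[Rcpp::export]]
List simulate_motion_cpp(const arma::vec& factors, double track_length,
                         double v_end, double v_mid, double dt, int n_laps) {
  const double half = track_length / 2.0;
  const arma::uword n_max = factors.n_elem;
  arma::vec x(n_max), v(n_max), fac(n_max);
  arma::ivec lap(n_max);
  double xi = 0.0;
  int lap_i = 1;
  arma::uword t = 0;
  for (; t < n_max; ++t) {
    double vbar = v_mid + (v_end - v_mid) * std::fabs(xi - half) / half;
    double vi = vbar * factors[t];
    x[t] = xi;
    v[t] = vi;
    fac[t] = factors[t];
    lap[t] = lap_i;
    xi += vi * dt;
    if (xi >= track_length) {
      xi = 0.0;       // teleport; residual distance discarded
      lap_i += 1;
      if (lap_i > n_laps) { ++t; break; }
    }
  }
  if (t == n_max && lap_i <= n_laps)
    stop("noise series exhausted before completing the requested laps");
  return List::create(_["x"] = x.head(t), _["v"] = v.head(t),
                      _["lap_id"] = lap.head(t), _["factor"] = fac.head(t));
}

static inline arma::vec logistic_vec(const arma::vec& x, double alpha,
                                     double x0) {
  return 1.0 / (1.0 + arma::exp(-alpha * (x - x0)));
}

// Euler integration of the rate network with short-term facilitation /
// depression, rhythmic theta drive, lap initialization current, gated
// spatial input and gated Hebbian plasticity of the input weights.
//
// Per-step order: drives from current theta and x -> update r with
// pre-update f, d, sigma_r(r) -> update f, d with pre-update sigma_r(r) ->
// update W_s with post-update sigma_r(r). Stored traces are the post-update
// sigma_r(r) and the current step's i_ext.
// [[Rcpp::export]]
List simulate_network_cpp(const arma::vec& x, const arma::vec& theta,
                          const arma::ivec& lap_id, const arma::mat& features,
                          double feat_bin_size, const arma::mat& W_rec,
                          List params, double dt, double theta_freq,
                          bool store_stp = false) {
  const arma::uword T = x.n_elem;
  const arma::uword n = W_rec.n_rows;
  const arma::uword n_feat = features.n_rows;
  const arma::uword n_bins = features.n_cols;

  const double tau_r = params["tau_r"], tau_f = params["tau_f"],
               tau_d = params["tau_d"], tau_w = params["tau_w"],
               kappa_theta = params["kappa_theta"],
               i_theta_max = params["i_theta_max"],
               i_theta_min = params["i_theta_min"],
               alpha_r = params["alpha_r"], x_r = params["x_r"],
               f0 = params["f0"], kappa_s = params["kappa_s"],
               beta_max = params["beta_max"], alpha_s = params["alpha_s"],
               x_s = params["x_s"];
  const int n_init_units = params["n_init_units"];
  const double init_window = 1.0 / theta_freq;

  arma::vec r(n, arma::fill::zeros), f(n), d(n, arma::fill::zeros);
  f.fill(f0);
  arma::mat Ws(n, n_feat, arma::fill::zeros);

  NumericMatrix sig_out(n, T), iext_out(n, T);
  arma::mat sig(sig_out.begin(), n, T, false, true);
  arma::mat iex(iext_out.begin(), n, T, false, true);
  NumericMatrix f_out, d_out;
  arma::mat ftr, dtr;
  if (store_stp) {
    f_out = NumericMatrix(n, T);
    d_out = NumericMatrix(n, T);
    ftr = arma::mat(f_out.begin(), n, T, false, true);
    dtr = arma::mat(d_out.begin(), n, T, false, true);
  }

  int cur_lap = -1;
  arma::uword lap_start = 0;

  for (arma::uword t = 0; t < T; ++t) {
    if (lap_id[t] != cur_lap) {
      cur_lap = lap_id[t];
      lap_start = t;
      r.zeros();
      d.zeros();
      f.fill(f0);
    }
    const double th = theta[t];
    const double beta = std::exp(kappa_s * std::sin(th)) / std::exp(kappa_s);
    const double i_th = -(i_theta_max - i_theta_min) *
                          std::exp(kappa_theta * std::cos(th)) /
                          std::exp(kappa_theta) +
                        i_theta_max;

    arma::uword bin = static_cast<arma::uword>(x[t] / feat_bin_size);
    if (bin >= n_bins) bin = n_bins - 1;
    const arma::vec s = features.col(bin);

    arma::vec srr = logistic_vec(r, alpha_r, x_r);
    arma::vec i_ext = beta_max * beta * logistic_vec(Ws * s, alpha_s, x_s);

    arma::vec dr = -r + i_th + W_rec * ((1.0 - d) % f % srr) + i_ext;
    if ((t - lap_start) * dt < init_window) {
      dr.head(n_init_units) += beta;
    }
    r += (dt / tau_r) * dr;
    f += (dt / tau_f) * (-f + (1.0 - f) % srr + f0);
    d += (dt / tau_d) * (-d + srr);

    arma::vec srr_new = logistic_vec(r, alpha_r, x_r);
    Ws += ((dt / tau_w) * beta) * ((srr_new - i_ext) * s.t());

    sig.col(t) = srr_new;
    iex.col(t) = i_ext;
    if (store_stp) {
      ftr.col(t) = f;
      dtr.col(t) = d;
    }
    if (t % 1000 == 0 && !r.is_finite())
      stop("network state became non-finite at step %d", (int)t);
  }
  if (!r.is_finite()) stop("network state became non-finite");

  List out = List::create(_["sigma"] = sig_out, _["i_ext"] = iext_out,
                          _["W_s"] = wrap(Ws));
  if (store_stp) {
    out["f"] = f_out;
    out["d"] = d_out;
  }
  return out;
}
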