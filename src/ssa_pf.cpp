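#include <Rcpp.h>
using namespace Rcpp;

// Mass-action propensity a_j = c_j * prod_i choose(x_i, p_ji)
// (number of distinct reactant multisets).
static inline double propensity(const double *rates, const int *Pre,
                                const int *x, int j, int n_R, int n_x) {
  double a = rates[j];
  for (int i = 0; i < n_x && a > 0.0; ++i) {
    int p = Pre[j + n_R * i];
    if (p == 0) continue;
    if (x[i] < p) return 0.0;
    a *= Rf_choose((double)x[i], (double)p);
  }
  return a;
}

// Exact SSA (direct method) from state x at time t to time t_end.
// Returns false if the event budget is exhausted.
static bool ssa_advance(std::vector<int> &x, double &t, double t_end,
                        const double *rates, const int *Pre, const int *Stoich,
                        int n_R, int n_x, R_xlen_t &events, R_xlen_t max_events,
                        std::vector<double> &a) {
  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < n_R; ++j) {
      a[j] = propensity(rates, Pre, x.data(), j, n_R, n_x);
      if (!R_FINITE(a[j]) || a[j] < 0.0)
        stop("non-finite or negative propensity encountered");
      a0 += a[j];
    }
    if (a0 <= 0.0) { t = t_end; return true; }  // absorbing state
    double dt = exp_rand() / a0;
    if (t + dt > t_end) { t = t_end; return true; }
    t += dt;
    if (++events > max_events)
      return false;
    double u = unif_rand() * a0, cum = 0.0;
    int j = n_R - 1;
    for (int k = 0; k < n_R; ++k) {
      cum += a[k];
      if (u <= cum) { j = k; break; }
    }
    for (int i = 0; i < n_x; ++i) x[i] += Stoich[j + n_R * i];
  }
}

// [[Rcpp::export]]
List ssa_simulate_cpp(NumericVector rates, IntegerMatrix Pre, IntegerMatrix Stoich,
                      IntegerVector x0, NumericVector tgrid, double t0,
                      bool record_jumps, double max_events_d) {
  int n_R = Pre.nrow(), n_x = Pre.ncol();
  R_xlen_t T = tgrid.size();
  IntegerMatrix grid_states(T, n_x);
  std::vector<int> x(x0.begin(), x0.end());
  std::vector<double> a(n_R);
  std::vector<double> jt;
  std::vector<int> js;
  double t = t0;
  R_xlen_t events = 0;
  R_xlen_t max_events = (R_xlen_t)max_events_d;

  for (R_xlen_t k = 0; k < T; ++k) {
    double t_end = tgrid[k];
    // step event-by-event so jumps can be recorded
    while (true) {
      double a0 = 0.0;
      for (int j = 0; j < n_R; ++j) {
        a[j] = propensity(rates.begin(), Pre.begin(), x.data(), j, n_R, n_x);
        if (!R_FINITE(a[j]) || a[j] < 0.0)
          stop("non-finite or negative propensity encountered");
        a0 += a[j];
      }
      if (a0 <= 0.0) { t = t_end; break; }
      double dt = exp_rand() / a0;
      if (t + dt > t_end) { t = t_end; break; }
      t += dt;
      if (++events > max_events)
        stop("SSA event budget exhausted; propensities may be diverging");
      double u = unif_rand() * a0, cum = 0.0;
      int j = n_R - 1;
      for (int kk = 0; kk < n_R; ++kk) {
        cum += a[kk];
        if (u <= cum) { j = kk; break; }
      }
      for (int i = 0; i < n_x; ++i) {
        x[i] += Stoich[j + n_R * i];
        if (x[i] < 0) stop("negative state reached; invalid stoichiometry");
      }
      if (record_jumps) {
        jt.push_back(t);
        for (int i = 0; i < n_x; ++i) js.push_back(x[i]);
      }
    }
    for (int i = 0; i < n_x; ++i) grid_states(k, i) = x[i];
  }

  List out = List::create(_["grid_states"] = grid_states);
  if (record_jumps) {
    R_xlen_t nj = (R_xlen_t)jt.size();
    IntegerMatrix jsm(nj, n_x);
    for (R_xlen_t r = 0; r < nj; ++r)
      for (int i = 0; i < n_x; ++i) jsm(r, i) = js[r * n_x + i];
    out["jump_times"] = NumericVector(jt.begin(), jt.end());
    out["jump_states"] = jsm;
  }
  return out;
}

// Bootstrap particle filter log-likelihood estimate for one trajectory.
// Observation model: y ~ N(C x, diag(sigma^2)).
// Returns -Inf if at some step every particle has zero weight.
// [[Rcpp::export]]
double pf_loglik_cpp(NumericVector rates, IntegerMatrix Pre, IntegerMatrix Stoich,
                     IntegerVector x0, NumericVector times, NumericMatrix ymat,
                     NumericMatrix Cobs, NumericVector sigma, int H, double t0,
                     double max_events_d) {
  int n_R = Pre.nrow(), n_x = Pre.ncol();
  int n_y = Cobs.nrow();
  R_xlen_t T = times.size();
  if (H < 1) stop("particle filter needs H >= 1");
  if (T == 0) return 0.0;

  std::vector<std::vector<int>> part(H, std::vector<int>(x0.begin(), x0.end()));
  std::vector<std::vector<int>> newpart(H, std::vector<int>(n_x));
  std::vector<double> a(n_R), logw(H), w(H);
  R_xlen_t max_events = (R_xlen_t)max_events_d;
  double loglik = 0.0;
  double t_prev = t0;

  for (R_xlen_t tau = 0; tau < T; ++tau) {
    double t_obs = times[tau];
    double maxlw = R_NegInf;
    for (int h = 0; h < H; ++h) {
      double t = t_prev;
      R_xlen_t events = 0;
      if (!ssa_advance(part[h], t, t_obs, rates.begin(), Pre.begin(),
                       Stoich.begin(), n_R, n_x, events, max_events, a))
        stop("SSA event budget exhausted inside the particle filter");
      double lw = 0.0;
      for (int c = 0; c < n_y; ++c) {
        double mu = 0.0;
        for (int i = 0; i < n_x; ++i) mu += Cobs(c, i) * part[h][i];
        lw += R::dnorm(ymat(tau, c), mu, sigma[c], 1);
      }
      logw[h] = lw;
      if (lw > maxlw) maxlw = lw;
    }
    // all weights zero (including log-weights below the double underflow
    // threshold, where the linear-domain estimate is exactly 0)
    if (!R_FINITE(maxlw) || maxlw < -708.396) return R_NegInf;
    double sumw = 0.0;
    for (int h = 0; h < H; ++h) { w[h] = std::exp(logw[h] - maxlw); sumw += w[h]; }
    loglik += maxlw + std::log(sumw / H);

    // multinomial resampling via sorted uniform spacings (O(H))
    double E = exp_rand(), cumE;
    std::vector<double> us(H);
    cumE = E;
    for (int h = 0; h < H; ++h) { us[h] = cumE; cumE += exp_rand(); }
    // us now holds H increasing points; normalize to (0, sumw)
    double scale = sumw / cumE;
    int h_src = 0; double cw = w[0];
    for (int h = 0; h < H; ++h) {
      double target = us[h] * scale;
      while (cw < target && h_src < H - 1) { ++h_src; cw += w[h_src]; }
      newpart[h] = part[h_src];
    }
    std::swap(part, newpart);
    t_prev = t_obs;
  }
  return loglik;
}
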