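#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Forward-Euler engine for the two-region item network.
//
// Per step (synchronous update; all derivatives evaluated at the
// previous-step state):
//   1. E, I and the analytic da/dt, dg/dt for both regions
//   2. weight update on existing links from the pre-update activations and
//      the analytic da/dt (Hebbian term gated per region, passive decay
//      always on)
//   3. salience Euler update from pre-update cortical activations (wake)
//   4. a, g updated and clamped to [0, 1]
//   5. cortical threshold crossings recorded; links instantiated between
//      co-active items (training only)
//
// W is indexed (pre, post). The hippocampus receives the previous-step
// cortical activation as feedforward drive; the cortex receives the input
// register plus (unless lesioned) rectified hippocampal feedback.

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

static inline double pos(double x) { return x > 0.0 ? x : 0.0; }

static double need(const List& par, const char* nm) {
  if (!par.containsElementNamed(nm))
    stop("missing model parameter '%s'", nm);
  return as<double>(par[nm]);
}

// [[Rcpp::export]]
List cpp_integrate(NumericVector a_c_in, NumericVector g_c_in,
                   NumericVector a_h_in, NumericVector g_h_in,
                   NumericMatrix W_c_in, NumericMatrix W_h_in,
                   LogicalMatrix ex_c_in, LogicalMatrix ex_h_in,
                   NumericVector s_in,
                   NumericVector input_c, NumericVector input_h,
                   int n_steps, List par,
                   bool sleep, bool hc_to_ctx,
                   bool learn_c, bool learn_h,
                   bool instantiate, bool track_salience,
                   LogicalVector crossed_in, IntegerVector stop_items,
                   int sample_every,
                   IntegerMatrix pairs_c, IntegerMatrix pairs_h) {
  const int N = a_c_in.size();
  if (g_c_in.size() != N || a_h_in.size() != N || g_h_in.size() != N ||
      s_in.size() != N || input_c.size() != N || input_h.size() != N ||
      W_c_in.nrow() != N || W_c_in.ncol() != N ||
      W_h_in.nrow() != N || W_h_in.ncol() != N)
    stop("state dimensions do not match the item catalog");

  NumericVector a_c = clone(a_c_in), g_c = clone(g_c_in);
  NumericVector a_h = clone(a_h_in), g_h = clone(g_h_in);
  NumericMatrix W_c = clone(W_c_in), W_h = clone(W_h_in);
  LogicalMatrix ex_c = clone(ex_c_in), ex_h = clone(ex_h_in);
  NumericVector s = clone(s_in);
  LogicalVector crossed = clone(crossed_in);

  const double dt      = need(par, "dt");
  const double sigma_a = sleep ? need(par, "sigma_a_sleep") : need(par, "sigma_a_wake");
  const double tau_a   = need(par, "tau_a");
  const double mu_c    = need(par, "mu_c"),  mu_h  = need(par, "mu_h");
  const double gamma   = need(par, "gamma"), alpha = need(par, "alpha");
  const double m_ord   = need(par, "m"),     t_a   = need(par, "t_a");
  const double zeta    = need(par, "zeta"),  beta  = need(par, "beta");
  const double theta   = need(par, "theta"), n_ord = need(par, "n");
  const double t_h     = need(par, "t_h");
  const double sigma_g = need(par, "sigma_g"), tau_g = need(par, "tau_g");
  const double kappa   = need(par, "kappa");
  const double Q       = need(par, "Q");
  const double eta_c   = need(par, "eta_c"), eta_h = need(par, "eta_h");
  const double tw_c    = need(par, "tau_w_c_eff"), tw_h = need(par, "tau_w_h_eff");
  const double tau_s   = need(par, "tau_s");
  const double lambda  = sleep ? need(par, "lambda_sleep") : need(par, "lambda_wake");
  const double thr     = need(par, "recall_threshold");
  const double co_thr  = need(par, "coactivation_threshold");
  const double tam     = std::pow(t_a, m_ord);
  const double thn     = std::pow(t_h, n_ord);

  std::vector<double> E_c(N), I_c(N), dadt_c(N), dgdt_c(N);
  std::vector<double> E_h(N), I_h(N), dadt_h(N), dgdt_h(N);
  std::vector<double> phi_c(N), phi_h(N);

  std::vector<int> cr_step, cr_item;
  std::vector<double> cr_act;

  const int kc = pairs_c.nrow(), kh = pairs_h.nrow();
  std::vector<int> samp_step;
  std::vector<double> samp_wc, samp_wh;  // row-major blocks of kc / kh

  const int n_stop = stop_items.size();
  int steps_run = 0;

  for (int it = 1; it <= n_steps; ++it) {
    double sum_ac = 0.0, sum_ah = 0.0;
    for (int x = 0; x < N; ++x) { sum_ac += a_c[x]; sum_ah += a_h[x]; }

    for (int x = 0; x < N; ++x) {
      double spread_c = 0.0, spread_h = 0.0;
      for (int y = 0; y < N; ++y) {
        spread_c += W_c(y, x) * a_c[y];
        spread_h += W_h(y, x) * a_h[y];
      }
      const double am = std::pow(a_c[x], m_ord);
      E_c[x] = mu_c * input_c[x] + gamma * spread_c + alpha * am / (am + tam);
      if (hc_to_ctx) E_c[x] += zeta * pos(a_h[x]);
      const double gn = std::pow(g_c[x], n_ord);
      I_c[x] = beta * (sum_ac - a_c[x]) + theta * gn / (gn + thn);
      dadt_c[x] = (-a_c[x] / tau_a + (1.0 - a_c[x]) * E_c[x] - a_c[x] * I_c[x]) / sigma_a;
      dgdt_c[x] = (-g_c[x] / tau_g + (1.0 - g_c[x]) * kappa * a_c[x]) / sigma_g;

      const double amh = std::pow(a_h[x], m_ord);
      E_h[x] = mu_h * a_c[x] + input_h[x] + gamma * spread_h + alpha * amh / (amh + tam);
      const double gnh = std::pow(g_h[x], n_ord);
      I_h[x] = beta * (sum_ah - a_h[x]) + theta * gnh / (gnh + thn);
      dadt_h[x] = (-a_h[x] / tau_a + (1.0 - a_h[x]) * E_h[x] - a_h[x] * I_h[x]) / sigma_a;
      dgdt_h[x] = (-g_h[x] / tau_g + (1.0 - g_h[x]) * kappa * a_h[x]) / sigma_g;
    }

    // plasticity from pre-update state; passive decay is never gated
    for (int y = 0; y < N; ++y) {
      phi_c[y] = pos(dadt_c[y]) - Q * pos(-dadt_c[y]);
      phi_h[y] = pos(dadt_h[y]) - Q * pos(-dadt_h[y]);
    }
    for (int y = 0; y < N; ++y) {
      for (int x = 0; x < N; ++x) {
        if (ex_c(x, y)) {
          double w = W_c(x, y);
          double dw = -w / tw_c;
          if (learn_c) dw += eta_c * a_c[x] * (1.0 - w) * phi_c[y];
          w += dt * dw;
          if (!R_finite(w))
            stop("numerical instability in cortical weight (%d -> %d)", x + 1, y + 1);
          W_c(x, y) = clamp01(w);
        }
        if (ex_h(x, y)) {
          double w = W_h(x, y);
          double dw = -w / tw_h;
          if (learn_h) dw += eta_h * a_h[x] * (1.0 - w) * phi_h[y];
          w += dt * dw;
          if (!R_finite(w))
            stop("numerical instability in hippocampal weight (%d -> %d)", x + 1, y + 1);
          W_h(x, y) = clamp01(w);
        }
      }
    }

    if (track_salience) {
      for (int x = 0; x < N; ++x) {
        s[x] += dt * (-s[x] / tau_s + lambda * a_c[x]);
        if (s[x] < 0.0) s[x] = 0.0;
      }
    }

    for (int x = 0; x < N; ++x) {
      const double a_new = a_c[x] + dt * dadt_c[x];
      if (!R_finite(a_new))
        stop("numerical instability in cortical item %d", x + 1);
      const double a_cl = clamp01(a_new);
      if (a_cl > thr && a_c[x] <= thr) {
        cr_step.push_back(it);
        cr_item.push_back(x + 1);
        cr_act.push_back(a_cl);
        crossed[x] = true;
      }
      a_c[x] = a_cl;
      g_c[x] = clamp01(g_c[x] + dt * dgdt_c[x]);

      const double ah_new = a_h[x] + dt * dadt_h[x];
      if (!R_finite(ah_new))
        stop("numerical instability in hippocampal item %d", x + 1);
      a_h[x] = clamp01(ah_new);
      g_h[x] = clamp01(g_h[x] + dt * dgdt_h[x]);
    }

    if (instantiate) {
      for (int x = 0; x < N; ++x) {
        if (a_c[x] <= co_thr && a_h[x] <= co_thr) continue;
        for (int y = 0; y < N; ++y) {
          if (y == x) continue;
          if (a_c[x] > co_thr && a_c[y] > co_thr && !ex_c(x, y)) ex_c(x, y) = true;
          if (a_h[x] > co_thr && a_h[y] > co_thr && !ex_h(x, y)) ex_h(x, y) = true;
        }
      }
    }

    if (sample_every > 0 && it % sample_every == 0) {
      samp_step.push_back(it);
      for (int k = 0; k < kc; ++k) samp_wc.push_back(W_c(pairs_c(k, 0) - 1, pairs_c(k, 1) - 1));
      for (int k = 0; k < kh; ++k) samp_wh.push_back(W_h(pairs_h(k, 0) - 1, pairs_h(k, 1) - 1));
    }

    steps_run = it;
    if (n_stop > 0) {
      bool all_done = true;
      for (int k = 0; k < n_stop; ++k)
        if (!crossed[stop_items[k] - 1]) { all_done = false; break; }
      if (all_done) break;
    }
  }

  const int ns = samp_step.size();
  NumericMatrix m_wc(ns, kc), m_wh(ns, kh);
  IntegerVector v_step(ns);
  for (int i = 0; i < ns; ++i) {
    v_step[i] = samp_step[i];
    for (int k = 0; k < kc; ++k) m_wc(i, k) = samp_wc[(size_t)i * kc + k];
    for (int k = 0; k < kh; ++k) m_wh(i, k) = samp_wh[(size_t)i * kh + k];
  }

  return List::create(
    _["a_c"] = a_c, _["g_c"] = g_c, _["a_h"] = a_h, _["g_h"] = g_h,
    _["W_c"] = W_c, _["W_h"] = W_h, _["ex_c"] = ex_c, _["ex_h"] = ex_h,
    _["s"] = s,
    _["cross_step"] = wrap(cr_step), _["cross_item"] = wrap(cr_item),
    _["cross_act"] = wrap(cr_act),
    _["samp_step"] = v_step, _["samp_wc"] = m_wc, _["samp_wh"] = m_wh,
    _["steps_run"] = steps_run, _["crossed"] = crossed);
}
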