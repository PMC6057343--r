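#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-variable quadratic cell model, forward Euler with optional voltage
// substeps. Parameter vector order: C, v_r, v_t, k, a, b, c, d, v_peak.
struct CellP {
  double C, vr, vt, k, a, b, c, d, vpeak;
  explicit CellP(const NumericVector& p)
    : C(p[0]), vr(p[1]), vt(p[2]), k(p[3]), a(p[4]), b(p[5]),
      c(p[6]), d(p[7]), vpeak(p[8]) {}
};

struct Cell {
  double v, u;
  bool event;
  double v_rec;  // recorded voltage: capped at v_peak on event steps
};

static inline void step(Cell& s, const CellP& p, double I, double dt,
                        int sub, double noise_sd) {
  double v = s.v, u = s.u;
  double h = dt / sub;
  for (int i = 0; i < sub; ++i)
    v += h * (p.k * (v - p.vr) * (v - p.vt) - u + I) / p.C;
  u += dt * p.a * (p.b * (v - p.vr) - u);
  if (noise_sd > 0) v += R::rnorm(0.0, noise_sd);
  if (!std::isfinite(v) || !std::isfinite(u))
    stop("non-finite cell state: integration blew up (I = %g, dt = %g)",
         I, dt);
  if (v >= p.vpeak) {
    s.v_rec = p.vpeak;
    s.v = p.c;
    s.u = u + p.d;
    s.event = true;
  } else {
    s.v_rec = v;
    s.v = v;
    s.u = u;
    s.event = false;
  }
}

// Superposed alpha-kernel output of an event line at time t. Events older
// than cutoff*lam are dropped (bounded relative error ~1e-3 per kernel).
static inline double line_out(const std::vector<double>& ev, double t,
                              double lam, double cutoff) {
  double s = 0.0;
  for (int i = (int)ev.size() - 1; i >= 0; --i) {
    double dt = t - ev[i];
    if (dt <= 0) continue;
    if (dt > cutoff * lam) break;
    s += (dt / lam) * std::exp((lam - dt) / lam);
  }
  return s;
}

// [[Rcpp::export]]
List simulate_cell_cpp(NumericVector params, NumericVector I_vec, double dt,
                       int v_substeps) {
  CellP p(params);
  Cell s{p.vr, 0.0, false, p.vr};
  int n = I_vec.size();
  NumericVector v(n);
  std::vector<double> events;
  for (int i = 0; i < n; ++i) {
    step(s, p, I_vec[i], dt, v_substeps, 0.0);
    v[i] = s.v_rec;
    if (s.event) events.push_back(i * dt);
  }
  return List::create(_["v"] = v, _["event_times"] = wrap(events));
}

// One trial of the bipartite or tripartite network.
//
// Per integration step at time t = step*dt:
//  (i)   presynaptic neurons integrate their stimulus current (on during
//        [stim_on, stim_off)); an event appends t to the neuron's synaptic
//        line and, in tripartite mode, to its IP3 line;
//  (ii)  postsynaptic neuron j integrates
//          sum_i w[i][j] * (syn_i(t) + fixed_w * glu_j(t)) +
//          fixed_w * glu_j(t)
//        (glutamate terms only in tripartite mode); its events append to
//        its K+ line;
//  (iii) astrocyte j integrates fixed_w * (sum_i IP3_i(t) + K_j(t)); its
//        events append to its glutamate line.
// Gaussian voltage noise (sd noise_sd) is added to every neuron (never the
// astrocytes) each step, drawn in fixed order: pre 1..n_pre, post 1..n_post.
// S_J accumulates max(v_j, 0)*dt of the recorded postsynaptic voltage;
// I_K accumulates each presynaptic synaptic line's output * dt.
// [[Rcpp::export]]
List simulate_trial_cpp(NumericVector neuron_p, NumericVector astro_p,
                        NumericMatrix weights, double fixed_w,
                        NumericVector stim, bool tripartite,
                        double noise_sd, int n_steps, double dt,
                        int v_substeps, double stim_on, double stim_off,
                        double lam_syn, double lam_ip3, double lam_k,
                        double lam_glu, double cutoff, bool glu_in_cleft,
                        bool record) {
  CellP pn(neuron_p), pa(astro_p);
  int n_pre = weights.nrow(), n_post = weights.ncol();
  int n_astro = tripartite ? n_post : 0;

  std::vector<Cell> pre(n_pre, Cell{pn.vr, 0.0, false, pn.vr});
  std::vector<Cell> post(n_post, Cell{pn.vr, 0.0, false, pn.vr});
  std::vector<Cell> astro(n_astro, Cell{pa.vr, 0.0, false, pa.vr});

  std::vector<std::vector<double>> syn(n_pre), ip3(n_pre), kli(n_post),
      glu(n_astro);

  NumericVector I_K(n_pre), S_J(n_post), I_glu(n_post);
  NumericMatrix v_pre, v_post, v_astro, post_input;
  if (record) {
    v_pre = NumericMatrix(n_steps, n_pre);
    v_post = NumericMatrix(n_steps, n_post);
    v_astro = NumericMatrix(n_steps, n_astro);
    post_input = NumericMatrix(n_steps, n_post);
  }

  std::vector<double> syn_out(n_pre), glu_out(n_astro > 0 ? n_astro : 1);

  for (int it = 0; it < n_steps; ++it) {
    double t = it * dt;
    bool on = (t >= stim_on && t < stim_off);

    // pathway outputs at the current time, before any event this step
    double ip3_sum = 0.0;
    for (int i = 0; i < n_pre; ++i) {
      syn_out[i] = line_out(syn[i], t, lam_syn, cutoff);
      I_K[i] += syn_out[i] * dt;
      if (tripartite) ip3_sum += line_out(ip3[i], t, lam_ip3, cutoff);
    }
    for (int j = 0; j < n_astro; ++j) {
      glu_out[j] = line_out(glu[j], t, lam_glu, cutoff);
      I_glu[j] += glu_out[j] * dt;
    }

    // (i) presynaptic neurons
    for (int i = 0; i < n_pre; ++i) {
      step(pre[i], pn, on ? stim[i] : 0.0, dt, v_substeps, noise_sd);
      if (pre[i].event) {
        syn[i].push_back(t);
        if (tripartite) ip3[i].push_back(t);
      }
      if (record) v_pre(it, i) = pre[i].v_rec;
    }

    // (ii) postsynaptic neurons
    for (int j = 0; j < n_post; ++j) {
      double I = 0.0, g = tripartite ? fixed_w * glu_out[j] : 0.0;
      double gc = glu_in_cleft ? g : 0.0;
      for (int i = 0; i < n_pre; ++i) I += weights(i, j) * (syn_out[i] + gc);
      I += g;  // direct glutamate path to the membrane
      step(post[j], pn, I, dt, v_substeps, noise_sd);
      // the event record doubles as the K+ line in tripartite mode
      if (post[j].event) kli[j].push_back(t);
      S_J[j] += std::max(post[j].v_rec, 0.0) * dt;
      if (record) {
        v_post(it, j) = post[j].v_rec;
        post_input(it, j) = I;
      }
    }

    // (iii) astrocytes
    for (int j = 0; j < n_astro; ++j) {
      double I = fixed_w * (ip3_sum + line_out(kli[j], t, lam_k, cutoff));
      step(astro[j], pa, I, dt, v_substeps, 0.0);
      if (astro[j].event) glu[j].push_back(t);
      if (record) v_astro(it, j) = astro[j].v_rec;
    }
  }

  List pre_ev(n_pre), post_ev(n_post), astro_ev(n_astro);
  for (int i = 0; i < n_pre; ++i) pre_ev[i] = wrap(syn[i]);
  for (int j = 0; j < n_post; ++j) post_ev[j] = wrap(kli[j]);
  for (int j = 0; j < n_astro; ++j) astro_ev[j] = wrap(glu[j]);

  List out = List::create(_["I_K"] = I_K, _["S_J"] = S_J,
                          _["I_glu"] = I_glu,
                          _["pre_events"] = pre_ev,
                          _["post_events"] = post_ev,
                          _["astro_events"] = astro_ev);
  if (record) {
    out["v_pre"] = v_pre;
    out["v_post"] = v_post;
    out["v_astro"] = v_astro;
    out["post_input"] = post_input;
  }
  return out;
}
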