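// Hot loops of the network simulators: continuous-time rate dynamics
// (deterministic / white noise / Poisson spiking input) and the spiking
// leaky integrate-and-fire network.  All randomness goes through R's RNG so
// that set.seed() in the R wrappers makes runs bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static inline double phi_tl(double x, double gamma, double phi_max) {
  double u = gamma + x;
  if (u < 0.0) return 0.0;
  if (u > phi_max) return phi_max;
  return u;
}

// y = W * phi(x) for a CSC sparse matrix (p: column pointers, i: row
// indices, v: values)
static void matvec_phi(const int* p, const int* ri, const double* v, int N,
                       const std::vector<double>& px, std::vector<double>& y) {
  std::fill(y.begin(), y.end(), 0.0);
  for (int j = 0; j < N; ++j) {
    const double pj = px[j];
    if (pj == 0.0) continue;
    for (int k = p[j]; k < p[j + 1]; ++k) y[ri[k]] += v[k] * pj;
  }
}

// Continuous-time rate network x' = -x + W phi(x) + I (+ white noise).
// Heun integration when delta_ext == 0, Euler-Maruyama otherwise.
// [[Rcpp::export(name = ".sim_rate_cpp")]]
List sim_rate_cpp(IntegerVector p, IntegerVector ri, NumericVector v, int N,
                  double gamma, double phi_max, double I, double delta_ext,
                  NumericVector x0, int n_steps, double dt, int keep_every) {
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> ph(N), y(N), xm(N), y2(N);
  const int* pp = INTEGER(p); const int* rr = INTEGER(ri);
  const double* vv = REAL(v);
  const int n_keep = n_steps / keep_every;
  NumericMatrix out(N, n_keep + 1);
  NumericVector times(n_keep + 1);
  for (int i = 0; i < N; ++i) out(i, 0) = x[i];
  times[0] = 0.0;
  const bool noisy = delta_ext > 0.0;
  const double noise_sd = std::sqrt(2.0 * delta_ext * dt);
  bool divergent = false;
  int kept = 0, step = 0;
  for (step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < N; ++i) ph[i] = phi_tl(x[i], gamma, phi_max);
    matvec_phi(pp, rr, vv, N, ph, y);
    if (noisy) {
      for (int i = 0; i < N; ++i)
        x[i] += dt * (-x[i] + y[i] + I) + noise_sd * norm_rand();
    } else {
      for (int i = 0; i < N; ++i) xm[i] = x[i] + dt * (-x[i] + y[i] + I);
      for (int i = 0; i < N; ++i) ph[i] = phi_tl(xm[i], gamma, phi_max);
      matvec_phi(pp, rr, vv, N, ph, y2);
      for (int i = 0; i < N; ++i)
        x[i] += 0.5 * dt * ((-x[i] + y[i] + I) + (-xm[i] + y2[i] + I));
    }
    double amax = 0.0;
    for (int i = 0; i < N; ++i) amax = std::max(amax, std::fabs(x[i]));
    if (amax > 1e12) { divergent = true; break; }
    if (step % keep_every == 0) {
      ++kept;
      for (int i = 0; i < N; ++i) out(i, kept) = x[i];
      times[kept] = step * dt;
    }
  }
  if (kept < n_keep) {
    out = out(_, Range(0, kept));
    times = times[Range(0, kept)];
  }
  return List::create(_["currents"] = out, _["times"] = times,
                      _["divergent"] = divergent,
                      _["steps_done"] = std::min(step, n_steps));
}

// Rate network driven by its own Poisson spikes:
// tau_bar x' = -x + sum_j W_ij chi_j(t), spikes thinned per step with count
// n_j ~ Poisson(phi(x_j) dt), each adding W_ij / tau_bar to target currents.
// [[Rcpp::export(name = ".sim_rate_poisson_cpp")]]
List sim_rate_poisson_cpp(IntegerVector p, IntegerVector ri, NumericVector v,
                          int N, double gamma, double phi_max, double tau_bar,
                          NumericVector x0, int n_steps, double dt,
                          int keep_every, bool record_spikes) {
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> inp(N);
  const int* pp = INTEGER(p); const int* rr = INTEGER(ri);
  const double* vv = REAL(v);
  const int n_keep = n_steps / keep_every;
  NumericMatrix out(N, n_keep + 1);
  NumericVector times(n_keep + 1);
  for (int i = 0; i < N; ++i) out(i, 0) = x[i];
  std::vector<int> sp_id;
  std::vector<double> sp_t;
  std::vector<double> spike_count(N, 0.0);
  bool divergent = false;
  int kept = 0;
  for (int step = 1; step <= n_steps; ++step) {
    std::fill(inp.begin(), inp.end(), 0.0);
    const double t = step * dt;
    for (int j = 0; j < N; ++j) {
      const double rate = phi_tl(x[j], gamma, phi_max);
      if (rate <= 0.0) continue;
      const int n_sp = (int) R::rpois(rate * dt);
      if (n_sp == 0) continue;
      spike_count[j] += n_sp;
      for (int k = pp[j]; k < pp[j + 1]; ++k) inp[rr[k]] += n_sp * vv[k];
      if (record_spikes)
        for (int s = 0; s < n_sp; ++s) { sp_id.push_back(j); sp_t.push_back(t); }
    }
    for (int i = 0; i < N; ++i)
      x[i] += dt * (-x[i] / tau_bar) + inp[i] / tau_bar;
    double amax = 0.0;
    for (int i = 0; i < N; ++i) amax = std::max(amax, std::fabs(x[i]));
    if (amax > 1e12) { divergent = true; break; }
    if (step % keep_every == 0) {
      ++kept;
      for (int i = 0; i < N; ++i) out(i, kept) = x[i];
      times[kept] = t;
    }
  }
  if (kept < n_keep) {
    out = out(_, Range(0, kept));
    times = times[Range(0, kept)];
  }
  return List::create(_["currents"] = out, _["times"] = times,
                      _["divergent"] = divergent,
                      _["spike_id"] = wrap(sp_id), _["spike_t"] = wrap(sp_t),
                      _["spike_count"] = wrap(spike_count));
}

// Spiking LIF network with delta synapses and a transmission delay.
// Exact exponential decay toward mu_0 between grid points; a presynaptic
// spike at t adds the PSP amplitude W_ij (mV) to V_i at t + delay.
// Inputs arriving during the refractory clamp are discarded.
// [[Rcpp::export(name = ".sim_lif_cpp")]]
List sim_lif_cpp(IntegerVector p, IntegerVector ri, NumericVector v, int N,
                 double tau_m, double V_th, double V_r, double tau_rp,
                 double mu_0, double noise_sd, NumericVector V0,
                 int n_steps, double dt, int delay_steps) {
  std::vector<double> V(V0.begin(), V0.end());
  const int* pp = INTEGER(p); const int* rr = INTEGER(ri);
  const double* vv = REAL(v);
  std::vector<int> refr(N, 0);                 // remaining refractory steps
  const int rp_steps = (int) std::lround(tau_rp / dt);
  const int D = delay_steps + 1;               // ring buffer depth
  std::vector<double> buf((size_t) D * N, 0.0);
  const double decay = std::exp(-dt / tau_m);
  const double drive = mu_0 * (1.0 - decay);
  const double nsd = noise_sd * std::sqrt(dt / tau_m);
  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(1 << 16);
  sp_t.reserve(1 << 16);
  for (int step = 1; step <= n_steps; ++step) {
    const int slot = step % D;
    double* arriving = &buf[(size_t) slot * N];
    const double t = step * dt;
    const int dest = (step + delay_steps) % D;
    double* future = &buf[(size_t) dest * N];
    for (int i = 0; i < N; ++i) {
      if (refr[i] > 0) { --refr[i]; arriving[i] = 0.0; continue; }
      double Vi = V[i] * decay + drive + arriving[i];
      arriving[i] = 0.0;
      if (noise_sd > 0.0) Vi += nsd * norm_rand();
      if (Vi >= V_th) {
        sp_id.push_back(i);
        sp_t.push_back(t);
        Vi = V_r;
        refr[i] = rp_steps;
        for (int k = pp[i]; k < pp[i + 1]; ++k) future[rr[k]] += vv[k];
      }
      V[i] = Vi;
    }
  }
  return List::create(_["spike_id"] = wrap(sp_id), _["spike_t"] = wrap(sp_t),
                      _["V"] = wrap(V));
}

// Discrete-time map x(t+1) = W phi(x(t)); trajectories stored densely.
// [[Rcpp::export(name = ".sim_discrete_cpp")]]
List sim_discrete_cpp(IntegerVector p, IntegerVector ri, NumericVector v,
                      int N, double gamma, double phi_max, NumericVector x0,
                      int n_steps) {
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> ph(N), y(N);
  const int* pp = INTEGER(p); const int* rr = INTEGER(ri);
  const double* vv = REAL(v);
  NumericMatrix out(N, n_steps + 1);
  for (int i = 0; i < N; ++i) out(i, 0) = x[i];
  bool divergent = false;
  int done = n_steps;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < N; ++i) ph[i] = phi_tl(x[i], gamma, phi_max);
    matvec_phi(pp, rr, vv, N, ph, y);
    double amax = 0.0;
    for (int i = 0; i < N; ++i) { x[i] = y[i]; amax = std::max(amax, std::fabs(x[i])); }
    for (int i = 0; i < N; ++i) out(i, step) = x[i];
    if (amax > 1e12) { divergent = true; done = step; break; }
  }
  if (done < n_steps) out = out(_, Range(0, done));
  return List::create(_["currents"] = out, _["divergent"] = divergent);
}
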