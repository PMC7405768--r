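#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <numeric>
using namespace Rcpp;

// Conductance-based integrate-and-fire network integrator.
//
// Normalized voltage: spikes at threshold 1 (E-cell thresholds adapt),
// reset to 0.  Membrane capacitance is 1, so conductances and currents are
// in units of s^-1.  Exponential-Euler update per step; synaptic events are
// queued at step resolution with per-class delays.  Mechanisms: I->E
// synaptic depression, E threshold adaptation, rate-indexed L6 feedback
// with synaptic failure and facilitation, ambient Poisson drive.
// All randomness comes from R's RNG (set.seed on the R side).
//
// Adjacency arrays are CSR with 0-based targets.
// [[Rcpp::export]]
List run_network_cpp(IntegerVector is_e,
                     IntegerVector adj_ptr, IntegerVector adj_tgt,
                     IntegerVector lgn_spike_step, IntegerVector lgn_spike_cell,
                     IntegerVector lgn_ptr, IntegerVector lgn_tgt,
                     IntegerVector l6_ptr, IntegerVector l6_tgt,
                     IntegerVector mem_ptr, IntegerVector mem_unit,
                     IntegerVector l6_member_n,
                     List par) {
  const int n = is_e.size();
  const int n_units = l6_ptr.size() - 1;
  const double dt_ms = as<double>(par["dt_ms"]);
  const double dt_s = dt_ms / 1000.0;
  const int n_steps = as<int>(par["n_steps"]);
  const double rec_start_ms = as<double>(par["rec_start_ms"]);
  const double g_leak = as<double>(par["g_leak"]);
  const double VE = as<double>(par["V_E"]), VI = as<double>(par["V_I"]);
  const double tau_e_s = as<double>(par["tau_e_ms"]) / 1000.0;
  const double tau_i_s = as<double>(par["tau_i_ms"]) / 1000.0;
  const int delay_e = std::max(1, (int)std::lround(as<double>(par["delay_e_ms"]) / dt_ms));
  const int delay_i = std::max(1, (int)std::lround(as<double>(par["delay_i_ms"]) / dt_ms));
  const int ref_e = std::max(1, (int)std::lround(as<double>(par["ref_e_ms"]) / dt_ms));
  const int ref_i = std::max(1, (int)std::lround(as<double>(par["ref_i_ms"]) / dt_ms));
  const double S_ee = as<double>(par["S_ee"]), S_ie = as<double>(par["S_ie"]);
  const double S_ei = as<double>(par["S_ei"]), S_ii = as<double>(par["S_ii"]);
  const double S_lgn_e = as<double>(par["S_lgn_e"]), S_lgn_i = as<double>(par["S_lgn_i"]);
  const double S_l6_e = as<double>(par["S_l6_e"]), S_l6_i = as<double>(par["S_l6_i"]);
  const double S_amb = as<double>(par["S_amb"]);
  const double amb_rate_e = as<double>(par["amb_rate_e"]);
  const double amb_rate_i = as<double>(par["amb_rate_i"]);
  const double dep_frac = as<double>(par["dep_frac"]);
  const double dep_tau_ms = as<double>(par["dep_tau_ms"]);
  const double thr_jump = as<double>(par["thr_jump"]);
  const double thr_tau_ms = as<double>(par["thr_tau_ms"]);
  const bool en_dep = as<bool>(par["enable_depression"]);
  const bool en_thr = as<bool>(par["enable_thr_adapt"]);
  const bool en_l6 = as<bool>(par["enable_l6"]) && n_units > 0;
  const double l6_floor = as<double>(par["l6_floor"]);
  const double l6_ceil = as<double>(par["l6_ceil"]);
  const double l6_mid = as<double>(par["l6_mid"]);
  const double l6_slope = as<double>(par["l6_slope"]);
  const double l6_fail = as<double>(par["l6_fail"]);
  const double l6_scale = as<double>(par["l6_scale"]);   // feedback knockdown
  const int l6_update = std::max(1, (int)std::lround(as<double>(par["l6_update_ms"]) / dt_ms));
  const int nbin = std::max(1, (int)std::lround(as<double>(par["l6_window_ms"]) /
                                                as<double>(par["l6_update_ms"])));
  const double l6_window_s = as<double>(par["l6_window_ms"]) / 1000.0;
  const bool record_cur = as<bool>(par["record_currents"]);
  NumericVector gE_const = par["gE_const"];   // length n or 1
  NumericVector gI_const = par["gI_const"];
  NumericVector v_init = par["v_init"];
  IntegerVector rec_v_ids = par["record_v_ids"];  // 1-based, may be empty

  const double de = std::exp(-dt_s / tau_e_s);
  const double di = std::exp(-dt_s / tau_i_s);
  const double dthr = std::exp(-dt_ms / thr_tau_ms);
  const double je = 1.0 / tau_e_s;  // conductance jump per unit weight
  const double ji = 1.0 / tau_i_s;

  std::vector<double> v(n), gLgn(n, 0), gRec(n, 0), gL6(n, 0), gAmb(n, 0), gI(n, 0);
  std::vector<double> thr_exc(n, 0), lastI(n, -1e12);
  std::vector<int> ref_until(n, -1);
  for (int i = 0; i < n; ++i)
    v[i] = v_init.size() == n ? v_init[i] : v_init[0];

  const int D = std::max(delay_e, delay_i) + 1;
  std::vector<double> pend_lgn((size_t)D * n, 0), pend_rec((size_t)D * n, 0),
      pend_l6((size_t)D * n, 0), pend_gI((size_t)D * n, 0);

  // L6 sliding-window spike counters
  std::vector<int> bin_counts(en_l6 ? (size_t)n_units * nbin : 0, 0);
  std::vector<int> win_total(en_l6 ? n_units : 0, 0);
  std::vector<double> l6_rate(en_l6 ? n_units : 0, l6_floor);
  std::vector<double> l6_fac(en_l6 ? n_units : 0, 1.0);
  int cur_bin = 0;

  std::vector<int> sp_n;
  std::vector<double> sp_t;
  sp_n.reserve(1 << 16);
  sp_t.reserve(1 << 16);

  std::vector<double> acc(record_cur ? (size_t)n * 6 : 0, 0.0);
  double acc_time = 0.0;

  std::vector<double> l6_rate_trace;
  const int n_rec_v = rec_v_ids.size();
  NumericMatrix vtrace(n_rec_v > 0 ? n_steps : 0, n_rec_v);

  int lgn_i = 0;
  const int n_lgn_ev = lgn_spike_step.size();
  RNGScope scope;

  for (int s = 0; s < n_steps; ++s) {
    const double t_ms = s * dt_ms;

    // LGN afferent events occurring at this step -> queue with E delay
    const int slot_e = (s + delay_e) % D;
    while (lgn_i < n_lgn_ev && lgn_spike_step[lgn_i] == s) {
      const int c = lgn_spike_cell[lgn_i];
      for (int k = lgn_ptr[c]; k < lgn_ptr[c + 1]; ++k) {
        const int j = lgn_tgt[k];
        pend_lgn[(size_t)slot_e * n + j] += (is_e[j] ? S_lgn_e : S_lgn_i) * je;
      }
      ++lgn_i;
    }

    if (en_l6) {
      // advance the sliding window and refresh unit rates every 5 ms
      if (s % l6_update == 0 && s > 0) {
        cur_bin = (cur_bin + 1) % nbin;
        for (int u = 0; u < n_units; ++u) {
          int* row = &bin_counts[(size_t)u * nbin];
          win_total[u] -= row[cur_bin];
          row[cur_bin] = 0;
          const double R = l6_member_n[u] > 0
            ? win_total[u] / (l6_member_n[u] * l6_window_s) : 0.0;
          const double rate = l6_floor + (l6_ceil - l6_floor) /
            (1.0 + std::exp(-(R - l6_mid) / l6_slope));
          l6_rate[u] = rate;
          const double rc = std::min(std::max(rate, 0.0), 90.0);
          l6_fac[u] = 1.0 + 0.1 * (rc - 30.0) / 30.0;
        }
        l6_rate_trace.push_back(
          std::accumulate(l6_rate.begin(), l6_rate.end(), 0.0) / n_units);
      }
      // unit spike emission and (non-failed) deliveries
      for (int u = 0; u < n_units; ++u) {
        if (unif_rand() < l6_rate[u] * dt_s) {
          const double wmul = l6_fac[u] * l6_scale;
          for (int k = l6_ptr[u]; k < l6_ptr[u + 1]; ++k) {
            if (unif_rand() < l6_fail) continue;
            const int j = l6_tgt[k];
            pend_l6[(size_t)slot_e * n + j] +=
              (is_e[j] ? S_l6_e : S_l6_i) * wmul * je;
          }
        }
      }
    }

    // decay conductances, apply this step's queued events + ambient
    const int slot = s % D;
    double* pl = &pend_lgn[(size_t)slot * n];
    double* pr = &pend_rec[(size_t)slot * n];
    double* p6 = &pend_l6[(size_t)slot * n];
    double* pi_ = &pend_gI[(size_t)slot * n];
    const bool rec_now = record_cur && t_ms >= rec_start_ms;
    if (rec_now) acc_time += dt_s;

    for (int i = 0; i < n; ++i) {
      gLgn[i] = gLgn[i] * de + pl[i];
      gRec[i] = gRec[i] * de + pr[i];
      gL6[i]  = gL6[i]  * de + p6[i];
      gI[i]   = gI[i]   * di + pi_[i];
      pl[i] = pr[i] = p6[i] = pi_[i] = 0.0;
      const double arate = is_e[i] ? amb_rate_e : amb_rate_i;
      double gA = gAmb[i] * de;
      if (arate > 0 && unif_rand() < arate * dt_s) gA += S_amb * je;
      gAmb[i] = gA;
      if (en_thr && is_e[i]) thr_exc[i] *= dthr;

      const double gEc = gE_const.size() == n ? gE_const[i] : gE_const[0];
      const double gIc = gI_const.size() == n ? gI_const[i] : gI_const[0];
      const double gE_tot = gLgn[i] + gRec[i] + gL6[i] + gA + gEc;
      const double gI_tot = gI[i] + gIc;

      if (s < ref_until[i]) {
        v[i] = 0.0;
      } else {
        const double G = g_leak + gE_tot + gI_tot;
        const double Vinf = (gE_tot * VE + gI_tot * VI) / G;
        v[i] = Vinf + (v[i] - Vinf) * std::exp(-G * dt_s);
        if (!std::isfinite(v[i]))
          stop("run_network_cpp: non-finite membrane potential in neuron %d at t = %.3f ms",
               i + 1, t_ms);
        const double thr = 1.0 + (is_e[i] ? thr_exc[i] : 0.0);
        if (v[i] >= thr) {
          sp_n.push_back(i + 1);
          sp_t.push_back(t_ms);
          v[i] = 0.0;
          ref_until[i] = s + (is_e[i] ? ref_e : ref_i);
          double w_to_e, w_to_i;
          int dly;
          double* pend;
          if (is_e[i]) {
            if (en_thr) thr_exc[i] += thr_jump;
            w_to_e = S_ee * je;
            w_to_i = S_ie * je;
            dly = delay_e;
            pend = &pend_rec[0];
            if (en_l6)
              for (int k = mem_ptr[i]; k < mem_ptr[i + 1]; ++k) {
                const int u = mem_unit[k];
                ++bin_counts[(size_t)u * nbin + cur_bin];
                ++win_total[u];
              }
          } else {
            double m = 1.0;
            if (en_dep)
              m = 1.0 - dep_frac * std::exp(-(t_ms - lastI[i]) / dep_tau_ms);
            lastI[i] = t_ms;
            w_to_e = S_ei * m * ji;
            w_to_i = S_ii * ji;
            dly = delay_i;
            pend = &pend_gI[0];
            if (en_l6)   // I spikes also count toward local L4 activity
              for (int k = mem_ptr[i]; k < mem_ptr[i + 1]; ++k) {
                const int u = mem_unit[k];
                ++bin_counts[(size_t)u * nbin + cur_bin];
                ++win_total[u];
              }
          }
          double* sl = pend + (size_t)((s + dly) % D) * n;
          for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
            const int j = adj_tgt[k];
            sl[j] += is_e[j] ? w_to_e : w_to_i;
          }
        }
      }

      if (rec_now) {
        double* a = &acc[(size_t)i * 6];
        const double vv = v[i];
        a[0] += gLgn[i] * (VE - vv) * dt_s;
        a[1] += gRec[i] * (VE - vv) * dt_s;
        a[2] += gL6[i] * (VE - vv) * dt_s;
        a[3] += (gA + gEc) * (VE - vv) * dt_s;
        a[4] += gI_tot * (VI - vv) * dt_s;
        a[5] += -g_leak * vv * dt_s;
      }
    }

    for (int k = 0; k < n_rec_v; ++k)
      vtrace(s, k) = v[rec_v_ids[k] - 1];
  }

  NumericMatrix currents(n, 6);
  if (record_cur && acc_time > 0)
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 6; ++c)
        currents(i, c) = acc[(size_t)i * 6 + c] / acc_time;
  colnames(currents) = CharacterVector::create("lgn", "l4e", "l6", "amb",
                                               "gaba", "leak");

  return List::create(
    _["spike_neuron"] = IntegerVector(sp_n.begin(), sp_n.end()),
    _["spike_t_ms"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["currents"] = currents,
    _["l6_rate_trace"] = NumericVector(l6_rate_trace.begin(), l6_rate_trace.end()),
    _["v_trace"] = vtrace);
}
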