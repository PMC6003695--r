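// Clock-driven integration engine for the LIF-SORN.
//
// One call advances the network by `duration_ms` at fixed step `dt`,
// handling: forward-Euler membrane integration with additive Gaussian
// noise, exponential conductance decay, axonal delay rings per connection
// class, short-term plasticity (per presynaptic excitatory neuron, applied
// at spike *arrival*), incremental nearest-neighbour STDP, once-per-second
// structural growth/pruning and synaptic normalization, per-step intrinsic
// plasticity, and inhomogeneous-Poisson external input from timed stimulus
// blocks. All times are absolute ms so state can be carried across calls.
//
// Update order within a step: (1) integrate membranes (+noise, +IP decay
// term), (2) detect spikes / reset / refractory, STDP potentiation,
// (3) enqueue deliveries, (4) apply due deliveries with STP factors and
// STDP depression, (5) external input, (6) once per simulated second:
// SP growth, SP pruning, then SN.

#include <Rcpp.h>
#include <random>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Csr {
  std::vector<int> ptr;  // size n+1
  std::vector<int> idx;  // synapse indices ordered by key neuron
  void build(const std::vector<int>& key, int n, size_t nsyn) {
    ptr.assign(n + 1, 0);
    idx.assign(nsyn, 0);
    for (size_t s = 0; s < nsyn; ++s) ptr[key[s] + 1]++;
    for (int i = 0; i < n; ++i) ptr[i + 1] += ptr[i];
    std::vector<int> cur(ptr.begin(), ptr.end() - 1);
    for (size_t s = 0; s < nsyn; ++s) idx[cur[key[s]]++] = (int)s;
  }
};

inline int64_t pair_key(int pre, int post, int n) {
  return (int64_t)pre * n + post;
}

}  // namespace

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(List state, NumericVector pos_x, NumericVector pos_y,
                List ee, List fixed_syn, List par, List mech,
                NumericMatrix stim, double duration_ms,
                NumericVector snapshot_times, IntegerVector cluster_id,
                int seed, bool record_spikes, IntegerVector v_record_ids) {
  // ---- parameters -------------------------------------------------------
  const int n_e = as<int>(par["n_e"]);
  const int n_i = as<int>(par["n_i"]);
  const int n = n_e + n_i;
  const double dt = as<double>(par["dt"]);
  const double E_L = as<double>(par["E_L"]), tau = as<double>(par["tau"]);
  const double E_e = as<double>(par["E_e"]), E_i = as<double>(par["E_i"]);
  const double tau_e = as<double>(par["tau_e"]), tau_i = as<double>(par["tau_i"]);
  const double sigma = as<double>(par["sigma"]);
  const double Vr_E = as<double>(par["V_reset_E"]), Vr_I = as<double>(par["V_reset_I"]);
  const int refrac_steps = as<int>(par["refrac_steps"]);
  const double eta_ip = as<double>(par["eta_ip"]);
  const double h_ip = as<double>(par["h_ip"]);  // target spikes per step
  const double U = as<double>(par["U"]);
  const double tau_f = as<double>(par["tau_f"]), tau_d = as<double>(par["tau_d"]);
  const double A_plus = as<double>(par["A_plus"]), A_minus = as<double>(par["A_minus"]);
  const double tau_plus = as<double>(par["tau_plus"]), tau_minus = as<double>(par["tau_minus"]);
  const int d_ee = as<int>(par["delay_ee_steps"]);
  const int d_ei = as<int>(par["delay_ei_steps"]);
  const int d_ie = as<int>(par["delay_ie_steps"]);
  const int d_ii = as<int>(par["delay_ii_steps"]);
  const double growth_mean = as<double>(par["growth_mean"]);
  const double growth_sd = as<double>(par["growth_sd"]);
  const double init_weight = as<double>(par["init_weight"]);
  const double prune_threshold = as<double>(par["prune_threshold"]);
  const double sigma_c = as<double>(par["sigma_c"]);
  const double n_input = as<double>(par["n_input"]);
  const double w_ff = as<double>(par["w_ff"]);
  const NumericVector w_total = as<NumericVector>(par["w_total"]);
  const int steps_per_sec = (int)std::lround(1000.0 / dt);

  const bool use_stdp = as<bool>(mech["stdp"]);
  const bool use_stp = as<bool>(mech["stp"]);
  const bool use_sn = as<bool>(mech["sn"]);
  const bool use_sp = as<bool>(mech["sp"]);
  const bool use_ip = as<bool>(mech["ip"]);
  const bool use_noise = as<bool>(mech["noise"]) && sigma > 0;

  // ---- state ------------------------------------------------------------
  std::vector<double> V = as<std::vector<double>>(state["V"]);
  std::vector<double> VT = as<std::vector<double>>(state["V_T"]);
  std::vector<double> ge = as<std::vector<double>>(state["g_e"]);
  std::vector<double> gi = as<std::vector<double>>(state["g_i"]);
  std::vector<double> gext = as<std::vector<double>>(state["g_ext"]);
  std::vector<int> refrac = as<std::vector<int>>(state["refrac"]);
  std::vector<double> u = as<std::vector<double>>(state["u"]);
  std::vector<double> xs = as<std::vector<double>>(state["x"]);
  std::vector<double> last_arr = as<std::vector<double>>(state["last_arr"]);
  std::vector<double> last_post = as<std::vector<double>>(state["last_post"]);
  const double t_begin = as<double>(state["time_ms"]);

  // ---- synapses ---------------------------------------------------------
  // EE dynamic (0-based internal; R passes 1-based)
  std::vector<int> ee_pre, ee_post;
  std::vector<double> ee_w;
  {
    IntegerVector p1 = ee["pre"], p2 = ee["post"];
    NumericVector w = ee["weight"];
    ee_pre.reserve(p1.size()); ee_post.reserve(p1.size()); ee_w.reserve(p1.size());
    for (int s = 0; s < p1.size(); ++s) {
      ee_pre.push_back(p1[s] - 1);
      ee_post.push_back(p2[s] - 1);
      ee_w.push_back(w[s]);
    }
  }
  std::unordered_set<int64_t> ee_set;
  ee_set.reserve(ee_pre.size() * 2 + 64);
  for (size_t s = 0; s < ee_pre.size(); ++s)
    ee_set.insert(pair_key(ee_pre[s], ee_post[s], n_e));
  Csr ee_out, ee_in;
  auto rebuild_ee = [&]() {
    ee_out.build(ee_pre, n_e, ee_pre.size());
    ee_in.build(ee_post, n_e, ee_post.size());
  };
  rebuild_ee();

  // fixed classes: EI (E->I, excitatory), IE, II (inhibitory)
  auto load_fixed = [&](const char* nm, std::vector<int>& pre,
                        std::vector<int>& post, std::vector<double>& w) {
    List cls = fixed_syn[nm];
    IntegerVector p1 = cls["pre"], p2 = cls["post"];
    NumericVector ww = cls["weight"];
    pre.assign(p1.begin(), p1.end());
    post.assign(p2.begin(), p2.end());
    for (auto& v : pre) v -= 1;
    for (auto& v : post) v -= 1;
    w.assign(ww.begin(), ww.end());
  };
  std::vector<int> ei_pre, ei_post, ie_pre, ie_post, ii_pre, ii_post;
  std::vector<double> ei_w, ie_w, ii_w;
  load_fixed("EI", ei_pre, ei_post, ei_w);
  load_fixed("IE", ie_pre, ie_post, ie_w);
  load_fixed("II", ii_pre, ii_post, ii_w);
  Csr ei_out, ie_out, ii_out;
  ei_out.build(ei_pre, n, ei_pre.size());
  ie_out.build(ie_pre, n, ie_pre.size());
  ii_out.build(ii_pre, n, ii_pre.size());

  // ---- delay rings ------------------------------------------------------
  const int ring_len = std::max(std::max(d_ee, d_ei), std::max(d_ie, d_ii)) + 1;
  std::vector<std::vector<int>> ring_ee(ring_len), ring_ei(ring_len),
      ring_ie(ring_len), ring_ii(ring_len);

  // ---- rng --------------------------------------------------------------
  std::mt19937_64 gen((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 1);
  std::normal_distribution<double> rnorm01(0.0, 1.0);
  std::poisson_distribution<int> rpois;
  std::uniform_real_distribution<double> runif01(0.0, 1.0);

  // ---- growth kernel (per-pre cumulative distance weights) --------------
  std::vector<double> kern_cum;      // n_e x n_e row cumsums
  std::vector<double> pre_cum;       // cumsum of row totals
  if (use_sp && n_e > 1) {
    kern_cum.resize((size_t)n_e * n_e);
    pre_cum.resize(n_e);
    double tot = 0.0;
    for (int m = 0; m < n_e; ++m) {
      double acc = 0.0;
      for (int q = 0; q < n_e; ++q) {
        if (q != m) {
          double dx = pos_x[m] - pos_x[q], dy = pos_y[m] - pos_y[q];
          acc += std::exp(-(dx * dx + dy * dy) / (2.0 * sigma_c * sigma_c));
        }
        kern_cum[(size_t)m * n_e + q] = acc;
      }
      tot += acc;
      pre_cum[m] = tot;
    }
  }

  // ---- stimulus blocks --------------------------------------------------
  const int n_blocks = stim.nrow();
  // columns: t0 t_end x0 y0 x1 y1 r_max alpha beta is_bar
  int first_pending = 0;
  std::vector<int> active;

  // ---- outputs ----------------------------------------------------------
  std::vector<double> sp_t;
  std::vector<int> sp_id;
  std::vector<double> tr_t, tr_cf, tr_meanw, tr_fwd, tr_bwd;
  std::vector<int> tr_ne, tr_ni;
  List snapshots;
  std::vector<double> snap_done_t;
  int next_snap = 0;
  NumericVector snap_sorted = clone(snapshot_times).sort();
  int sec_spikes_e = 0, sec_spikes_i = 0;

  const double noise_amp = sigma * std::sqrt(2.0 * dt / tau);
  const double dec_e = std::exp(-dt / tau_e);
  const double dec_i = std::exp(-dt / tau_i);
  const double dec_u = std::exp(-dt / tau_f);
  const double dec_x = std::exp(-dt / tau_d);

  const long n_steps = (long)std::lround(duration_ms / dt);
  const long step0 = (long)std::lround(t_begin / dt);
  NumericMatrix v_trace(v_record_ids.size() > 0 ? n_steps : 0,
                        v_record_ids.size());
  std::vector<int> spiked_now;
  spiked_now.reserve(256);

  const int max_clu = 9;  // cluster labels 1..8 (0 = none)
  bool have_clusters = cluster_id.size() == n_e;

  for (long k = 0; k < n_steps; ++k) {
    const long abs_step = step0 + k;
    const double t_now = (abs_step + 1) * dt;  // time at end of this step
    const int slot = (int)(abs_step % ring_len);

    // (1) integrate membranes
    for (int i = 0; i < n; ++i) {
      if (refrac[i] > 0) continue;
      double v = V[i];
      double dv = -(v - E_L) - (ge[i] + gext[i]) * (v - E_e) - gi[i] * (v - E_i);
      v += dv * dt / tau;
      if (use_noise) v += noise_amp * rnorm01(gen);
      V[i] = v;
    }
    // conductance decay (exact exponential)
    for (int i = 0; i < n; ++i) {
      ge[i] *= dec_e;
      gext[i] *= dec_e;
      gi[i] *= dec_i;
    }
    // STP relaxation
    if (use_stp) {
      for (int m = 0; m < n_e; ++m) {
        u[m] = U + (u[m] - U) * dec_u;
        xs[m] = 1.0 + (xs[m] - 1.0) * dec_x;
      }
    }

    // (2) spike detection / reset; STDP potentiation; (3) enqueue
    spiked_now.clear();
    for (int i = 0; i < n; ++i) {
      if (refrac[i] > 0) {
        refrac[i]--;
        V[i] = (i < n_e) ? Vr_E : Vr_I;
        continue;
      }
      if (V[i] >= VT[i]) {
        spiked_now.push_back(i);
        refrac[i] = refrac_steps;
        if (i < n_e) {
          V[i] = Vr_E;
          sec_spikes_e++;
          if (record_spikes) { sp_t.push_back(t_now); sp_id.push_back(i + 1); }
          if (use_stdp) {
            for (int s = ee_in.ptr[i]; s < ee_in.ptr[i + 1]; ++s) {
              int j = ee_in.idx[s];
              double dtv = t_now - last_arr[ee_pre[j]];
              if (std::isfinite(dtv) && dtv > 0) {
                double w2 = ee_w[j] + A_plus * std::exp(-dtv / tau_plus);
                ee_w[j] = w2 > 0 ? w2 : 0.0;
              }
            }
          }
          last_post[i] = t_now;
          ring_ee[(slot + d_ee) % ring_len].push_back(i);
          ring_ei[(slot + d_ei) % ring_len].push_back(i);
        } else {
          V[i] = Vr_I;
          sec_spikes_i++;
          if (record_spikes) { sp_t.push_back(t_now); sp_id.push_back(i + 1); }
          ring_ie[(slot + d_ie) % ring_len].push_back(i);
          ring_ii[(slot + d_ii) % ring_len].push_back(i);
        }
      }
    }
    // intrinsic plasticity (every step, every excitatory neuron)
    if (use_ip) {
      for (int i = 0; i < n_e; ++i) VT[i] -= eta_ip * h_ip;
      for (int i : spiked_now)
        if (i < n_e) VT[i] += eta_ip;
    }

    // membrane traces (end-of-step values)
    for (int c = 0; c < v_record_ids.size(); ++c)
      v_trace(k, c) = V[v_record_ids[c] - 1];

    // (4) due deliveries (this step's slot)
    for (int m : ring_ee[slot]) {
      double u_pre = use_stp ? u[m] : 1.0;
      double x_pre = use_stp ? xs[m] : 1.0;
      double eff = u_pre * x_pre;
      for (int s = ee_out.ptr[m]; s < ee_out.ptr[m + 1]; ++s) {
        int j = ee_out.idx[s];
        ge[ee_post[j]] += ee_w[j] * eff;
        if (use_stdp) {
          double dtv = last_post[ee_post[j]] - t_now;
          if (std::isfinite(dtv) && dtv < 0) {
            double w2 = ee_w[j] + A_minus * std::exp(dtv / tau_minus);
            ee_w[j] = w2 > 0 ? w2 : 0.0;
          }
        }
      }
      if (use_stp) {
        u[m] = u_pre + U * (1.0 - u_pre);
        xs[m] = x_pre - x_pre * u_pre;
      }
      last_arr[m] = t_now;
    }
    ring_ee[slot].clear();
    for (int m : ring_ei[slot])
      for (int s = ei_out.ptr[m]; s < ei_out.ptr[m + 1]; ++s)
        ge[ei_post[ei_out.idx[s]]] += ei_w[ei_out.idx[s]];
    ring_ei[slot].clear();
    for (int m : ring_ie[slot])
      for (int s = ie_out.ptr[m]; s < ie_out.ptr[m + 1]; ++s)
        gi[ie_post[ie_out.idx[s]]] += ie_w[ie_out.idx[s]];
    ring_ie[slot].clear();
    for (int m : ring_ii[slot])
      for (int s = ii_out.ptr[m]; s < ii_out.ptr[m + 1]; ++s)
        gi[ii_post[ii_out.idx[s]]] += ii_w[ii_out.idx[s]];
    ring_ii[slot].clear();

    // (5) external input
    if (n_blocks > 0) {
      double t_mid = abs_step * dt;  // stimulus evaluated at step start
      while (first_pending < n_blocks && stim(first_pending, 0) <= t_mid) {
        active.push_back(first_pending);
        first_pending++;
      }
      for (size_t a = 0; a < active.size();) {
        if (stim(active[a], 1) < t_mid) {
          active.erase(active.begin() + a);
        } else {
          ++a;
        }
      }
      for (int b : active) {
        double bt0 = stim(b, 0), bt1 = stim(b, 1);
        double x0 = stim(b, 2), y0 = stim(b, 3), x1 = stim(b, 4), y1 = stim(b, 5);
        double rmax = stim(b, 6), alpha = stim(b, 7), beta = stim(b, 8);
        bool is_bar = stim(b, 9) > 0.5;
        double cut = alpha * std::pow(34.5, 1.0 / beta);  // rate < 1e-15*rmax
        double cut2 = cut * cut;
        double ux, uy, vx = 0, vy = 0, len2 = 0;
        if (is_bar) {
          vx = x1 - x0; vy = y1 - y0; len2 = vx * vx + vy * vy;
          ux = x0; uy = y0;
        } else {
          double frac = bt1 > bt0 ? (t_mid - bt0) / (bt1 - bt0) : 0.0;
          ux = x0 + (x1 - x0) * frac;
          uy = y0 + (y1 - y0) * frac;
        }
        double mean_fac = n_input * rmax * dt / 1000.0;
        for (int i = 0; i < n_e; ++i) {
          double d2;
          if (is_bar && len2 > 0) {
            double tt = ((pos_x[i] - x0) * vx + (pos_y[i] - y0) * vy) / len2;
            tt = tt < 0 ? 0 : (tt > 1 ? 1 : tt);
            double dx = pos_x[i] - x0 - tt * vx, dy = pos_y[i] - y0 - tt * vy;
            d2 = dx * dx + dy * dy;
          } else {
            double dx = pos_x[i] - ux, dy = pos_y[i] - uy;
            d2 = dx * dx + dy * dy;
          }
          if (d2 > cut2) continue;
          double mean = mean_fac * std::exp(-std::pow(std::sqrt(d2) / alpha, beta));
          if (mean <= 0) continue;
          int cnt = rpois(gen, std::poisson_distribution<int>::param_type(mean));
          if (cnt > 0) gext[i] += w_ff * cnt;
        }
      }
    }

    // (6) once per simulated second: SP growth, SP prune, then SN
    if ((abs_step + 1) % steps_per_sec == 0) {
      // sanity: abort on non-finite state
      double chk = 0;
      for (int i = 0; i < n; ++i) chk += V[i];
      if (!std::isfinite(chk))
        stop("non-finite membrane potential at t = %.1f ms", t_now);

      bool structure_changed = false;
      if (use_sp && n_e > 1) {
        // growth: n_new candidate pairs drawn from the distance kernel over
        // all ordered pairs; candidates that already exist yield nothing.
        // This self-limits growth as each neuron's kernel neighbourhood
        // saturates, which is what makes the connection fraction settle at
        // the kernel's effective volume fraction (~0.1 at full scale).
        double draw = growth_mean + growth_sd * rnorm01(gen);
        long n_new = (long)std::llround(draw);
        if (n_new < 0) n_new = 0;
        long added = 0;
        double tot = pre_cum[n_e - 1];
        for (long c = 0; c < n_new; ++c) {
          double r1 = runif01(gen) * tot;
          int m = (int)(std::lower_bound(pre_cum.begin(), pre_cum.end(), r1) -
                        pre_cum.begin());
          if (m >= n_e) m = n_e - 1;
          const double* row = &kern_cum[(size_t)m * n_e];
          double r2 = runif01(gen) * row[n_e - 1];
          int q = (int)(std::lower_bound(row, row + n_e, r2) - row);
          if (q >= n_e) q = n_e - 1;
          if (q == m) continue;
          int64_t key = pair_key(m, q, n_e);
          if (ee_set.count(key)) continue;
          ee_set.insert(key);
          ee_pre.push_back(m);
          ee_post.push_back(q);
          ee_w.push_back(init_weight);
          added++;
        }
        if (added > 0) structure_changed = true;
        // prune (strict <)
        size_t keep = 0;
        for (size_t s = 0; s < ee_pre.size(); ++s) {
          if (ee_w[s] >= prune_threshold) {
            ee_pre[keep] = ee_pre[s];
            ee_post[keep] = ee_post[s];
            ee_w[keep] = ee_w[s];
            keep++;
          } else {
            ee_set.erase(pair_key(ee_pre[s], ee_post[s], n_e));
            structure_changed = true;
          }
        }
        ee_pre.resize(keep); ee_post.resize(keep); ee_w.resize(keep);
        if (structure_changed) rebuild_ee();
      }
      if (use_sn && !ee_pre.empty()) {
        for (int i = 0; i < n_e; ++i) {
          double sum = 0;
          for (int s = ee_in.ptr[i]; s < ee_in.ptr[i + 1]; ++s)
            sum += ee_w[ee_in.idx[s]];
          if (sum > 0) {
            double f = w_total[i] / sum;
            for (int s = ee_in.ptr[i]; s < ee_in.ptr[i + 1]; ++s)
              ee_w[ee_in.idx[s]] *= f;
          }
        }
      }
      // per-second trace
      tr_t.push_back(t_now);
      double cf = n_e > 1 ? (double)ee_pre.size() / ((double)n_e * (n_e - 1)) : 0;
      tr_cf.push_back(cf);
      double wsum = 0;
      for (double w : ee_w) wsum += w;
      tr_meanw.push_back(ee_w.empty() ? 0 : wsum / ee_w.size());
      if (have_clusters) {
        std::vector<double> fsum(max_clu, 0), bsum(max_clu, 0);
        std::vector<int> fcnt(max_clu, 0), bcnt(max_clu, 0);
        for (size_t s = 0; s < ee_pre.size(); ++s) {
          int c1 = cluster_id[ee_pre[s]], c2 = cluster_id[ee_post[s]];
          if (c1 > 0 && c2 > 0) {
            if (c2 == c1 + 1) { fsum[c1] += ee_w[s]; fcnt[c1]++; }
            else if (c2 == c1 - 1) { bsum[c2] += ee_w[s]; bcnt[c2]++; }
          }
        }
        double fm = 0, bm = 0; int fn = 0, bn = 0;
        for (int c = 1; c < max_clu; ++c) {
          if (fcnt[c] > 0) { fm += fsum[c] / fcnt[c]; fn++; }
          if (bcnt[c] > 0) { bm += bsum[c] / bcnt[c]; bn++; }
        }
        tr_fwd.push_back(fn > 0 ? fm / fn : NA_REAL);
        tr_bwd.push_back(bn > 0 ? bm / bn : NA_REAL);
      } else {
        tr_fwd.push_back(NA_REAL);
        tr_bwd.push_back(NA_REAL);
      }
      tr_ne.push_back(sec_spikes_e);
      tr_ni.push_back(sec_spikes_i);
      sec_spikes_e = 0;
      sec_spikes_i = 0;
    }

    // weight snapshots
    while (next_snap < snap_sorted.size() && snap_sorted[next_snap] <= t_now + 1e-9) {
      IntegerVector sp1(ee_pre.size()), sp2(ee_pre.size());
      NumericVector sw(ee_pre.size());
      for (size_t s = 0; s < ee_pre.size(); ++s) {
        sp1[s] = ee_pre[s] + 1;
        sp2[s] = ee_post[s] + 1;
        sw[s] = ee_w[s];
      }
      snapshots.push_back(List::create(_["time_ms"] = snap_sorted[next_snap],
                                       _["pre"] = sp1, _["post"] = sp2,
                                       _["weight"] = sw));
      snap_done_t.push_back(snap_sorted[next_snap]);
      next_snap++;
    }
  }

  // ---- pack results -----------------------------------------------------
  IntegerVector out_pre(ee_pre.size()), out_post(ee_pre.size());
  NumericVector out_w(ee_pre.size());
  for (size_t s = 0; s < ee_pre.size(); ++s) {
    out_pre[s] = ee_pre[s] + 1;
    out_post[s] = ee_post[s] + 1;
    out_w[s] = ee_w[s];
  }
  List out_state = List::create(
      _["V"] = V, _["V_T"] = VT, _["g_e"] = ge, _["g_i"] = gi,
      _["g_ext"] = gext, _["refrac"] = refrac, _["u"] = u, _["x"] = xs,
      _["last_arr"] = last_arr, _["last_post"] = last_post,
      _["time_ms"] = t_begin + duration_ms);
  return List::create(
      _["state"] = out_state,
      _["ee"] = List::create(_["pre"] = out_pre, _["post"] = out_post,
                             _["weight"] = out_w),
      _["spike_t"] = sp_t, _["spike_id"] = sp_id,
      _["trace"] = List::create(_["time_ms"] = tr_t, _["cf"] = tr_cf,
                                _["mean_weight"] = tr_meanw,
                                _["fwd_weight"] = tr_fwd,
                                _["bwd_weight"] = tr_bwd,
                                _["spikes_exc"] = tr_ne,
                                _["spikes_inh"] = tr_ni),
      _["snapshots"] = snapshots, _["v_trace"] = v_trace);
}
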