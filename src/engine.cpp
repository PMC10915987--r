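// Time-stepped network integrator.
//
// Gating variables advance by exponential (Rush-Larsen) updates using
// voltage tables precomputed in R from the channel catalog; membrane
// voltages advance by a semi-implicit step (conductances frozen over the
// step, linear solve per compartment pair). Synaptic conductances are
// aggregated per (target neuron, receptor) as bi-exponential states with
// latency-delayed spike deliveries on a dt-quantized ring buffer.
//
// Units: mV, ms, S/cm^2 (densities), uS (point conductances), nA (point
// currents), mA/cm^2 (current densities), mM, uF/cm^2.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>

using namespace Rcpp;

namespace {

struct GateVar {
  int power;
  int kind;   // 0 voltage, 1 calcium, 2 sodium
  int form;   // ion-gated functional form code
  double c0, c1, c2;
  std::vector<double> inf, edt;  // voltage tables
};

struct Variant {
  double erev;
  int ion_source;    // 0 none, 1 Ca, 2 Na
  std::vector<GateVar> vars;
};

inline double powi(double x, int p) {
  switch (p) {
    case 1: return x;
    case 2: return x * x;
    case 3: return x * x * x;
    case 4: { double x2 = x * x; return x2 * x2; }
    default: return std::pow(x, p);
  }
}

struct Delivery { int slot; double w; };

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List model) {
  const double dt = as<double>(model["dt"]);
  const long n_steps = (long)as<double>(model["n_steps"]);
  const int stride = as<int>(model["record_stride"]);
  const double v_abort = 200.0;

  IntegerVector pop_id = model["pop_id"];
  IntegerVector ncomp = model["ncomp"];
  NumericVector area = model["area"];   // length 2n
  NumericVector cm = model["cm"];       // length 2n
  NumericVector v_init = model["v0"];   // length 2n
  NumericVector gc = model["g_c"];      // per neuron, uS
  const int n = pop_id.size();
  const int npop = as<int>(model["n_pop"]);

  IntegerVector chan_ptr = model["chan_ptr"];       // length 2n+1
  IntegerVector chan_var = model["chan_var"];
  IntegerVector chan_code = model["chan_code"];
  NumericVector chan_gmax = model["chan_gmax"];
  const int n_chan = chan_var.size();

  List var_list = model["variants"];
  const double vg0 = as<double>(model["vgrid0"]);
  const double dvg = as<double>(model["vgrid_step"]);
  const int nvg = as<int>(model["vgrid_n"]);
  std::vector<Variant> variants(var_list.size());
  for (int i = 0; i < var_list.size(); ++i) {
    List v = var_list[i];
    variants[i].erev = as<double>(v["erev"]);
    variants[i].ion_source = as<int>(v["ion_source"]);
    List vars = v["vars"];
    for (int j = 0; j < vars.size(); ++j) {
      List vv = vars[j];
      GateVar g;
      g.power = as<int>(vv["power"]);
      g.kind = as<int>(vv["kind"]);
      g.form = as<int>(vv["form"]);
      NumericVector coef = vv["coef"];
      g.c0 = coef.size() > 0 ? coef[0] : 0;
      g.c1 = coef.size() > 1 ? coef[1] : 0;
      g.c2 = coef.size() > 2 ? coef[2] : 0;
      if (g.kind == 0) {
        g.inf = as<std::vector<double>>(vv["inf"]);
        g.edt = as<std::vector<double>>(vv["edt"]);
      }
      variants[i].vars.push_back(g);
    }
  }
  const int n_codes = as<int>(model["n_codes"]);

  NumericVector ca_rest = model["ca_rest"], ca_phi = model["ca_phi"],
                ca_tau = model["ca_tau"];
  NumericVector na_rest = model["na_rest"], na_phi = model["na_phi"],
                na_tau = model["na_tau"];
  LogicalVector has_ca = model["has_ca"], has_na = model["has_na"];
  NumericVector ca0 = model["ca0"], na0 = model["na0"];

  NumericMatrix syn_er (as<NumericMatrix>(model["syn_e"]));        // npop x 4
  NumericMatrix syn_edr(as<NumericMatrix>(model["syn_edecay_r"]));
  NumericMatrix syn_edd(as<NumericMatrix>(model["syn_edecay_d"]));
  NumericMatrix syn_norm(as<NumericMatrix>(model["syn_norm"]));
  IntegerVector e_src = model["edge_src"], e_tgt = model["edge_tgt"],
                e_rec = model["edge_rec"], e_del = model["edge_delay"];
  NumericVector e_w = model["edge_w"];
  const int n_edge = e_src.size();
  NumericVector wgb_tot = model["gabab_wtot"];  // per neuron, uS
  const double gb_k3 = as<double>(model["gb_k3"]);
  const double gb_k4 = as<double>(model["gb_k4"]);
  const double gb_kd = as<double>(model["gb_kd"]);

  std::vector<int> src_ptr(n + 1, 0);
  for (int e = 0; e < n_edge; ++e) src_ptr[e_src[e] + 1]++;
  for (int i = 0; i < n; ++i) src_ptr[i + 1] += src_ptr[i];
  std::vector<int> src_edge(n_edge);
  { std::vector<int> fill(src_ptr.begin(), src_ptr.end() - 1);
    for (int e = 0; e < n_edge; ++e) src_edge[fill[e_src[e]]++] = e; }

  IntegerVector gj_i = model["gj_i"], gj_j = model["gj_j"];
  NumericVector gj_g = model["gj_g"];
  const int n_gj = gj_i.size();

  IntegerVector inj_neuron = model["inj_neuron"], inj_comp = model["inj_comp"];
  NumericVector inj_t0 = model["inj_t0"], inj_t1 = model["inj_t1"],
                inj_amp = model["inj_amp"];
  const int n_inj = inj_neuron.size();

  NumericVector pert_t = model["pert_t"];
  IntegerVector pert_kind = model["pert_kind"], pert_pop = model["pert_pop"],
                pert_code = model["pert_code"];
  NumericVector pert_fac = model["pert_factor"];
  const int n_pert = pert_t.size();

  IntegerVector rec_v_ids = model["record_v"];  // compartment idx (0-based)
  IntegerVector rec_dip_ids = model["record_dipole"]; // 2-comp neuron ids
  IntegerVector rec_cur_ids = model["record_currents"];
  const int n_rec_v = rec_v_ids.size();
  const int n_rec_d = rec_dip_ids.size();
  const int n_rec_c = rec_cur_ids.size();
  const long n_rec_t = n_steps / stride;

  NumericMatrix out_v(n_rec_t, n_rec_v);
  NumericMatrix out_dip(n_rec_t, n_rec_d);

  // channel -> compartment index map, and current-recording columns
  std::vector<int> chan_comp(n_chan);
  for (int idx = 0; idx < 2 * n; ++idx)
    for (int k = chan_ptr[idx]; k < chan_ptr[idx + 1]; ++k) chan_comp[k] = idx;
  std::vector<std::vector<int>> cur_chan_idx(n_rec_c);
  int total_cur_cols = 0;
  for (int r = 0; r < n_rec_c; ++r) {
    int i = rec_cur_ids[r];
    for (int c = 0; c < ncomp[i]; ++c)
      for (int k = chan_ptr[2 * i + c]; k < chan_ptr[2 * i + c + 1]; ++k)
        cur_chan_idx[r].push_back(k);
    total_cur_cols += (int)cur_chan_idx[r].size();
  }
  NumericMatrix out_cur(n_rec_c > 0 ? n_rec_t : 0, total_cur_cols);

  // ---- state ----
  std::vector<double> v(2 * n);
  for (int i = 0; i < 2 * n; ++i) v[i] = v_init[i];
  std::vector<double> ca(2 * n), nai(2 * n);
  for (int i = 0; i < 2 * n; ++i) {
    ca[i] = ca0.size() == 2 * n ? ca0[i] : ca_rest[i];
    nai[i] = na0.size() == 2 * n ? na0[i] : na_rest[i];
  }

  std::vector<int> gate_ptr(n_chan + 1, 0);
  for (int k = 0; k < n_chan; ++k)
    gate_ptr[k + 1] = gate_ptr[k] + (int)variants[chan_var[k]].vars.size();
  std::vector<double> gate(gate_ptr[n_chan]);
  for (int k = 0; k < n_chan; ++k) {
    const int idx = chan_comp[k];
    const double V = v[idx];
    int gi = (int)((V - vg0) / dvg);
    if (gi < 0) gi = 0;
    if (gi > nvg - 2) gi = nvg - 2;
    const double fr = (V - (vg0 + gi * dvg)) / dvg;
    const Variant& vt = variants[chan_var[k]];
    for (size_t j = 0; j < vt.vars.size(); ++j) {
      const GateVar& gv = vt.vars[j];
      double x;
      if (gv.kind == 0) {
        x = gv.inf[gi] * (1 - fr) + gv.inf[gi + 1] * fr;
      } else {
        const double ion = (gv.kind == 1) ? ca[idx] : nai[idx];
        if (gv.form == 1) { const double a = gv.c0 * ion * ion; x = a / (a + gv.c1); }
        else if (gv.form == 2) x = gv.c0 / (1 + std::pow(gv.c1 / ion, gv.c2));
        else { const double i2 = ion * ion; x = i2 / (i2 + gv.c0 * gv.c0); }
      }
      gate[gate_ptr[k] + j] = x;
    }
  }

  std::vector<double> syn_a(4 * n, 0.0), syn_b(4 * n, 0.0);
  std::vector<double> gb_g(n, 0.0);

  std::vector<double> chan_mult(npop * n_codes, 1.0);
  std::vector<double> rec_mult(npop * 4, 1.0);

  int max_del = 1;
  for (int e = 0; e < n_edge; ++e) if (e_del[e] > max_del) max_del = e_del[e];
  const int ring_len = max_del + 2;
  std::vector<std::vector<Delivery>> ring(ring_len);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector<long> last_spike(n, -1000000);
  const int refr_steps = std::max(1, (int)std::lround(1.0 / dt));

  std::vector<double> i_point(2 * n);
  std::string abort_msg;
  int pert_next = 0;

  for (long step = 0; step < n_steps && abort_msg.empty(); ++step) {
    const double t = step * dt;
    const bool do_rec = (step % stride == 0) && (step / stride) < n_rec_t;
    const long rec_row = step / stride;

    while (pert_next < n_pert && pert_t[pert_next] <= t + 1e-9) {
      const int kind = pert_kind[pert_next], code = pert_code[pert_next],
                pp = pert_pop[pert_next];
      const double f = pert_fac[pert_next];
      for (int p = 0; p < npop; ++p) {
        if (pp >= 0 && p != pp) continue;
        if (kind == 0) chan_mult[p * n_codes + code] = f;
        else rec_mult[p * 4 + code] = f;
      }
      ++pert_next;
    }

    {
      std::vector<Delivery>& due = ring[step % ring_len];
      for (size_t q = 0; q < due.size(); ++q) {
        syn_a[due[q].slot] += due[q].w;
        syn_b[due[q].slot] += due[q].w;
      }
      due.clear();
    }

    std::fill(i_point.begin(), i_point.end(), 0.0);
    for (int q = 0; q < n_gj; ++q) {
      const double cur = gj_g[q] * (v[2 * gj_j[q]] - v[2 * gj_i[q]]);
      i_point[2 * gj_i[q]] += cur;
      i_point[2 * gj_j[q]] -= cur;
    }
    for (int q = 0; q < n_inj; ++q) {
      if (t >= inj_t0[q] && t < inj_t1[q])
        i_point[2 * inj_neuron[q] + inj_comp[q]] += inj_amp[q];
    }

    for (int i = 0; i < n; ++i) {
      const int nc = ncomp[i];
      const int p = pop_id[i];
      double Gd[2] = {0, 0}, GEd[2] = {0, 0};
      double i_ca[2] = {0, 0}, i_na[2] = {0, 0};

      for (int c = 0; c < nc; ++c) {
        const int idx = 2 * i + c;
        const double V = v[idx];
        int gi = (int)((V - vg0) / dvg);
        if (gi < 0) gi = 0;
        if (gi > nvg - 2) gi = nvg - 2;
        const double fr = (V - (vg0 + gi * dvg)) / dvg;

        for (int k = chan_ptr[idx]; k < chan_ptr[idx + 1]; ++k) {
          const Variant& vt = variants[chan_var[k]];
          double open = 1.0;
          const int gp = gate_ptr[k];
          for (size_t j = 0; j < vt.vars.size(); ++j) {
            const GateVar& gv = vt.vars[j];
            double x = gate[gp + j];
            if (gv.kind == 0) {
              const double xinf = gv.inf[gi] * (1 - fr) + gv.inf[gi + 1] * fr;
              const double ed = gv.edt[gi] * (1 - fr) + gv.edt[gi + 1] * fr;
              x = xinf + (x - xinf) * ed;
            } else {
              const double ion = (gv.kind == 1) ? ca[idx] : nai[idx];
              double xinf, tau;
              if (gv.form == 1) {
                const double a = gv.c0 * ion * ion;
                xinf = a / (a + gv.c1);
                tau = 1.0 / (a + gv.c1); if (tau < gv.c2) tau = gv.c2;
              } else if (gv.form == 2) {
                xinf = gv.c0 / (1 + std::pow(gv.c1 / ion, gv.c2));
                tau = 1.0;
              } else {
                const double i2 = ion * ion;
                xinf = i2 / (i2 + gv.c0 * gv.c0);
                tau = gv.c1 / (1 + i2 / (gv.c0 * gv.c0));
                if (tau < gv.c2) tau = gv.c2;
              }
              x = xinf + (x - xinf) * std::exp(-dt / tau);
            }
            if (x < 0) x = 0; else if (x > 1) x = 1;
            gate[gp + j] = x;
            open *= powi(x, gv.power);
          }
          const double geff = chan_gmax[k] * open *
            chan_mult[p * n_codes + chan_code[k]];
          Gd[c] += geff;
          GEd[c] += geff * vt.erev;
          if (vt.ion_source == 1) i_ca[c] += geff * (V - vt.erev);
          else if (vt.ion_source == 2) i_na[c] += geff * (V - vt.erev);
        }
      }

      // synapses: excitatory onto the dendritic (last) compartment,
      // inhibitory onto the somatic compartment
      double Gp[2] = {0, 0}, GpE[2] = {0, 0};
      {
        const int cd = nc - 1;
        for (int r = 0; r < 4; ++r) {
          const int slot = 4 * i + r;
          syn_a[slot] *= syn_edr(p, r);
          syn_b[slot] *= syn_edd(p, r);
          double g = syn_norm(p, r) * (syn_b[slot] - syn_a[slot]);
          if (g < 0) g = 0;
          const int c = (r <= 1) ? cd : 0;
          double geff;
          if (r == 3) {
            const double wt = wgb_tot[i];
            const double s = wt > 0 ? g / wt : 0.0;
            double G = gb_g[i];
            G += dt * (gb_k3 * s - gb_k4 * G);
            if (G < 0) G = 0;
            gb_g[i] = G;
            const double G4 = G * G * G * G;
            geff = wt * G4 / (G4 + gb_kd) * rec_mult[p * 4 + r];
          } else if (r == 1) {
            const double B =
              1.0 / (1.0 + 0.278 * std::exp(-0.062 * v[2 * i + c]));
            geff = g * B * rec_mult[p * 4 + r];
          } else {
            geff = g * rec_mult[p * 4 + r];
          }
          Gp[c] += geff;
          GpE[c] += geff * syn_er(p, r);
        }
      }

      const double vs_old = v[2 * i];

      if (nc == 1) {
        const int idx = 2 * i;
        const double kpt = 1e-6 / area[idx];
        const double G = Gd[0] + Gp[0] * kpt;
        const double GE = GEd[0] + (GpE[0] + i_point[idx]) * kpt;
        const double k = dt * 1e3 / cm[idx];  // S/cm^2 * mV / (uF/cm^2) = V/s
        v[idx] = (v[idx] + k * GE) / (1 + k * G);
      } else {
        const int is = 2 * i, id = 2 * i + 1;
        const double kpts = 1e-6 / area[is], kptd = 1e-6 / area[id];
        const double gcs = gc[i] * kpts, gcd = gc[i] * kptd;
        const double Gs = Gd[0] + Gp[0] * kpts, Gdd = Gd[1] + Gp[1] * kptd;
        const double Bs = GEd[0] + (GpE[0] + i_point[is]) * kpts;
        const double Bd = GEd[1] + (GpE[1] + i_point[id]) * kptd;
        const double ks = dt * 1e3 / cm[is], kd = dt * 1e3 / cm[id];
        const double a11 = 1 + ks * (Gs + gcs), a12 = -ks * gcs;
        const double a21 = -kd * gcd, a22 = 1 + kd * (Gdd + gcd);
        const double r1 = v[is] + ks * Bs, r2 = v[id] + kd * Bd;
        const double det = a11 * a22 - a12 * a21;
        v[is] = (r1 * a22 - a12 * r2) / det;
        v[id] = (a11 * r2 - a21 * r1) / det;
      }

      for (int c = 0; c < nc; ++c) {
        const int idx = 2 * i + c;
        if (has_ca[idx]) {
          const double infl = -ca_phi[idx] * std::min(i_ca[c], 0.0);
          const double targ = ca_rest[idx] + infl * ca_tau[idx];
          const double a = std::exp(-dt / ca_tau[idx]);
          const double cc = targ + (ca[idx] - targ) * a;
          ca[idx] = cc > ca_rest[idx] ? cc : ca_rest[idx];
        }
        if (has_na[idx]) {
          const double infl = -na_phi[idx] * std::min(i_na[c], 0.0);
          const double targ = na_rest[idx] + infl * na_tau[idx];
          const double a = std::exp(-dt / na_tau[idx]);
          const double cc = targ + (nai[idx] - targ) * a;
          nai[idx] = cc > na_rest[idx] ? cc : na_rest[idx];
        }
      }

      // spike: upward crossing of 0 mV on the somatic compartment,
      // 1 ms refractory latch
      if (vs_old < 0.0 && v[2 * i] >= 0.0 &&
          step - last_spike[i] > refr_steps) {
        last_spike[i] = step;
        spike_id.push_back(i + 1);
        spike_t.push_back(t + dt);
        for (int q = src_ptr[i]; q < src_ptr[i + 1]; ++q) {
          const int e = src_edge[q];
          ring[(step + e_del[e]) % ring_len].push_back(
            Delivery{4 * e_tgt[e] + e_rec[e], e_w[e]});
        }
      }

      if (std::abs(v[2 * i]) > v_abort || std::isnan(v[2 * i]) ||
          (nc == 2 && (std::abs(v[2 * i + 1]) > v_abort ||
                       std::isnan(v[2 * i + 1])))) {
        abort_msg = "instability: neuron " + std::to_string(i + 1) +
          " at t=" + std::to_string(t) + " ms";
      }
    }

    if (do_rec && abort_msg.empty()) {
      for (int r = 0; r < n_rec_v; ++r)
        out_v(rec_row, r) = v[rec_v_ids[r]];
      for (int r = 0; r < n_rec_d; ++r) {
        const int i = rec_dip_ids[r];
        out_dip(rec_row, r) = gc[i] * (v[2 * i + 1] - v[2 * i]);
      }
      int col = 0;
      for (int r = 0; r < n_rec_c; ++r) {
        for (size_t q = 0; q < cur_chan_idx[r].size(); ++q) {
          const int k = cur_chan_idx[r][q];
          const int idx = chan_comp[k];
          const Variant& vt = variants[chan_var[k]];
          double open = 1.0;
          for (size_t j = 0; j < vt.vars.size(); ++j)
            open *= powi(gate[gate_ptr[k] + j], vt.vars[j].power);
          out_cur(rec_row, col++) =
            chan_gmax[k] * open *
            chan_mult[pop_id[idx / 2] * n_codes + chan_code[k]] *
            (v[idx] - vt.erev);
        }
      }
    }
  }

  // final state (used for resting-state relaxation)
  NumericVector v_final(2 * n), ca_final(2 * n), na_final(2 * n);
  for (int i = 0; i < 2 * n; ++i) {
    v_final[i] = v[i];
    ca_final[i] = ca[i];
    na_final[i] = nai[i];
  }

  return List::create(
    _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["v"] = out_v,
    _["dipole"] = out_dip,
    _["currents"] = out_cur,
    _["v_final"] = v_final,
    _["ca_final"] = ca_final,
    _["na_final"] = na_final,
    _["abort"] = abort_msg);
}
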