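// Fixed-step RK4 integration of the coupled thalamic network.
//
// Units at the interface: mV, ms, uA/cm2 (intrinsic currents), nA
// (synaptic/applied currents), nS, MOhm, uM.  The membrane equation is
//   C dV/dt = -gL (V-EL) - gKL (V-EKL) - sum I_int
//             - 1e-3 * sum I_syn / A + 1e-3 * I_app / A
// Voltage-dependent gating kinetics arrive as lookup tables of
// A(V) = phi/tau and B(V) = phi*x_inf/tau so that dx/dt = B - A x;
// calcium-dependent gates (AHP) use their rate form directly.
//
// Chemical synaptic conductances are aggregated per postsynaptic cell and
// receptor class and maintained event-driven: every gating variable s of a
// given receptor class decays by the same per-step factor when no
// transmitter pulse is active, so the aggregates decay by that factor too,
// and only cells with an active transmitter pulse (or a depression update
// at a spike) scatter corrections along their outgoing edges.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

struct Channel {
  double g;       // mS/cm2
  double E;       // mV; ignored when use_eca
  bool use_eca;
  int p, q;       // gate exponents (q = 0: no inactivation gate)
  int mkind;      // 0 = voltage table, 1 = calcium-dependent rates (AHP)
  int mtab, htab; // table column indices (-1 = none)
  bool can;       // Michaelis-Menten Ca scaling (CAN current)
  int moff, hoff; // gate offsets within a cell's gate block
  const double *Am, *Bm, *Ah, *Bh; // raw table columns
};

struct Population {
  int n;
  double area, g_KL, E_L, E_KL, tau_ca, ca_rest;
  std::vector<double> g_L;
  std::vector<Channel> ch;
  int ngate;
  int offset;     // global cell index of first cell
};

struct Pathway {
  int pre_pop;
  int n_pre;
  double gA, gN, gG; // nS
  int gclass;        // 2 = GABA(-80), 3 = GABA(-70), -1 for excitatory
  bool std_on;
  std::vector<int> row_ptr;   // CSR over local presynaptic index
  std::vector<int> col;       // global postsynaptic ids
  std::vector<double> Dpost;  // post-spike available fraction per pre
  std::vector<double> t_last; // last presynaptic spike time per pre
};

inline double p4(double x) {
  // RK4 update polynomial for a linear decay ODE: approximates exp(x)
  return 1.0 + x * (1.0 + x * (0.5 + x * (1.0 / 6.0 + x / 24.0)));
}

} // namespace

// [[Rcpp::export(name = ".run_network_cpp")]]
List run_network_cpp(List popsL, List tables, List chemL, List gapL,
                     List synL, List driveL, List stimL, List cfg) {
  const double dt = as<double>(cfg["dt"]);
  const int n_steps = as<int>(cfg["n_steps"]);
  const int stride = as<int>(cfg["stride"]);
  const bool check = as<bool>(cfg["check"]);
  IntegerVector trace_ids = cfg["trace_ids"];

  // gating tables
  const double v_min = as<double>(tables["v_min"]);
  const double dv = as<double>(tables["dv"]);
  NumericMatrix tabA = tables["A"], tabB = tables["B"], tabX = tables["X"];
  const int ntab_rows = tabA.nrow();

  // populations
  const int npop = popsL.size();
  std::vector<Population> pops(npop);
  int N = 0;
  for (int p = 0; p < npop; ++p) {
    List pl = popsL[p];
    Population &P = pops[p];
    P.n = as<int>(pl["n"]);
    P.area = as<double>(pl["area"]);
    P.g_KL = as<double>(pl["g_KL"]);
    P.E_L = as<double>(pl["E_L"]);
    P.E_KL = as<double>(pl["E_KL"]);
    P.tau_ca = as<double>(pl["tau_ca"]);
    P.ca_rest = as<double>(pl["ca_rest"]);
    P.g_L = as<std::vector<double> >(pl["g_L"]);
    NumericVector g = pl["ch_g"], E = pl["ch_E"];
    IntegerVector cp = pl["ch_p"], cq = pl["ch_q"], mk = pl["ch_mkind"],
      mt = pl["ch_mtab"], ht = pl["ch_htab"], cn = pl["ch_can"];
    int ng = 0;
    for (int c = 0; c < g.size(); ++c) {
      Channel ch;
      ch.g = g[c];
      ch.use_eca = NumericVector::is_na(E[c]);
      ch.E = ch.use_eca ? 0.0 : E[c];
      ch.p = cp[c]; ch.q = cq[c];
      ch.mkind = mk[c]; ch.mtab = mt[c]; ch.htab = ht[c];
      ch.can = cn[c] != 0;
      ch.moff = ng++;
      ch.hoff = (ch.q > 0) ? ng++ : -1;
      ch.Am = ch.mtab >= 0 ? &tabA(0, ch.mtab) : 0;
      ch.Bm = ch.mtab >= 0 ? &tabB(0, ch.mtab) : 0;
      ch.Ah = ch.htab >= 0 ? &tabA(0, ch.htab) : 0;
      ch.Bh = ch.htab >= 0 ? &tabB(0, ch.htab) : 0;
      P.ch.push_back(ch);
    }
    P.ngate = ng;
    P.offset = N;
    N += P.n;
  }

  // flat state vector: per population [V(n)][Ca(n)][gates(n*ngate)]
  std::vector<int> baseV(npop), baseCa(npop), baseG(npop);
  int M = 0;
  for (int p = 0; p < npop; ++p) {
    baseV[p] = M; M += pops[p].n;
    baseCa[p] = M; M += pops[p].n;
    baseG[p] = M; M += pops[p].n * pops[p].ngate;
  }
  std::vector<double> y(M), k1(M), k2(M), k3(M), k4(M), yt(M);

  // synapse constants
  const double U = as<double>(synL["U"]);
  const double tau_d = as<double>(synL["tau_d"]);
  const int delay_steps = as<int>(synL["delay_steps"]);
  const int pulse_steps = as<int>(synL["pulse_steps"]);
  const double pulse_amp = as<double>(synL["pulse_amp"]);
  const double aA = as<double>(synL["alpha_ampa"]), bA = as<double>(synL["beta_ampa"]);
  const double aN = as<double>(synL["alpha_nmda"]), bN = as<double>(synL["beta_nmda"]);
  const double aG = as<double>(synL["alpha_gaba"]), bG = as<double>(synL["beta_gaba"]);
  const double tau_input = as<double>(synL["tau_input"]);

  // pathways -> CSR
  std::vector<Pathway> paths;
  for (int k = 0; k < chemL.size(); ++k) {
    List pl = chemL[k];
    Pathway pw;
    pw.pre_pop = as<int>(pl["pre_pop"]);
    pw.gA = as<double>(pl["g_ampa"]);
    pw.gN = as<double>(pl["g_nmda"]);
    pw.gG = as<double>(pl["g_gaba"]);
    double Eg = as<double>(pl["E_gaba"]);
    pw.gclass = pw.gG > 0 ? (std::abs(Eg + 80) < 1e-9 ? 2 : 3) : -1;
    pw.std_on = as<bool>(pl["std"]);
    IntegerVector pre = pl["pre"], post = pl["post"]; // 0-based local
    int post_pop = as<int>(pl["post_pop"]);
    pw.n_pre = pops[pw.pre_pop].n;
    pw.row_ptr.assign(pw.n_pre + 1, 0);
    for (int e = 0; e < pre.size(); ++e) pw.row_ptr[pre[e] + 1]++;
    for (int i = 0; i < pw.n_pre; ++i) pw.row_ptr[i + 1] += pw.row_ptr[i];
    pw.col.resize(pre.size());
    std::vector<int> cur(pw.row_ptr.begin(), pw.row_ptr.end() - 1);
    for (int e = 0; e < pre.size(); ++e)
      pw.col[cur[pre[e]]++] = pops[post_pop].offset + post[e];
    pw.Dpost.assign(pw.n_pre, 1.0);
    pw.t_last.assign(pw.n_pre, -1e30);
    paths.push_back(pw);
  }
  // outgoing pathway indices per population
  std::vector<std::vector<int> > paths_of_pop(npop);
  for (size_t k = 0; k < paths.size(); ++k)
    paths_of_pop[paths[k].pre_pop].push_back((int)k);

  // gap junctions (global ids)
  IntegerVector gap_a = gapL["a"], gap_b = gapL["b"];
  NumericVector gap_R = gapL["R"];
  const int n_gap = gap_a.size();

  // Poisson drive events (precomputed, sorted by step)
  IntegerVector ev_step = driveL["ev_step"], ev_cell = driveL["ev_cell"];
  NumericVector g_inc = driveL["g_inc"]; // per global cell, nS

  // stimulation
  NumericVector wave = stimL["wave"];
  IntegerVector wave_mask = stimL["pop_mask"];
  const int trig_pop = as<int>(stimL["trigger_pop"]);
  const double trig_amp = as<double>(stimL["trigger_amp"]);
  const double trig_on = as<double>(stimL["trigger_on"]);
  const double trig_off = as<double>(stimL["trigger_off"]);

  // dynamic synaptic state
  std::vector<double> sA(N, 0.0), sN(N, 0.0), sG(N, 0.0);
  std::vector<double> G_A(N, 0.0), G_N(N, 0.0), G_80(N, 0.0), G_70(N, 0.0);
  std::vector<double> g_in(N, 0.0), eCa(N), prevV(N), Isyn_gap(N);
  std::vector<double> last_spike(N, -1e30);
  std::vector<int> active_until(N, -1);
  std::vector<int> pend(N * 8), pend_n(N, 0), pend_head(N, 0);
  std::vector<double> Iapp_pop(npop, 0.0);
  const double nernst_k = 1e3 * 8.31441 * 309.15 / (2.0 * 96489.0);
  const double ca_out = 2000.0; // uM
  const double ca_flux = 1e-6 / (2.0 * 96489.0 * 0.5e-4) * 1e6; // uM/ms per uA/cm2
  const double decA = p4(-bA * dt), decN = p4(-bN * dt), decG = p4(-bG * dt);
  const double decIn = std::exp(-dt / tau_input);

  // initialisation: two-leak fixed point, gates at steady state, Ca at rest
  for (int p = 0; p < npop; ++p) {
    Population &P = pops[p];
    for (int i = 0; i < P.n; ++i) {
      double v0 = (P.g_L[i] * P.E_L + P.g_KL * P.E_KL) / (P.g_L[i] + P.g_KL);
      y[baseV[p] + i] = v0;
      y[baseCa[p] + i] = P.ca_rest;
      eCa[P.offset + i] = nernst_k * std::log(ca_out / P.ca_rest);
      double fi = (v0 - v_min) / dv;
      int ti = (int)fi; if (ti < 0) ti = 0; if (ti > ntab_rows - 2) ti = ntab_rows - 2;
      double fr = fi - ti;
      for (size_t c = 0; c < P.ch.size(); ++c) {
        const Channel &ch = P.ch[c];
        double m0;
        if (ch.mkind == 1) {
          double al = 0.02 * P.ca_rest;
          m0 = al / (al + 0.1);
        } else {
          m0 = tabX(ti, ch.mtab) * (1 - fr) + tabX(ti + 1, ch.mtab) * fr;
        }
        y[baseG[p] + i * P.ngate + ch.moff] = m0;
        if (ch.q > 0)
          y[baseG[p] + i * P.ngate + ch.hoff] =
            tabX(ti, ch.htab) * (1 - fr) + tabX(ti + 1, ch.htab) * fr;
      }
    }
  }

  // recordings
  const int nrec = n_steps / stride + 1;
  NumericMatrix mean_v(nrec, npop), iapp_rec(nrec, npop);
  NumericMatrix traces(trace_ids.size() > 0 ? nrec : 0, trace_ids.size());
  NumericVector t_rec(nrec);
  std::vector<double> spk_t; std::vector<int> spk_id;
  double gate_lo = 1e30, gate_hi = -1e30, ca_lo = 1e30, s_hi = -1e30;

  // map global cell id -> index of V in the flat state vector
  std::vector<int> vidx(N);
  for (int p = 0; p < npop; ++p)
    for (int i = 0; i < pops[p].n; ++i) vidx[pops[p].offset + i] = baseV[p] + i;

  auto f = [&](const std::vector<double> &ys, std::vector<double> &dy) {
    std::memset(Isyn_gap.data(), 0, N * sizeof(double));
    for (int e = 0; e < n_gap; ++e) {
      const int a = gap_a[e], b = gap_b[e];
      const double d = (ys[vidx[b]] - ys[vidx[a]]) / gap_R[e];
      Isyn_gap[b] += d;   // nA, positive = outward
      Isyn_gap[a] -= d;
    }
    for (int p = 0; p < npop; ++p) {
      const Population &P = pops[p];
      const int bV = baseV[p], bC = baseCa[p], bGt = baseG[p];
      const int ng = P.ngate, nch = (int)P.ch.size();
      const double iapp = Iapp_pop[p];
      for (int i = 0; i < P.n; ++i) {
        const int gi = P.offset + i;
        const double V = ys[bV + i];
        const double Ca = ys[bC + i];
        double fi = (V - v_min) / dv;
        int ti = (int)fi;
        if (ti < 0) { ti = 0; fi = 0; }
        else if (ti > ntab_rows - 2) { ti = ntab_rows - 2; fi = ntab_rows - 2; }
        const double fr = fi - ti;
        const double *gbl = &ys[bGt + i * ng];
        double *dgbl = &dy[bGt + i * ng];
        double I_int = 0.0, I_ca = 0.0;
        for (int c = 0; c < nch; ++c) {
          const Channel &ch = P.ch[c];
          const double m = gbl[ch.moff];
          double dm;
          if (ch.mkind == 1) {
            // AHP gate: alpha = 0.02 [Ca] (uM), beta = 0.1 (1/ms)
            const double al = 0.02 * Ca;
            dm = al * (1.0 - m) - 0.1 * m;
          } else {
            const double A = ch.Am[ti] + (ch.Am[ti + 1] - ch.Am[ti]) * fr;
            const double B = ch.Bm[ti] + (ch.Bm[ti + 1] - ch.Bm[ti]) * fr;
            dm = B - A * m;
          }
          dgbl[ch.moff] = dm;
          double open;
          switch (ch.p) {
            case 1: open = m; break;
            case 2: open = m * m; break;
            case 3: open = m * m * m; break;
            default: open = m * m * m * m;
          }
          if (ch.q > 0) {
            const double h = gbl[ch.hoff];
            const double Ah = ch.Ah[ti] + (ch.Ah[ti + 1] - ch.Ah[ti]) * fr;
            const double Bh = ch.Bh[ti] + (ch.Bh[ti + 1] - ch.Bh[ti]) * fr;
            dgbl[ch.hoff] = Bh - Ah * h;
            open *= h;
          }
          if (ch.can) open *= Ca / (0.2 + Ca);
          const double E = ch.use_eca ? eCa[gi] : ch.E;
          const double I = ch.g * open * (V - E);
          I_int += I;
          if (ch.use_eca) I_ca += I;
        }
        // chemical + afferent conductances (nS) -> nA
        double I_chem = G_A[gi] * V + g_in[gi] * V
          + G_80[gi] * (V + 80.0) + G_70[gi] * (V + 70.0);
        if (G_N[gi] != 0.0)
          I_chem += G_N[gi] * V / (1.0 + std::exp(-(V + 25.0) / 12.5));
        const double I_syn = 1e-3 * I_chem + Isyn_gap[gi]; // nA
        dy[bV + i] = -P.g_L[i] * (V - P.E_L) - P.g_KL * (V - P.E_KL) - I_int
          - 1e-3 * I_syn / P.area + 1e-3 * iapp / P.area;
        dy[bC + i] = -I_ca * ca_flux + (P.ca_rest - Ca) / P.tau_ca;
      }
    }
  };

  auto rebuild_G = [&]() {
    std::fill(G_A.begin(), G_A.end(), 0.0);
    std::fill(G_N.begin(), G_N.end(), 0.0);
    std::fill(G_80.begin(), G_80.end(), 0.0);
    std::fill(G_70.begin(), G_70.end(), 0.0);
    for (size_t k = 0; k < paths.size(); ++k) {
      Pathway &pw = paths[k];
      const int off = pops[pw.pre_pop].offset;
      for (int i = 0; i < pw.n_pre; ++i) {
        const double D = pw.Dpost[i];
        for (int e = pw.row_ptr[i]; e < pw.row_ptr[i + 1]; ++e) {
          const int post = pw.col[e];
          if (pw.gA > 0) G_A[post] += pw.gA * D * sA[off + i];
          if (pw.gN > 0) G_N[post] += pw.gN * D * sN[off + i];
          if (pw.gclass == 2) G_80[post] += pw.gG * D * sG[off + i];
          if (pw.gclass == 3) G_70[post] += pw.gG * D * sG[off + i];
        }
      }
    }
  };

  // record helper
  auto record = [&](int rrow, double t) {
    t_rec[rrow] = t;
    for (int p = 0; p < npop; ++p) {
      double sum = 0.0;
      for (int i = 0; i < pops[p].n; ++i) sum += y[baseV[p] + i];
      mean_v(rrow, p) = pops[p].n > 0 ? sum / pops[p].n : NA_REAL;
      iapp_rec(rrow, p) = Iapp_pop[p];
    }
    for (int j = 0; j < trace_ids.size(); ++j)
      traces(rrow, j) = y[vidx[trace_ids[j]]];
  };

  // stimulation schedule for step `st` (current time = st*dt)
  auto set_iapp = [&](int st) {
    const double t = st * dt;
    for (int p = 0; p < npop; ++p) {
      double a = 0.0;
      if (wave.size() > 0 && wave_mask[p] && st < (int)wave.size()) a += wave[st];
      if (p == trig_pop && t >= trig_on && t < trig_off) a += trig_amp;
      Iapp_pop[p] = a;
    }
  };

  int ev_ptr = 0;
  const int n_ev = ev_step.size();
  int rrow = 0;
  set_iapp(0);
  record(rrow++, 0.0);

  const double lamA = aA * pulse_amp + bA, sinfA = aA * pulse_amp / lamA;
  const double lamN = aN * pulse_amp + bN, sinfN = aN * pulse_amp / lamN;
  const double lamG = aG * pulse_amp + bG, sinfG = aG * pulse_amp / lamG;
  const double actA = p4(-lamA * dt), actN = p4(-lamN * dt), actG = p4(-lamG * dt);

  for (int st = 0; st < n_steps; ++st) {
    const double t0 = st * dt, t1 = (st + 1) * dt;
    // save pre-step voltages for spike detection
    for (int gi = 0; gi < N; ++gi) prevV[gi] = y[vidx[gi]];

    // RK4 step
    f(y, k1);
    for (int j = 0; j < M; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
    f(yt, k2);
    for (int j = 0; j < M; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
    f(yt, k3);
    for (int j = 0; j < M; ++j) yt[j] = y[j] + dt * k3[j];
    f(yt, k4);
    for (int j = 0; j < M; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    // clamp gates, floor calcium, refresh Nernst potential
    for (int p = 0; p < npop; ++p) {
      Population &P = pops[p];
      for (int i = 0; i < P.n; ++i) {
        double *g = &y[baseG[p] + i * P.ngate];
        for (int j = 0; j < P.ngate; ++j) {
          if (g[j] < 0.0) g[j] = 0.0; else if (g[j] > 1.0) g[j] = 1.0;
          if (check) {
            if (g[j] < gate_lo) gate_lo = g[j];
            if (g[j] > gate_hi) gate_hi = g[j];
          }
        }
        double &ca = y[baseCa[p] + i];
        if (ca < 1e-6) ca = 1e-6;
        if (check && ca < ca_lo) ca_lo = ca;
        eCa[P.offset + i] = nernst_k * std::log(ca_out / ca);
      }
    }

    // synaptic gating: global decay of s and aggregates
    for (int gi = 0; gi < N; ++gi) {
      sA[gi] *= decA; sN[gi] *= decN; sG[gi] *= decG;
      G_A[gi] *= decA; G_N[gi] *= decN;
      G_80[gi] *= decG; G_70[gi] *= decG;
      g_in[gi] *= decIn;
    }

    // transmitter pulses: activate pending onsets, then correct active cells
    for (int gi = 0; gi < N; ++gi) {
      while (pend_n[gi] > 0 && pend[gi * 8 + pend_head[gi]] <= st) {
        int until = pend[gi * 8 + pend_head[gi]] + pulse_steps;
        if (until > active_until[gi]) active_until[gi] = until;
        pend_head[gi] = (pend_head[gi] + 1) % 8;
        pend_n[gi]--;
      }
      if (active_until[gi] > st) {
        // undo the passive decay, apply the active update, scatter deltas
        int p = 0;
        while (pops[p].offset + pops[p].n <= gi) ++p;
        bool exc = paths_of_pop[p].size() > 0 &&
          paths[paths_of_pop[p][0]].gclass == -1;
        double dA = 0, dN = 0, dGd = 0;
        if (exc) {
          double oldA = sA[gi] / decA, oldN = sN[gi] / decN;
          double newA = sinfA + (oldA - sinfA) * actA;
          double newN = sinfN + (oldN - sinfN) * actN;
          dA = newA - sA[gi]; dN = newN - sN[gi];
          sA[gi] = newA; sN[gi] = newN;
        } else {
          double oldG = sG[gi] / decG;
          double newG = sinfG + (oldG - sinfG) * actG;
          dGd = newG - sG[gi];
          sG[gi] = newG;
        }
        const int loc = gi - pops[p].offset;
        for (size_t kk = 0; kk < paths_of_pop[p].size(); ++kk) {
          Pathway &pw = paths[paths_of_pop[p][kk]];
          const double D = pw.Dpost[loc];
          for (int e = pw.row_ptr[loc]; e < pw.row_ptr[loc + 1]; ++e) {
            const int post = pw.col[e];
            if (pw.gA > 0) G_A[post] += pw.gA * D * dA;
            if (pw.gN > 0) G_N[post] += pw.gN * D * dN;
            if (pw.gclass == 2) G_80[post] += pw.gG * D * dGd;
            if (pw.gclass == 3) G_70[post] += pw.gG * D * dGd;
          }
        }
      }
    }
    if (check) {
      for (int gi = 0; gi < N; ++gi) {
        if (sA[gi] > s_hi) s_hi = sA[gi];
        if (sG[gi] > s_hi) s_hi = sG[gi];
      }
    }

    // afferent Poisson events land at the end of the step
    while (ev_ptr < n_ev && ev_step[ev_ptr] == st) {
      g_in[ev_cell[ev_ptr]] += g_inc[ev_cell[ev_ptr]];
      ++ev_ptr;
    }

    // spike detection (upward crossing of 0 mV, 1.5 ms refractory)
    for (int p = 0; p < npop; ++p) {
      Population &P = pops[p];
      for (int i = 0; i < P.n; ++i) {
        const int gi = P.offset + i;
        const double Vn = y[baseV[p] + i];
        if (!std::isfinite(Vn))
          stop("numerical instability: non-finite voltage in population %d, cell %d at t = %.2f ms", p + 1, i + 1, t1);
        if (Vn >= 0.0 && prevV[gi] < 0.0 && t1 - last_spike[gi] >= 1.5) {
          // linear interpolation of the upward 0 mV crossing inside the step
          const double tspk = t0 + dt * (0.0 - prevV[gi]) / (Vn - prevV[gi]);
          last_spike[gi] = tspk;
          spk_t.push_back(tspk);
          spk_id.push_back(gi);
          if (pend_n[gi] < 8) {
            pend[gi * 8 + (pend_head[gi] + pend_n[gi]) % 8] = st + delay_steps;
            pend_n[gi]++;
          }
          // depression update on all outgoing pathways
          for (size_t kk = 0; kk < paths_of_pop[p].size(); ++kk) {
            Pathway &pw = paths[paths_of_pop[p][kk]];
            double Dold = pw.Dpost[i], Dnew;
            if (pw.std_on) {
              double Dpre = (pw.t_last[i] < -1e29) ? 1.0 :
                1.0 - (1.0 - Dold) * std::exp(-(t1 - pw.t_last[i]) / tau_d);
              Dnew = Dpre * (1.0 - U);
            } else {
              Dnew = 1.0;
            }
            pw.t_last[i] = t1;
            if (Dnew != Dold) {
              const double dD = Dnew - Dold;
              pw.Dpost[i] = Dnew;
              for (int e = pw.row_ptr[i]; e < pw.row_ptr[i + 1]; ++e) {
                const int post = pw.col[e];
                if (pw.gA > 0) G_A[post] += pw.gA * dD * sA[gi];
                if (pw.gN > 0) G_N[post] += pw.gN * dD * sN[gi];
                if (pw.gclass == 2) G_80[post] += pw.gG * dD * sG[gi];
                if (pw.gclass == 3) G_70[post] += pw.gG * dD * sG[gi];
              }
            }
          }
        }
      }
    }

    // periodic exact rebuild of the aggregates (guards drift/underflow)
    if ((st & 8191) == 8191) rebuild_G();

    set_iapp(st + 1);
    if ((st + 1) % stride == 0) record(rrow++, t1);
    if ((st & 16383) == 0) Rcpp::checkUserInterrupt();
  }

  List diag = List::create(
    _["gate_min"] = check ? gate_lo : NA_REAL,
    _["gate_max"] = check ? gate_hi : NA_REAL,
    _["ca_min"] = check ? ca_lo : NA_REAL,
    _["s_max"] = check ? s_hi : NA_REAL);

  return List::create(
    _["spike_t"] = wrap(spk_t),
    _["spike_id"] = wrap(spk_id),
    _["t_rec"] = t_rec,
    _["mean_v"] = mean_v,
    _["iapp"] = iapp_rec,
    _["traces"] = traces,
    _["diag"] = diag);
}
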