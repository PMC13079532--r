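// Daily coupled hydrology / soil-carbon loop. Mirrors the exported R step
// functions (step_hydrology, step_carbon, route_network) arithmetic exactly;
// the R functions are the readable single-step reference, this is the fast
// multi-year path.
#include <Rcpp.h>
using namespace Rcpp;

// State layout: one row per (reach, land-cover unit), columns
// snow, S, Sq, Ss, SOC_o, SOC_m, D -- identical to the R model_state matrix.
enum { SNOW = 0, SW, SQ, SS, SOCO, SOCM, DPOOL, NSTATE };

// Hydro params: T_snow, DDF, a_pet, C_soil, beta_q, tau_q, tau_s
enum { P_TSNOW = 0, P_DDF, P_APET, P_CSOIL, P_BETA, P_TAUQ, P_TAUS };
// Carbon params: k_p, Q10, T_ref, k_sorb, k_min, k_min_m, I_litter
enum { C_KP = 0, C_Q10, C_TREF, C_KSORB, C_KMIN, C_KMINM, C_ILIT };

// [[Rcpp::export]]
List sim_core_cpp(NumericMatrix Tm, NumericMatrix Pm, NumericVector area,
                  NumericMatrix shares, NumericMatrix hp, NumericMatrix cp,
                  NumericVector ps_flow, NumericVector ps_load,
                  NumericVector c_gw, NumericVector instream_loss,
                  NumericMatrix state0, bool save_traj) {
  const int n = Tm.nrow();
  const int R = Tm.ncol();
  const int U = shares.ncol();
  const double MM_KM2_TO_M3S = 1000.0 / 86400.0;
  const double EPS_EXPORT = 0.1;  // mm, avoids division by zero in dry soil

  std::vector<double> st(R * U * NSTATE);
  for (int i = 0; i < R * U; ++i)
    for (int v = 0; v < NSTATE; ++v) st[i * NSTATE + v] = state0(i, v);

  NumericMatrix Q(n, R), conc(n, R), load(n, R), her_o(n, R), smd_o(n, R),
      aet_o(n, R), qloc_o(n, R), qslow_o(n, R), min_o(n, R), exp_o(n, R);
  NumericMatrix traj(save_traj ? n : 1, save_traj ? R * U * NSTATE : 1);

  for (int d = 0; d < n; ++d) {
    if (save_traj)
      for (int j = 0; j < R * U * NSTATE; ++j) traj(d, j) = st[j];
    double Q_up = 0.0, load_up = 0.0;
    for (int r = 0; r < R; ++r) {
      const double Ta = Tm(d, r), Pp = Pm(d, r);
      double q_local = 0.0, q_slow_agg = 0.0, her_agg = 0.0, smd_agg = 0.0,
             aet_agg = 0.0, min_agg = 0.0, exp_agg = 0.0, export_gs = 0.0;
      for (int u = 0; u < U; ++u) {
        const int i = r * U + u;
        double *s = &st[i * NSTATE];
        const double T_snow = hp(i, P_TSNOW), DDF = hp(i, P_DDF),
                     a_pet = hp(i, P_APET), C_soil = hp(i, P_CSOIL),
                     beta_q = hp(i, P_BETA), tau_q = hp(i, P_TAUQ),
                     tau_s = hp(i, P_TAUS);
        // hydrology
        const double snowfall = (Ta < T_snow) ? Pp : 0.0;
        const double rain = Pp - snowfall;
        s[SNOW] += snowfall;
        double melt = DDF * std::max(0.0, Ta - T_snow);
        if (melt > s[SNOW]) melt = s[SNOW];
        s[SNOW] -= melt;
        const double W = rain + melt;
        const double pet = a_pet * std::max(0.0, Ta);
        double aet = pet * s[SW] / C_soil;
        if (aet > s[SW] + W) aet = s[SW] + W;
        double her = s[SW] + W - aet - C_soil;
        if (her < 0.0) her = 0.0;
        double S = s[SW] + W - aet - her;
        if (S < 0.0) S = 0.0;
        if (S > C_soil) S = C_soil;
        s[SW] = S;
        s[SQ] += beta_q * her;
        const double q_quick = s[SQ] / tau_q;
        s[SQ] -= q_quick;
        s[SS] += (1.0 - beta_q) * her;
        const double q_slow = s[SS] / tau_s;
        s[SS] -= q_slow;
        // carbon
        const double k_p = cp(i, C_KP), Q10 = cp(i, C_Q10),
                     T_ref = cp(i, C_TREF), k_sorb = cp(i, C_KSORB),
                     k_min = cp(i, C_KMIN), k_min_m = cp(i, C_KMINM),
                     I_lit = cp(i, C_ILIT);
        double production =
            k_p * s[SOCO] * std::pow(Q10, (Ta - T_ref) / 10.0) * (S / C_soil);
        if (production > s[SOCO]) production = s[SOCO];
        double sorption = k_sorb * s[DPOOL];
        double miner_d = k_min * s[DPOOL];
        double exf = her / (S + EPS_EXPORT);
        if (exf > 1.0) exf = 1.0;
        double expc = s[DPOOL] * exf;
        const double tot = sorption + miner_d + expc;
        if (tot > s[DPOOL] && tot > 0.0) {
          const double sc = s[DPOOL] / tot;
          sorption *= sc; miner_d *= sc; expc *= sc;
        }
        double miner_m = k_min_m * s[SOCM];
        if (miner_m > s[SOCM]) miner_m = s[SOCM];
        s[SOCO] += I_lit - production;
        s[SOCM] += sorption - miner_m;
        s[DPOOL] += production - sorption - miner_d - expc;
        // reach aggregation (area-share weighting)
        const double w = shares(r, u);
        q_local += w * (q_quick + q_slow);
        q_slow_agg += w * q_slow;
        her_agg += w * her;
        smd_agg += w * (C_soil - S);
        aet_agg += w * aet;
        min_agg += w * (miner_d + miner_m);
        exp_agg += w * expc;
        export_gs += w * expc * area[r] * 1e6 / 86400.0;
      }
      // routing: local runoff + upstream + point sources
      const double f = area[r] * MM_KM2_TO_M3S;
      const double Qr = q_local * f + Q_up + ps_flow[r];
      const double loadr = export_gs + c_gw[r] * q_slow_agg * f +
                           load_up * (1.0 - instream_loss[r]) + ps_load[r];
      Q(d, r) = Qr;
      load(d, r) = loadr;
      conc(d, r) = (Qr > 0.0) ? loadr / Qr : NA_REAL;
      her_o(d, r) = her_agg;
      smd_o(d, r) = smd_agg;
      aet_o(d, r) = aet_agg;
      qloc_o(d, r) = q_local;
      qslow_o(d, r) = q_slow_agg;
      min_o(d, r) = min_agg;
      exp_o(d, r) = exp_agg;
      Q_up = Qr;
      load_up = loadr;
    }
  }

  NumericMatrix fin(R * U, NSTATE);
  for (int i = 0; i < R * U; ++i)
    for (int v = 0; v < NSTATE; ++v) fin(i, v) = st[i * NSTATE + v];

  List out = List::create(
      _["Q"] = Q, _["conc"] = conc, _["load"] = load, _["her"] = her_o,
      _["smd"] = smd_o, _["aet"] = aet_o, _["q_local"] = qloc_o,
      _["q_slow"] = qslow_o, _["miner"] = min_o, _["export"] = exp_o,
      _["state_final"] = fin);
  if (save_traj) out["trajectory"] = traj;
  return out;
}
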