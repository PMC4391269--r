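#include <Rcpp.h>
using namespace Rcpp;

// Fast path of the hourly carbon-balance loop, used by the calibration
// objective where thousands of simulations are required.  Mirrors the R
// engine in simulate_plant() statement by statement; their agreement is
// asserted in the test suite.  Returns the end-of-day state (s, M_L, M_i,
// M_r) for every simulated day.
// [[Rcpp::export(name = ".sim_state_cpp")]]
NumericMatrix sim_state_cpp(int ndays, int P, int het_end,
                            NumericVector A_das, NumericVector r_das,
                            NumericVector iota_d, NumericVector rho_d,
                            NumericVector ls_d, NumericVector lt_d,
                            double germ_ls, double germ_lt,
                            NumericVector constants) {
  const double Cc   = constants["carbon_conc"];
  const double sig  = constants["sigma"];
  const double rL36 = constants["rL_maint"] * 3600.0;
  const double ri36 = constants["ri_maint_coeff"] * 3600.0;
  const double rr36 = constants["rr_maint_coeff"] * 3600.0;
  const double gL   = constants["gL_growth_coeff"];
  const double gi   = constants["gi_growth_coeff"];
  const double gr   = constants["gr_growth_coeff"];
  const double E    = constants["exudation"];
  const double shade = constants["shaded_photo_fraction"];
  const double mobr = constants["seed_mobilization_ratio"];
  const double s0   = constants["initial_leaf_area"];
  const double ML0  = constants["initial_leaf_mass"];

  const int nightH = 24 - P;
  double s = s0, M_L = ML0, M_i = 0.0, M_r = 0.0;
  double starch = 0.0;
  const double R0 = ML0;
  double reserve = R0;
  const double mob_day_g = mobr * R0;

  NumericMatrix out(ndays, 4);

  for (int d = 0; d < ndays; ++d) {
    const bool het = (d + 1) <= het_end;
    const double A = A_das[d];
    const double r_proj = r_das[d];
    const double io = iota_d[d], rh = rho_d[d];
    const double ls = ls_d[d], lt = lt_d[d];
    double night_draw = 0.0;

    for (int h = 0; h < 24; ++h) {
      double nar, io_h, rh_h, ls_h, lt_h;
      if (het) {
        double mob_g = mob_day_g / 24.0;
        if (mob_g > reserve) mob_g = reserve;
        reserve -= mob_g;
        nar = mob_g * Cc - rL36 * s;
        io_h = 0.0; rh_h = 0.0; ls_h = germ_ls; lt_h = germ_lt;
      } else if (h < P) {
        const double s_eff = r_proj * s + shade * (1.0 - r_proj) * s;
        const double fx = A * s_eff * 3600.0;
        starch += fx * sig;
        const double ex = (M_r > 0.0) ? E : 0.0;
        nar = fx * (1.0 - sig) - (ri36 * M_i + rr36 * M_r) - ex;
        io_h = io; rh_h = rh; ls_h = ls; lt_h = lt;
      } else {
        if (h == P) night_draw = starch / nightH;
        double draw = night_draw;
        if (draw > starch) draw = starch;
        starch -= draw;
        const double ex = (M_r > 0.0) ? E : 0.0;
        nar = draw - (rL36 * s + ri36 * M_i + rr36 * M_r) - ex;
        io_h = io; rh_h = rh; ls_h = ls; lt_h = lt;
      }

      if (nar > 0.0) {
        const double G = nar / Cc;
        const double dMi = G * io_h * (1.0 - gi);
        const double dMr = G * rh_h * (1.0 - gr);
        const double dMLs = G * ls_h * (1.0 - gL);
        const double dMLt = G * lt_h * (1.0 - gL);
        const double ds = (s / M_L) * dMLs;
        M_i += dMi; M_r += dMr;
        M_L += dMLs + dMLt;
        s += ds;
      }
    }

    out(d, 0) = s;
    out(d, 1) = M_L;
    out(d, 2) = M_i;
    out(d, 3) = M_r;
  }
  colnames(out) = CharacterVector::create("s", "M_L", "M_i", "M_r");
  return out;
}
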