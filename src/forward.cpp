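#include <Rcpp.h>
using namespace Rcpp;

// Daily seven-pool carbon update over a driver window. Mirrors the R
// reference stepper exactly; the R wrapper validates inputs and converts
// the result to tibbles. Parameter layout matches param_names() in R:
//  0-6   initial pools (c_f, c_w, c_fr, c_cr, c_lit, c_cwd, c_som)
//  7-14  allocation fractions, (wet, dry) pairs for f, w, fr, cr
// 15-22  turnover rates, same pairing
// 23-24  d_lit, d_cwd
// 25-32  autotrophic respired fractions, same pairing
// 33-35  rf_lit, rf_cwd, rf_som

static double acm_gpp_c(double lai, double tmax, double tmin, double rad,
                        double co2, int doy, const NumericVector &a,
                        double leaf_n, double psi_d, double rtot,
                        double lat_deg) {
  if (lai <= 0.0) return 0.0;
  double gc = std::pow(std::fabs(psi_d), a[9]) /
              (a[5] * rtot + 0.5 * (tmax - tmin));
  double pp = lai * leaf_n / gc * a[0] * std::exp(a[7] * tmax);
  double qq = a[2] - a[3];
  double disc = (co2 + qq - pp) * (co2 + qq - pp) -
                4.0 * (co2 * qq - pp * a[2]);
  double ci = 0.5 * (co2 + qq - pp + std::sqrt(disc));
  double e0 = a[6] * lai * lai / (lai * lai + a[8]);
  double dec = -23.4 * std::cos(2.0 * M_PI * (doy + 10) / 365.0) * M_PI / 180.0;
  double lat = lat_deg * M_PI / 180.0;
  double mult = std::tan(lat) * std::tan(dec);
  if (mult > 1.0) mult = 1.0;
  if (mult < -1.0) mult = -1.0;
  double dayl = 24.0 / M_PI * std::acos(-mult);
  double cps = e0 * rad * gc * (co2 - ci) / (e0 * rad + gc * (co2 - ci));
  double g = cps * (a[1] * dayl + a[4]);
  return g > 0.0 ? g : 0.0;
}

// [[Rcpp::export]]
List run_forward_cpp(NumericVector par, IntegerVector dry,
                     NumericVector tmin, NumericVector tmax,
                     NumericVector rad, NumericVector co2,
                     NumericVector swc, IntegerVector doy,
                     double w_opt, double s_shape,
                     bool use_acm, NumericVector standin,
                     NumericVector acm_coef, double leaf_n, double psi_d,
                     double rtot, double lat_deg,
                     double leaf_c_per_area, double t_ref) {
  const int n = tmin.size();
  NumericMatrix pools(n, 7);
  NumericMatrix fluxes(n, 18);
  double c[7];
  for (int k = 0; k < 7; ++k) c[k] = par[k];
  const double ln_wopt = std::log(w_opt);

  bool ok = true;
  int fail_day = -1, fail_pool = -1;

  for (int i = 0; i < n && ok; ++i) {
    const int sd = dry[i] ? 1 : 0;
    const double a_f = par[7 + sd], a_w = par[9 + sd], a_fr = par[11 + sd],
                 a_cr = par[13 + sd];
    const double t_f = par[15 + sd], t_w = par[17 + sd], t_fr = par[19 + sd],
                 t_cr = par[21 + sd];
    const double d_lit = par[23], d_cwd = par[24];
    const double rf_f = par[25 + sd], rf_w = par[27 + sd],
                 rf_fr = par[29 + sd], rf_cr = par[31 + sd];
    const double rf_lit = par[33], rf_cwd = par[34], rf_som = par[35];

    const double lai = c[0] / leaf_c_per_area;
    double g;
    if (use_acm) {
      g = acm_gpp_c(lai, tmax[i], tmin[i], rad[i], co2[i], doy[i], acm_coef,
                    leaf_n, psi_d, rtot, lat_deg);
    } else {
      g = standin[0] * (1.0 - std::exp(-standin[1] * lai)) * rad[i] /
          (rad[i] + standin[2]);
    }

    const double al_f = a_f * g, al_w = a_w * g, al_fr = a_fr * g,
                 al_cr = a_cr * g;
    const double r_f = rf_f * al_f, r_w = rf_w * al_w, r_fr = rf_fr * al_fr,
                 r_cr = rf_cr * al_cr;

    const double lit_f = t_f * c[0];
    const double lit_fr = t_fr * c[2];
    const double cwd_w = t_w * c[1];
    const double cwd_cr = t_cr * c[3];
    const double dec_lit = d_lit * c[4];
    const double dec_cwd = d_cwd * c[5];

    const double tmean = 0.5 * (tmin[i] + tmax[i]);
    const double tf = std::pow(2.0, (tmean - t_ref) / 10.0);
    const double z = (std::log(swc[i]) - ln_wopt) / s_shape;
    const double mf = std::exp(-0.5 * z * z);
    const double env = tf * mf;
    const double r_lit = rf_lit * c[4] * env;
    const double r_cwd = rf_cwd * c[5] * env;
    const double r_som = rf_som * c[6] * env;

    c[0] += al_f * (1.0 - rf_f) - lit_f;
    c[1] += al_w * (1.0 - rf_w) - cwd_w;
    c[2] += al_fr * (1.0 - rf_fr) - lit_fr;
    c[3] += al_cr * (1.0 - rf_cr) - cwd_cr;
    c[4] += lit_f + lit_fr - dec_lit - r_lit;
    c[5] += cwd_w + cwd_cr - dec_cwd - r_cwd;
    c[6] += dec_lit + dec_cwd - r_som;

    for (int k = 0; k < 7; ++k) {
      if (c[k] < 0.0) {
        ok = false;
        fail_day = i + 1;
        fail_pool = k + 1;
        break;
      }
    }
    if (!ok) break;

    const double r_a = r_f + r_w + r_fr + r_cr;
    const double r_h = r_lit + r_cwd + r_som;
    for (int k = 0; k < 7; ++k) pools(i, k) = c[k];
    fluxes(i, 0) = g;
    fluxes(i, 1) = al_f;  fluxes(i, 2) = al_w;
    fluxes(i, 3) = al_fr; fluxes(i, 4) = al_cr;
    fluxes(i, 5) = r_f;   fluxes(i, 6) = r_w;
    fluxes(i, 7) = r_fr;  fluxes(i, 8) = r_cr;
    fluxes(i, 9) = r_lit; fluxes(i, 10) = r_cwd; fluxes(i, 11) = r_som;
    fluxes(i, 12) = r_a;  fluxes(i, 13) = r_h;
    fluxes(i, 14) = r_a + r_h;
    fluxes(i, 15) = r_a + r_h - g;
    fluxes(i, 16) = lit_f;
    fluxes(i, 17) = al_w * (1.0 - rf_w);
  }

  return List::create(_["ok"] = ok, _["fail_day"] = fail_day,
                      _["fail_pool"] = fail_pool, _["pools"] = pools,
                      _["fluxes"] = fluxes);
}
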