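#include <Rcpp.h>
using namespace Rcpp;

// Connor-Stevens point neuron driven by the transduction current, with an
// additive Brownian current term (Euler-Maruyama on V, exponential Euler on
// the gating variables). Units: mV, ms, uA/cm2, mS/cm2, uF/cm2.
//
// Rate functions are the canonical Connor-Stevens set (temperature factor
// 3.8 folded into the coefficients). The transduction current (pA) enters
// through a dimensionless gain mapping it onto membrane current density.

struct CsPars {
  double C, gNa, ENa, gK, EK, gA, EA, gL, EL;
};

static inline double vtrap(double x, double y) {
  // x/(1 - exp(-x/y)) guarded near 0
  return std::fabs(x / y) < 1e-6 ? y * (1.0 + x / (2.0 * y)) : x / (1.0 - std::exp(-x / y));
}

static inline void cs_gates(double V, double *xinf, double *tau) {
  double am = 0.38  * vtrap(V + 29.7, 10.0);
  double bm = 15.2  * std::exp(-0.0556 * (V + 54.7));
  double ah = 0.266 * std::exp(-0.05   * (V + 48.0));
  double bh = 3.8 / (1.0 + std::exp(-0.1 * (V + 18.0)));
  double an = 0.02  * vtrap(V + 45.7, 10.0);
  double bn = 0.25  * std::exp(-0.0125 * (V + 55.7));
  xinf[0] = am / (am + bm); tau[0] = 1.0 / (am + bm);
  xinf[1] = ah / (ah + bh); tau[1] = 1.0 / (ah + bh);
  xinf[2] = an / (an + bn); tau[2] = 1.0 / (an + bn);
  xinf[3] = std::pow(0.0761 * std::exp(0.0314 * (V + 94.22)) /
                     (1.0 + std::exp(0.0346 * (V + 1.17))), 1.0 / 3.0);
  tau[3]  = 0.3632 + 1.158 / (1.0 + std::exp(0.0497 * (V + 55.96)));
  xinf[4] = std::pow(1.0 / (1.0 + std::exp(0.0688 * (V + 53.3))), 4.0);
  tau[4]  = 1.24 + 2.678 / (1.0 + std::exp(0.0624 * (V + 50.0)));
}

// Gating update uses a voltage-indexed lookup table of steady states and
// per-step exponential decay factors (0.02 mV resolution, linear
// interpolation), rebuilt when the step size changes.
struct GateTable {
  double vmin, vmax, dv, dtm;
  std::vector<double> xinf, efac;   // n_v * 5 each
  void build(double dtm_) {
    vmin = -120.0; vmax = 60.0; dv = 0.02; dtm = dtm_;
    int nv = (int)((vmax - vmin) / dv) + 2;
    xinf.assign(nv * 5, 0.0);
    efac.assign(nv * 5, 0.0);
    double xi[5], tau[5];
    for (int i = 0; i < nv; ++i) {
      cs_gates(vmin + i * dv, xi, tau);
      for (int j = 0; j < 5; ++j) {
        xinf[i * 5 + j] = xi[j];
        efac[i * 5 + j] = std::exp(-dtm / tau[j]);
      }
    }
  }
};
static GateTable g_table;

// [[Rcpp::export]]
List cpp_bsg_simulate(NumericVector I, double dt_in, double dt, List pars,
                      double sigma, double gain, double v0,
                      bool return_v, int v_stride) {
  CsPars P;
  P.C = pars["C"]; P.gNa = pars["gNa"]; P.ENa = pars["ENa"];
  P.gK = pars["gK"]; P.EK = pars["EK"]; P.gA = pars["gA"];
  P.EA = pars["EA"]; P.gL = pars["gL"]; P.EL = pars["EL"];

  const double t_end = (I.size() - 1) * dt_in;          // seconds
  const long n = (long)std::floor(t_end / dt + 0.5);
  const double dtm = dt * 1e3;                          // ms
  const double sq = sigma * std::sqrt(dtm) / P.C;
  if (g_table.xinf.empty() || g_table.dtm != dtm) g_table.build(dtm);

  double V = v0, xinf[5], tau[5], g[5];
  cs_gates(V, xinf, tau);
  for (int j = 0; j < 5; ++j) g[j] = xinf[j];

  std::vector<double> spikes;
  std::vector<double> vtrace;
  if (return_v) vtrace.reserve(n / v_stride + 1);
  double last_spike = -1.0;   // s
  bool above = V >= 0.0;
  RNGScope rng;

  for (long i = 0; i < n; ++i) {
    double t = i * dt;                                  // s
    // linear interpolation of input current (pA -> uA/cm2 via gain)
    double ft = t / dt_in;
    long k = (long)ft; if (k >= I.size() - 1) k = I.size() - 2;
    double fr = ft - k;
    double Iin = gain * ((1.0 - fr) * I[k] + fr * I[k + 1]);

    double m = g[0], h = g[1], nn = g[2], a = g[3], b = g[4];
    double Iion = P.gNa * m * m * m * h * (V - P.ENa)
                + P.gK * nn * nn * nn * nn * (V - P.EK)
                + P.gA * a * a * a * b * (V - P.EA)
                + P.gL * (V - P.EL);
    double Vn = V + dtm / P.C * (Iin - Iion);
    if (sigma > 0.0) Vn += sq * norm_rand();
    if (!std::isfinite(Vn))
      stop("BSG integration blew up at t = %f s", t);

    // table lookup with linear interpolation in V
    double Vc = V < g_table.vmin ? g_table.vmin :
                (V > g_table.vmax ? g_table.vmax : V);
    double fi = (Vc - g_table.vmin) / g_table.dv;
    int ki = (int)fi;
    double w1 = fi - ki;
    const double *x0 = &g_table.xinf[ki * 5], *x1 = x0 + 5;
    const double *e0 = &g_table.efac[ki * 5], *e1 = e0 + 5;
    for (int j = 0; j < 5; ++j) {
      double xi = x0[j] + w1 * (x1[j] - x0[j]);
      double ef = e0[j] + w1 * (e1[j] - e0[j]);
      g[j] = xi + (g[j] - xi) * ef;
    }

    // spike: upward crossing of 0 mV with 2 ms lockout
    if (!above && Vn >= 0.0) {
      double ts = t + dt;
      if (last_spike < 0.0 || ts - last_spike >= 2e-3) {
        spikes.push_back(ts);
        last_spike = ts;
      }
    }
    above = Vn >= 0.0;
    V = Vn;
    if (return_v && (i % v_stride == 0)) vtrace.push_back(V);
  }

  List out = List::create(_["spikes"] = wrap(spikes));
  if (return_v) {
    out["v"] = wrap(vtrace);
    out["v_dt"] = dt * v_stride;
  }
  return out;
}
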