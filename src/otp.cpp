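#include <Rcpp.h>
using namespace Rcpp;

// Odorant transduction cascade: second-order peri-receptor low-pass filter
// driving bound-receptor kinetics, the co-receptor channel with calcium
// feedback, and a Hill-type transduction current.
//
// Filter (unit DC gain):  y'' + 2*beta1*alpha1*y' + alpha1^2*y = alpha1^2*w
// where w(t) = u(t) + gamma*du(t) is filtered once (the filter is linear).
// Concentration profile: v = max(y, 0).
//
// State kinetics:
//   x1' = b*v*(1 - x1) - d*x1
//   x2' = alpha2*x1*(1 - x2) - beta2*x2 - kappa*x2^pw*x3^pw
//   x3' = alpha3*x2 - beta3*x3
// Transduction current: I = x2^p / (x2^p + c^p) * Imax.
//
// Fixed-step RK4; fractional powers evaluated on the non-negative clamp of
// the state (solver undershoot would otherwise produce NaN).

static inline double fracpow(double x, double pw) {
  return x > 0.0 ? std::pow(x, pw) : 0.0;
}

struct OtpPars {
  double alpha1, beta1, alpha2, beta2, alpha3, beta3, kappa, c, p, Imax;
  double b, d, pw;
};

static inline void otp_deriv(const double *s, double w, const OtpPars &P,
                             double *ds) {
  double v = s[0] > 0.0 ? s[0] : 0.0;
  ds[0] = s[1];
  ds[1] = P.alpha1 * P.alpha1 * (w - s[0]) - 2.0 * P.beta1 * P.alpha1 * s[1];
  ds[2] = P.b * v * (1.0 - s[2]) - P.d * s[2];
  ds[3] = P.alpha2 * s[2] * (1.0 - s[3]) - P.beta2 * s[3]
          - P.kappa * fracpow(s[3], P.pw) * fracpow(s[4], P.pw);
  ds[4] = P.alpha3 * s[3] - P.beta3 * s[4];
}

// [[Rcpp::export]]
NumericMatrix cpp_otp_integrate(NumericVector w, double dt, List pars,
                                double b, double d, double pw,
                                NumericVector init) {
  OtpPars P;
  P.alpha1 = pars["alpha1"]; P.beta1 = pars["beta1"];
  P.alpha2 = pars["alpha2"]; P.beta2 = pars["beta2"];
  P.alpha3 = pars["alpha3"]; P.beta3 = pars["beta3"];
  P.kappa  = pars["kappa"];  P.c     = pars["c"];
  P.p      = pars["p"];      P.Imax  = pars["Imax"];
  P.b = b; P.d = d; P.pw = pw;

  const int n = w.size();
  NumericMatrix out(n, 5);  // v, x1, x2, x3, I
  double s[5] = {0.0, 0.0, init[0], init[1], init[2]};
  double k1[5], k2[5], k3[5], k4[5], tmp[5];
  const double cp = std::pow(P.c, P.p);
  double excursion = 0.0;  // worst pre-projection bound violation

  for (int i = 0; i < n; ++i) {
    double v = s[0] > 0.0 ? s[0] : 0.0;
    double x2c = s[3] > 0.0 ? s[3] : 0.0;
    double x2p = std::pow(x2c, P.p);
    out(i, 0) = v;
    out(i, 1) = s[2];
    out(i, 2) = s[3];
    out(i, 3) = s[4];
    out(i, 4) = x2p / (x2p + cp) * P.Imax;
    if (i == n - 1) break;

    double w0 = w[i], w1 = w[i + 1], wm = 0.5 * (w0 + w1);
    otp_deriv(s, w0, P, k1);
    for (int j = 0; j < 5; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    otp_deriv(tmp, wm, P, k2);
    for (int j = 0; j < 5; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    otp_deriv(tmp, wm, P, k3);
    for (int j = 0; j < 5; ++j) tmp[j] = s[j] + dt * k3[j];
    otp_deriv(tmp, w1, P, k4);
    for (int j = 0; j < 5; ++j)
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (!std::isfinite(s[2]) || !std::isfinite(s[3]) || !std::isfinite(s[4]))
      stop("OTP integration blew up at t = %f s (non-finite state)", i * dt);
    // project back onto the invariant set [0,1] x [0,1] x [0,Inf); the
    // exact dynamics keep the states there, the discrete step may not
    for (int j = 2; j < 5; ++j) {
      if (s[j] < 0.0) { excursion = std::max(excursion, -s[j]); s[j] = 0.0; }
      if (j < 4 && s[j] > 1.0) {
        excursion = std::max(excursion, s[j] - 1.0);
        s[j] = 1.0;
      }
    }
  }
  out.attr("excursion") = excursion;
  return out;
}
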