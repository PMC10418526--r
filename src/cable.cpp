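#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Multicompartment cable integrator for an unbranched retinal ganglion cell
// (dendrite tip -> soma -> axon initial region -> distal axon), with
// Fohlmeister-Miller style membrane dynamics (Na, delayed-rectifier K,
// A-type K, Ca, Ca-gated K, leak) under an extracellular potential drive.
//
// Units: mV, ms, mS, uF, uA, mM. With these, g*V is uA and C*dV/dt is uA.
//
// Scheme: Rush-Larsen exponential update for gating variables at the old
// voltage, explicit Euler for the calcium pool, then a backward-Euler
// tridiagonal solve for the voltages with channel conductances frozen over
// the step. The extracellular potential enters through the axial coupling of
// the intracellular potential V_i = V_m + V_e.

static inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1), stable near x = 0 (limit y)
  double r = x / y;
  if (std::fabs(r) < 1e-7) return y * (1.0 - r / 2.0);
  return x / (std::exp(r) - 1.0);
}

struct Rates {
  double am, bm, ah, bh, an, bn, aa, ba, aha, bha, ac, bc;
};

static inline Rates rates(double v, double q = 1.0) {
  Rates r;
  r.am  = 0.6  * vtrap(-(v + 30.0), 10.0);
  r.bm  = 20.0 * std::exp(-(v + 55.0) / 18.0);
  r.ah  = 0.4  * std::exp(-(v + 50.0) / 20.0);
  r.bh  = 6.0  / (1.0 + std::exp(-0.1 * (v + 20.0)));
  r.an  = 0.02 * vtrap(-(v + 40.0), 10.0);
  r.bn  = 0.4  * std::exp(-(v + 50.0) / 80.0);
  r.aa  = 0.006 * vtrap(-(v + 90.0), 10.0);
  r.ba  = 0.1  * std::exp(-(v + 30.0) / 10.0);
  r.aha = 0.04 * std::exp(-(v + 70.0) / 20.0);
  r.bha = 0.6  / (1.0 + std::exp(-0.1 * (v + 40.0)));
  r.ac  = 0.3  * vtrap(-(v + 13.0), 10.0);
  r.bc  = 10.0 * std::exp(-(v + 38.0) / 18.0);
  if (q != 1.0) {
    r.am *= q; r.bm *= q; r.ah *= q; r.bh *= q; r.an *= q; r.bn *= q;
    r.aa *= q; r.ba *= q; r.aha *= q; r.bha *= q; r.ac *= q; r.bc *= q;
  }
  return r;
}

static const double FARADAY = 96485.33;  // C/mol
static const double RT2F_MV = 13.3655;   // RT/2F at 310 K, in mV

// [[Rcpp::export]]
List cable_integrate(NumericVector cm,        // uF per compartment
                     NumericVector gax,       // mS, axial, length n-1
                     NumericVector gna, NumericVector gk, NumericVector ga,
                     NumericVector gca, NumericVector gkca, NumericVector gl,
                     NumericVector vol_shell, // cm^3, Ca shell per compartment
                     double ena, double ek, double v_rest,
                     double cao, double ca_rest, double tau_ca, double ca_diss,
                     NumericVector na_shift,  // mV shift of Na activation
                     NumericVector ve_mv_per_ua, // mV per uA stimulus
                     NumericVector scale,     // waveform scale per step
                     double amp_ua, double dt, int record_every,
                     double q_rate) {         // temperature factor on rates
  const int n = cm.size();
  const int nsteps = scale.size();
  if (gax.size() != n - 1) stop("axial conductance length must be n-1");

  std::vector<double> v(n, v_rest), m(n), h(n), nn(n), a(n), ha(n), c(n),
      ca(n, ca_rest), el(n);

  // steady-state gating at rest
  {
    Rates r = rates(v_rest);
    for (int i = 0; i < n; ++i) {
      Rates rm = rates(v_rest - na_shift[i]);
      m[i] = rm.am / (rm.am + rm.bm);
      h[i] = r.ah / (r.ah + r.bh);
      nn[i] = r.an / (r.an + r.bn);
      a[i] = r.aa / (r.aa + r.ba);
      ha[i] = r.aha / (r.aha + r.bha);
      c[i] = r.ac / (r.ac + r.bc);
    }
  }
  // leak reversal balancing the resting ionic currents exactly
  const double eca0 = RT2F_MV * std::log(cao / ca_rest);
  for (int i = 0; i < n; ++i) {
    if (gl[i] <= 0.0) stop("leak conductance must be positive");
    double kfrac = (ca_rest / ca_diss) * (ca_rest / ca_diss);
    kfrac = kfrac / (1.0 + kfrac);
    double iact = gna[i] * std::pow(m[i], 3) * h[i] * (v_rest - ena) +
                  (gk[i] * std::pow(nn[i], 4) +
                   ga[i] * std::pow(a[i], 3) * ha[i] +
                   gkca[i] * kfrac) * (v_rest - ek) +
                  gca[i] * std::pow(c[i], 3) * (v_rest - eca0);
    el[i] = v_rest + iact / gl[i];
  }

  const int nrec = nsteps / record_every + 1;
  NumericMatrix vout(n, nrec);
  NumericVector tout(nrec);
  for (int i = 0; i < n; ++i) vout(i, 0) = v[i];
  tout[0] = 0.0;
  int irec = 1;

  std::vector<double> sub(n), dia(n), sup(n), rhs(n), gtot(n), src(n),
      ve(n), cp(n);

  for (int k = 0; k < nsteps; ++k) {
    // gating (Rush-Larsen at old voltage)
    for (int i = 0; i < n; ++i) {
      Rates r = rates(v[i], q_rate);
      Rates rm = rates(v[i] - na_shift[i], q_rate);
      double tm = 1.0 / (rm.am + rm.bm), minf = rm.am * tm;
      m[i] = minf + (m[i] - minf) * std::exp(-dt / tm);
      double th = 1.0 / (r.ah + r.bh), hinf = r.ah * th;
      h[i] = hinf + (h[i] - hinf) * std::exp(-dt / th);
      double tn = 1.0 / (r.an + r.bn), ninf = r.an * tn;
      nn[i] = ninf + (nn[i] - ninf) * std::exp(-dt / tn);
      double ta = 1.0 / (r.aa + r.ba), ainf = r.aa * ta;
      a[i] = ainf + (a[i] - ainf) * std::exp(-dt / ta);
      double tha = 1.0 / (r.aha + r.bha), hainf = r.aha * tha;
      ha[i] = hainf + (ha[i] - hainf) * std::exp(-dt / tha);
      double tc = 1.0 / (r.ac + r.bc), cinf = r.ac * tc;
      c[i] = cinf + (c[i] - cinf) * std::exp(-dt / tc);
    }
    // calcium pool and channel aggregates
    for (int i = 0; i < n; ++i) {
      double eca = RT2F_MV * std::log(cao / ca[i]);
      double gca_i = gca[i] * std::pow(c[i], 3);
      double ica = gca_i * (v[i] - eca);  // uA
      if (vol_shell[i] > 0.0 && gca[i] > 0.0) {
        // uA/(C/mol * cm^3) = 1e-3 mM/ms
        double dca = -ica / (2.0 * FARADAY * vol_shell[i]) * 1e-3 -
                     (ca[i] - ca_rest) / tau_ca;
        ca[i] += dt * dca;
        if (ca[i] < 1e-8) ca[i] = 1e-8;
        eca = RT2F_MV * std::log(cao / ca[i]);
      }
      double kf = (ca[i] / ca_diss) * (ca[i] / ca_diss);
      kf = kf / (1.0 + kf);
      double gkca_i = gkca[i] * kf;
      double gna_i = gna[i] * std::pow(m[i], 3) * h[i];
      double gk_i = gk[i] * std::pow(nn[i], 4) + ga[i] * std::pow(a[i], 3) * ha[i];
      gtot[i] = gna_i + gk_i + gkca_i + gca_i + gl[i];
      src[i] = gna_i * ena + (gk_i + gkca_i) * ek + gca_i * eca + gl[i] * el[i];
    }
    // extracellular potentials at end of step
    const double s = scale[k] * amp_ua;
    for (int i = 0; i < n; ++i) ve[i] = s * ve_mv_per_ua[i];
    // assemble tridiagonal (cm/dt + G + L) v_new = cm/dt v + src - L ve
    for (int i = 0; i < n; ++i) {
      double d = cm[i] / dt + gtot[i];
      double lve = 0.0;
      if (i > 0)     { d += gax[i - 1]; lve += gax[i - 1] * (ve[i] - ve[i - 1]); }
      if (i < n - 1) { d += gax[i];     lve += gax[i] * (ve[i] - ve[i + 1]); }
      dia[i] = d;
      sub[i] = (i > 0) ? -gax[i - 1] : 0.0;
      sup[i] = (i < n - 1) ? -gax[i] : 0.0;
      rhs[i] = cm[i] / dt * v[i] + src[i] - lve;
    }
    // Thomas solve
    cp[0] = sup[0] / dia[0];
    rhs[0] = rhs[0] / dia[0];
    for (int i = 1; i < n; ++i) {
      double mlt = 1.0 / (dia[i] - sub[i] * cp[i - 1]);
      cp[i] = sup[i] * mlt;
      rhs[i] = (rhs[i] - sub[i] * rhs[i - 1]) * mlt;
    }
    v[n - 1] = rhs[n - 1];
    for (int i = n - 2; i >= 0; --i) v[i] = rhs[i] - cp[i] * v[i + 1];

    for (int i = 0; i < n; ++i)
      if (!std::isfinite(v[i]))
        stop("membrane state became non-finite at compartment %d, step %d",
             i + 1, k + 1);

    if ((k + 1) % record_every == 0 && irec < nrec) {
      for (int i = 0; i < n; ++i) vout(i, irec) = v[i];
      tout[irec] = (k + 1) * dt;
      ++irec;
    }
  }

  return List::create(_["t"] = tout, _["v"] = vout);
}
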