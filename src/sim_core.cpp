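// Fixed-step (default 50 us / 20 kHz) hybrid engine coupling a force source
// (replayed twitch or Hill fixture) to a 3-element Windkessel through the
// thin-walled-sphere ventricle mapping. Ventricular volume is the integrated
// state; length is derived from it each step, so volume bookkeeping is exact.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double fl_fun(double L, double L0, double w) {
  double x = (L - L0) / (w * L0);
  double v = 1.0 - x * x;
  return v > 0.0 ? v : 0.0;
}

// Hill force-velocity factor; v > 0 is shortening. Lengthening limb is a
// linear ramp saturating at `cap` (reached at 10% of v_max lengthening speed).
static inline double fv_fun(double v, double vmax, double a, double cap) {
  if (v >= 0.0) {
    if (v >= vmax) return 0.0;
    return (1.0 - v / vmax) / (1.0 + v / (a * vmax));
  }
  double f = 1.0 + (cap - 1.0) * (-v) / (0.1 * vmax);
  return f > cap ? cap : f;
}

static inline double passive_fun(double L, double k, double beta, double slack,
                                 double L0) {
  if (L <= slack) return 0.0;
  return k * std::expm1(beta * (L - slack) / L0);
}

// normalised double-exponential activation drive, peak 1 at the analytic argmax
static inline double act_fun(double tb, double tr, double tf, double norm) {
  double a = std::exp(-tb / tf) - std::exp(-tb / tr);
  return a > 0.0 ? a / norm : 0.0;
}

struct HillPars {
  double smax, flw, vmax, acurv, pk, pbeta, slack, tr, tf, anorm, cap;
};

// [[Rcpp::export]]
List sim_core(List cfg) {
  const double dt = as<double>(cfg["dt"]);
  const long nsteps = (long)as<double>(cfg["n_steps"]);
  const int decim = as<int>(cfg["decim"]);
  const int mode = as<int>(cfg["mode"]);      // 0 windkessel, 1 isometric
  const int muscle = as<int>(cfg["muscle"]);  // 0 replay, 1 hill
  const double area = as<double>(cfg["area"]);
  const double r_ref = as<double>(cfg["r_ref"]);
  const double hw = as<double>(cfg["h"]);
  const double L_ref = as<double>(cfg["L_ref"]);
  const double L0 = as<double>(cfg["L0"]);
  double Rp = as<double>(cfg["Rp"]);
  double Cc = as<double>(cfg["C"]);
  double Zc = as<double>(cfg["Zc"]);
  const double period = as<double>(cfg["period"]);
  const long spb = (long)std::lround(period / dt);  // steps per beat
  const double refill_rate = as<double>(cfg["refill_rate"]);
  const double trig = as<double>(cfg["trigger_frac"]);
  const double L_ED = as<double>(cfg["L_ED"]);
  double Pp = as<double>(cfg["Pp0"]);
  double L = as<double>(cfg["L_init"]);

  NumericVector trace, trace_mid;
  HillPars hp = {0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1.1};
  if (muscle == 0) {
    trace = as<NumericVector>(cfg["trace"]);
    trace_mid = as<NumericVector>(cfg["trace_mid"]);  // sampled at (i+1/2) dt
    if ((long)trace.size() != spb || (long)trace_mid.size() != spb)
      stop("replay trace length (%d) must equal steps per beat (%d)",
           (int)trace.size(), (int)spb);
  } else {
    hp.smax = as<double>(cfg["sigma_max"]);
    hp.flw = as<double>(cfg["fl_width"]);
    hp.vmax = as<double>(cfg["v_max"]);
    hp.acurv = as<double>(cfg["a_curv"]);
    hp.pk = as<double>(cfg["passive_k"]);
    hp.pbeta = as<double>(cfg["passive_beta"]);
    hp.slack = as<double>(cfg["slack"]);
    hp.tr = as<double>(cfg["t_rise"]);
    hp.tf = as<double>(cfg["t_fall"]);
    hp.anorm = as<double>(cfg["act_norm"]);
    hp.cap = as<double>(cfg["fv_cap"]);
  }

  NumericVector iv_time = as<NumericVector>(cfg["iv_time"]);
  IntegerVector iv_which = as<IntegerVector>(cfg["iv_which"]);  // 0 Rp 1 C 2 Zc
  NumericVector iv_value = as<NumericVector>(cfg["iv_value"]);
  LogicalVector iv_defer = as<LogicalVector>(cfg["iv_defer"]);
  const int n_iv = iv_time.size();
  std::vector<bool> iv_done(n_iv, false);
  NumericVector iv_applied(n_iv, NA_REAL);

  const double c43 = 4.0 * M_PI / 3.0;
  double V = c43 * std::pow(r_ref * L / L_ref, 3.0);
  const double V_ED = c43 * std::pow(r_ref * L_ED / L_ref, 3.0);

  bool valve = false;
  double vprev = 0.0;   // previous-step kinematic velocity (closed phases)
  double peak_prev = 0.0, peak_cur = 0.0;
  double sig_trig_prev = 0.0, thresh_prev = 0.0;
  bool refill_prev = false;
  double decay = std::exp(-dt / (Rp * Cc));

  const long nlog = (nsteps + decim - 1) / decim;
  NumericMatrix out(nlog, 12);
  long k = 0;
  long beat = 0;

  for (long i = 0; i < nsteps; ++i) {
    const double t = i * dt;
    const long b = i / spb;
    bool new_beat = false;
    if (b != beat) {  // new beat: roll the per-beat peak used by refill logic
      beat = b;
      peak_prev = peak_cur;
      peak_cur = 0.0;
      new_beat = true;
    }
    const double tb = (i % spb) * dt;

    const double r = std::cbrt(V / c43);
    L = L_ref * r / r_ref;

    // sig_trig: activation-proxy stress used for refill/diastole detection
    // (isometric active stress for the Hill fixture; trace stress in replay)
    double sig_trig, sig, F, P, Q = 0.0;
    double P_drive;  // pressure held constant over the step for the Pp update
    if (muscle == 0) {
      // replay: prescribed force, no velocity feedback -> explicit causal
      // chain with the algebraic diode flow
      F = trace[i % spb];
      sig = F / area;
      sig_trig = sig;
      P = 2.0 * sig * hw / r;
      // midpoint sampling of the prescribed force centres the trapezoidal
      // Pp drive (second-order in dt); the valve logic stays causal at t
      P_drive = 2.0 * (trace_mid[i % spb] / area) * hw / r;
      if (!valve && P > Pp) valve = true;
      if (valve) {
        Q = (P - Pp) / Zc;
        if (Q <= 0.0) {
          valve = false;
          Q = 0.0;
        }
      }
    } else {
      const double a = act_fun(tb, hp.tr, hp.tf, hp.anorm);
      const double fl = fl_fun(L, L0, hp.flw);
      const double pass = passive_fun(L, hp.pk, hp.pbeta, hp.slack, L0);
      const double s_iso = a * hp.smax * fl;  // v = 0 active stress
      sig_trig = s_iso;
      const double lap = 2.0 * hw / r;
      const double P0 = lap * (s_iso + pass);  // isometric pressure
      if (!valve && P0 > Pp) valve = true;
      if (valve && P0 <= Pp) valve = false;  // cannot sustain ejection
      if (valve && mode == 0) {
        // auxotonic operating point: solve the force-velocity / afterload
        // balance lap*(s_iso*fv(v) + pass) = Pp + Zc*kQ*v implicitly
        // (the explicit previous-step-velocity coupling is unstable here:
        // its discrete loop gain exceeds 1 for physiologic Zc)
        const double kQ = 4.0 * M_PI * r * r * r_ref / L_ref;  // Q = kQ*v
        double lo = 0.0, hi = hp.vmax;
        const double fhi =
            lap * (s_iso * fv_fun(hp.vmax, hp.vmax, hp.acurv, hp.cap) +
                   pass) -
            Pp - Zc * kQ * hp.vmax;
        if (fhi >= 0.0) {
          lo = hi;  // even v_max cannot relieve the load (degenerate)
        } else {
          for (int it = 0; it < 50; ++it) {
            const double mid = 0.5 * (lo + hi);
            const double f =
                lap * (s_iso * fv_fun(mid, hp.vmax, hp.acurv, hp.cap) +
                       pass) -
                Pp - Zc * kQ * mid;
            if (f > 0.0)
              lo = mid;
            else
              hi = mid;
          }
        }
        const double v = 0.5 * (lo + hi);
        sig = s_iso * fv_fun(v, hp.vmax, hp.acurv, hp.cap) + pass;
        Q = kQ * v;
      } else if (valve) {
        // isometric mode with valve open: length clamped, algebraic flow
        sig = s_iso + pass;
        Q = (lap * sig - Pp) / Zc;
        if (Q <= 0.0) {
          valve = false;
          Q = 0.0;
        }
      } else {
        // closed valve: kinematic velocity (refill lengthening or rest)
        sig = s_iso * fv_fun(vprev, hp.vmax, hp.acurv, hp.cap) + pass;
      }
      P = lap * sig;
      P_drive = P;
      F = sig * area;
    }
    const double Pa = valve ? (Pp + Q * Zc) : Pp;

    // diastolic refill: valve closed, activation below the trigger fraction
    // of the previous beat's peak, clipped so L never overshoots L_ED
    double inflow = 0.0;
    bool refilling = false;
    const double thresh = trig * peak_prev;
    if (!valve && sig_trig < thresh && V < V_ED && refill_rate > 0.0) {
      inflow = refill_rate * dt;
      if (!refill_prev && !new_beat) {
        // sub-step onset: the trigger crossed between the previous sample
        // and this one; add the missed fraction so the onset time is
        // grid-independent (linear interpolation of the trigger margin).
        // Skipped at beat boundaries, where the threshold jumps
        // discontinuously rather than being crossed.
        const double m0 = sig_trig_prev - thresh_prev;
        const double m1 = sig_trig - thresh;
        if (m0 > 0.0 && m1 < 0.0)
          inflow += refill_rate * dt * (-m1) / (m0 - m1);
      }
      if (V + inflow > V_ED) inflow = V_ED - V;
      refilling = inflow > 0.0;
    }
    refill_prev = refilling;
    sig_trig_prev = sig_trig;
    thresh_prev = thresh;

    if (i % decim == 0) {
      out(k, 0) = t;
      out(k, 1) = F;
      out(k, 2) = sig;
      out(k, 3) = L;
      out(k, 4) = P;
      out(k, 5) = Pa;
      out(k, 6) = Pp;
      out(k, 7) = Q;
      out(k, 8) = V;
      out(k, 9) = valve ? 1.0 : 0.0;
      out(k, 10) = refilling ? 1.0 : 0.0;
      out(k, 11) = (double)beat;
      ++k;
    }

    // advance peripheral pressure: exact exponential when closed,
    // trapezoidal (implicit midpoint) with P held constant when open
    if (valve) {
      const double aa = P_drive / (Zc * Cc);
      const double bb = (1.0 / Zc + 1.0 / Rp) / Cc;
      Pp = ((1.0 - 0.5 * bb * dt) * Pp + aa * dt) / (1.0 + 0.5 * bb * dt);
    } else {
      Pp *= decay;
    }

    // advance volume; length follows from the sphere mapping
    if (mode == 0) {
      V += inflow - Q * dt;
      const double rnew = std::cbrt(V / c43);
      const double Lnew = L_ref * rnew / r_ref;
      vprev = -(Lnew - L) / dt;
      L = Lnew;
    } else {
      vprev = 0.0;  // length clamped
    }

    if (sig_trig > peak_cur) peak_cur = sig_trig;

    for (int j = 0; j < n_iv; ++j) {
      if (!iv_done[j] && t >= iv_time[j]) {
        const bool dia = !valve && (sig_trig < trig * peak_prev);
        if (!iv_defer[j] || dia) {
          if (iv_which[j] == 0)
            Rp = iv_value[j];
          else if (iv_which[j] == 1)
            Cc = iv_value[j];
          else
            Zc = iv_value[j];
          decay = std::exp(-dt / (Rp * Cc));
          iv_done[j] = true;
          iv_applied[j] = t;
        }
      }
    }

    if (!std::isfinite(Pp) || !std::isfinite(V) || V <= 0.0)
      stop("simulation diverged at t = %g s (beat %d): non-finite or "
           "non-positive state after the volume update",
           t, (int)(beat + 1));
  }

  return List::create(_["log"] = out(Range(0, k - 1), Range(0, 11)),
                      _["iv_applied"] = iv_applied,
                      _["Pp_final"] = Pp, _["L_final"] = L,
                      _["peak_prev"] = peak_prev);
}

// Isotonic (flat-topped work-loop) controller with the Hill fixture.
// Phase machine per beat:
//   0 isometric hold until F >= afterload
//   1 isotonic shortening: bisect the Hill force-velocity relation for the
//     velocity that balances the afterload
//   2 isometric relaxation once no non-negative velocity sustains the load
//   3 constant-velocity re-lengthening back to end-diastolic length
// [[Rcpp::export]]
List isotonic_core(List cfg) {
  const double dt = as<double>(cfg["dt"]);
  const long nsteps = (long)as<double>(cfg["n_steps"]);
  const int decim = as<int>(cfg["decim"]);
  const double area = as<double>(cfg["area"]);
  const double L0 = as<double>(cfg["L0"]);
  const double period = as<double>(cfg["period"]);
  const long spb = (long)std::lround(period / dt);
  const double trig = as<double>(cfg["trigger_frac"]);
  const double L_ED = as<double>(cfg["L_ED"]);
  const double afterload = as<double>(cfg["afterload"]);  // N
  const double relength_frac = as<double>(cfg["relength_frac"]);
  double L = as<double>(cfg["L_init"]);

  HillPars hp;
  hp.smax = as<double>(cfg["sigma_max"]);
  hp.flw = as<double>(cfg["fl_width"]);
  hp.vmax = as<double>(cfg["v_max"]);
  hp.acurv = as<double>(cfg["a_curv"]);
  hp.pk = as<double>(cfg["passive_k"]);
  hp.pbeta = as<double>(cfg["passive_beta"]);
  hp.slack = as<double>(cfg["slack"]);
  hp.tr = as<double>(cfg["t_rise"]);
  hp.tf = as<double>(cfg["t_fall"]);
  hp.anorm = as<double>(cfg["act_norm"]);
  hp.cap = as<double>(cfg["fv_cap"]);

  const double target_sig = afterload / area;
  int phase = 0;
  double v_re = 0.0;
  double peak_prev = 0.0, peak_cur = 0.0;
  long beat = 0;

  const long nlog = (nsteps + decim - 1) / decim;
  NumericMatrix out(nlog, 6);
  long k = 0;

  for (long i = 0; i < nsteps; ++i) {
    const double t = i * dt;
    const long b = i / spb;
    if (b != beat) {
      beat = b;
      peak_prev = peak_cur;
      peak_cur = 0.0;
      phase = 0;
    }
    const double tb = (i % spb) * dt;
    const double a = act_fun(tb, hp.tr, hp.tf, hp.anorm);
    const double fl = fl_fun(L, L0, hp.flw);
    const double pass = passive_fun(L, hp.pk, hp.pbeta, hp.slack, L0);
    const double sig0 = a * hp.smax * fl + pass;  // v = 0 total stress

    double v = 0.0, sig = sig0, sig_act = a * hp.smax * fl;

    if (phase == 0 && sig0 >= target_sig) phase = 1;
    if (phase == 1) {
      if (sig0 < target_sig) {
        phase = 2;  // cannot sustain the afterload at any v >= 0
      } else {
        double lo = 0.0, hi = hp.vmax;
        for (int it = 0; it < 60; ++it) {
          const double mid = 0.5 * (lo + hi);
          const double s = a * hp.smax * fl *
                               fv_fun(mid, hp.vmax, hp.acurv, hp.cap) +
                           pass;
          if (s > target_sig)
            lo = mid;
          else
            hi = mid;
        }
        v = 0.5 * (lo + hi);
        sig_act = a * hp.smax * fl * fv_fun(v, hp.vmax, hp.acurv, hp.cap);
        sig = sig_act + pass;
      }
    }
    if (phase == 2 && sig_act < trig * peak_prev) {
      phase = 3;
      const double trem = period - tb;
      v_re = (L < L_ED && trem > dt) ? (L_ED - L) / (relength_frac * trem)
                                     : 0.0;
    }
    if (phase == 3) {
      if (L >= L_ED) {
        v = 0.0;
        L = L_ED;
      } else {
        v = -v_re;  // negative shortening velocity = lengthening
        sig_act = a * hp.smax * fl * fv_fun(v, hp.vmax, hp.acurv, hp.cap);
        sig = sig_act + pass;
      }
    }

    const double F = sig * area;
    if (i % decim == 0) {
      out(k, 0) = t;
      out(k, 1) = F;
      out(k, 2) = sig;
      out(k, 3) = L;
      out(k, 4) = (double)phase;
      out(k, 5) = (double)beat;
      ++k;
    }

    L -= v * dt;
    if (phase == 3 && L > L_ED) L = L_ED;
    if (sig_act > peak_cur) peak_cur = sig_act;
    if (!std::isfinite(L) || L <= 0.0)
      stop("isotonic controller diverged at t = %g s (beat %d)", t,
           (int)(beat + 1));
  }

  return List::create(_["log"] = out(Range(0, k - 1), Range(0, 5)),
                      _["L_final"] = L);
}
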