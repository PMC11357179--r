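/* Coupled victim + perpetrator lumped PBPK system for deSolve.
 *
 * States (amounts in mg):
 *   y[0] lumen_v   y[1] central_v   y[2] peripheral_v   y[3] eliminated_v
 *   y[4] lumen_p   y[5] central_p   y[6] peripheral_p   y[7] eliminated_p
 *
 * Concentrations are whole-blood mg/L (central amount / V1). Gut extraction
 * is applied algebraically to the absorption flux (Qgut-type availability),
 * hepatic extraction by the well-stirred model; both respond at every time
 * step to the perpetrator's unbound exposure through competitive inhibition.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 36

static double parms[N_PARMS];

#define Qh        parms[0]
#define Qent      parms[1]
#define V1v       parms[2]
#define k12v      parms[3]
#define k21v      parms[4]
#define kav       parms[5]
#define CLrv      parms[6]
#define fubv      parms[7]
#define H4v       parms[8]   /* unbound hepatic CLint, CYP3A4 path, L/h */
#define H5v       parms[9]
#define G4v       parms[10]  /* fu_gut-scaled gut CLint, L/h */
#define G5v       parms[11]
#define Rv_rate   parms[12]  /* mg/h */
#define Rv_int    parms[13]  /* h; 0 = continuous */
#define Rv_dur    parms[14]
#define Rv_end    parms[15]
#define HAS_P     parms[16]
#define V1p       parms[17]
#define k12p      parms[18]
#define k21p      parms[19]
#define kap       parms[20]
#define CLrp      parms[21]
#define fubp      parms[22]
#define H4p       parms[23]
#define H5p       parms[24]
#define G4p       parms[25]
#define G5p       parms[26]
#define Rp_rate   parms[27]
#define Rp_int    parms[28]
#define Rp_dur    parms[29]
#define Rp_end    parms[30]
#define Ki4       parms[31]  /* mg/L, unbound */
#define Ki5       parms[32]
#define IGUT_FLUX parms[33]  /* mg/L, oral-perpetrator absorption-flux estimate */
#define LUM_THR   parms[34]  /* mg; absorption phase while lumen_p > this */
#define P_ORAL    parms[35]

void tacswitch_initparms(void (*odeparms)(int *, double *))
{
  int n = N_PARMS;
  odeparms(&n, parms);
}

static double infusion_rate(double t, double rate, double interval,
                            double dur, double end)
{
  if (rate <= 0.0 || t > end) return 0.0;
  if (interval <= 0.0) return rate;
  double tm = fmod(t, interval);
  return (tm < dur) ? rate : 0.0;
}

void tacswitch_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
  double iu_sys = 0.0, igut = 0.0;
  double f4h = 1.0, f5h = 1.0, f4g = 1.0, f5g = 1.0;

  if (HAS_P > 0.5) {
    double cp = y[5] / V1p;          /* perpetrator blood conc, mg/L */
    if (cp < 0.0) cp = 0.0;
    iu_sys = fubp * cp;
    igut = (P_ORAL > 0.5 && y[4] > LUM_THR) ? IGUT_FLUX : iu_sys;
    f4h = 1.0 / (1.0 + iu_sys / Ki4);
    f5h = 1.0 / (1.0 + iu_sys / Ki5);
    f4g = 1.0 / (1.0 + igut / Ki4);
    f5g = 1.0 / (1.0 + igut / Ki5);
  }

  /* victim gut availability and hepatic clearance under current inhibition */
  double clg_v = G4v * f4g + G5v * f5g;
  double fg_v = Qent / (Qent + clg_v);
  double x_v = fubv * (H4v * f4h + H5v * f5h);
  double clh_v = Qh * x_v / (Qh + x_v);
  double fh_v = 1.0 - clh_v / Qh;

  double c1v = y[1] / V1v;
  double abs_v = kav * y[0];
  double rin_v = infusion_rate(*t, Rv_rate, Rv_int, Rv_dur, Rv_end);
  double el_v = (clh_v + CLrv) * c1v;

  ydot[0] = -abs_v;
  ydot[1] = abs_v * fg_v * fh_v + rin_v - el_v - k12v * y[1] + k21v * y[2];
  ydot[2] = k12v * y[1] - k21v * y[2];
  ydot[3] = abs_v * (1.0 - fg_v * fh_v) + el_v;

  if (HAS_P > 0.5) {
    /* perpetrator: linear PK, no auto-inhibition */
    double clg_p = G4p + G5p;
    double fg_p = Qent / (Qent + clg_p);
    double x_p = fubp * (H4p + H5p);
    double clh_p = Qh * x_p / (Qh + x_p);
    double fh_p = 1.0 - clh_p / Qh;

    double c1p = y[5] / V1p;
    double abs_p = kap * y[4];
    double rin_p = infusion_rate(*t, Rp_rate, Rp_int, Rp_dur, Rp_end);
    double el_p = (clh_p + CLrp) * c1p;

    ydot[4] = -abs_p;
    ydot[5] = abs_p * fg_p * fh_p + rin_p - el_p - k12p * y[5] + k21p * y[6];
    ydot[6] = k12p * y[5] - k21p * y[6];
    ydot[7] = abs_p * (1.0 - fg_p * fh_p) + el_p;
  } else {
    ydot[4] = ydot[5] = ydot[6] = ydot[7] = 0.0;
  }

  if (ip[0] >= 4) {
    yout[0] = fg_v;
    yout[1] = fh_v;
    yout[2] = clh_v;
    yout[3] = igut;
  }
}

static const R_CMethodDef cMethods[] = {
  {"tacswitch_derivs", (DL_FUNC) &tacswitch_derivs, 6, NULL},
  {NULL, NULL, 0, NULL}
};

void R_init_tacswitch(DllInfo *dll)
{
  R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
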