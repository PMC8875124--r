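/* Compiled RHS of the MCPK reaction network for deSolve.
 * State layout and parameter order must match R/species.R and R/parameters.R.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 44
static double p[NPAR];

/* parameter indices (order of .paramOrder) */
enum {
  i_ka_sol, i_ka_cap, i_F_sol, i_F_cap, i_Vc, i_Vp,
  i_q_D0, i_q_DH, i_q_DC, i_q_DD,
  i_kon_D0, i_koff_D0, i_kcat_D0,
  i_kon_DH, i_koff_DH, i_kcat_DH,
  i_kon_DD, i_koff_DD, i_kcat_DD,
  i_kon_K, i_koff_K, i_kcat_K,
  i_kBon, i_kBoff,
  i_Vmax_pH, i_Km_pH, i_Vmax_2C19, i_Km_2C19,
  i_ke_D0, i_ke_DH, i_ke_DC, i_ke_DD,
  i_kr, i_TE, i_kdeg, i_kt, i_kEdeg,
  i_ka_K, i_V_K, i_E0,
  i_eps, i_Vmax_2C8, i_Km_2C8, i_use_2C8
};

/* state indices */
enum {
  s_D0s, s_D0cap, s_D0c, s_D0p, s_DHc, s_DHp, s_DCc, s_DCp, s_DDc, s_DDp,
  s_M, s_U, s_Koral, s_Kc, s_Ef, s_EB, s_ED0, s_EDH, s_EDD, s_EK, s_EmRNA
};

void mcpk_initmod(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, p);
}

static double hinge(double x, double eps)
{
  if (eps <= 0.0) return x > 0.0 ? x : 0.0;
  double z = x / eps;
  if (z > 30.0) return x;
  if (z < -30.0) return 0.0;
  return eps * log1p(exp(z));
}

void mcpk_rhs(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
  const double Vc = p[i_Vc], Vp = p[i_Vp], rvK = p[i_Vc] / p[i_V_K];

  const double b0 = p[i_kon_D0] * y[s_D0c] * y[s_Ef];
  const double u0 = p[i_koff_D0] * y[s_ED0];
  const double c0 = p[i_kcat_D0] * y[s_ED0];
  const double bH = p[i_kon_DH] * y[s_DHc] * y[s_Ef];
  const double uH = p[i_koff_DH] * y[s_EDH];
  const double cH = p[i_kcat_DH] * y[s_EDH];
  const double bD = p[i_kon_DD] * y[s_DDc] * y[s_Ef];
  const double uD = p[i_koff_DD] * y[s_EDD];
  const double cD = p[i_kcat_DD] * y[s_EDD];
  const double bK = p[i_kon_K] * y[s_Kc] * y[s_Ef];
  const double uK = p[i_koff_K] * y[s_EK];
  const double cK = p[i_kcat_K] * y[s_EK];

  const double vpH = p[i_Vmax_pH] * y[s_DCc] / (p[i_Km_pH] + y[s_DCc]);
  const double v19 = p[i_Vmax_2C19] * y[s_DDc] / (p[i_Km_2C19] + y[s_DDc]);
  const double v8 = p[i_use_2C8] > 0.0
    ? p[i_Vmax_2C8] * y[s_D0c] / (p[i_Km_2C8] + y[s_D0c]) : 0.0;

  const double rel = p[i_kr] * hinge(p[i_TE] - y[s_EB], p[i_eps]);
  const double kE = p[i_kEdeg];

  ydot[s_D0s] = -p[i_ka_sol] * y[s_D0s];
  ydot[s_D0cap] = -p[i_ka_cap] * y[s_D0cap];
  ydot[s_D0c] = (p[i_ka_sol] * y[s_D0s] + p[i_ka_cap] * y[s_D0cap]) / Vc
    - b0 + u0 + kE * y[s_ED0]
    - p[i_q_D0] * (y[s_D0c] - y[s_D0p]) - p[i_ke_D0] * y[s_D0c] - v8;
  ydot[s_D0p] = p[i_q_D0] * (Vc / Vp) * (y[s_D0c] - y[s_D0p]);
  ydot[s_DHc] = c0 + v8 - bH + uH + kE * y[s_EDH]
    - p[i_q_DH] * (y[s_DHc] - y[s_DHp]) - p[i_ke_DH] * y[s_DHc];
  ydot[s_DHp] = p[i_q_DH] * (Vc / Vp) * (y[s_DHc] - y[s_DHp]);
  ydot[s_DCc] = cH - vpH - p[i_q_DC] * (y[s_DCc] - y[s_DCp])
    - p[i_ke_DC] * y[s_DCc];
  ydot[s_DCp] = p[i_q_DC] * (Vc / Vp) * (y[s_DCc] - y[s_DCp]);
  ydot[s_DDc] = vpH - v19 - bD + uD + kE * y[s_EDD]
    - p[i_q_DD] * (y[s_DDc] - y[s_DDp]) - p[i_ke_DD] * y[s_DDc];
  ydot[s_DDp] = p[i_q_DD] * (Vc / Vp) * (y[s_DDc] - y[s_DDp]);
  ydot[s_M] = (cD + v19) * Vc;
  ydot[s_U] = (p[i_ke_D0] * y[s_D0c] + p[i_ke_DH] * y[s_DHc]
               + p[i_ke_DC] * y[s_DCc] + p[i_ke_DD] * y[s_DDc]) * Vc;
  ydot[s_Koral] = -p[i_ka_K] * y[s_Koral];
  ydot[s_Kc] = p[i_ka_K] * y[s_Koral] / p[i_V_K] - (bK - uK - kE * y[s_EK]) * rvK;
  ydot[s_Ef] = (-b0 + u0 + c0) + (-bH + uH + cH) + (-bD + uD + cD)
    + (-bK + uK + cK) - p[i_kBon] * y[s_Ef] + p[i_kBoff] * y[s_EB]
    + p[i_kt] * y[s_EmRNA] + kE * (p[i_E0] - y[s_Ef]);
  ydot[s_EB] = p[i_kBon] * y[s_Ef] - p[i_kBoff] * y[s_EB] - kE * y[s_EB];
  ydot[s_ED0] = b0 - u0 - c0 - kE * y[s_ED0];
  ydot[s_EDH] = bH - uH - cH - kE * y[s_EDH];
  ydot[s_EDD] = bD - uD - cD - kE * y[s_EDD];
  ydot[s_EK] = bK - uK - cK - kE * y[s_EK];
  ydot[s_EmRNA] = rel - p[i_kdeg] * y[s_EmRNA];
}

static const R_CMethodDef CEntries[] = {
  {"mcpk_initmod", (DL_FUNC) &mcpk_initmod, 1},
  {"mcpk_rhs", (DL_FUNC) &mcpk_rhs, 6},
  {NULL, NULL, 0}
};

void R_init_mcpk(DllInfo *dll)
{
  R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
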