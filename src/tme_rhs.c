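/* Compiled right-hand side of the 18-state tumour microenvironment model.
 *
 * Parameter vector layout (91 entries) must match
 * tme_parameter_names(extended = TRUE) on the R side exactly.
 * State layout matches tme_state_names().
 */

#include <R.h>
#include <math.h>

static double p[91];

/* parameter indices, registry order */
enum {
  i_lambda_VEN = 0, i_delta_ENIL12, i_delta_EN, i_delta_ENOx, i_EN0,
  i_lambda_VA, i_lambda_VM, i_lambda_VCOx, i_lambda_VOx, i_delta_V,
  i_lambda_OxEN, i_delta_1, i_delta_2, i_delta_3, i_delta_4, i_delta_5,
  i_delta_6, i_delta_Ox,
  i_A_TN, i_delta_TN, i_delta_TNOx,
  i_lambda_ThH, i_lambda_ThD, i_lambda_ThIL12, i_delta_ThTr, i_delta_ThIL10,
  i_delta_Th, i_delta_ThOx,
  i_lambda_TcD, i_lambda_TcIL12, i_delta_TcTr, i_delta_TcIL10, i_delta_Tc,
  i_delta_TcOx,
  i_lambda_TrD, i_lambda_TrOx, i_delta_Tr, i_delta_TrOx,
  i_A_DN, i_lambda_DC, i_lambda_DH, i_lambda_DOx, i_delta_DN, i_delta_DNOx,
  i_delta_DC, i_delta_D,
  i_A_MN, i_lambda_MIL10, i_lambda_MIL12, i_lambda_MTh, i_delta_MN,
  i_delta_M,
  i_lambda_C, i_lambda_CIL6, i_lambda_CA, i_C0, i_delta_CTc, i_delta_CTcOx,
  i_delta_COx, i_delta_C,
  i_alpha_NC, i_delta_N,
  i_lambda_A, i_A0, i_delta_A,
  i_lambda_HD, i_lambda_HN, i_lambda_HM, i_lambda_HTc, i_lambda_HC,
  i_delta_H,
  i_lambda_IL12M, i_lambda_IL12D, i_delta_IL12,
  i_lambda_IL10M, i_lambda_IL10D, i_lambda_IL10Tr, i_lambda_IL10Th,
  i_lambda_IL10Tc, i_lambda_IL10C, i_lambda_IL10Ox, i_delta_IL10,
  i_lambda_IL6A, i_lambda_IL6M, i_lambda_IL6MOx, i_lambda_IL6D,
  i_lambda_IL6Ox, i_delta_IL6,
  i_ox_crit1, i_ox_crit2, i_m_hill
};

/* state indices, canonical order */
enum {
  s_EN = 0, s_V, s_Ox, s_TN, s_Th, s_Tc, s_Tr, s_DN, s_D, s_MN, s_M, s_C,
  s_N, s_A, s_H, s_IL12, s_IL10, s_IL6
};

void tme_initmod(void (*odeparms)(int *, double *))
{
  int n = 91;
  odeparms(&n, p);
}

static double hill(double x, double oxc, double m)
{
  double cm = pow(oxc, m);
  return cm / (cm + pow(x, m));
}

void tme_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
  double EN = y[s_EN], V = y[s_V], Ox = y[s_Ox], TN = y[s_TN], Th = y[s_Th],
    Tc = y[s_Tc], Tr = y[s_Tr], DN = y[s_DN], D = y[s_D], MN = y[s_MN],
    M = y[s_M], C = y[s_C], N = y[s_N], A = y[s_A], H = y[s_H],
    IL12 = y[s_IL12], IL10 = y[s_IL10], IL6 = y[s_IL6];

  /* hill() is even in x around 0 in effect; tiny negative solver excursions
     of oxygen would otherwise produce NaN through pow() */
  double Oxc = Ox > 0.0 ? Ox : 0.0;
  double f1 = hill(Oxc, p[i_ox_crit1], p[i_m_hill]);
  double f2 = hill(Oxc, p[i_ox_crit2], p[i_m_hill]);

  double act_Th = p[i_lambda_ThH] * H + p[i_lambda_ThD] * D +
    p[i_lambda_ThIL12] * IL12;
  double act_Tc = p[i_lambda_TcD] * D + p[i_lambda_TcIL12] * IL12;
  double act_Tr = p[i_lambda_TrD] * D + p[i_lambda_TrOx] * f1;
  double act_D = p[i_lambda_DC] * C + p[i_lambda_DH] * H +
    p[i_lambda_DOx] * f1;
  double act_M = p[i_lambda_MIL10] * IL10 + p[i_lambda_MIL12] * IL12 +
    p[i_lambda_MTh] * Th;
  double kill_C = p[i_delta_CTc] * Tc + p[i_delta_CTcOx] * f1 * Tc +
    p[i_delta_COx] * f2 + p[i_delta_C];

  ydot[s_EN] = p[i_lambda_VEN] * V * (1.0 - EN / p[i_EN0]) * EN -
    p[i_delta_ENIL12] * IL12 * EN -
    (p[i_delta_EN] + p[i_delta_ENOx] * f2) * EN;

  ydot[s_V] = p[i_lambda_VA] * A + p[i_lambda_VM] * M +
    p[i_lambda_VCOx] * C * f1 + p[i_lambda_VOx] * f1 - p[i_delta_V] * V;

  ydot[s_Ox] = p[i_lambda_OxEN] * EN -
    p[i_delta_1] * (TN + Th + Tc + Tr) * Ox -
    p[i_delta_2] * (DN + D) * Ox -
    p[i_delta_3] * (MN + M) * Ox -
    p[i_delta_4] * C * Ox - p[i_delta_5] * A * Ox -
    p[i_delta_6] * EN * Ox - p[i_delta_Ox] * Ox;

  ydot[s_TN] = p[i_A_TN] - (act_Th + act_Tc + act_Tr) * TN -
    (p[i_delta_TN] + p[i_delta_TNOx] * f2) * TN;

  ydot[s_Th] = act_Th * TN -
    (p[i_delta_ThTr] * Tr + p[i_delta_ThIL10] * IL10) * Th -
    (p[i_delta_Th] + p[i_delta_ThOx] * f2) * Th;

  ydot[s_Tc] = act_Tc * TN -
    (p[i_delta_TcTr] * Tr + p[i_delta_TcIL10] * IL10) * Tc -
    (p[i_delta_Tc] + p[i_delta_TcOx] * f2) * Tc;

  ydot[s_Tr] = act_Tr * TN - (p[i_delta_Tr] + p[i_delta_TrOx] * f2) * Tr;

  ydot[s_DN] = p[i_A_DN] - act_D * DN -
    (p[i_delta_DN] + p[i_delta_DNOx] * f2) * DN;

  ydot[s_D] = act_D * DN -
    (p[i_delta_DC] * C + p[i_delta_D] + p[i_delta_DNOx] * f2) * D;

  ydot[s_MN] = p[i_A_MN] - (act_M + p[i_delta_MN]) * MN;

  ydot[s_M] = act_M * MN - p[i_delta_M] * M;

  ydot[s_C] = (p[i_lambda_C] + p[i_lambda_CIL6] * IL6 +
               p[i_lambda_CA] * A) * (1.0 - C / p[i_C0]) * C - kill_C * C;

  ydot[s_N] = p[i_alpha_NC] * kill_C * C - p[i_delta_N] * N;

  ydot[s_A] = p[i_lambda_A] * (1.0 - A / p[i_A0]) * A - p[i_delta_A] * A;

  ydot[s_H] = p[i_lambda_HD] * D + p[i_lambda_HN] * N + p[i_lambda_HM] * M +
    p[i_lambda_HTc] * Tc + p[i_lambda_HC] * C - p[i_delta_H] * H;

  ydot[s_IL12] = p[i_lambda_IL12M] * M + p[i_lambda_IL12D] * D -
    p[i_delta_IL12] * IL12;

  ydot[s_IL10] = p[i_lambda_IL10M] * M + p[i_lambda_IL10D] * D +
    p[i_lambda_IL10Tr] * Tr + p[i_lambda_IL10Th] * Th +
    p[i_lambda_IL10Tc] * Tc + p[i_lambda_IL10C] * C +
    p[i_lambda_IL10Ox] * f1 - p[i_delta_IL10] * IL10;

  ydot[s_IL6] = p[i_lambda_IL6A] * A + p[i_lambda_IL6M] * M +
    p[i_lambda_IL6MOx] * M * f1 + p[i_lambda_IL6D] * D +
    p[i_lambda_IL6Ox] * f1 - p[i_delta_IL6] * IL6;
}
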