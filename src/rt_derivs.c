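/* Compiled right-hand side of the dimensionless tumour growth /
 * radiotherapy model, in the deSolve compiled-model convention.
 *
 * State: y[0] = T (undamaged viable), y[1] = TS (sub-lethally damaged),
 *        y[2] = TR (lethally damaged), y[3] = c (oxygen).
 * The dose rate R is piecewise constant and is passed as a parameter;
 * the integrator is restarted at every irradiation window boundary.
 *
 * Parameter layout must match pack_parms() in R/rhs.R.
 */
#include <R.h>

static double parms[17];
#define Q1     parms[0]
#define Q3     parms[1]
#define V0     parms[2]
#define CMIN   parms[3]
#define G      parms[4]
#define Q2     parms[5]
#define DELTA1 parms[6]
#define DELTA1S parms[7]
#define THETA1 parms[8]
#define THETA2 parms[9]
#define NU     parms[10]
#define LAM    parms[11]
#define LAMS   parms[12]
#define MU     parms[13]
#define XI     parms[14]
#define ETAR   parms[15]
#define RDOSE  parms[16]

void rt_initmod(void (*odeparms)(int *, double *))
{
    int n = 17;
    odeparms(&n, parms);
}

void rt_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double T = y[0], TS = y[1], TR = y[2], c = y[3];
    double Sigma = T + TS + TR + V0;
    double free_space = 1.0 - Sigma;
    /* (c_min - c) H(c_min - c): continuous starvation switch, H(0) = 1 */
    double starv = (CMIN - c >= 0.0) ? (CMIN - c) : 0.0;
    double cR = c * RDOSE;

    ydot[0] = Q2 * c * T * free_space
            - (DELTA1 * starv + LAM * cR + NU * cR) * T
            + MU * TS;
    ydot[1] = THETA2 * Q2 * c * TS * free_space
            - (DELTA1S * starv + LAMS * cR + MU + XI) * TS
            + NU * cR * T;
    ydot[2] = LAM * cR * T + (XI + LAMS * cR) * TS - ETAR * TR;
    ydot[3] = G * (1.0 - c) * V0
            - Q1 * (T + THETA1 * TS) * c
            - Q3 * (T + THETA2 * TS) * c * free_space;
}
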