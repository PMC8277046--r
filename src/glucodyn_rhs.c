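/* Right-hand side of the glucose-limited growth ODE system, in the form
 * expected by deSolve's compiled-model interface.
 *
 * States:     y[0] = N (live confluence, %), y[1] = D (dead confluence, %),
 *             y[2] = G (glucose, mM)
 * Parameters: kp, kd, kbys (day^-1); v (mM cell^-1 day^-1); theta (%);
 *             gstar, gmin (mM); cpct (cells per confluence-%).
 *
 * Model-variant masking (kbys = 0 or kd = 0) is applied by the caller
 * before the parameters reach this function.
 */
#include <math.h>
#include <R.h>

static double parms[8];
#define KP    parms[0]
#define KD    parms[1]
#define KBYS  parms[2]
#define V     parms[3]
#define THETA parms[4]
#define GSTAR parms[5]
#define GMIN  parms[6]
#define CPCT  parms[7]

void glucodyn_initmod(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

void glucodyn_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    /* negative excursions below solver tolerance are treated as 0 */
    double N = y[0] > 0.0 ? y[0] : 0.0;
    double D = y[1] > 0.0 ? y[1] : 0.0;
    double G = y[2] > 0.0 ? y[2] : 0.0;

    double sd = (1.0 - G / (G + GMIN)) * tanh(*t);
    double sp = 1.0 - sd;
    /* dead-cell fraction; defined as 0 when the well is empty */
    double fd = (N + D) > 0.0 ? D / (N + D) : 0.0;

    double grow = KP * N * (1.0 - N / THETA) * sp;
    double starv = KD * N * sd;
    double byst = KBYS * N * fd;

    ydot[0] = grow - starv - byst;
    ydot[1] = starv + byst;
    ydot[2] = -V * CPCT * N * G / (G + GSTAR);
}
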