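/* Compiled right-hand sides for the phage competition ODE models,
 * in deSolve's compiled-model interface (initfunc + derivs).
 *
 * Fixed-propensity model, state y = (B0, B1, B2, L1, L2, P1, P2):
 *   dB0/dt = g*B0 - eta*Ptot*B0
 *   dBi/dt = g*Bi + eta*Pi*B0 - delta*Bi
 *   dLi/dt = g*Li + fi*delta*Bi
 *   dPi/dt = beta*(1-fi)*delta*Bi - eta*Pi*Btot
 * with g = gamma*(1 - Btot/K), Btot = B0+B1+B2+L1+L2, Ptot = P1+P2.
 *
 * MOI model, state y = (B0, B11, B12, B13, B21, B22, B23, L1, L2, P1, P2):
 * infected compartments Bim carry no logistic growth term; MOI truncated at 3
 * (B_{i,3} has no adsorption outflow, but free phage adsorbing anywhere are
 * still removed through -eta*Pi*Btot).
 */
#include <R.h>

static double pf[7]; /* gamma, K, eta, beta, delta, f1, f2 */

void phg_init_fixed(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, pf);
}

void phg_derivs_fixed(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double gam = pf[0], K = pf[1], eta = pf[2], beta = pf[3], delta = pf[4];
    double f1 = pf[5], f2 = pf[6];
    double B0 = y[0], B1 = y[1], B2 = y[2], L1 = y[3], L2 = y[4];
    double P1 = y[5], P2 = y[6];
    double Btot = B0 + B1 + B2 + L1 + L2;
    double Ptot = P1 + P2;
    double g = gam * (1.0 - Btot / K);

    ydot[0] = g * B0 - eta * Ptot * B0;
    ydot[1] = g * B1 + eta * P1 * B0 - delta * B1;
    ydot[2] = g * B2 + eta * P2 * B0 - delta * B2;
    ydot[3] = g * L1 + f1 * delta * B1;
    ydot[4] = g * L2 + f2 * delta * B2;
    ydot[5] = beta * (1.0 - f1) * delta * B1 - eta * P1 * Btot;
    ydot[6] = beta * (1.0 - f2) * delta * B2 - eta * P2 * Btot;
}

static double pm[11]; /* gamma, K, eta, beta, delta, f1(1..3), f2(1..3) */

void phg_init_moi(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, pm);
}

void phg_derivs_moi(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double gam = pm[0], K = pm[1], eta = pm[2], beta = pm[3], delta = pm[4];
    double f11 = pm[5], f12 = pm[6], f13 = pm[7];
    double f21 = pm[8], f22 = pm[9], f23 = pm[10];
    double B0 = y[0];
    double B11 = y[1], B12 = y[2], B13 = y[3];
    double B21 = y[4], B22 = y[5], B23 = y[6];
    double L1 = y[7], L2 = y[8], P1 = y[9], P2 = y[10];
    double Btot = B0 + B11 + B12 + B13 + B21 + B22 + B23 + L1 + L2;
    double Ptot = P1 + P2;
    double g = gam * (1.0 - Btot / K);

    ydot[0] = g * B0 - eta * Ptot * B0;
    ydot[1] = eta * P1 * B0 - eta * P1 * B11 - delta * B11;
    ydot[2] = eta * P1 * B11 - eta * P1 * B12 - delta * B12;
    ydot[3] = eta * P1 * B12 - delta * B13;
    ydot[4] = eta * P2 * B0 - eta * P2 * B21 - delta * B21;
    ydot[5] = eta * P2 * B21 - eta * P2 * B22 - delta * B22;
    ydot[6] = eta * P2 * B22 - delta * B23;
    ydot[7] = g * L1 + delta * (f11 * B11 + f12 * B12 + f13 * B13);
    ydot[8] = g * L2 + delta * (f21 * B21 + f22 * B22 + f23 * B23);
    ydot[9] = beta * delta * ((1.0 - f11) * B11 + (1.0 - f12) * B12 +
                              (1.0 - f13) * B13) - eta * P1 * Btot;
    ydot[10] = beta * delta * ((1.0 - f21) * B21 + (1.0 - f22) * B22 +
                               (1.0 - f23) * B23) - eta * P2 * Btot;
}
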