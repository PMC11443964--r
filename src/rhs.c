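/* Generic single-compartment conductance-based model right-hand side for
 * deSolve. The model (channel gating curves, exponents, reversals, calcium
 * dynamics, applied-current protocol) is passed from R as one flat double
 * vector via cg_set_parms() before each integration; the encoding is built
 * in R from the model-definition YAML so that R and C share one kinetics
 * source. Units: mV, ms, mS/cm2, uA/cm2, uF/cm2, uM.
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>

#define CG_MAXP 4096
#define CG_HEAD 15
#define CG_BLK  40

static double cg_parms[CG_MAXP];

SEXP cg_set_parms(SEXP p)
{
    int n = LENGTH(p);
    if (n > CG_MAXP) error("condegen: parameter vector too long");
    memcpy(cg_parms, REAL(p), n * sizeof(double));
    return R_NilValue;
}

/* parametric gating curves; ids must match .curve_forms in R/curves.R */
static double eval_curve(const double *c, double V)
{
    const double *p = c + 1;
    switch ((int) c[0]) {
    case 0: return p[0];
    case 1: return 1.0 / (1.0 + exp((V + p[0]) / p[1]));
    case 2: return p[0] + p[1] / (1.0 + exp((V + p[2]) / p[3]));
    case 3: return p[0] + p[1] / (exp((V + p[2]) / p[3]) +
                                  exp((V + p[4]) / p[5]));
    case 4: return (p[0] / (1.0 + exp((V + p[1]) / p[2]))) *
                   (p[3] + p[4] / (1.0 + exp((V + p[5]) / p[6])));
    }
    return NA_REAL;
}

/* deSolve compiled-model derivative routine.
 * Header layout (cg_parms):
 *  0 C, 1 gleak, 2 E_leak, 3 n_channels, 4 has_calcium, 5 tau_ca, 6 f_ca,
 *  7 ca_rest, 8 eca_mode(0 fixed/1 nernst), 9 nernst coef, 10 ca_out,
 *  11 I_const, 12 I_step, 13 t_on, 14 t_off.
 * Then per channel a CG_BLK block:
 *  0 gbar, 1 a, 2 b, 3 E_is_calcium, 4 E, 5 calcium_source, 6 ca_half,
 *  7 instantaneous, 8..15 m_inf curve, 16..23 tau_m, 24..31 h_inf,
 *  32..39 tau_h  (each curve: form id + up to 7 parameters).
 * States: y[0] = V, then m (if gated, non-instantaneous) and h per channel
 * in order, finally Ca if the model has calcium dynamics.
 */
void cg_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double *P = cg_parms;
    double C = P[0], gleak = P[1], Eleak = P[2];
    int nch = (int) P[3];
    int hasca = (int) P[4];
    double V = y[0];
    double Ca = hasca ? y[*neq - 1] : 0.0;
    double Eca_nernst = 0.0;

    if (hasca && (int) P[8] == 1) {
        double cai = Ca > 1e-9 ? Ca : 1e-9;
        Eca_nernst = P[9] * log(P[10] / cai);
    }

    double I = P[11];
    if (*t >= P[13] && *t < P[14]) I += P[12];

    double Itot = -gleak * (V - Eleak) + I;
    double ica = 0.0;
    int k = 1;

    for (int j = 0; j < nch; j++) {
        const double *B = P + CG_HEAD + j * CG_BLK;
        double gbar = B[0];
        int a = (int) B[1], b = (int) B[2];
        double E = ((int) B[3]) ? Eca_nernst : B[4];
        double m = 1.0, h = 1.0;

        if (a > 0) {
            double minf = eval_curve(B + 8, V);
            if (B[6] > 0.0) minf *= Ca / (Ca + B[6]);
            if ((int) B[7]) {       /* instantaneous gate */
                m = minf;
            } else {
                m = y[k];
                ydot[k] = (minf - m) / eval_curve(B + 16, V);
                k++;
            }
        }
        if (b > 0) {
            double hinf = eval_curve(B + 24, V);
            h = y[k];
            ydot[k] = (hinf - h) / eval_curve(B + 32, V);
            k++;
        }
        double gi = gbar;
        for (int q = 0; q < a; q++) gi *= m;
        for (int q = 0; q < b; q++) gi *= h;
        double Ii = gi * (V - E);
        Itot -= Ii;
        if ((int) B[5]) ica += Ii;
    }
    ydot[0] = Itot / C;
    if (hasca) ydot[k] = (-P[6] * ica - Ca + P[7]) / P[5];
}
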