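/* Right-hand side of the linearly coupled two-compartment oral PK model,
 * in the form expected by deSolve's compiled-function interface.
 *
 * State (8): x_gut, x_cen, x_per, x_elim, y_gut, y_cen, y_per, y_elim
 * Parameters (16): for drug X k_abs, k_cp, k_pc, k_el and interaction
 * coefficients g_abs, g_cp, g_pc, g_el; then the same eight for drug Y.
 * Each effective rate is baseline + g * (partner amount in the driving
 * compartment): g_abs is driven by the partner's gut amount, g_cp and
 * g_el by the partner's central amount, g_pc by the partner's
 * peripheral amount.  The *_elim components accumulate the elimination
 * flux so that gut + central + peripheral + eliminated is conserved.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[16];

void cpk_init(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, parms);
}

void cpk_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    /* drug X effective rates, modified by drug Y amounts */
    double ax_abs = parms[0] + parms[4] * y[4];
    double ax_cp  = parms[1] + parms[5] * y[5];
    double ax_pc  = parms[2] + parms[6] * y[6];
    double ax_el  = parms[3] + parms[7] * y[5];
    /* drug Y effective rates, modified by drug X amounts */
    double ay_abs = parms[8]  + parms[12] * y[0];
    double ay_cp  = parms[9]  + parms[13] * y[1];
    double ay_pc  = parms[10] + parms[14] * y[2];
    double ay_el  = parms[11] + parms[15] * y[1];

    ydot[0] = -ax_abs * y[0];
    ydot[1] =  ax_abs * y[0] - ax_cp * y[1] + ax_pc * y[2] - ax_el * y[1];
    ydot[2] =  ax_cp * y[1] - ax_pc * y[2];
    ydot[3] =  ax_el * y[1];

    ydot[4] = -ay_abs * y[4];
    ydot[5] =  ay_abs * y[4] - ay_cp * y[5] + ay_pc * y[6] - ay_el * y[5];
    ydot[6] =  ay_cp * y[5] - ay_pc * y[6];
    ydot[7] =  ay_el * y[5];
}
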