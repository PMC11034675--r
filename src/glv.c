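/* Compiled right-hand side for the generalized Lotka-Volterra model,
 * dN_i/dt = N_i (r_i - sum_j beta_ij N_j), in the deSolve compiled-model
 * calling convention.  Several replicate cultures sharing one parameter
 * set can be integrated as a single block-diagonal system (nrep blocks of
 * n species each), which is what the fitting routines rely on.
 *
 * Parameter vector layout (padded to GLV_PARMS_LEN doubles):
 *   parms[0] = n (species per block)
 *   parms[1] = nrep (number of replicate blocks)
 *   parms[2 .. 2+n-1]       = r
 *   parms[2+n .. 2+n+n*n-1] = beta, row-major (beta[i*n + j] = effect of j on i)
 */
#include <R.h>

#define GLV_PARMS_LEN 1200

static double parms[GLV_PARMS_LEN];

void glv_initmod(void (*odeparms)(int *, double *))
{
    int N = GLV_PARMS_LEN;
    odeparms(&N, parms);
}

void glv_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int n = (int) parms[0];
    int nrep = (int) parms[1];
    double *r = parms + 2;
    double *beta = parms + 2 + n;
    int k, i, j;

    for (k = 0; k < nrep; k++) {
        double *yk = y + k * n;
        double *dk = ydot + k * n;
        for (i = 0; i < n; i++) {
            double Ni = yk[i] > 0.0 ? yk[i] : 0.0;
            double s = r[i];
            for (j = 0; j < n; j++) {
                double Nj = yk[j] > 0.0 ? yk[j] : 0.0;
                s -= beta[i * n + j] * Nj;
            }
            dk[i] = s * Ni;
        }
    }
}
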