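/* Compiled right-hand side of the coupled selection--learning ODE system,
 * in the standard deSolve compiled-model form.
 *
 * State vector: y = (rho_1..rho_n, phi_11..phi_nn)  with phi column-major,
 * phi[i,j] = y[n + i + n*j] = directed weight from input j onto focal i.
 *
 * Parameter vector (padded to PAR_LEN on the R side):
 *   [0]  n                 number of neuronal loci
 *   [1]  lambda            learning rate
 *   [2]  landscape type    0 = directional, 1 = stabilizing
 *   [3]  beta              stabilizing sharpness
 *   [4]  target            stabilizing target count T
 *   [5]  fixed M           >= 0 freezes the switching probability, < 0 dynamic
 *   [6]  allow negative weights (0/1)
 *   [7]  freeze rho (0/1)
 *   [8]  freeze phi (0/1)
 *   [9]  steady-state tolerance for the root function
 *   [10..15]               reserved
 *   [16 .. 16+n-1]         per-locus selection gradient S_i (directional)
 *   [16+n .. 16+n+n*n-1]   adjacency mask, column-major
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define PAR_LEN 3000
#define MAX_N   50

static double pv[PAR_LEN];

void evo_init(void (*odeparms)(int *, double *))
{
    int N = PAR_LEN;
    odeparms(&N, pv);
}

static void evo_rates(double *y, double *ydot)
{
    int    n       = (int) pv[0];
    double lambda  = pv[1];
    int    lstype  = (int) pv[2];
    double beta    = pv[3];
    double target  = pv[4];
    double fixedM  = pv[5];
    int    allow_n = (int) pv[6];
    int    f_rho   = (int) pv[7];
    int    f_phi   = (int) pv[8];
    const double *S    = pv + 16;
    const double *mask = pv + 16 + n;

    double rho[MAX_N], xb[MAX_N], Y[MAX_N], M[MAX_N], sig[MAX_N];
    double sumrho = 0.0;
    int i, j;

    for (i = 0; i < n; i++) {
        double r = y[i];
        if (r < 0.0) r = 0.0;
        if (r > 1.0) r = 1.0;
        rho[i] = r;
        xb[i]  = 2.0 * r - 1.0;
        sumrho += r;
    }
    for (i = 0; i < n; i++) {
        double acc = 0.0;
        for (j = 0; j < n; j++) {
            if (mask[i + n * j] != 0.0)
                acc += y[n + i + n * j] * xb[j];
        }
        Y[i] = acc;
        M[i] = (fixedM >= 0.0) ? fixedM : 0.5 * exp(-acc * acc);
        sig[i] = (lstype == 0)
            ? S[i]
            : 2.0 * beta * (target - (sumrho - rho[i]) - 0.5);
    }
    for (i = 0; i < n; i++)
        ydot[i] = f_rho ? 0.0
            : rho[i] * (1.0 - rho[i]) * sig[i] + M[i] * (1.0 - 2.0 * rho[i]);

    for (j = 0; j < n; j++) {
        for (i = 0; i < n; i++) {
            int k = n + i + n * j;
            if (f_phi || mask[i + n * j] == 0.0) {
                ydot[k] = 0.0;
            } else {
                double ph = y[k];
                double d  = lambda * (Y[i] * xb[j] - Y[i] * Y[i] * ph);
                if (!allow_n && ph <= 0.0 && d < 0.0) d = 0.0;
                ydot[k] = d;
            }
        }
    }
}

void evo_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    evo_rates(y, ydot);
}

/* root at max |dy/dt| == steady_tol: lets lsodar stop at the equilibrium */
void evo_root(int *neq, double *t, double *y, int *ng, double *gout)
{
    double ydot[MAX_N + MAX_N * MAX_N];
    double mx = 0.0;
    int i;
    evo_rates(y, ydot);
    for (i = 0; i < *neq; i++) {
        double a = fabs(ydot[i]);
        if (a > mx) mx = a;
    }
    gout[0] = mx - pv[9];
}

static const R_CMethodDef cMethods[] = {
    {NULL, NULL, 0}
};

void R_init_evoneuro(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
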