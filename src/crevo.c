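/* Compiled right-hand sides for the consumer-resource model.
 *
 * State vector y = (n_1..n_S, c_1..c_p): strain densities then resource
 * concentrations.  Parameters are passed once per integration through
 * crevo_set_parms() and read from static storage, laid out as
 *
 *   [0] p   (number of resources)
 *   [1] S   (number of strains)
 *   [2] delta (per-capita death rate)
 *   [3] c_fin (depletion threshold for the root function; < 0 when unused)
 *   [4 .. 4+p-1]          s   (supply rates)
 *   [4+p .. 4+2p-1]       K   (Monod half-saturation constants)
 *   [4+2p .. 4+3p-1]      mu  (resource decay rates)
 *   [4+3p .. 4+3p+S*p-1]  A   (S x p effective allocation matrix alpha^q,
 *                              column-major)
 *
 * dc_j/dt = s_j - (sum_i n_i A_ij) r_j(c_j) - mu_j c_j
 * dn_i/dt = (sum_j A_ij r_j(c_j) - delta) n_i,   r_j(c) = c/(K_j + c).
 *
 * Negative components (transient integrator undershoot) contribute zero
 * uptake/consumption; hard clipping happens at checkpoints on the R side.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <string.h>

#define CREVO_MAX_P 256

static double *cr_parms = NULL;
static R_xlen_t cr_np = 0;

SEXP crevo_set_parms(SEXP parms)
{
    R_xlen_t n = XLENGTH(parms);
    if (n < 4)
        error("parameter vector too short");
    if (cr_parms != NULL) {
        R_Free(cr_parms);
        cr_parms = NULL;
    }
    cr_parms = R_Calloc(n, double);
    memcpy(cr_parms, REAL(parms), n * sizeof(double));
    cr_np = n;
    if ((int) cr_parms[0] > CREVO_MAX_P)
        error("at most %d resources are supported", CREVO_MAX_P);
    return R_NilValue;
}

void crevo_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int p = (int) cr_parms[0];
    int S = (int) cr_parms[1];
    double delta = cr_parms[2];
    const double *s = cr_parms + 4;
    const double *K = s + p;
    const double *mu = K + p;
    const double *A = mu + p; /* S x p, column-major */
    double r[CREVO_MAX_P];
    int i, j;

    for (j = 0; j < p; j++) {
        double c = y[S + j] > 0 ? y[S + j] : 0;
        r[j] = c / (K[j] + c);
    }
    for (j = 0; j < p; j++) {
        const double *Aj = A + (size_t) j * S;
        double load = 0;
        for (i = 0; i < S; i++) {
            double n = y[i] > 0 ? y[i] : 0;
            load += n * Aj[i];
        }
        double c = y[S + j] > 0 ? y[S + j] : 0;
        ydot[S + j] = s[j] - load * r[j] - mu[j] * c;
    }
    for (i = 0; i < S; i++) {
        double g = -delta;
        for (j = 0; j < p; j++)
            g += A[(size_t) j * S + i] * r[j];
        double n = y[i] > 0 ? y[i] : 0;
        ydot[i] = g * n;
    }
}

/* Root function: total resource concentration hits c_fin (batch depletion). */
void crevo_root(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip)
{
    int p = (int) cr_parms[0];
    int S = (int) cr_parms[1];
    double tot = 0;
    int j;
    for (j = 0; j < p; j++)
        tot += y[S + j];
    gout[0] = tot - cr_parms[3];
}

static const R_CallMethodDef CallEntries[] = {
    {"crevo_set_parms", (DL_FUNC) &crevo_set_parms, 1},
    {NULL, NULL, 0}
};

void R_init_crevo(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    /* deSolve looks crevo_derivs / crevo_root up by name */
    R_useDynamicSymbols(dll, TRUE);
}
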