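/* Compiled right-hand side of the spatial GLV system for deSolve.
 *
 * The model (patch count P, species count N, demographic vectors,
 * graph Laplacian, per-patch interaction matrices, stopping thresholds)
 * is staged once per integration via C_glv_set_model(); the derivative
 * and root callbacks then run without any R-level overhead, which is
 * what makes banded finite-difference Jacobians affordable in the
 * stiff high-dispersal regime.
 *
 * Parameter block layout (doubles, column-major matrices):
 *   [0] P  [1] N  [2] h2  [3] phi_max  [4] residual_tol  [5] neg_floor
 *   [6 .. ]              r (N), K (N), D (N)
 *   then                 L (P*P), per-patch A blocks (P * N*N),
 *                        A[i + N*j] = effect of species j on species i
 * State vector: y[i + N*p], species fastest within patch.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

static SEXP model_ref = NULL;
static double *mp = NULL;      /* parameter block */
static double *scratch = NULL; /* ydot buffer for the residual root */
static R_len_t scratch_len = 0;

SEXP C_glv_set_model(SEXP ctx)
{
    if (TYPEOF(ctx) != REALSXP)
        error("model parameter block must be a numeric vector");
    if (model_ref != NULL)
        R_ReleaseObject(model_ref);
    R_PreserveObject(ctx);
    model_ref = ctx;
    mp = REAL(ctx);
    int P = (int) mp[0], N = (int) mp[1];
    R_len_t need = (R_len_t) P * N;
    if (need > scratch_len) {
        if (scratch != NULL) R_Free(scratch);
        scratch = R_Calloc(need, double);
        scratch_len = need;
    }
    return R_NilValue;
}

void C_glv_deriv(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int P = (int) mp[0], N = (int) mp[1];
    double h2 = mp[2];
    const double *r = mp + 6;
    const double *K = r + N;
    const double *D = K + N;
    const double *L = D + N;
    const double *A = L + (size_t) P * P;

    for (int p = 0; p < P; p++) {
        const double *Ap = A + (size_t) p * N * N;
        const double *phi = y + (size_t) p * N;
        double *d = ydot + (size_t) p * N;
        for (int i = 0; i < N; i++) {
            double s = 0.0;
            const double *row = Ap + i;
            for (int j = 0; j < N; j++)
                s += row[(size_t) N * j] * phi[j];
            d[i] = phi[i] * (r[i] * (1.0 - phi[i] / K[i]) + s);
        }
    }
    /* diffusive dispersal: ydot += (D_i / h2) * sum_q L[p,q] y[i,q] */
    for (int p = 0; p < P; p++) {
        double *d = ydot + (size_t) p * N;
        for (int q = 0; q < P; q++) {
            double l = L[p + (size_t) P * q];
            if (l != 0.0) {
                const double *phiq = y + (size_t) q * N;
                for (int i = 0; i < N; i++)
                    d[i] += D[i] / h2 * l * phiq[i];
            }
        }
    }
}

/* root 1: divergence guard (any |phi| reaching phi_max)
 * root 2: stationarity (max |dphi/dt| falling to residual_tol)
 * root 3: a density undershooting the negative floor; the caller clamps
 *         it to exactly zero (an invariant state of the dynamics) and
 *         resumes, preventing runaway negative excursions without
 *         putting a kink into the vector field itself */
void C_glv_root(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip)
{
    double ymax = 0.0, ymin = 0.0, res = 0.0;
    for (int k = 0; k < *neq; k++) {
        double a = fabs(y[k]);
        if (a > ymax) ymax = a;
        if (y[k] < ymin) ymin = y[k];
    }
    C_glv_deriv(neq, t, y, scratch, out, ip);
    for (int k = 0; k < *neq; k++) {
        double a = fabs(scratch[k]);
        if (a > res) res = a;
    }
    gout[0] = mp[3] - ymax;
    gout[1] = res - mp[4];
    gout[2] = ymin + mp[5];
}
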