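#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_glv_set_model(SEXP ctx);
void C_glv_deriv(int *, double *, double *, double *, double *, int *);
void C_glv_root(int *, double *, double *, int *, double *, double *, int *);

static const R_CallMethodDef call_entries[] = {
    {"C_glv_set_model", (DL_FUNC) &C_glv_set_model, 1},
    {NULL, NULL, 0}
};

void R_init_glvmeta(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* C_glv_deriv / C_glv_root are looked up by deSolve by name */
    R_useDynamicSymbols(dll, TRUE);
}
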