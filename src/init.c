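#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP cg_set_parms(SEXP p);
void cg_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
    {"cg_set_parms", (DL_FUNC) &cg_set_parms, 1},
    {NULL, NULL, 0}
};

void R_init_condegen(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* keep dynamic lookup enabled: deSolve resolves cg_derivs by name */
    R_useDynamicSymbols(dll, TRUE);
}
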