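#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void glv_initmod(void (*odeparms)(int *, double *));
void glv_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

/* deSolve resolves these by name via getNativeSymbolInfo(); registering
 * them keeps the lookup valid when dynamic symbol search is disabled. */
static const R_CMethodDef CEntries[] = {
    {"glv_initmod", (DL_FUNC) &glv_initmod, 1},
    {"glv_derivs",  (DL_FUNC) &glv_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_glvcomm(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
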