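#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP C_reaction_rhs(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                           SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_reaction_rhs", (DL_FUNC) &C_reaction_rhs, 10},
    {NULL, NULL, 0}
};

void R_init_soursim(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
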